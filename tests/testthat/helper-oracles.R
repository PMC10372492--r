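# Independent oracles used across tests.

# Brute-force distortion-product oracle: loop over ALL coefficient vectors
# with |n_i| <= max_order and 1 <= sum|n_i| <= max_order, then collapse
# {v, -v} sign classes by keying each class on the lexicographically
# smaller of the two string keys. Independent of the package's canonical
# representation.
brute_force_products <- function(freq_hz, max_order) {
  M <- length(freq_hz)
  cc <- as.matrix(expand.grid(rep(list(seq(-max_order, max_order)), M)))
  ord <- rowSums(abs(cc))
  cc <- cc[ord >= 1 & ord <= max_order, , drop = FALSE]
  key <- apply(cc, 1, paste, collapse = ",")
  key_neg <- apply(-cc, 1, paste, collapse = ",")
  class_id <- ifelse(key < key_neg, key, key_neg)
  keep <- !duplicated(class_id)
  list(n_classes = sum(keep),
       freqs = sort(abs(as.vector(cc[keep, , drop = FALSE] %*% freq_hz))))
}

# Closed-form recinormal facts for a promptness model N(mu, sigma):
# median RT = 1/mu (promptness median = mu), miss probability with
# timeout -> Inf is P(p <= 0) = pnorm(-mu/sigma).
recinormal_median_rt <- function(mu_p) 1 / mu_p
recinormal_miss_prob <- function(mu_p, sigma_p) pnorm(-mu_p / sigma_p)

# Naive (censoring-ignoring) Gaussian fit on observed promptness only.
naive_promptness_fit <- function(dataset) {
  p <- 1 / dataset$rt_s[!is.na(dataset$rt_s) & dataset$rt_s > 0]
  c(mu = mean(p), sigma = sqrt(mean((p - mean(p))^2)))
}
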