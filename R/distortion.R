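# Nonlinear intermodulation distortion products. A nonlinearity acting on
# carriers f_1..f_M generates components at |n_1 f_1 + ... + n_M f_M| with
# integer n_i; the order of a product is sum(|n_i|). Since the physical
# frequency takes an absolute value, {v, -v} coefficient vectors alias to
# the same component, so one canonical representative is kept per class
# (first nonzero coefficient positive).

#' Construct a carrier set
#'
#' @param freq_hz positive carrier frequencies (Hz) — acoustic tones or
#'   direct-stimulation pulse rates.
#' @param ear per-carrier laterality: `"left"`, `"right"` or `"mono"`
#'   (recycled).
#' @param labels optional carrier labels.
#' @return a `carrier_set` data frame with columns `freq_hz`, `ear`,
#'   `label`.
#' @export
carrier_set <- function(freq_hz, ear = "mono", labels = NULL) {
  if (length(freq_hz) < 1) stop("need at least one carrier")
  if (any(!is.finite(freq_hz)) || any(freq_hz <= 0))
    stop("carrier frequencies must be positive and finite")
  ear <- rep_len(match.arg(ear, c("left", "right", "mono"),
                           several.ok = TRUE), length(freq_hz))
  if (is.null(labels))
    labels <- paste0(substr(ear, 1, 1), seq_along(freq_hz))
  structure(data.frame(freq_hz = freq_hz, ear = ear, label = labels,
                       stringsAsFactors = FALSE),
            class = c("carrier_set", "data.frame"))
}

# All canonical coefficient vectors with 1 <= sum(|n|) <= max_order for M
# carriers, as a matrix (one row per class).
canonical_coefficients <- function(M, max_order) {
  if (max_order < 1) stop("`max_order` must be >= 1")
  if (M > 6) stop("more than 6 carriers: enumeration would be excessive")
  grids <- rep(list(seq(-max_order, max_order)), M)
  cc <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(cc) <- NULL
  ord <- rowSums(abs(cc))
  cc <- cc[ord >= 1 & ord <= max_order, , drop = FALSE]
  # canonical: first nonzero coefficient positive
  first_nz <- apply(cc, 1, function(v) v[which(v != 0)[1]])
  cc[first_nz > 0, , drop = FALSE]
}

product_laterality <- function(coeffs, ears) {
  involved <- unique(ears[coeffs != 0])
  if (all(c("left", "right") %in% involved)) "binaural"
  else if ("left" %in% involved) "monaural-left"
  else if ("right" %in% involved) "monaural-right"
  else "mono"
}

#' Enumerate nonlinear distortion products of a carrier set
#'
#' Lists one canonical representative per sign class of coefficient
#' vectors with order between 1 and `max_order`, computes each product's
#' frequency `|sum(n_i f_i)|`, classifies laterality (binaural iff the
#' nonzero coefficients touch carriers of both ears), and groups products
#' whose frequencies coincide within `tol_hz` (lowest order first within a
#' group). Zero-frequency (DC) products are retained but flagged
#' non-measurable.
#'
#' @param carriers a [carrier_set()].
#' @param max_order maximum order `sum(|n_i|)` (>= 1).
#' @param band_hz optional length-2 frequency band filter (Hz).
#' @param tol_hz frequency-coincidence tolerance (Hz, default 0.1).
#' @return data frame of class `distortion_products`: `coeffs` (list of
#'   integer vectors), `coeff_label`, `order`, `freq_hz`, `laterality`,
#'   `is_harmonic` (exactly one nonzero coefficient), `measurable`
#'   (`freq_hz > 0`), `freq_group` (coincidence group id).
#' @export
enumerate_products <- function(carriers, max_order, band_hz = NULL,
                               tol_hz = 0.1) {
  stopifnot(inherits(carriers, "carrier_set"), tol_hz >= 0)
  cc <- canonical_coefficients(nrow(carriers), max_order)
  freq <- abs(as.vector(cc %*% carriers$freq_hz))
  ord <- rowSums(abs(cc))
  if (!is.null(band_hz)) {
    stopifnot(length(band_hz) == 2)
    keep <- freq >= band_hz[1] & freq <= band_hz[2]
    cc <- cc[keep, , drop = FALSE]; freq <- freq[keep]; ord <- ord[keep]
  }
  if (nrow(cc) == 0) {
    out <- data.frame(coeff_label = character(0), order = integer(0),
                      freq_hz = numeric(0), laterality = character(0),
                      is_harmonic = logical(0), measurable = logical(0),
                      freq_group = integer(0))
    out$coeffs <- list()
    class(out) <- c("distortion_products", "data.frame")
    return(out)
  }
  # frequency-coincidence groups within tol_hz
  o <- order(freq, ord)
  grp <- integer(length(freq))
  g <- 1L
  grp[o[1]] <- g
  if (length(o) > 1) for (k in 2:length(o)) {
    if (freq[o[k]] - freq[o[k - 1]] > tol_hz) g <- g + 1L
    grp[o[k]] <- g
  }
  lat <- apply(cc, 1, product_laterality, ears = carriers$ear)
  out <- data.frame(
    coeff_label = apply(cc, 1, function(v)
      paste0("(", paste(ifelse(v > 0, paste0("+", v), v), collapse = ","),
             ")")),
    order = as.integer(ord),
    freq_hz = freq,
    laterality = lat,
    is_harmonic = rowSums(cc != 0) == 1,
    measurable = freq > 0,
    freq_group = grp,
    stringsAsFactors = FALSE)
  out$coeffs <- lapply(seq_len(nrow(cc)), function(i) as.integer(cc[i, ]))
  out <- out[order(out$freq_group, out$order, out$coeff_label), ]
  rownames(out) <- NULL
  class(out) <- c("distortion_products", "data.frame")
  out
}

#' Count distortion-product classes and distinct frequencies
#'
#' Reports both the number of canonical coefficient classes and the number
#' of distinct product frequencies at the given tolerance; the two differ
#' whenever carriers are commensurable.
#'
#' @inheritParams enumerate_products
#' @return list with `n_classes` and `n_frequencies`.
#' @export
count_products <- function(carriers, max_order, tol_hz = 0.1) {
  pr <- enumerate_products(carriers, max_order, tol_hz = tol_hz)
  list(n_classes = nrow(pr), n_frequencies = length(unique(pr$freq_group)))
}

#' Predict (e)ASSR target frequencies for bilateral stimulation rates
#'
#' Enumerates distortion products of the combined left/right carrier
#' (pulse-rate) set restricted to the EEG analysis band, sorted by order
#' then frequency. Second-order difference products (coefficients +1/-1 on
#' two carriers) are flagged as the primary steady-state response targets;
#' a 0 Hz difference (identical rates) is flagged degenerate.
#'
#' @param left_rates_hz,right_rates_hz per-ear carrier or pulse-rate lists
#'   (Hz); at least one rate per stimulated side.
#' @param max_order maximum product order (default 2).
#' @param eeg_band_hz analysis band (default `c(0, 120)`, the usable EEG
#'   bandwidth for steady-state analysis).
#' @param tol_hz frequency-coincidence tolerance.
#' @return a `distortion_products` data frame with extra columns
#'   `primary` and `degenerate`.
#' @export
predict_eassr_targets <- function(left_rates_hz, right_rates_hz,
                                  max_order = 2, eeg_band_hz = c(0, 120),
                                  tol_hz = 0.1) {
  if (length(left_rates_hz) < 1 || length(right_rates_hz) < 1)
    stop("need at least one rate per stimulated side")
  cs <- carrier_set(c(left_rates_hz, right_rates_hz),
                    ear = rep(c("left", "right"),
                              c(length(left_rates_hz),
                                length(right_rates_hz))))
  pr <- enumerate_products(cs, max_order, band_hz = eeg_band_hz,
                           tol_hz = tol_hz)
  n_nz <- vapply(pr$coeffs, function(v) sum(v != 0), integer(1))
  c_sum <- vapply(pr$coeffs, sum, integer(1))
  pr$primary <- pr$order == 2 & n_nz == 2 & c_sum == 0
  pr$degenerate <- pr$primary & pr$freq_hz == 0
  pr <- pr[order(pr$order, pr$freq_hz, pr$coeff_label), ]
  rownames(pr) <- NULL
  pr
}

#' Write distortion products to CSV
#'
#' @param products a `distortion_products` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_products_csv <- function(products, path) {
  out <- products
  out$coeffs <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
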