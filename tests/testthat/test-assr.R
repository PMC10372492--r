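test_that("coherent spectrum recovers an on-bin sinusoid exactly", {
  rec <- synthesize_eeg(data.frame(freq_hz = 41, amplitude = 1),
                        list(white_sd = 0, pink_sd = 0),
                        n_epochs = 10, epoch_length_s = 4, rate_hz = 256,
                        seed = 1)
  sp <- coherent_spectrum(rec)
  i41 <- which(sp$freq_hz == 41)
  expect_equal(sp$amplitude[i41], 1, tolerance = 1e-9)
  expect_lt(max(sp$amplitude[-c(1, i41)]), 1e-9)
  expect_equal(sp$bin_width_hz, 0.25)
})

test_that("record and epoch invariants are enforced", {
  expect_error(eeg_record(rnorm(100), 128, 1.003, 1), "integer")
  expect_error(eeg_record(rnorm(100), 128, 1, c(1, 50)), "fit within")
  rec <- synthesize_eeg(data.frame(freq_hz = 10, amplitude = 1),
                        list(white_sd = 0, pink_sd = 0),
                        n_epochs = 2, epoch_length_s = 1, rate_hz = 64,
                        seed = 1)
  expect_error(coherent_spectrum(rec), "allow_coarse")
  expect_silent(coherent_spectrum(rec, allow_coarse = TRUE))
  expect_error(synthesize_eeg(data.frame(freq_hz = 200, amplitude = 1),
                              list(white_sd = 0, pink_sd = 0),
                              rate_hz = 256), "Nyquist")
})

test_that("Parseval: epoch-average variance equals spectral power", {
  rec <- synthesize_eeg(data.frame(freq_hz = c(11, 41),
                                   amplitude = c(0.5, 1),
                                   phase = c(0.3, 1.1)),
                        list(white_sd = 1, pink_sd = 0.5),
                        n_epochs = 6, epoch_length_s = 2, rate_hz = 128,
                        seed = 2)
  sp <- coherent_spectrum(rec)
  # one-sided amplitudes: variance = sum A_k^2 / 2 over interior bins,
  # plus the full Nyquist power (that bin is not doubled)
  nb <- length(sp$amplitude)
  amp <- sp$amplitude[2:(nb - 1)]
  expect_equal(sum(amp^2) / 2 + sp$amplitude[nb]^2, sp$epoch_var,
               tolerance = 1e-8)
})

test_that("coherent gain: signal bin constant, noise floor ~ 1/sqrt(n)", {
  sig_amp <- function(n_ep) {
    rec <- synthesize_eeg(data.frame(freq_hz = 41, amplitude = 1),
                          list(white_sd = 2, pink_sd = 0),
                          n_epochs = n_ep, epoch_length_s = 2,
                          rate_hz = 128, seed = 3)
    sp <- coherent_spectrum(rec)
    noise_bins <- setdiff(seq_along(sp$freq_hz),
                          c(1, which(abs(sp$freq_hz - 41) < 1.1)))
    c(signal = sp$amplitude[sp$freq_hz == 41],
      floor = sqrt(mean(sp$amplitude[noise_bins]^2)))
  }
  a4 <- sig_amp(4); a64 <- sig_amp(64)
  expect_equal(a4[["signal"]], a64[["signal"]], tolerance = 0.1)
  expect_equal(a4[["floor"]] / a64[["floor"]], sqrt(64 / 4),
               tolerance = 0.35)
})

test_that("component detection is scale invariant and bin-strict", {
  rec <- synthesize_eeg(data.frame(freq_hz = 41, amplitude = 0.5),
                        list(white_sd = 1, pink_sd = 0),
                        n_epochs = 16, epoch_length_s = 2, rate_hz = 128,
                        seed = 4)
  sp <- coherent_spectrum(rec)
  ct <- detect_component(sp, 41)
  rec2 <- rec
  rec2$samples <- rec2$samples * 1000
  ct2 <- detect_component(coherent_spectrum(rec2), 41)
  expect_equal(ct2$f_statistic, ct$f_statistic, tolerance = 1e-9)
  expect_equal(ct$df, c(2, 40))
  expect_error(detect_component(sp, 41.25), "between bins")
  expect_error(detect_component(sp, 63.5), "edge")
})

test_that("detector holds its false-positive rate on pure noise", {
  none <- data.frame(freq_hz = numeric(0), amplitude = numeric(0))
  rej <- vapply(1:300, function(r) {
    rec <- synthesize_eeg(none, list(white_sd = 1, pink_sd = 0),
                          n_epochs = 8, epoch_length_s = 2, rate_hz = 128,
                          seed = 5000 + r)
    detect_component(coherent_spectrum(rec), 41)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("detector power approaches 1 at high SNR", {
  # amplitude set for a ~20 dB expected spectral F-ratio
  n <- 2 * 128; n_ep <- 8
  amp <- 2 * sqrt(100 / (n * n_ep))
  det <- vapply(1:100, function(r) {
    rec <- synthesize_eeg(data.frame(freq_hz = 41, amplitude = amp),
                          list(white_sd = 1, pink_sd = 0),
                          n_epochs = n_ep, epoch_length_s = 2,
                          rate_hz = 128, seed = 6000 + r)
    detect_component(coherent_spectrum(rec), 41)$p_value < 0.001
  }, logical(1))
  expect_gt(mean(det), 0.95)
})

test_that("synthetic noise follows the requested spectral slope", {
  # pink-only record: log-power vs log-frequency slope ~ -1
  none <- data.frame(freq_hz = numeric(0), amplitude = numeric(0))
  pows <- 0
  for (r in 1:20) {
    rec <- synthesize_eeg(none, list(white_sd = 0, pink_sd = 1),
                          n_epochs = 1, epoch_length_s = 4, rate_hz = 256,
                          seed = 7000 + r)
    sp <- coherent_spectrum(rec)
    pows <- pows + sp$amplitude^2
  }
  f <- sp$freq_hz
  keep <- f >= 1 & f <= 60
  slope <- coef(lm(log(pows[keep]) ~ log(f[keep])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.25)
  # white-only: flat
  for (r in 1:20) {
    rec <- synthesize_eeg(none, list(white_sd = 1, pink_sd = 0),
                          n_epochs = 1, epoch_length_s = 4, rate_hz = 256,
                          seed = 8000 + r)
    sp <- coherent_spectrum(rec)
    if (r == 1) pw <- 0
    pw <- pw + sp$amplitude^2
  }
  slope_w <- coef(lm(log(pw[keep]) ~ log(f[keep])))[2]
  expect_lt(abs(slope_w), 0.2)
})

test_that("identical seeds reproduce the record bit for bit", {
  comp <- data.frame(freq_hz = 41, amplitude = 1)
  r1 <- synthesize_eeg(comp, list(white_sd = 1, pink_sd = 1), 4, 2, 128, 9)
  r2 <- synthesize_eeg(comp, list(white_sd = 1, pink_sd = 1), 4, 2, 128, 9)
  expect_identical(r1$samples, r2$samples)
})
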