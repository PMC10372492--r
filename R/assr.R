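# Auditory steady-state response (ASSR) detection in epoch-averaged
# EEG-like records. Stimulus-locked components survive coherent
# (time-domain) epoch averaging while background EEG averages out as
# 1/sqrt(n_epochs); detection uses the standard spectral F-test of the
# target bin against neighboring noise bins.

#' Construct a single-channel EEG-like record
#'
#' @param samples microvolt sample vector (one channel).
#' @param rate_hz sampling rate (Hz).
#' @param epoch_length_s epoch duration (s); `epoch_length_s * rate_hz`
#'   must be integral.
#' @param epoch_onsets 1-based sample indices of stimulus-locked epoch
#'   onsets; every epoch must fit within the record.
#' @return an `eeg_record` object.
#' @export
eeg_record <- function(samples, rate_hz, epoch_length_s, epoch_onsets) {
  stopifnot(rate_hz > 0, epoch_length_s > 0)
  n_ep <- epoch_length_s * rate_hz
  if (abs(n_ep - round(n_ep)) > 1e-9)
    stop("epoch_length_s * rate_hz must be an integer number of samples")
  n_ep <- as.integer(round(n_ep))
  if (length(epoch_onsets) < 1) stop("need at least one epoch")
  if (any(epoch_onsets < 1) ||
      any(epoch_onsets + n_ep - 1L > length(samples)))
    stop("all epochs must fit within the record")
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 epoch_length_s = epoch_length_s,
                 epoch_samples = n_ep,
                 epoch_onsets = as.integer(epoch_onsets)),
            class = "eeg_record")
}

#' Coherent (epoch-averaged) amplitude spectrum
#'
#' Averages the stimulus-locked epochs in the time domain, then takes the
#' discrete Fourier transform of the average. Bin width is
#' `1/epoch_length_s`; amplitudes are one-sided (`2|X|/N`, except DC and
#' Nyquist) in the units of the record (microvolts). Steady-state analysis
#' needs sub-Hz resolution, so epochs shorter than 2 s (bins wider than
#' 0.5 Hz) are rejected unless `allow_coarse = TRUE`.
#'
#' @param record an [eeg_record()].
#' @param allow_coarse permit epochs shorter than 2 s.
#' @return an `assr_spectrum`: list with `freq_hz`, `amplitude` (one-sided,
#'   microvolts), `complex` (unscaled DFT of the epoch average), `n_epochs`,
#'   `bin_width_hz`, `epoch_var` (variance of the epoch average, for
#'   Parseval checks).
#' @export
coherent_spectrum <- function(record, allow_coarse = FALSE) {
  stopifnot(inherits(record, "eeg_record"))
  if (record$epoch_length_s < 2 && !allow_coarse)
    stop("epoch shorter than 2 s gives bins wider than 0.5 Hz; ",
         "set allow_coarse = TRUE to override")
  n <- record$epoch_samples
  idx <- outer(0:(n - 1L), record$epoch_onsets, `+`)
  avg <- rowMeans(matrix(record$samples[idx], nrow = n))
  X <- stats::fft(avg)
  half <- 0:(n %/% 2)
  amp <- Mod(X[half + 1]) / n
  scale2 <- rep(2, length(half))
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[length(half)] <- 1
  structure(list(freq_hz = half / record$epoch_length_s,
                 amplitude = amp * scale2,
                 complex = X[half + 1],
                 n_epochs = length(record$epoch_onsets),
                 bin_width_hz = 1 / record$epoch_length_s,
                 epoch_var = mean((avg - mean(avg))^2)),
            class = "assr_spectrum")
}

#' Spectral F-test for a steady-state component
#'
#' Tests the power at the target frequency bin against the mean power of
#' `n_neighbors` bins on each side, excluding the two bins immediately
#' adjacent to the target (spectral-leakage guard). Under
#' Gaussian background noise the ratio follows an F distribution with
#' `(2, 4 * n_neighbors)` degrees of freedom (each complex bin carries two
#' degrees of freedom). The statistic is scale-invariant.
#'
#' @param spectrum an [coherent_spectrum()] result.
#' @param target_freq_hz frequency to test (Hz); must fall on a bin within
#'   a small tolerance (half of `tol_frac` bin widths).
#' @param n_neighbors noise bins per side (default 10).
#' @param tol_frac tolerated bin misalignment as a fraction of the bin
#'   width (default 0.01).
#' @return a `component_test`: `freq_hz` (bin center), `amplitude`
#'   (one-sided, microvolts), `snr_db`, `f_statistic`, `df`, `p_value`.
#' @export
detect_component <- function(spectrum, target_freq_hz, n_neighbors = 10,
                             tol_frac = 0.01) {
  stopifnot(inherits(spectrum, "assr_spectrum"), n_neighbors >= 2)
  bw <- spectrum$bin_width_hz
  k <- target_freq_hz / bw
  if (abs(k - round(k)) > tol_frac)
    stop(sprintf(
      "target %g Hz falls between bins (bin width %g Hz)", target_freq_hz, bw))
  k <- as.integer(round(k))
  nb <- length(spectrum$freq_hz)
  lo <- k - 1L - n_neighbors; hi <- k + 1L + n_neighbors
  if (k < 1L || lo < 1L || hi > nb - 1L)
    stop("target too close to the spectrum edge for the neighbor band")
  pow <- Mod(spectrum$complex)^2
  neigh <- c((lo:(k - 2L)), ((k + 2L):hi)) + 1L
  f_stat <- pow[k + 1L] / mean(pow[neigh])
  df <- c(2, 4 * n_neighbors)
  structure(list(freq_hz = spectrum$freq_hz[k + 1L],
                 amplitude = spectrum$amplitude[k + 1L],
                 snr_db = 10 * log10(f_stat),
                 f_statistic = f_stat, df = df,
                 p_value = stats::pf(f_stat, df[1], df[2],
                                     lower.tail = FALSE)),
            class = "component_test")
}

#' @export
print.component_test <- function(x, ...) {
  cat(sprintf(
    "component at %.3f Hz: amplitude %.4g uV, SNR %.1f dB, F(%d,%d) = %.2f, p = %.3g\n",
    x$freq_hz, x$amplitude, x$snr_db, x$df[1], x$df[2], x$f_statistic,
    x$p_value))
  invisible(x)
}

#' Synthesize a stimulus-locked EEG-like record
#'
#' Builds `n_epochs` contiguous epochs, each the same sum of fixed-phase
#' sinusoids (the stimulus-locked components) plus noise drawn
#' independently per epoch as a white + 1/f mixture.
#'
#' @param components data frame with columns `freq_hz`, `amplitude`
#'   (microvolts) and optionally `phase` (radians, default 0); may have
#'   zero rows. All frequencies must be below Nyquist.
#' @param noise_spec list with `white_sd` and `pink_sd` (microvolts;
#'   either may be 0).
#' @param n_epochs number of epochs.
#' @param epoch_length_s epoch duration (s).
#' @param rate_hz sampling rate (Hz).
#' @param seed integer seed; identical seeds give identical records.
#' @return an [eeg_record()].
#' @export
synthesize_eeg <- function(components, noise_spec = list(white_sd = 1,
                                                         pink_sd = 0),
                           n_epochs = 20, epoch_length_s = 4,
                           rate_hz = 256, seed = 1) {
  stopifnot(n_epochs >= 1)
  n <- round(epoch_length_s * rate_hz)
  t <- (0:(n - 1)) / rate_hz
  sig <- numeric(n)
  if (nrow(components) > 0) {
    if (any(components$freq_hz >= rate_hz / 2))
      stop("component frequency at or above Nyquist")
    ph <- if (is.null(components$phase)) rep(0, nrow(components))
          else components$phase
    for (i in seq_len(nrow(components)))
      sig <- sig + components$amplitude[i] *
        cos(2 * pi * components$freq_hz[i] * t + ph[i])
  }
  rng <- local_rng(seed)
  eps <- matrix(0, n, n_epochs)
  if (noise_spec$white_sd > 0)
    eps <- eps + noise_spec$white_sd * stats::rnorm(n * n_epochs)
  if (noise_spec$pink_sd > 0)
    for (j in seq_len(n_epochs))
      eps[, j] <- eps[, j] + noise_spec$pink_sd * pink_noise(n)
  rng_restore(rng)
  samples <- as.vector(eps + sig)
  eeg_record(samples, rate_hz, epoch_length_s,
             epoch_onsets = seq(1L, by = n, length.out = n_epochs))
}

# Unit-variance 1/f ("pink") noise by spectral shaping of white noise.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))            # guard DC
  f[f > n / 2] <- n - f[f > n / 2] + 1
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}
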