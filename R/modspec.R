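# Spectrographic analysis of synthesized ripples: short-time band-envelope
# extraction on a log-frequency axis and the 2-D envelope-modulation
# spectrum. Deliberately independent of the synthesis path (which works
# component-wise), so it can serve as an oracle for it.

#' Short-time band envelopes on a log-frequency (octave) axis
#'
#' Computes a Hann-windowed short-time Fourier transform of a waveform
#' segment and takes the RMS magnitude across FFT bins falling into
#' log-frequency bands of width `d_oct` octaves above `f_min_hz` (RMS, not
#' the mean, so that a band's envelope is dominated by the spectral main
#' lobes it contains rather than diluted by empty leakage bins).
#'
#' @param samples numeric waveform.
#' @param rate_hz sampling rate (Hz).
#' @param f_min_hz,f_max_hz analysis band (Hz).
#' @param d_oct octave bin width (default 0.25).
#' @param n_window STFT window length in samples (Hann), default 512.
#' @param hop STFT hop in samples, default `n_window / 4`.
#' @return list with `env` (matrix, octave bins x frames), `x_oct` (bin
#'   centers, octaves), `t_s` (frame centers, s), `frame_rate_hz`.
#' @export
band_envelopes <- function(samples, rate_hz, f_min_hz, f_max_hz,
                           d_oct = 0.25, n_window = 512,
                           hop = n_window %/% 4) {
  n <- length(samples)
  if (n < n_window) stop("segment shorter than one STFT window")
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(n_window) - 1) / n_window))
  starts <- seq(1L, n - n_window + 1L, by = hop)
  freqs <- (0:(n_window %/% 2)) * rate_hz / n_window
  n_oct <- log2(f_max_hz / f_min_hz)
  edges <- seq(0, n_oct, by = d_oct)
  if (length(edges) < 3L) stop("analysis band too narrow for octave binning")
  bin_of <- rep(NA_integer_, length(freqs))
  inb <- freqs >= f_min_hz & freqs <= f_max_hz
  bin_of[inb] <- findInterval(log2(freqs[inb] / f_min_hz), edges,
                              rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  bin_of[bin_of > nb] <- nb
  env <- matrix(0, nrow = nb, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- samples[starts[j]:(starts[j] + n_window - 1L)] * win
    mag <- Mod(stats::fft(seg))[seq_along(freqs)]
    env[, j] <- vapply(seq_len(nb), function(b)
      sqrt(mean(mag[which(bin_of == b)]^2)), numeric(1))
  }
  list(env = env, x_oct = edges[-length(edges)] + d_oct / 2,
       t_s = (starts - 1 + n_window / 2) / rate_hz,
       frame_rate_hz = rate_hz / hop)
}

#' 2-D envelope-modulation spectrum of a ripple waveform
#'
#' Extracts band envelopes from the rippled segment of a waveform, removes
#' each band's mean level (the carrier spectral shape), and takes a 2-D
#' discrete Fourier transform over (octave position, time). A moving ripple
#' with parameters (density, velocity) produces a spectral peak at exactly
#' those modulation coordinates.
#'
#' @param wave a `ripple_waveform` from [synthesize_ripple()].
#' @param d_oct,n_window,hop passed to [band_envelopes()].
#' @return list with `power` (matrix over (density, velocity) bins),
#'   `density_cpo`, `velocity_hz` (bin coordinate vectors, signed), and
#'   `peak` (list: `density_cpo`, `velocity_hz`, canonicalized so
#'   `velocity_hz >= 0`).
#' @export
envelope_modulation_spectrum <- function(wave, d_oct = 0.25, n_window = 512,
                                         hop = n_window %/% 4) {
  stopifnot(inherits(wave, "ripple_waveform"))
  sp <- wave$spec
  rip <- wave$samples[wave$markers["ripple_onset"]:length(wave$samples)]
  be <- band_envelopes(rip, wave$rate_hz, sp$f_min_hz, sp$f_max_hz,
                       d_oct = d_oct, n_window = n_window, hop = hop)
  env <- be$env
  env <- env / rowMeans(env) - 1      # per-band modulation about its mean
  nb <- nrow(env); nt <- ncol(env)
  X <- stats::fft(env)                # 2-D DFT (rows: octave, cols: time)
  pow <- Mod(X)^2
  dens <- fft_freqs(nb, 1 / d_oct)
  velo <- fft_freqs(nt, be$frame_rate_hz)
  # peak search excluding the DC bin
  pow[1, 1] <- 0
  idx <- arrayInd(which.max(pow), dim(pow))
  pk_d <- dens[idx[1]]; pk_v <- velo[idx[2]]
  if (pk_v < 0 || (pk_v == 0 && pk_d < 0)) { pk_d <- -pk_d; pk_v <- -pk_v }
  list(power = pow, density_cpo = dens, velocity_hz = velo,
       peak = list(density_cpo = pk_d, velocity_hz = pk_v))
}

# DFT bin frequencies for n points at sampling rate fs, wrapped to +/- fs/2.
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k * fs / n
}
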