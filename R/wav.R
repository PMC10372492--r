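# Minimal mono PCM WAV writer/reader (16- or 24-bit). Kept deliberately
# small: ripple trials are mono fixed-rate PCM, nothing more.

#' Write a waveform to a mono PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to the requested bit
#' depth.
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param rate_hz sampling rate (Hz).
#' @param path output file.
#' @param bits 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate_hz, path, bits = 16) {
  stopifnot(bits %in% c(16L, 24L), rate_hz > 0)
  x <- pmin(1, pmax(-1, samples))
  bytes_per <- bits %/% 8
  n_data <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  w_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                endian = "little")
  w_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                endian = "little")
  writeChar("RIFF", con, eos = NULL); w_u32(36 + n_data)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w_u32(16)
  w_u16(1); w_u16(1)                       # PCM, mono
  w_u32(round(rate_hz)); w_u32(round(rate_hz) * bytes_per)
  w_u16(bytes_per); w_u16(bits)
  writeChar("data", con, eos = NULL); w_u32(n_data)
  full <- 2^(bits - 1)
  q <- as.integer(round(x * (full - 1)))
  if (bits == 16) {
    writeBin(q, con, size = 2, endian = "little")
  } else {
    q[q < 0] <- q[q < 0] + 2^24
    raw3 <- as.raw(rbind(q %% 256, (q %/% 256) %% 256, q %/% 65536))
    writeBin(as.vector(raw3), con)
  }
  invisible(path)
}

#' Read a mono PCM WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric, scaled to `[-1, 1]`) and
#'   `rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r_u16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  r_u32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  rate <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- r_u32()
    if (id == "fmt ") {
      fmt <- r_u16(); nch <- r_u16(); rate <- r_u32(); r_u32(); r_u16()
      bits <- r_u16()
      if (fmt != 1 || nch != 1) stop("only mono PCM supported")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      full <- 2^(bits - 1)
      if (bits == 16) {
        samples <- readBin(con, "integer", n = sz / 2, size = 2,
                           endian = "little") / (full - 1)
      } else {
        raw3 <- matrix(as.integer(readBin(con, "raw", sz)), nrow = 3)
        q <- raw3[1, ] + 256 * raw3[2, ] + 65536 * raw3[3, ]
        q[q >= 2^23] <- q[q >= 2^23] - 2^24
        samples <- q / (full - 1)
      }
      break
    } else readBin(con, "raw", sz)
  }
  list(samples = samples, rate_hz = rate)
}

#' Write a synthesized ripple trial to WAV with a sidecar CSV
#'
#' The sidecar lists ripple id, velocity, density, modulation depth, the
#' realized noise-lead duration, and the ripple-onset sample.
#'
#' @param wave a `ripple_waveform` from [synthesize_ripple()].
#' @param path output WAV path; the sidecar is `<path>.csv`.
#' @param ripple_id identifier written to the sidecar.
#' @param bits PCM bit depth.
#' @return `path`, invisibly.
#' @export
write_ripple_wav <- function(wave, path, ripple_id = 1, bits = 16) {
  stopifnot(inherits(wave, "ripple_waveform"))
  peak <- max(abs(wave$samples))
  x <- if (peak > 1) wave$samples / peak else wave$samples
  write_wav(x, wave$rate_hz, path, bits = bits)
  sp <- wave$spec
  utils::write.csv(
    data.frame(ripple_id = ripple_id, velocity_hz = sp$velocity_hz,
               density_cpo = sp$density_cpo, mod_depth = sp$mod_depth,
               noise_lead_s = wave$noise_lead_s,
               ripple_onset_sample = wave$markers[["ripple_onset"]]),
    paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
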