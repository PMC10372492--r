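# Moving spectrotemporal ripple stimuli: specification, synthesis, and
# ripple-grid experiment design.

#' Create a moving spectrotemporal ripple specification
#'
#' A moving spectrotemporal (ST) ripple is a broadband or band-limited
#' carrier whose log-frequency envelope is a drifting sinusoid
#' \deqn{R(x, t) = 1 + \Delta M \cos(2\pi(\Omega x + \omega t))}
#' with \eqn{x} the spectral position in octaves above `f_min_hz`,
#' \eqn{t} time since ripple onset, \eqn{\Omega} the spectral density
#' (cycles/octave), \eqn{\omega} the temporal velocity (Hz) and
#' \eqn{\Delta M} the modulation depth.
#'
#' @param velocity_hz temporal velocity \eqn{\omega} in Hz (signed).
#' @param density_cpo spectral density \eqn{\Omega} in cycles/octave (signed).
#' @param mod_depth modulation depth \eqn{\Delta M} in `[0, 1]`.
#' @param ripple_dur_s duration of the rippled segment (s), > 0.
#' @param noise_lead_range_s length-2 interval (s) from which the flat-noise
#'   lead duration is drawn uniformly per trial.
#' @param f_min_hz,f_max_hz carrier band edges in Hz, `f_min_hz < f_max_hz`.
#' @param carrier_kind one of `"tone-complex"`, `"white-noise"`,
#'   `"pink-noise"`. Noise carriers are realized as dense random-phase tone
#'   complexes (1/64-octave spacing) with component amplitudes shaped to the
#'   white (flat per Hz) or pink (flat per octave) power spectrum, which
#'   gives exact per-component envelope control.
#' @param tone_spacing_oct component spacing for the tone-complex carrier,
#'   in octaves (default 1/20).
#' @param level_scale overall RMS target of the waveform (arbitrary units).
#' @return an object of class `ripple_spec`.
#' @seealso [synthesize_ripple()], [design_ripple_grid()]
#' @export
ripple_spec <- function(velocity_hz, density_cpo, mod_depth = 0.8,
                        ripple_dur_s = 1, noise_lead_range_s = c(1, 3),
                        f_min_hz = 250, f_max_hz = 10000,
                        carrier_kind = c("tone-complex", "white-noise",
                                         "pink-noise"),
                        tone_spacing_oct = 1 / 20, level_scale = 0.1) {
  carrier_kind <- match.arg(carrier_kind)
  stopifnot(is.numeric(velocity_hz), length(velocity_hz) == 1L,
            is.finite(velocity_hz),
            is.numeric(density_cpo), length(density_cpo) == 1L,
            is.finite(density_cpo))
  if (!is.numeric(mod_depth) || mod_depth < 0 || mod_depth > 1)
    stop("`mod_depth` must lie in [0, 1]")
  if (!(ripple_dur_s > 0)) stop("`ripple_dur_s` must be > 0")
  if (length(noise_lead_range_s) != 2L || noise_lead_range_s[1] < 0 ||
      diff(noise_lead_range_s) < 0)
    stop("`noise_lead_range_s` must be a non-decreasing interval with lower bound >= 0")
  if (!(f_min_hz > 0 && f_min_hz < f_max_hz))
    stop("need 0 < f_min_hz < f_max_hz")
  if (!(tone_spacing_oct > 0)) stop("`tone_spacing_oct` must be > 0")
  structure(
    list(velocity_hz = velocity_hz, density_cpo = density_cpo,
         mod_depth = mod_depth, ripple_dur_s = ripple_dur_s,
         noise_lead_range_s = as.numeric(noise_lead_range_s),
         f_min_hz = f_min_hz, f_max_hz = f_max_hz,
         carrier_kind = carrier_kind, tone_spacing_oct = tone_spacing_oct,
         level_scale = level_scale),
    class = "ripple_spec")
}

#' @export
print.ripple_spec <- function(x, ...) {
  cat(sprintf(
    "ripple_spec: velocity %g Hz, density %g c/o, depth %g, %s carrier %g-%g Hz\n",
    x$velocity_hz, x$density_cpo, x$mod_depth, x$carrier_kind,
    x$f_min_hz, x$f_max_hz))
  invisible(x)
}

#' Spectral position in octaves above the band's lowest frequency
#'
#' @param freq_hz frequency (Hz), must satisfy `freq_hz >= f_min_hz > 0`.
#' @param f_min_hz lowest frequency in the stimulus band (Hz).
#' @return octaves above `f_min_hz`, i.e. `log2(freq_hz / f_min_hz)`.
#' @examples
#' octave_position(1000, 500) # 1
#' @export
octave_position <- function(freq_hz, f_min_hz) {
  if (any(!is.finite(f_min_hz)) || any(f_min_hz <= 0))
    stop("`f_min_hz` must be positive")
  if (any(!is.finite(freq_hz)) || any(freq_hz < f_min_hz))
    stop("`freq_hz` must satisfy freq_hz >= f_min_hz")
  log2(freq_hz / f_min_hz)
}

#' Ripple envelope gain at an (octave, time) point
#'
#' Evaluates \eqn{1 + \Delta M \cos(2\pi(\Omega x + \omega t))}. The sign
#' convention is fixed: positive `velocity_hz` together with positive
#' `density_cpo` yields a downward spectral sweep (see [ripple_direction()]).
#'
#' @param x_oct spectral position in octaves above `f_min_hz`.
#' @param t_s time in seconds since ripple onset (>= 0).
#' @param spec a [ripple_spec()].
#' @return envelope gain in `[1 - mod_depth, 1 + mod_depth]`; vectorized
#'   over `x_oct` and `t_s`.
#' @export
ripple_envelope <- function(x_oct, t_s, spec) {
  stopifnot(inherits(spec, "ripple_spec"))
  if (any(t_s < 0)) stop("`t_s` must be >= 0 (time since ripple onset)")
  1 + spec$mod_depth *
    cos(2 * pi * (spec$density_cpo * x_oct + spec$velocity_hz * t_s))
}

#' Ripple drift direction under a chosen sign convention
#'
#' Under the default (`"ratio"`) convention a ripple is an upward spectral
#' sweep iff `velocity_hz / density_cpo < 0`, otherwise downward. The
#' alternative `"flipped"` convention swaps the two labels; both appear in
#' the literature, so the convention is an explicit, flippable flag rather
#' than a hard-wired choice. Ripples with `velocity_hz == 0` or
#' `density_cpo == 0` are stationary (`"none"`).
#'
#' @param velocity_hz,density_cpo ripple parameters (vectorized).
#' @param convention `"ratio"` (default) or `"flipped"`.
#' @return character vector in `c("upward", "downward", "none")`.
#' @export
ripple_direction <- function(velocity_hz, density_cpo,
                             convention = c("ratio", "flipped")) {
  convention <- match.arg(convention)
  d <- ifelse(velocity_hz == 0 | density_cpo == 0, "none",
              ifelse(velocity_hz / density_cpo < 0, "upward", "downward"))
  if (convention == "flipped")
    d <- ifelse(d == "upward", "downward", ifelse(d == "downward", "upward", d))
  d
}

# Component frequencies (Hz) for a given spec; noise carriers use a dense
# 1/64-octave complex regardless of tone_spacing_oct.
ripple_components <- function(spec) {
  spacing <- if (spec$carrier_kind == "tone-complex")
    spec$tone_spacing_oct else 1 / 64
  n_oct <- log2(spec$f_max_hz / spec$f_min_hz)
  k <- 0:floor(n_oct / spacing + 1e-9)
  f <- spec$f_min_hz * 2^(k * spacing)
  if (length(f) < 1L) stop("carrier band too narrow for any component")
  # amplitude weights: equal per component (tone complex / pink: equal power
  # per octave on the log-spaced grid), white: power flat per Hz => amp ~ sqrt(f)
  w <- switch(spec$carrier_kind,
              "white-noise" = sqrt(f / spec$f_min_hz),
              rep(1, length(f)))
  list(freq_hz = f, x_oct = k * spacing, weight = w)
}

#' Synthesize a moving spectrotemporal ripple trial
#'
#' Generates one trial waveform: a flat-carrier lead of duration drawn
#' uniformly from `spec$noise_lead_range_s`, followed by the rippled segment
#' of duration `spec$ripple_dur_s`. The carrier is a superposition of
#' log-spaced tones with independent uniform random phases; during the
#' rippled segment each component's instantaneous amplitude is scaled by the
#' ripple envelope at its octave position. The lead uses the identical
#' carrier realization with the envelope held at 1, so the only change at
#' ripple onset is the modulation itself. The rippled segment is rescaled so
#' its long-term RMS equals the lead's ("same carrier and mean sound
#' level"); a raised-cosine onset ramp is applied at stimulus start only,
#' never at ripple onset, which must remain the detection event.
#'
#' @param spec a [ripple_spec()].
#' @param seed integer seed driving component phases and the lead-duration
#'   draw; identical seeds give bit-identical waveforms.
#' @param rate_hz sampling rate (Hz), default 44100.
#' @param ramp_s raised-cosine onset ramp duration at stimulus start (s).
#' @param rms_equalize rescale the rippled segment to the lead's RMS
#'   (default `TRUE`).
#' @return a `ripple_waveform`: list with `samples`, `rate_hz`, and
#'   `markers` (`noise_onset`, `ripple_onset`, 1-based sample indices),
#'   plus the realized `noise_lead_s` and the generating `spec`.
#' @export
synthesize_ripple <- function(spec, seed, rate_hz = 44100, ramp_s = 0.005,
                              rms_equalize = TRUE) {
  stopifnot(inherits(spec, "ripple_spec"))
  if (spec$ripple_dur_s < 1 / rate_hz)
    stop("`ripple_dur_s` is shorter than one sample")
  comp <- ripple_components(spec)
  rng <- local_rng(seed)
  lead_s <- stats::runif(1, spec$noise_lead_range_s[1],
                         spec$noise_lead_range_s[2])
  phases <- stats::runif(length(comp$freq_hz), 0, 2 * pi)
  rng_restore(rng)

  n_lead <- round(lead_s * rate_hz)
  n_rip <- round(spec$ripple_dur_s * rate_hz)
  t_all <- (seq_len(n_lead + n_rip) - 1) / rate_hz
  t_rip <- t_all[(n_lead + 1):(n_lead + n_rip)] - n_lead / rate_hz

  # carriers: components x samples kept as a loop over components to bound
  # memory at one sample vector per component
  lead <- numeric(n_lead)
  rip <- numeric(n_rip)
  for (i in seq_along(comp$freq_hz)) {
    carrier <- comp$weight[i] *
      sin(2 * pi * comp$freq_hz[i] * t_all + phases[i])
    lead <- lead + carrier[seq_len(n_lead)]
    env <- 1 + spec$mod_depth *
      cos(2 * pi * (spec$density_cpo * comp$x_oct[i] +
                    spec$velocity_hz * t_rip))
    rip <- rip + env * carrier[(n_lead + 1):(n_lead + n_rip)]
  }
  if (rms_equalize && spec$mod_depth > 0) {
    r_lead <- sqrt(mean(lead^2))
    r_rip <- sqrt(mean(rip^2))
    if (r_rip > 0) rip <- rip * (r_lead / r_rip)
  }
  x <- c(lead, rip)
  x <- x * (spec$level_scale / sqrt(mean(x^2)))
  n_ramp <- min(round(ramp_s * rate_hz), n_lead)
  if (n_ramp > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 1) / n_ramp))
    x[seq_len(n_ramp)] <- x[seq_len(n_ramp)] * ramp
  }
  structure(
    list(samples = x, rate_hz = rate_hz,
         markers = c(noise_onset = 1L, ripple_onset = n_lead + 1L),
         noise_lead_s = lead_s, spec = spec),
    class = "ripple_waveform")
}

#' Design a full ripple-grid reaction-time experiment
#'
#' Builds the Cartesian grid of (velocity, density) ripples, flags the
#' `(0, 0)` cell as the unmodulated catch stimulus, and returns a seeded,
#' fully randomized trial order. A standard design of 8 velocities
#' (0, 4, 8, ..., 256 Hz) by 11 densities (-3 to +3 cycles/octave in 0.6
#' steps) yields 88 ripples including the catch, i.e. 1760 trials at 20
#' trials per ripple.
#'
#' @param velocities_hz,densities_cpo axis value vectors (no duplicates).
#' @param trials_per_ripple trials per grid cell (>= 1).
#' @param seed integer seed for the trial-order randomization.
#' @param ... further arguments passed to [ripple_spec()] for every cell.
#' @return a `ripple_grid`: list with `cells` (data frame: ripple_id,
#'   velocity_hz, density_cpo, is_catch), `specs` (list of [ripple_spec()]),
#'   `n_trials`, and `trial_order` (data frame: trial, ripple_id).
#' @export
design_ripple_grid <- function(velocities_hz, densities_cpo,
                               trials_per_ripple = 20, seed = 1, ...) {
  if (length(velocities_hz) < 1L || length(densities_cpo) < 1L)
    stop("axis value lists must be non-empty")
  if (anyDuplicated(velocities_hz) || anyDuplicated(densities_cpo))
    stop("duplicate values in an axis list")
  if (trials_per_ripple < 1) stop("`trials_per_ripple` must be >= 1")
  cells <- expand.grid(velocity_hz = velocities_hz,
                       density_cpo = densities_cpo,
                       KEEP.OUT.ATTRS = FALSE)
  cells$ripple_id <- seq_len(nrow(cells))
  cells$is_catch <- cells$velocity_hz == 0 & cells$density_cpo == 0
  cells <- cells[, c("ripple_id", "velocity_hz", "density_cpo", "is_catch")]
  specs <- lapply(seq_len(nrow(cells)), function(i)
    ripple_spec(cells$velocity_hz[i], cells$density_cpo[i], ...))
  n_trials <- as.integer(round(nrow(cells) * trials_per_ripple))
  rng <- local_rng(seed)
  order_ids <- sample(rep(cells$ripple_id, each = trials_per_ripple))
  rng_restore(rng)
  structure(
    list(cells = cells, specs = specs, n_trials = n_trials,
         trial_order = data.frame(trial = seq_len(n_trials),
                                  ripple_id = order_ids)),
    class = "ripple_grid")
}

#' Select the speech-relevant ripples of a grid
#'
#' Natural speech is dominated by temporal modulations up to roughly 10 Hz
#' and spectral modulations within about one cycle/octave; this returns the
#' grid cells inside that region, excluding the catch cell.
#'
#' @param grid a [design_ripple_grid()] result.
#' @param max_velocity_hz,max_density_cpo inclusive thresholds on
#'   `|velocity|` and `|density|` (defaults 10 Hz, 1.0 c/o).
#' @return the subset of `grid$cells` rows that qualify.
#' @export
classify_speech_ripples <- function(grid, max_velocity_hz = 10,
                                    max_density_cpo = 1.0) {
  stopifnot(inherits(grid, "ripple_grid"))
  keep <- abs(grid$cells$velocity_hz) <= max_velocity_hz &
    abs(grid$cells$density_cpo) <= max_density_cpo & !grid$cells$is_catch
  grid$cells[keep, , drop = FALSE]
}
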