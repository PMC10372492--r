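test_that("octave position maps frequency ratios to log2 octaves", {
  expect_equal(octave_position(1000, 500), 1.0)
  expect_equal(octave_position(500, 500), 0.0)
  expect_equal(octave_position(2000, 500), 2.0)
  expect_error(octave_position(100, 500), "freq_hz")
  expect_error(octave_position(1000, -1), "positive")
})

test_that("ripple envelope follows 1 + depth * cos and its bounds", {
  sp <- ripple_spec(4, -1.2, mod_depth = 0.8)
  expect_equal(ripple_envelope(0, 0, sp), 1.8)
  sp0 <- ripple_spec(4, -1.2, mod_depth = 0)
  expect_equal(ripple_envelope(runif(5), runif(5), sp0), rep(1, 5))
  # mean over one full temporal period at fixed octave position is 1
  t <- seq(0, 1 / 4, length.out = 4001)[-4001]
  expect_equal(mean(ripple_envelope(0.3, t, sp)), 1, tolerance = 1e-10)
  # bounds
  env <- ripple_envelope(runif(200, 0, 5), runif(200, 0, 2), sp)
  expect_true(all(env >= 1 - 0.8 - 1e-12 & env <= 1 + 0.8 + 1e-12))
  expect_error(ripple_envelope(0, -1, sp), "t_s")
})

test_that("spec invariants are enforced at construction", {
  expect_error(ripple_spec(4, 1, mod_depth = 1.5), "mod_depth")
  expect_error(ripple_spec(4, 1, ripple_dur_s = 0), "ripple_dur_s")
  expect_error(ripple_spec(4, 1, f_min_hz = 2000, f_max_hz = 1000), "f_min")
  expect_error(ripple_spec(4, 1, noise_lead_range_s = c(-1, 2)), "interval")
})

test_that("tone-complex component count matches the closed-form count", {
  # floor(20 * log2(10000/250)) + 1 = 107 components at 1/20 octave
  sp <- ripple_spec(4, -1.2, f_min_hz = 250, f_max_hz = 10000)
  comp <- ripplemetrics:::ripple_components(sp)
  expect_equal(length(comp$freq_hz), floor(20 * log2(10000 / 250)) + 1)
  expect_equal(length(comp$freq_hz), 107L)
})

test_that("synthesized ripple has matched segment RMS and exact markers", {
  sp <- ripple_spec(8, 0.6, mod_depth = 0.8, ripple_dur_s = 0.5,
                    noise_lead_range_s = c(0.4, 0.8),
                    f_min_hz = 250, f_max_hz = 4000)
  w <- synthesize_ripple(sp, seed = 11, rate_hz = 16000)
  expect_true(all(is.finite(w$samples)))
  i0 <- w$markers[["ripple_onset"]]
  expect_gt(i0, w$markers[["noise_onset"]])
  lead <- w$samples[1:(i0 - 1)]
  rip <- w$samples[i0:length(w$samples)]
  expect_equal(sqrt(mean(lead^2)) / sqrt(mean(rip^2)), 1, tolerance = 0.01)
  # realized lead duration within the configured draw interval
  expect_true(w$noise_lead_s >= 0.4 && w$noise_lead_s <= 0.8)
})

test_that("identical seeds give bit-identical waveforms", {
  sp <- ripple_spec(16, -0.6, ripple_dur_s = 0.3,
                    noise_lead_range_s = c(0.2, 0.4), f_max_hz = 4000)
  w1 <- synthesize_ripple(sp, seed = 5, rate_hz = 8000)
  w2 <- synthesize_ripple(sp, seed = 5, rate_hz = 8000)
  expect_identical(w1$samples, w2$samples)
  w3 <- synthesize_ripple(sp, seed = 6, rate_hz = 8000)
  expect_false(identical(w1$samples, w3$samples))
})

test_that("band-envelope modulation depth matches the specified depth", {
  # one component per octave band (1-octave tone spacing) so each band
  # envelope tracks a single component; slow ripple so the short-time
  # window does not smear the modulation
  sp <- ripple_spec(2, 0.5, mod_depth = 0.8, ripple_dur_s = 2,
                    noise_lead_range_s = c(0.3, 0.3),
                    f_min_hz = 250, f_max_hz = 4000,
                    tone_spacing_oct = 1)
  w <- synthesize_ripple(sp, seed = 21, rate_hz = 9000)
  rip <- w$samples[w$markers[["ripple_onset"]]:length(w$samples)]
  # analysis bands centered on the components (half-octave offset), so
  # each band holds exactly one component's spectral lobe
  be <- band_envelopes(rip, 9000, 250 / sqrt(2), 4000 * sqrt(2),
                       d_oct = 1, n_window = 256)
  # drop frames whose window straddles the segment edges
  env <- be$env[, 5:(ncol(be$env) - 4)]
  depth <- apply(env, 1, function(e)
    (max(e) - min(e)) / (max(e) + min(e)))
  # min/max band envelope = (1 -/+ depth) x carrier envelope within 2%
  expect_lt(max(abs(depth - 0.8)), 0.02 * 1.8)
})

test_that("2-D modulation spectrum peaks at the generating parameters", {
  for (par in list(c(8, 0.5), c(16, -1), c(4, 1.5))) {
    sp <- ripple_spec(par[1], par[2], mod_depth = 0.9, ripple_dur_s = 1,
                      noise_lead_range_s = c(0.2, 0.2),
                      f_min_hz = 250, f_max_hz = 4000)
    w <- synthesize_ripple(sp, seed = 31, rate_hz = 9000)
    ms <- envelope_modulation_spectrum(w)
    v_bin <- diff(ms$velocity_hz[1:2])
    d_bin <- diff(ms$density_cpo[1:2])
    expect_lt(abs(ms$peak$velocity_hz - par[1]), v_bin + 1e-9)
    expect_lt(abs(ms$peak$density_cpo - par[2]), d_bin + 1e-9)
  }
})

test_that("zero modulation depth leaves no off-DC modulation power", {
  sp <- ripple_spec(8, 0.6, mod_depth = 0, ripple_dur_s = 1,
                    noise_lead_range_s = c(0.2, 0.2),
                    f_min_hz = 250, f_max_hz = 4000)
  w <- synthesize_ripple(sp, seed = 41, rate_hz = 9000)
  ms <- envelope_modulation_spectrum(w)
  off_dc <- max(ms$power)
  # compare with a modulated twin: its peak dwarfs the unmodulated floor
  spm <- ripple_spec(8, 0.6, mod_depth = 0.8, ripple_dur_s = 1,
                     noise_lead_range_s = c(0.2, 0.2),
                     f_min_hz = 250, f_max_hz = 4000)
  msm <- envelope_modulation_spectrum(synthesize_ripple(spm, seed = 41,
                                                        rate_hz = 9000))
  expect_gt(max(msm$power) / off_dc, 50)
})

test_that("flipping the density sign reverses the envelope drift direction", {
  lag_between_bands <- function(density) {
    # adjacent one-octave bands: |density| * 1 octave < 1/2 cycle keeps
    # the envelope lag unambiguous
    sp <- ripple_spec(4, density, mod_depth = 0.9, ripple_dur_s = 1.5,
                      noise_lead_range_s = c(0.2, 0.2),
                      f_min_hz = 250, f_max_hz = 4000,
                      tone_spacing_oct = 1)
    w <- synthesize_ripple(sp, seed = 51, rate_hz = 9000)
    rip <- w$samples[w$markers[["ripple_onset"]]:length(w$samples)]
    be <- band_envelopes(rip, 9000, 250, 4000, d_oct = 1, n_window = 256)
    cc <- ccf(be$env[2, ], be$env[3, ], lag.max = 8, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  l_pos <- lag_between_bands(+0.25)
  l_neg <- lag_between_bands(-0.25)
  expect_true(sign(l_pos) != 0 && sign(l_neg) != 0)
  expect_equal(sign(l_pos), -sign(l_neg))
})

test_that("direction labels follow the convention and its flip", {
  expect_equal(ripple_direction(4, -1.2), "upward")
  expect_equal(ripple_direction(8, 0.6), "downward")
  expect_equal(ripple_direction(0, 1), "none")
  expect_equal(ripple_direction(4, -1.2, convention = "flipped"),
               "downward")
})

test_that("ripple grid design enumerates cells, catch and trial order", {
  g <- design_ripple_grid(c(0, 4, 8, 16, 32, 64, 128, 256),
                          seq(-3, 3, by = 0.6), trials_per_ripple = 20,
                          seed = 2)
  expect_equal(nrow(g$cells), 88L)
  expect_equal(sum(g$cells$is_catch), 1L)
  expect_equal(g$n_trials, 1760L)
  expect_equal(sort(table(g$trial_order$ripple_id)),
               sort(rep(20L, 88)), ignore_attr = TRUE)
  # seeded randomization reproducible
  g2 <- design_ripple_grid(c(0, 4, 8, 16, 32, 64, 128, 256),
                           seq(-3, 3, by = 0.6), 20, seed = 2)
  expect_identical(g$trial_order, g2$trial_order)
  # degenerate single-cell grid is the catch alone
  g1 <- design_ripple_grid(0, 0, trials_per_ripple = 1)
  expect_equal(nrow(g1$cells), 1L)
  expect_true(g1$cells$is_catch)
  expect_error(design_ripple_grid(c(4, 4), 1, 1), "duplicate")
})

test_that("speech-ripple selection obeys the modulation thresholds", {
  g <- design_ripple_grid(c(0, 4, 8, 16, 32, 64, 128, 256),
                          seq(-3, 3, by = 0.6), 1)
  sp <- classify_speech_ripples(g)
  expect_equal(nrow(sp), 8L)  # {0,4,8} x {-0.6,0,0.6} minus the catch
  expect_true(all(abs(sp$velocity_hz) <= 10 & abs(sp$density_cpo) <= 1))
  g2 <- design_ripple_grid(256, 3, 1)
  expect_equal(nrow(classify_speech_ripples(g2)), 0L)
  all_cells <- classify_speech_ripples(g, Inf, Inf)
  expect_equal(nrow(all_cells), 87L)
})

test_that("WAV round trip preserves samples at quantization accuracy", {
  x <- sin(2 * pi * 440 * (0:999) / 8000) * 0.5
  f <- tempfile(fileext = ".wav")
  write_wav(x, 8000, f, bits = 16)
  r <- read_wav(f)
  expect_equal(r$rate_hz, 8000)
  expect_equal(r$samples, x, tolerance = 1 / 2^14)
  write_wav(x, 8000, f, bits = 24)
  r24 <- read_wav(f)
  expect_equal(r24$samples, x, tolerance = 1 / 2^22)
  unlink(f)
})
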