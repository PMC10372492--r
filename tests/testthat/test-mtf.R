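# Helper: fits data frame for a full grid from a value function.
make_fits <- function(vels, dens, value_fn, n_used = 20) {
  g <- expand.grid(velocity_hz = vels, density_cpo = dens,
                   KEEP.OUT.ATTRS = FALSE)
  g$mu_p <- mapply(value_fn, g$velocity_hz, g$density_cpo)
  g$n_used <- n_used
  g
}

std_vels <- c(0, 4, 8, 16, 32, 64, 128, 256)
std_dens <- seq(-3, 3, by = 0.6)

test_that("MTF assembly fills cells, masks the catch and reports alarms", {
  grid <- design_ripple_grid(std_vels, std_dens, 1)
  fits <- make_fits(std_vels, std_dens, function(v, d) 3 + 0.001 * v)
  fits$false_alarm_rate <- ifelse(fits$velocity_hz == 0 &
                                    fits$density_cpo == 0, 0.07, NA)
  m <- assemble_mtf(fits, grid)
  expect_equal(sum(!is.na(m$values)), 87L)
  expect_true(is.na(m$values[match(0, m$velocities_hz),
                             match(0, m$densities_cpo)]))
  expect_equal(m$catch_false_alarm_rate, 0.07)
  # cells below the trial floor are masked
  fits2 <- fits
  fits2$n_used[2] <- 3
  m2 <- assemble_mtf(fits2, grid)
  expect_equal(sum(is.na(m2$values)), 2L)
  # unknown keys rejected; all-masked warns
  fits3 <- fits[1:2, ]
  fits3$velocity_hz <- c(5, 7)
  expect_error(assemble_mtf(fits3, grid), "not in the grid")
  fits4 <- fits
  fits4$mu_p <- NA_real_
  expect_warning(assemble_mtf(fits4, grid), "masked")
})

test_that("cross-sections recover the generating marginals of a separable grid", {
  vfun <- function(v) 2 + exp(-((v - 8) / 40)^2)
  sfun <- function(d) 1 + 0.2 * cos(d)
  grid <- design_ripple_grid(std_vels, std_dens, 1)
  fits <- make_fits(std_vels, std_dens, function(v, d) vfun(v) * sfun(d))
  m <- assemble_mtf(fits, grid)
  cs <- cross_sections(m)
  # proportional to the generating vectors (catch excluded)
  tm <- cs$tmtf
  expect_equal(tm$mu_p / vfun(tm$velocity_hz),
               rep(sfun(0), nrow(tm)), tolerance = 1e-12)
  sm <- cs$smtf
  expect_equal(sm$mu_p / sfun(sm$density_cpo),
               rep(vfun(0), nrow(sm)), tolerance = 1e-12)
  # absent axis errors
  m2 <- mtf_grid(c(4, 8), c(0.6, 1.2), matrix(1:4, 2))
  expect_error(cross_sections(m2), "density = 0")
  # constant grid gives flat cross-sections
  mc <- assemble_mtf(make_fits(std_vels, std_dens,
                               function(v, d) 3), grid)
  csc <- cross_sections(mc)
  expect_equal(var(csc$tmtf$mu_p), 0)
})

test_that("separability index is exactly 1 for rank-1 grids", {
  v <- 2 + seq_along(std_vels) / 4
  s <- 1 + abs(std_dens) / 3
  m <- mtf_grid(std_vels, std_dens, outer(v, s))
  expect_equal(separability_index(m), 1.0, tolerance = 1e-12)
  # masked catch cell imputation preserves separability
  vals <- outer(v, s)
  vals[match(0, std_vels), match(0, std_dens)] <- NA
  m2 <- mtf_grid(std_vels, std_dens, vals)
  expect_equal(separability_index(m2), 1.0, tolerance = 1e-12)
})

test_that("separability index degrades from 1 with noise and for pure noise", {
  set.seed(71)
  v <- 2 + seq_along(std_vels) / 4
  s <- 1 + abs(std_dens) / 3
  base <- outer(v, s)
  noisy <- base + matrix(rnorm(length(base), 0, 0.02 * mean(base)),
                         nrow(base))
  expect_gt(separability_index(mtf_grid(std_vels, std_dens,
                                        abs(noisy))), 0.9)
  # i.i.d. mean-zero noise (grand-mean centered view) sits well below 0.9
  null_idx <- vapply(1:50, function(r) {
    g <- mtf_grid(std_vels, std_dens,
                  matrix(abs(rnorm(88, 0, 1)), 8, 11))
    separability_index(g, center = "grand")
  }, numeric(1))
  expect_lt(quantile(null_idx, 0.95), 0.9)
})

test_that("separability index is invariant to permutation and scaling", {
  set.seed(72)
  vals <- abs(matrix(rnorm(24, 3), 4, 6))
  m <- mtf_grid(1:4, 1:6 / 2, vals)
  i0 <- separability_index(m)
  pr <- sample(4); pc <- sample(6)
  mp <- mtf_grid(1:4, 1:6 / 2, vals[pr, pc])
  expect_equal(separability_index(mp), i0, tolerance = 1e-12)
  ms <- mtf_grid(1:4, 1:6 / 2, vals * 7.3)
  expect_equal(separability_index(ms), i0, tolerance = 1e-12)
  expect_error(separability_index(mtf_grid(1, 1, matrix(1))), "2 x 2")
})

test_that("direction asymmetry contrasts downward against upward cells", {
  # mirror-symmetric grid: zero exactly
  vals <- outer(c(1, 2), c(1.5, 2, 1.5))
  m <- mtf_grid(c(4, 8), c(-0.6, 0, 0.6), vals)
  expect_equal(direction_asymmetry(m), 0)
  # doubling the upward cells gives (m - 2m)/(3m) = -1/3
  vals2 <- vals
  vals2[, 1] <- vals2[, 1] * 2    # negative density + positive velocity = upward
  m2 <- mtf_grid(c(4, 8), c(-0.6, 0, 0.6), vals2)
  expect_equal(direction_asymmetry(m2), -1 / 3, tolerance = 1e-12)
  # convention flip flips the sign
  expect_equal(direction_asymmetry(m2, convention = "flipped"), 1 / 3,
               tolerance = 1e-12)
  # one side fully masked errors
  vals3 <- vals
  vals3[, 1] <- NA
  expect_error(direction_asymmetry(mtf_grid(c(4, 8), c(-0.6, 0, 0.6),
                                            vals3)), "direction")
})

test_that("grid CSV round trip and subject averaging preserve values", {
  v <- 2 + seq_along(std_vels) / 4
  s <- 1 + abs(std_dens) / 3
  m <- mtf_grid(std_vels, std_dens, outer(v, s))
  f <- tempfile(fileext = ".csv")
  write_mtf_csv(m, f)
  m2 <- read_mtf_csv(f)
  expect_equal(m2$values, m$values, ignore_attr = TRUE)
  unlink(f)
  avg <- average_mtf(list(m, mtf_grid(std_vels, std_dens,
                                      outer(v, s) * 3)))
  expect_equal(avg$values, outer(v, s) * 2, ignore_attr = TRUE)
  avg_rt <- average_mtf(list(m, m), on = "rt")
  expect_equal(avg_rt$values, outer(v, s), ignore_attr = TRUE)
})
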