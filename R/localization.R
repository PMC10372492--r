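# Free-field sound-localization regression under level roving. The
# response azimuth is modelled as a bilinear function of target azimuth
# and absolute sound level,
#   R_azi = b0 + alpha * T_azi + lambda * L_snd,
# with b0 the response bias (deg), alpha the dimensionless azimuth gain
# and lambda the level gain (deg/dB). An ideal listener has b0 = lambda =
# 0 and alpha = 1; a listener relying purely on the head-shadow (level)
# cue shows alpha ~ 0 with nonzero b0 and lambda, which is why the level
# must be roved over a 20-25 dB range to make lambda identifiable.

#' Construct a localization trial table
#'
#' @param target_azimuth_deg stimulus azimuths (deg).
#' @param sound_level_db roved absolute sound levels (dB).
#' @param response_azimuth_deg response azimuths (deg).
#' @param sound_type per-trial stimulus class: `"LP"` (0.25-1.5 kHz,
#'   ITD-dominated), `"HP"` (3-10 kHz, ILD-dominated) or `"BB"`
#'   (0.25-10 kHz broadband).
#' @return a `localization_trials` data frame.
#' @export
localization_trials <- function(target_azimuth_deg, sound_level_db,
                                response_azimuth_deg, sound_type = "BB") {
  if (!all(sound_type %in% c("LP", "HP", "BB")))
    stop("sound_type must be one of LP, HP, BB")
  if (any(!is.finite(target_azimuth_deg)) ||
      any(!is.finite(response_azimuth_deg)))
    stop("azimuths must be finite")
  structure(data.frame(target_azimuth_deg = target_azimuth_deg,
                       sound_level_db = sound_level_db,
                       response_azimuth_deg = response_azimuth_deg,
                       sound_type = rep_len(sound_type,
                                            length(target_azimuth_deg)),
                       stringsAsFactors = FALSE),
            class = c("localization_trials", "data.frame"))
}

#' Fit the bilinear localization regression for one sound type
#'
#' Ordinary least squares of response azimuth on an intercept, the target
#' azimuth, and the roved sound level, fitted separately per sound type.
#' Coefficient confidence intervals come from a seeded nonparametric
#' bootstrap (resampling trials with replacement, percentile intervals).
#'
#' @param trials a [localization_trials()] table (other sound types are
#'   ignored).
#' @param sound_type which stimulus class to fit (`"BB"`, `"LP"`, `"HP"`).
#' @param n_bootstrap bootstrap resamples (default 2000; 0 skips CIs).
#' @param seed integer seed for the bootstrap.
#' @param conf_level CI level (default 0.95).
#' @param min_trials minimum trials required (default 10).
#' @return a `localization_fit`: `bias_deg` (b0), `azimuth_gain` (alpha),
#'   `level_gain_deg_per_db` (lambda), `r_squared`, `n`, `ci` (matrix of
#'   percentile intervals), `sound_type`.
#' @export
fit_localization <- function(trials, sound_type = "BB", n_bootstrap = 2000,
                             seed = 1, conf_level = 0.95, min_trials = 10) {
  stopifnot(is.data.frame(trials))
  d <- trials[trials$sound_type == sound_type, , drop = FALSE]
  n <- nrow(d)
  if (n < min_trials)
    stop(sprintf("fewer than %d trials of sound type %s", min_trials,
                 sound_type))
  if (diff(range(d$sound_level_db)) <= 0)
    stop("sound level was not roved: lambda is not identifiable")
  X <- cbind(1, d$target_azimuth_deg, d$sound_level_db)
  if (qr(X)$rank < 3) stop("rank-deficient design matrix")
  y <- d$response_azimuth_deg
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  ci <- NULL
  if (n_bootstrap > 0) {
    rng <- local_rng(seed)
    idx <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE), nrow = n)
    rng_restore(rng)
    boots <- matrix(NA_real_, n_bootstrap, 3)
    for (b in seq_len(n_bootstrap)) {
      i <- idx[, b]
      boots[b, ] <- tryCatch(.lm.fit(X[i, , drop = FALSE],
                                     y[i])$coefficients,
                             error = function(e) rep(NA_real_, 3))
    }
    a <- (1 - conf_level) / 2
    ci <- t(apply(boots, 2, stats::quantile, probs = c(a, 1 - a),
                  na.rm = TRUE))
    dimnames(ci) <- list(c("bias_deg", "azimuth_gain",
                           "level_gain_deg_per_db"),
                         c("lower", "upper"))
  }
  structure(list(bias_deg = unname(beta[1]),
                 azimuth_gain = unname(beta[2]),
                 level_gain_deg_per_db = unname(beta[3]),
                 r_squared = r2, n = n, ci = ci,
                 conf_level = conf_level, sound_type = sound_type),
            class = "localization_fit")
}

#' @export
print.localization_fit <- function(x, ...) {
  cat(sprintf(
    "localization fit [%s], n = %d: b0 = %.2f deg, alpha = %.3f, lambda = %.3f deg/dB (R^2 = %.3f)\n",
    x$sound_type, x$n, x$bias_deg, x$azimuth_gain,
    x$level_gain_deg_per_db, x$r_squared))
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% bootstrap CIs:\n", 100 * x$conf_level))
    print(round(x$ci, 3))
  }
  invisible(x)
}

#' Simulate localization trials from the bilinear model
#'
#' Target azimuths are drawn uniformly over `azimuth_range_deg` (default
#' the practical free-field range of +/-75 deg), levels uniformly over
#' `level_range_db` (default a 25 dB rove), and responses follow the
#' bilinear model plus Gaussian response noise.
#'
#' @param bias_deg,azimuth_gain,level_gain_deg_per_db generating
#'   coefficients (b0, alpha, lambda).
#' @param n number of trials (30-50 per sound type is typically enough).
#' @param azimuth_range_deg target range (deg), default `c(-75, 75)`.
#' @param level_range_db rove range (dB), default `c(45, 70)`.
#' @param noise_sd_deg response noise SD (deg), default 8.
#' @param sound_type stimulus class label.
#' @param seed integer seed.
#' @return a [localization_trials()] table.
#' @export
simulate_localization <- function(bias_deg = 0, azimuth_gain = 1,
                                  level_gain_deg_per_db = 0, n = 50,
                                  azimuth_range_deg = c(-75, 75),
                                  level_range_db = c(45, 70),
                                  noise_sd_deg = 8, sound_type = "BB",
                                  seed = 1) {
  stopifnot(n >= 1, diff(azimuth_range_deg) >= 0, diff(level_range_db) >= 0)
  rng <- local_rng(seed)
  t_azi <- stats::runif(n, azimuth_range_deg[1], azimuth_range_deg[2])
  lev <- stats::runif(n, level_range_db[1], level_range_db[2])
  noise <- if (noise_sd_deg > 0) stats::rnorm(n, 0, noise_sd_deg) else 0
  rng_restore(rng)
  r_azi <- bias_deg + azimuth_gain * t_azi +
    level_gain_deg_per_db * lev + noise
  localization_trials(t_azi, lev, r_azi, sound_type)
}
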