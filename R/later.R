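# LATER-model reaction-time analysis. Under the LATER model a decision
# signal rises linearly from a starting level to threshold at a rate drawn
# once per trial from a Gaussian; the reciprocal reaction time ("promptness"
# p = 1/RT) is then Gaussian. Only the two ratios mu_p and sigma_p of the
# underlying rate/threshold parameters are identifiable from RT data, so
# they are the model's parametrization here. Misses (no response before the
# timeout) are promptness values left-censored at 1/timeout and enter the
# likelihood as such.

#' Construct a reaction-time dataset
#'
#' @param rt_s reaction times in seconds measured from the change (ripple)
#'   onset; `NA` marks a miss (no response before `timeout_s`). Negative
#'   values mark button presses before the onset; they are counted as false
#'   alarms and never enter fitting.
#' @param timeout_s response deadline (s); every non-miss RT must be
#'   within `(0, timeout_s]`.
#' @param min_rt_s anticipatory cutoff (s): responses faster than this are
#'   below the auditory sensorimotor floor and flagged as outliers, not
#'   data. Default 0.08.
#' @param condition optional condition label.
#' @return an `rt_dataset` object.
#' @export
rt_dataset <- function(rt_s, timeout_s = Inf, min_rt_s = 0.08,
                       condition = "cond") {
  if (!(timeout_s > min_rt_s) || !(min_rt_s > 0))
    stop("need timeout_s > min_rt_s > 0")
  ok <- is.na(rt_s) | rt_s < 0 | (rt_s > 0 & rt_s <= timeout_s)
  if (!all(ok)) stop("non-miss rt_s must lie in (0, timeout_s]")
  structure(list(rt_s = as.numeric(rt_s), timeout_s = timeout_s,
                 min_rt_s = min_rt_s, condition = condition),
            class = "rt_dataset")
}

# Partition a dataset into usable promptness values, miss count,
# anticipatory-outlier count and false-alarm count.
rt_partition <- function(d) {
  stopifnot(inherits(d, "rt_dataset"))
  rt <- d$rt_s
  fa <- !is.na(rt) & rt < 0
  miss <- is.na(rt)
  antic <- !is.na(rt) & rt >= 0 & rt < d$min_rt_s
  use <- !(fa | miss | antic)
  list(p = 1 / rt[use], n_miss = sum(miss), n_outliers = sum(antic),
       n_false_alarms = sum(fa), n_used = sum(use),
       censor = 1 / d$timeout_s)
}

#' Simulate reaction times from a LATER (recinormal) model
#'
#' Each trial draws a promptness `p ~ N(mu_p, sigma_p)`; draws at or below
#' `1/timeout_s` (including non-positive ones, i.e. reaction times beyond
#' the deadline) are misses, otherwise `rt = 1/p`.
#'
#' @param mu_p,sigma_p mean and SD of promptness (1/s); `sigma_p >= 0`.
#' @param n number of trials.
#' @param timeout_s response deadline (s); default `Inf`.
#' @param seed integer seed.
#' @param min_rt_s anticipatory cutoff recorded in the dataset.
#' @param condition condition label.
#' @return an [rt_dataset()] with `NA` for misses.
#' @export
simulate_rt <- function(mu_p, sigma_p, n, timeout_s = Inf, seed = 1,
                        min_rt_s = 0.08, condition = "sim") {
  stopifnot(n >= 1, sigma_p >= 0, mu_p > 0)
  rng <- local_rng(seed)
  p <- stats::rnorm(n, mu_p, sigma_p)
  rng_restore(rng)
  rt <- ifelse(p <= 1 / timeout_s, NA_real_, 1 / p)
  rt_dataset(rt, timeout_s = timeout_s, min_rt_s = min_rt_s,
             condition = condition)
}

# Negative log-likelihood and gradient of a censored Gaussian promptness
# sample. theta = c(mu, log_sigma). p: observed promptness; m: miss count;
# cens: censoring point (promptness below which a trial is a miss).
later_nll <- function(theta, obs, m, cens) {
  mu <- theta[1]; s <- exp(theta[2])
  z <- (obs - mu) / s
  nll <- length(obs) * (theta[2] + 0.5 * log(2 * pi)) + 0.5 * sum(z^2)
  if (m > 0 && is.finite(cens))
    nll <- nll - m * stats::pnorm((cens - mu) / s, log.p = TRUE)
  nll
}

later_nll_grad <- function(theta, obs, m, cens) {
  mu <- theta[1]; s <- exp(theta[2])
  z <- (obs - mu) / s
  g_mu <- -sum(z) / s
  g_ls <- length(obs) - sum(z^2)
  if (m > 0 && is.finite(cens)) {
    zc <- (cens - mu) / s
    mills <- exp(stats::dnorm(zc, log = TRUE) -
                 stats::pnorm(zc, log.p = TRUE))
    g_mu <- g_mu + m * mills / s
    g_ls <- g_ls + m * mills * zc
  }
  c(g_mu, g_ls)
}

#' Fit the LATER model by censored maximum likelihood
#'
#' Maximum-likelihood Gaussian fit on promptness. Misses contribute a
#' left-censored term `Phi((1/timeout - mu_p)/sigma_p)` to the likelihood;
#' anticipatory trials (`rt < min_rt_s`) and false alarms are excluded and
#' counted. Without misses the closed-form Gaussian MLE is returned
#' exactly; with misses the likelihood is maximized by BFGS with an
#' analytic gradient from a moment-based multi-start.
#'
#' @param dataset an [rt_dataset()].
#' @param min_trials minimum number of usable trials (default 10).
#' @return a `later_fit`: `mu_p`, `sigma_p`, `vcov` (observed-information
#'   covariance of `(mu_p, sigma_p)`), `loglik`, counts
#'   (`n_used`, `n_misses`, `n_outliers`, `n_false_alarms`), `condition`.
#' @export
fit_later <- function(dataset, min_trials = 10) {
  part <- rt_partition(dataset)
  if (part$n_used == 0) stop("all trials missed or excluded; nothing to fit")
  if (part$n_used < min_trials)
    stop(sprintf("fewer than %d usable trials", min_trials))
  p <- part$p; m <- part$n_miss; cens <- part$censor
  n <- length(p)
  mu0 <- mean(p); s0 <- sqrt(mean((p - mu0)^2))
  if (s0 <= .Machine$double.eps * max(1, abs(mu0)) * 10)
    stop("zero promptness variance: sigma_p at boundary, model degenerate")
  if (m == 0 || !is.finite(cens)) {
    mu_hat <- mu0; s_hat <- s0
    ll <- -later_nll(c(mu_hat, log(s_hat)), p, 0, cens)
  } else {
    starts <- list(c(mu0, log(s0)), c(mu0 - s0, log(s0 * 1.5)))
    best <- NULL
    for (st in starts) {
      o <- stats::optim(st, later_nll, later_nll_grad, obs = p, m = m,
                        cens = cens, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
      if (is.null(best) || o$value < best$value) best <- o
    }
    mu_hat <- best$par[1]; s_hat <- exp(best$par[2])
    ll <- -best$value
  }
  # observed information on the (mu_p, sigma_p) scale
  H <- stats::optimHess(c(mu_hat, log(s_hat)), later_nll, later_nll_grad,
                        obs = p, m = m, cens = cens)
  J <- diag(c(1, 1 / s_hat))        # d(mu, log s)/d(mu, s)
  V <- tryCatch(solve(t(J) %*% H %*% J), error = function(e)
    matrix(NA_real_, 2, 2))
  dimnames(V) <- list(c("mu_p", "sigma_p"), c("mu_p", "sigma_p"))
  structure(list(mu_p = mu_hat, sigma_p = s_hat, vcov = V, loglik = ll,
                 n_used = part$n_used, n_misses = m,
                 n_outliers = part$n_outliers,
                 n_false_alarms = part$n_false_alarms,
                 timeout_s = dataset$timeout_s,
                 condition = dataset$condition),
            class = "later_fit")
}

#' @export
print.later_fit <- function(x, ...) {
  cat(sprintf(
    "LATER fit [%s]: mu_p = %.4f 1/s, sigma_p = %.4f 1/s (logLik %.2f)\n",
    x$condition, x$mu_p, x$sigma_p, x$loglik))
  cat(sprintf("  trials: %d used, %d missed, %d anticipatory, %d false alarms\n",
              x$n_used, x$n_misses, x$n_outliers, x$n_false_alarms))
  invisible(x)
}

#' Reciprobit coordinates and straight-line summary
#'
#' In a reciprobit plot the cumulative response probability (probit scale)
#' is plotted against negative promptness `-1/RT`, so short reaction times
#' sit on the left and misses at the far right; recinormal data fall on a
#' straight line. Cumulative probabilities use the `(i - 0.5)/n` plotting
#' convention with misses counted in `n`, so the censored tail depresses
#' the line rather than being discarded.
#'
#' @param dataset an [rt_dataset()] with at least 3 usable trials.
#' @return a `reciprobit_fit`: `points` (data frame `x = -1/rt`,
#'   `y = probit cumulative probability`, `rt_s`), `slope`, `intercept`,
#'   `median_rt_s` (read from the line at probability 0.5), `goodness`
#'   (R^2 of the line), and trial counts.
#' @export
reciprobit_points <- function(dataset) {
  part <- rt_partition(dataset)
  if (part$n_used < 3) stop("need at least 3 usable trials")
  n_tot <- part$n_used + part$n_miss
  p <- sort(part$p, decreasing = TRUE)     # fastest response first
  cum <- (seq_along(p) - 0.5) / n_tot
  x <- -p
  y <- stats::qnorm(cum)
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  med <- if (is.finite(slope) && intercept > 0 && slope > 0)
    slope / intercept else NA_real_
  structure(list(
    points = data.frame(x = x, y = y, rt_s = 1 / p),
    slope = unname(slope), intercept = unname(intercept),
    median_rt_s = unname(med), goodness = r2,
    n_used = part$n_used, n_outliers = part$n_outliers,
    n_misses = part$n_miss), class = "reciprobit_fit")
}

# Joint censored ML fit of two conditions under equality constraints.
# share: character subset of c("mu", "sigma").
later_joint_fit <- function(partA, partB, share) {
  parts <- list(partA, partB)
  share_mu <- "mu" %in% share
  share_sigma <- "sigma" %in% share
  # theta layout: mus (1 or 2), then log sigmas (1 or 2)
  n_mu <- if (share_mu) 1L else 2L
  n_ls <- if (share_sigma) 1L else 2L
  idx_mu <- if (share_mu) c(1L, 1L) else c(1L, 2L)
  idx_ls <- if (share_sigma) c(1L, 1L) else c(1L, 2L)
  unpack <- function(theta) list(mu = theta[idx_mu],
                                 ls = theta[n_mu + idx_ls])
  nll <- function(theta) {
    u <- unpack(theta)
    sum(vapply(1:2, function(j)
      later_nll(c(u$mu[j], u$ls[j]), parts[[j]]$p, parts[[j]]$n_miss,
                parts[[j]]$censor), numeric(1)))
  }
  grad <- function(theta) {
    u <- unpack(theta)
    g <- numeric(n_mu + n_ls)
    for (j in 1:2) {
      gj <- later_nll_grad(c(u$mu[j], u$ls[j]), parts[[j]]$p,
                           parts[[j]]$n_miss, parts[[j]]$censor)
      g[idx_mu[j]] <- g[idx_mu[j]] + gj[1]
      g[n_mu + idx_ls[j]] <- g[n_mu + idx_ls[j]] + gj[2]
    }
    g
  }
  pool <- c(partA$p, partB$p)
  mu0 <- mean(pool); s0 <- stats::sd(pool)
  theta0 <- c(if (share_mu) mu0 else c(mean(partA$p), mean(partB$p)),
              log(rep(if (share_sigma) s0 else s0, n_ls)))
  o <- stats::optim(theta0, nll, grad, method = "BFGS",
                    control = list(reltol = 1e-12, maxit = 1000))
  u <- unpack(o$par)
  list(loglik = -o$value, df = n_mu + n_ls,
       mu_p = u$mu, sigma_p = exp(u$ls))
}

#' Compare two reaction-time conditions by nested likelihood-ratio tests
#'
#' Compares the models: both parameters shared; shared `sigma_p` with free
#' `mu_p` ("shift" — parallel reciprobit lines moving horizontally); shared
#' `mu_p` with free `sigma_p` ("slope" change); both free. Reports each
#' likelihood-ratio statistic with df and p-value and the preferred model
#' at level `alpha`, chosen hierarchically: the shared model is kept unless
#' the full model improves on it; then the simplest single-parameter
#' relaxation that the full model does not beat is preferred.
#'
#' @param datasetA,datasetB two [rt_dataset()] objects.
#' @param alpha test level (default 0.05).
#' @return a `later_comparison`: `fits` (per-model log-likelihoods and
#'   estimates), `tests` (data frame of LRTs), `preferred`, `alpha`.
#' @export
compare_conditions <- function(datasetA, datasetB, alpha = 0.05) {
  pa <- rt_partition(datasetA); pb <- rt_partition(datasetB)
  if (pa$n_used < 3 || pb$n_used < 3) stop("both datasets must be fittable")
  models <- list(
    shared = later_joint_fit(pa, pb, c("mu", "sigma")),
    shift  = later_joint_fit(pa, pb, "sigma"),
    slope  = later_joint_fit(pa, pb, "mu"),
    full   = later_joint_fit(pa, pb, character(0)))
  lrt <- function(m0, m1) {
    stat <- max(0, 2 * (models[[m1]]$loglik - models[[m0]]$loglik))
    df <- models[[m1]]$df - models[[m0]]$df
    data.frame(null = m0, alt = m1, statistic = stat, df = df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  tests <- rbind(lrt("shared", "full"), lrt("shared", "shift"),
                 lrt("shared", "slope"), lrt("shift", "full"),
                 lrt("slope", "full"))
  p_of <- function(null, alt)
    tests$p_value[tests$null == null & tests$alt == alt]
  preferred <-
    if (p_of("shared", "full") >= alpha) "shared"
    else if (p_of("shift", "full") >= alpha) "shift"
    else if (p_of("slope", "full") >= alpha) "slope"
    else "full"
  structure(list(fits = models, tests = tests, preferred = preferred,
                 alpha = alpha), class = "later_comparison")
}

#' @export
print.later_comparison <- function(x, ...) {
  cat("LATER condition comparison (likelihood-ratio tests)\n")
  print(x$tests, row.names = FALSE)
  cat(sprintf("preferred model at alpha = %g: %s\n", x$alpha, x$preferred))
  invisible(x)
}

#' Flag outlying and anticipatory trials
#'
#' Flags trials whose promptness lies outside `mu_p +/- k_sd * sigma_p`
#' under a fitted model, and trials faster than the anticipatory cutoff
#' `min_rt_s` (below the auditory sensorimotor floor).
#'
#' @param dataset an [rt_dataset()].
#' @param fit a [fit_later()] result.
#' @param k_sd promptness SD multiple for the deviation flag (default 3;
#'   `Inf` disables it).
#' @return data frame with `rt_s`, `promptness`, and logical flags
#'   `anticipatory`, `deviant`, `miss`, `false_alarm`, `flagged`.
#' @export
detect_outliers <- function(dataset, fit, k_sd = 3) {
  stopifnot(inherits(dataset, "rt_dataset"), inherits(fit, "later_fit"))
  rt <- dataset$rt_s
  miss <- is.na(rt)
  fa <- !miss & rt < 0
  p <- ifelse(miss | fa, NA_real_, 1 / rt)
  antic <- !miss & !fa & rt < dataset$min_rt_s
  dev <- !miss & !fa & !antic &
    abs(p - fit$mu_p) > k_sd * fit$sigma_p
  dev[is.na(dev)] <- FALSE
  data.frame(rt_s = rt, promptness = p, anticipatory = antic,
             deviant = dev, miss = miss, false_alarm = fa,
             flagged = antic | dev | fa)
}
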