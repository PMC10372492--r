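# Spectrotemporal modulation transfer functions (MTFs) assembled from
# per-ripple promptness fits: the "mode" of each cell's promptness
# distribution is the fitted Gaussian mean mu_p (mode = mean for a
# Gaussian). Axis layout is explicit metadata: velocities are rows,
# densities are columns.

#' Construct an MTF grid
#'
#' @param velocities_hz ordered velocity axis (rows).
#' @param densities_cpo ordered density axis (columns).
#' @param values numeric matrix of promptness modes mu_p (1/s),
#'   `length(velocities_hz)` x `length(densities_cpo)`; `NA` marks a
#'   masked cell.
#' @param catch_false_alarm_rate false-alarm rate estimated from the
#'   (0, 0) catch cell, reported alongside the grid (`NA` if unknown).
#' @return an `mtf_grid` object.
#' @export
mtf_grid <- function(velocities_hz, densities_cpo, values,
                     catch_false_alarm_rate = NA_real_) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(velocities_hz), length(densities_cpo))))
    stop("`values` must be |velocities| x |densities|")
  if (any(values < 0, na.rm = TRUE))
    stop("promptness values must be >= 0")
  structure(list(velocities_hz = velocities_hz,
                 densities_cpo = densities_cpo,
                 values = values,
                 catch_false_alarm_rate = catch_false_alarm_rate),
            class = "mtf_grid")
}

#' Assemble an MTF grid from per-ripple LATER fits
#'
#' Places each cell's fitted `mu_p` into the (velocity, density) matrix of
#' a grid design. Cells without a fit, with fewer than `min_trials` usable
#' trials, or with a non-finite estimate are masked. The (0, 0) catch cell
#' is always masked for MTF purposes: it has no modulation to detect, and
#' its response rate is reported separately as the false-alarm rate.
#'
#' @param per_ripple_fits data frame with columns `velocity_hz`,
#'   `density_cpo`, `mu_p`, and optionally `n_used` and
#'   `false_alarm_rate` (read from the catch row if present).
#' @param grid_design a [design_ripple_grid()] result.
#' @param min_trials mask cells with fewer usable trials (default 10).
#' @return an [mtf_grid()].
#' @export
assemble_mtf <- function(per_ripple_fits, grid_design, min_trials = 10) {
  stopifnot(inherits(grid_design, "ripple_grid"),
            is.data.frame(per_ripple_fits),
            all(c("velocity_hz", "density_cpo", "mu_p") %in%
                  names(per_ripple_fits)))
  vels <- sort(unique(grid_design$cells$velocity_hz))
  dens <- sort(unique(grid_design$cells$density_cpo))
  key <- function(v, d) paste(v, d, sep = "|")
  grid_keys <- key(grid_design$cells$velocity_hz,
                   grid_design$cells$density_cpo)
  fit_keys <- key(per_ripple_fits$velocity_hz, per_ripple_fits$density_cpo)
  if (!all(fit_keys %in% grid_keys))
    stop("per-ripple fits contain (velocity, density) keys not in the grid")
  vals <- matrix(NA_real_, length(vels), length(dens))
  for (i in seq_len(nrow(per_ripple_fits))) {
    r <- per_ripple_fits[i, ]
    if (!is.null(per_ripple_fits$n_used) &&
        !is.na(r$n_used) && r$n_used < min_trials) next
    if (!is.finite(r$mu_p)) next
    vals[match(r$velocity_hz, vels), match(r$density_cpo, dens)] <- r$mu_p
  }
  fa <- NA_real_
  is_catch_fit <- per_ripple_fits$velocity_hz == 0 &
    per_ripple_fits$density_cpo == 0
  if (any(is_catch_fit) && !is.null(per_ripple_fits$false_alarm_rate))
    fa <- per_ripple_fits$false_alarm_rate[which(is_catch_fit)[1]]
  ic <- match(0, vels); jc <- match(0, dens)
  if (!is.na(ic) && !is.na(jc)) vals[ic, jc] <- NA_real_
  if (all(is.na(vals)))
    warning("all grid cells are masked: no usable fits")
  mtf_grid(vels, dens, vals, catch_false_alarm_rate = fa)
}

#' Temporal and spectral cross-sections of an MTF grid
#'
#' The temporal MTF is the slice at density 0 (sensitivity versus ripple
#' velocity); the spectral MTF is the slice at velocity 0 (versus density).
#' The catch cell (0, 0) is excluded from both.
#'
#' @param grid an [mtf_grid()].
#' @return list of two data frames, `tmtf` (`velocity_hz`, `mu_p`) and
#'   `smtf` (`density_cpo`, `mu_p`); a slice whose axis value is absent
#'   from the grid raises an error.
#' @export
cross_sections <- function(grid) {
  stopifnot(inherits(grid, "mtf_grid"))
  j0 <- match(0, grid$densities_cpo)
  i0 <- match(0, grid$velocities_hz)
  if (is.na(j0) && is.na(i0))
    stop("grid contains neither a density = 0 column nor a velocity = 0 row")
  tmtf <- smtf <- NULL
  if (!is.na(j0)) {
    keep <- grid$velocities_hz != 0
    tmtf <- data.frame(velocity_hz = grid$velocities_hz[keep],
                       mu_p = grid$values[keep, j0])
  } else stop("grid has no density = 0 column for the temporal MTF")
  if (!is.na(i0)) {
    keep <- grid$densities_cpo != 0
    smtf <- data.frame(density_cpo = grid$densities_cpo[keep],
                       mu_p = grid$values[i0, keep])
  } else stop("grid has no velocity = 0 row for the spectral MTF")
  list(tmtf = tmtf, smtf = smtf)
}

# Impute masked cells multiplicatively (row mean * column mean / grand
# mean), iterated to a fixed point so that a separable (rank-1) matrix is
# completed exactly; falls back to additive row + column - grand imputation
# when the grand mean is ~ 0.
mtf_impute <- function(values, max_iter = 200) {
  na_idx <- which(is.na(values))
  if (length(na_idx) == 0) return(values)
  ij <- arrayInd(na_idx, dim(values))
  rm0 <- rowMeans(values, na.rm = TRUE)
  cm0 <- colMeans(values, na.rm = TRUE)
  if (any(is.nan(rm0[ij[, 1]])) || any(is.nan(cm0[ij[, 2]])))
    stop("cannot impute: an entire row or column is masked")
  scale <- max(abs(values), na.rm = TRUE)
  values[na_idx] <- mean(values, na.rm = TRUE)
  for (it in seq_len(max_iter)) {
    rm_ <- rowMeans(values); cm_ <- colMeans(values); gm <- mean(values)
    new <- if (abs(gm) > 1e-12 * scale)
      rm_[ij[, 1]] * cm_[ij[, 2]] / gm
    else rm_[ij[, 1]] + cm_[ij[, 2]] - gm
    delta <- max(abs(new - values[na_idx]))
    values[na_idx] <- new
    if (delta < 1e-14 * scale) break
  }
  values
}

#' Spectrotemporal separability index of an MTF grid
#'
#' Singular-value decomposition of the (imputed) value matrix; the index is
#' the fraction of total squared singular value carried by the first
#' component, `sigma_1^2 / sum(sigma_i^2)`, in `(0, 1]`. A fully separable
#' MTF (`values = v(velocity) * s(density)`) gives exactly 1. Masked cells
#' are imputed multiplicatively from row and column means, which preserves
#' separable structure. With `center = "grand"` the grand mean is removed
#' first, which asks a different question — how separable the modulation
#' about the mean level is — at the cost of breaking the rank-1 = 1.0
#' identity.
#'
#' @param grid an [mtf_grid()].
#' @param center `"none"` (default) or `"grand"`.
#' @return scalar index in `(0, 1]`.
#' @export
separability_index <- function(grid, center = c("none", "grand")) {
  stopifnot(inherits(grid, "mtf_grid"))
  center <- match.arg(center)
  v <- grid$values
  ok <- !is.na(v)
  if (sum(rowSums(ok) > 0) < 2 || sum(colSums(ok) > 0) < 2 ||
      sum(ok) < 4)
    stop("need at least a 2 x 2 unmasked submatrix")
  v <- mtf_impute(v)
  if (center == "grand") v <- v - mean(v)
  d <- svd(v, nu = 0, nv = 0)$d
  d[1]^2 / sum(d^2)
}

#' Up/down direction-asymmetry index of an MTF grid
#'
#' Compares mean promptness over downward-moving cells with that over
#' upward-moving cells: `(mean_down - mean_up) / (mean_down + mean_up)`,
#' in `[-1, 1]`. Direction labels come from [ripple_direction()] under the
#' chosen sign convention, so flipping the convention flips the index's
#' sign. Cells on the axes (velocity 0 or density 0) have no direction and
#' are excluded, as are masked cells.
#'
#' @param grid an [mtf_grid()].
#' @param convention passed to [ripple_direction()].
#' @return scalar index in `[-1, 1]`.
#' @export
direction_asymmetry <- function(grid, convention = c("ratio", "flipped")) {
  stopifnot(inherits(grid, "mtf_grid"))
  convention <- match.arg(convention)
  dir <- outer(grid$velocities_hz, grid$densities_cpo,
               function(v, d) ripple_direction(v, d, convention))
  up <- grid$values[dir == "upward"]
  dn <- grid$values[dir == "downward"]
  up <- up[!is.na(up)]; dn <- dn[!is.na(dn)]
  if (length(up) == 0 || length(dn) == 0)
    stop("grid lacks unmasked cells in one of the two drift directions")
  (mean(dn) - mean(up)) / (mean(dn) + mean(up))
}

#' Average MTF grids across subjects
#'
#' Element-wise average over grids sharing the same axes, either on
#' promptness (default) or on reaction time (averaging `1/mu_p` and
#' inverting back).
#'
#' @param grids list of [mtf_grid()] objects with identical axes.
#' @param on `"promptness"` or `"rt"`.
#' @return an [mtf_grid()] of the averages.
#' @export
average_mtf <- function(grids, on = c("promptness", "rt")) {
  on <- match.arg(on)
  stopifnot(length(grids) >= 1, all(vapply(grids, inherits, logical(1),
                                           "mtf_grid")))
  g1 <- grids[[1]]
  for (g in grids[-1])
    if (!identical(g$velocities_hz, g1$velocities_hz) ||
        !identical(g$densities_cpo, g1$densities_cpo))
      stop("grids must share identical axes")
  arr <- simplify2array(lapply(grids, function(g)
    if (on == "rt") 1 / g$values else g$values))
  avg <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  avg[is.nan(avg)] <- NA_real_
  if (on == "rt") avg <- 1 / avg
  mtf_grid(g1$velocities_hz, g1$densities_cpo, avg,
           catch_false_alarm_rate = mean(vapply(
             grids, function(g) g$catch_false_alarm_rate, numeric(1)),
             na.rm = TRUE))
}

#' Write / read an MTF grid as a long-format CSV
#'
#' Columns: `velocity_hz`, `density_cpo`, `mu_p`, `masked`.
#' @param grid an [mtf_grid()].
#' @param path file path.
#' @return `read_mtf_csv` returns an [mtf_grid()];
#'   `write_mtf_csv` returns `path` invisibly.
#' @export
write_mtf_csv <- function(grid, path) {
  stopifnot(inherits(grid, "mtf_grid"))
  long <- expand.grid(velocity_hz = grid$velocities_hz,
                      density_cpo = grid$densities_cpo,
                      KEEP.OUT.ATTRS = FALSE)
  long$mu_p <- as.vector(grid$values)
  long$masked <- is.na(long$mu_p)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mtf_csv
#' @export
read_mtf_csv <- function(path) {
  long <- utils::read.csv(path)
  vels <- sort(unique(long$velocity_hz))
  dens <- sort(unique(long$density_cpo))
  vals <- matrix(NA_real_, length(vels), length(dens))
  vals[cbind(match(long$velocity_hz, vels),
             match(long$density_cpo, dens))] <- long$mu_p
  mtf_grid(vels, dens, vals)
}

#' Summary report of an MTF grid
#'
#' @param grid an [mtf_grid()].
#' @param convention direction convention for the asymmetry index.
#' @return list with the separability index, direction asymmetry,
#'   cross-sections, masked-cell count and catch false-alarm rate.
#' @export
mtf_report <- function(grid, convention = "ratio") {
  stopifnot(inherits(grid, "mtf_grid"))
  cs <- tryCatch(cross_sections(grid), error = function(e) NULL)
  list(
    separability = tryCatch(separability_index(grid),
                            error = function(e) NA_real_),
    direction_asymmetry = tryCatch(
      direction_asymmetry(grid, convention), error = function(e) NA_real_),
    cross_sections = cs,
    n_masked = sum(is.na(grid$values)),
    n_cells = length(grid$values),
    catch_false_alarm_rate = grid$catch_false_alarm_rate)
}
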