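# Run configuration: a YAML file with a global seed and per-module
# parameter blocks. Unknown keys are rejected so typos fail loudly; every
# stochastic stage derives its own seed from the global seed and the stage
# name via derive_seed().

config_schema <- list(
  seed = "integer",
  out_dir = "character",
  log_level = "character",
  stimuli = list(
    velocities_hz = "numeric", densities_cpo = "numeric",
    trials_per_ripple = "integer", mod_depth = "numeric",
    ripple_dur_s = "numeric", f_min_hz = "numeric", f_max_hz = "numeric",
    carrier_kind = "character", tone_spacing_oct = "numeric"),
  later = list(
    timeout_s = "numeric", min_rt_s = "numeric", min_trials = "integer"),
  mtf = list(min_trials = "integer", convention = "character"),
  pipeline = list(
    mu_base = "numeric", mu_peak = "numeric", peak_velocity_hz = "numeric",
    velocity_bandwidth_oct = "numeric", density_bandwidth_cpo = "numeric",
    sigma_cv = "numeric", false_alarm_rate = "numeric"))

config_defaults <- function() {
  list(
    seed = 1L, out_dir = "ripplemetrics-run", log_level = "info",
    stimuli = list(
      velocities_hz = c(0, 4, 8, 16, 32, 64, 128, 256),
      densities_cpo = seq(-3, 3, by = 0.6),
      trials_per_ripple = 20L, mod_depth = 0.8, ripple_dur_s = 1,
      f_min_hz = 250, f_max_hz = 10000, carrier_kind = "tone-complex",
      tone_spacing_oct = 1 / 20),
    later = list(timeout_s = 2, min_rt_s = 0.08, min_trials = 10L),
    mtf = list(min_trials = 10L, convention = "ratio"),
    pipeline = list(
      mu_base = 2.5, mu_peak = 3.5, peak_velocity_hz = 8,
      velocity_bandwidth_oct = 2.5, density_bandwidth_cpo = 2,
      sigma_cv = 0.2, false_alarm_rate = 0.05))
}

check_unknown_keys <- function(x, schema, path = "") {
  bad <- character(0)
  for (k in names(x)) {
    full <- if (path == "") k else paste0(path, ".", k)
    if (!k %in% names(schema)) {
      bad <- c(bad, full)
    } else if (is.list(schema[[k]]) && is.list(x[[k]])) {
      bad <- c(bad, check_unknown_keys(x[[k]], schema[[k]], full))
    }
  }
  bad
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, fills defaults for
#' everything unspecified, and validates parameter ranges (e.g. modulation
#' depth in `[0, 1]`). The result drives [run_pipeline()]; derived
#' per-stage seeds are a pure function of the global `seed`, so identical
#' configurations yield identical runs.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  bad <- check_unknown_keys(user, config_schema)
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(config_defaults(), user)
  with(cfg$stimuli, {
    if (mod_depth < 0 || mod_depth > 1)
      stop("stimuli.mod_depth must lie in [0, 1]")
    if (!(f_min_hz > 0 && f_min_hz < f_max_hz))
      stop("need 0 < stimuli.f_min_hz < stimuli.f_max_hz")
    if (ripple_dur_s <= 0) stop("stimuli.ripple_dur_s must be > 0")
  })
  if (!(cfg$later$timeout_s > cfg$later$min_rt_s &&
        cfg$later$min_rt_s > 0))
    stop("need later.timeout_s > later.min_rt_s > 0")
  if (cfg$pipeline$false_alarm_rate < 0 ||
      cfg$pipeline$false_alarm_rate > 1)
    stop("pipeline.false_alarm_rate must lie in [0, 1]")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}
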