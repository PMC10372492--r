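# Seed handling: every stochastic operation takes an explicit seed and
# restores the caller's RNG state, so independent streams never interact.

# Set the RNG to `seed` (if non-NULL) and return the previous state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  old
}

rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a per-operation seed from a global seed
#'
#' Deterministic, platform-independent stream splitting: the derived seed is
#' a 31-bit polynomial hash of the global seed, the operation name, and a
#' repetition index, so each (operation, repetition) pair gets an
#' independent, reproducible stream.
#'
#' @param global_seed integer global seed.
#' @param op_name character scalar naming the operation.
#' @param rep repetition index (default 1).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(global_seed, op_name, rep = 1) {
  stopifnot(length(op_name) == 1L, is.character(op_name))
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(global_seed) %% m + m) %% m
  for (code in c(utf8ToInt(op_name), 30011 + as.numeric(rep))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
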