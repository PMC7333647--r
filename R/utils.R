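# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Sub-seeds for pipeline stages and per-patient generators are derived from a
#' single master seed by a fixed counter scheme, so cohorts can be extended
#' (more patients, more repetitions) without reshuffling earlier draws.
#' The scheme is `(master * 48271 + H(stage) + 1009 * index) mod (2^31 - 1)`,
#' where `H` is a small polynomial hash of the stage label. All arithmetic is
#' done in double precision (exact below 2^53) and the result is < 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. "genomic", "image", "cv").
#' @param index nonnegative integer counter (e.g. patient index, repetition).
#' @return an integer seed in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% m
  s <- ((abs(as.numeric(master)) %% m) * 48271) %% m
  as.integer((s + h + 1009 * (as.numeric(index) %% m)) %% m)
}

# Stop with a classed condition so callers/tests can match on class.
stop_cfg <- function(...) {
  stop(errorCondition(paste0(...), class = c("cicr_config_error", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("cicr_data_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fraction in [0,1] check with a helpful message.
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_cfg(name, " must be a single value in [0, 1], got ",
             paste(format(x), collapse = ", "))
  }
  invisible(x)
}
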