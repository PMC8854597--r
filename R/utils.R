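# Internal helpers shared across modules.

#' Derive a reproducible stage seed from a master seed
#'
#' A single pipeline seed fans out to one seed per stage so that any stage can
#' be re-run in isolation and still reproduce its random stream. The derived
#' seed is a deterministic hash of the master seed and the stage name, kept
#' below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer master seed.
#' @param stage character stage name, e.g. `"perturb"`.
#' @param index optional integer sub-index (e.g. replicate number).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) %% 65536
  val <- (abs(seed) %% 2^20) * 1999L + h * 131L + (index %% 2^10) * 7919L
  as.integer(val %% 2147483646)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stops with a srimpute-classed condition so tests can target our errors.
#' @keywords internal
abort_srimpute <- function(msg, class) {
  stop(structure(
    class = c(class, "srimpute_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# One structured log line per pipeline stage.
#' @keywords internal
log_stage <- function(stage, ..., verbose = TRUE) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  details <- paste(..., sep = " ")
  message(sprintf("[srimpute] %s: %s", stage, details))
}
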