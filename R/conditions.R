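# Classed error helpers so callers (and tests) can distinguish failure modes.

stop_with <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "optomo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_geometry <- function(fmt, ...) stop_with("optomo_geometry_error", fmt, ...)
stop_value    <- function(fmt, ...) stop_with("optomo_value_error", fmt, ...)
stop_format   <- function(fmt, ...) stop_with("optomo_format_error", fmt, ...)
stop_io       <- function(fmt, ...) stop_with("optomo_io_error", fmt, ...)
stop_fit      <- function(fmt, ...) stop_with("optomo_fit_error", fmt, ...)
stop_tracking <- function(fmt, ...) stop_with("optomo_tracking_error", fmt, ...)
stop_index    <- function(fmt, ...) stop_with("optomo_index_error", fmt, ...)
stop_config   <- function(fmt, ...) stop_with("optomo_config_error", fmt, ...)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulator internals do not
#' disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
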