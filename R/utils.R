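# Internal helpers shared across modules.

mx_stop <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "mx_error", "error"),
                      call = sys.call(-1)))
}

mx_format_error <- function(msg, ...) mx_stop(msg, "mx_format_error", ...)
mx_validation_error <- function(msg, ...) mx_stop(msg, "mx_validation_error", ...)
mx_io_error <- function(msg, ...) mx_stop(msg, "mx_io_error", ...)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals (half-set splits, simulations) do not
#' disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# number formatting used by all text writers: 10 significant digits keeps
# write/read round trips within 1e-9 relative error while staying readable
mx_num <- function(x) formatC(x, format = "g", digits = 10)
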