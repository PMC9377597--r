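# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions are reproducible without clobbering the
#' user's random stream. With `seed = NULL` the expression runs on the
#' current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# stopifnot-style check with a readable message
.check <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

.is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

.is_binary <- function(x) is.numeric(x) && all(x %in% c(0, 1))
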