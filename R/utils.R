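# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state so
#' that library calls never perturb a user's simulation stream.
#'
#' @param seed single integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with a consistent prefix; all argument-validation errors route here
# so callers can rely on conditionMessage() containing the offending name.
abort_domain <- function(...) {
  stop(paste0(...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
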