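#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never disturb the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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

# Branch lengths formatted for Newick assembly; %.10g survives read.tree.
fmt_len <- function(x) sprintf("%.10g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
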