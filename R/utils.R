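#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the random number generator seeded to \code{seed},
#' then restores the caller's RNG state, so seeded helpers do not perturb
#' the global random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (length(seed) != 1L || is.na(seed) || seed != as.integer(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# single-string assertion used across the package
assertString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop("'", what, "' must be a single non-empty string")
  invisible(x)
}

assertBinaryVector <- function(x, what) {
  if (!is.numeric(x) && !is.logical(x))
    stop("'", what, "' must be a numeric 0/1 vector")
  x <- as.numeric(x)
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("'", what, "' must contain only 0 and 1")
  x
}
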