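# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so generators are deterministic without clobbering the
#' global random stream.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; kept within 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647L)
}

# Symmetry check up to machine-level tolerance.
assertSymmetric <- function(m, what = "matrix", tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    stop(what, " must be a symmetric square matrix", call. = FALSE)
  }
  invisible(TRUE)
}

assertCount <- function(x, what, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  }
  invisible(TRUE)
}
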