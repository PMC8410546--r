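#' @keywords internal
"_PACKAGE"

# Run an expression under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic operations in the package
# go through this so that (inputs, seed) fully determine every output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Moore-Penrose pseudo-inverse
#'
#' SVD-based pseudo-inverse with a relative singular-value tolerance, used
#' wherever an operator construction must survive rank-deficient input.
#'
#' @param x real matrix.
#' @param rtol singular values below \code{rtol * max(singular value)} are
#'   treated as zero.
#' @return the pseudo-inverse of \code{x}.
#' @export
pinv <- function(x, rtol = 1e-12) {
  x <- as.matrix(x)
  s <- svd(x)
  keep <- s$d > rtol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Solve A x = b for symmetric A, falling back to the pseudo-inverse when A is
# (numerically) singular.
sym_solve <- function(A, B) {
  out <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(out) || any(!is.finite(out))) out <- pinv(A) %*% B
  out
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# Row-wise Euclidean distance matrix between the rows of `pos` (n x 3).
distance_matrix <- function(pos) {
  as.matrix(stats::dist(pos))
}

# Pearson correlation that returns NA (instead of erroring/warning) when
# either input is constant.
safe_cor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}
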