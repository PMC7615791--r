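#' @keywords internal
#' @useDynLib dagae, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_symmetric <- function(m, tol = 1e-8, name = "matrix") {
  if (!is_square(m)) stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(name, " is not symmetric within tolerance ", tol, call. = FALSE)
  invisible(TRUE)
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Clips eigenvalues below `floor` up to `floor` and renormalizes to unit
#' diagonal, yielding a symmetric positive semi-definite matrix with ones on
#' the diagonal. Used wherever template perturbation or jitter can push a
#' correlation matrix out of the PSD cone.
#'
#' @param m symmetric matrix (approximate correlation matrix).
#' @param floor smallest eigenvalue allowed after repair.
#' @return a valid correlation matrix of the same dimension.
#' @export
nearest_psd_corr <- function(m, floor = 1e-6) {
  check_symmetric(m, tol = 1e-6, name = "correlation matrix")
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < floor) {
    v <- pmax(e$values, floor)
    m <- e$vectors %*% (v * t(e$vectors))
    m <- (m + t(m)) / 2
  }
  d <- sqrt(diag(m))
  if (any(d <= 0)) stop("degenerate diagonal during PSD repair", call. = FALSE)
  m <- m / tcrossprod(d)
  diag(m) <- 1
  m
}

# Draw n iid N(0, Sigma) vectors (columns). Uses the symmetric eigen square
# root so mildly rank-deficient covariances are handled.
sample_mvn_cols <- function(n, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(stats::rnorm(nrow(sigma) * n), nrow(sigma), n)
  sq %*% z
}
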