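#' Construct a subject record
#'
#' A subject bundles the ROI time-series matrix `F` (N x T), its Pearson BFN
#' `A` (N x N), and the class label `y` with one-hot encoding `[1,0]` for
#' class 0 (control) and `[0,1]` for class 1 (patient).
#'
#' @param id subject identifier.
#' @param F ROI-by-time feature matrix.
#' @param A Pearson connectivity matrix (computed from `F` if `NULL`).
#' @param y class label, 0 or 1.
#' @return a `subject` object.
#' @export
new_subject <- function(id, F, A = NULL, y) {
  if (!is.matrix(F) || !all(is.finite(F)))
    stop("F must be a finite numeric matrix", call. = FALSE)
  if (!(y %in% c(0L, 1L))) stop("label must be 0 or 1", call. = FALSE)
  if (is.null(A)) A <- pearson_bfn(F)
  validate_bfn(A, n = nrow(F))
  structure(list(id = as.character(id), F = F, A = A, y = as.integer(y),
                 y_onehot = if (y == 0L) c(1, 0) else c(0, 1)),
            class = "subject")
}

validate_bfn <- function(A, n = NULL, tol = 1e-10) {
  if (!is_square(A)) stop("BFN must be square", call. = FALSE)
  if (!is.null(n) && nrow(A) != n) stop("BFN dimension mismatch", call. = FALSE)
  if (!all(is.finite(A))) stop("BFN has non-finite entries", call. = FALSE)
  if (max(abs(A - t(A))) > tol) stop("BFN not symmetric within 1e-10", call. = FALSE)
  if (max(abs(diag(A) - 1)) > tol) stop("BFN diagonal must be 1", call. = FALSE)
  if (min(A) < -1 - tol || max(A) > 1 + tol)
    stop("BFN entries must lie in [-1, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Pearson brain functional network from ROI time series
#'
#' Entry (i, j) is the Pearson correlation of rows i and j of `F`. Rows with
#' zero variance get correlation 0 to every other row (and 1 on the
#' diagonal) so that downstream graph convolutions stay finite.
#'
#' @param F N x T matrix of ROI time series, T >= 3.
#' @return symmetric N x N matrix with unit diagonal, entries in \[-1, 1\].
#' @export
pearson_bfn <- function(F) {
  if (!is.matrix(F)) stop("F must be a matrix", call. = FALSE)
  if (!all(is.finite(F))) stop("F has non-finite entries", call. = FALSE)
  if (ncol(F) < 3L) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(F, 1L, stats::sd)
  a <- suppressWarnings(stats::cor(t(F)))
  zero <- sds == 0
  if (any(zero)) {
    a[zero, ] <- 0
    a[, zero] <- 0
  }
  diag(a) <- 1
  a[a > 1] <- 1
  a[a < -1] <- -1
  (a + t(a)) / 2
}
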