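#' Fit the per-ROI linear dimension reducer
#'
#' For each ROI, the T-dimensional time-series vectors of the training
#' subjects are reduced to p dimensions by PCA (principal axes fitted on the
#' training pool for that ROI only). The sign of each axis is fixed so its
#' largest-magnitude loading is positive, making the fit deterministic given
#' input order. After projection, each dimension is rescaled by its
#' training max-abs so reduced features live in \[-1, 1\] — the range of the
#' tanh-bounded encoder output the adversarial prior must be comparable to.
#'
#' @param subjects training subjects only.
#' @param p latent dimension per ROI (default 32).
#' @return a `reducer` object with per-ROI means, rotations and scales.
#' @export
fit_reducer <- function(subjects, p = 32L) {
  if (length(subjects) < 2L) stop("need at least 2 training subjects", call. = FALSE)
  n <- nrow(subjects[[1]]$F); tt <- ncol(subjects[[1]]$F)
  m <- length(subjects)
  max_rank <- min(tt, m - 1L)
  if (p > max_rank)
    stop("p = ", p, " exceeds the PCA rank ", max_rank,
         " (min of T and n_train - 1)", call. = FALSE)
  rois <- lapply(seq_len(n), function(i) {
    x <- t(vapply(subjects, function(s) s$F[i, ], numeric(tt)))  # m x T
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    sv <- svd(xc, nu = 0, nv = p)
    rot <- sv$v
    for (j in seq_len(p)) {
      k <- which.max(abs(rot[, j]))
      if (rot[k, j] < 0) rot[, j] <- -rot[, j]
    }
    z <- xc %*% rot
    scale <- pmax(apply(abs(z), 2L, max), 1e-8)
    list(mean = mu, rotation = rot, scale = scale)
  })
  structure(list(rois = rois, p = as.integer(p), n_rois = n, n_time = tt),
            class = "reducer")
}

#' Reduce a subject's feature matrix to latent node features
#'
#' @param reducer a fitted [fit_reducer()] object.
#' @param F N x T feature matrix.
#' @return N x p matrix of scaled principal-component scores.
#' @export
reduce_features <- function(reducer, F) {
  stopifnot(inherits(reducer, "reducer"))
  if (nrow(F) != reducer$n_rois || ncol(F) != reducer$n_time)
    stop("feature matrix shape does not match the fitted reducer", call. = FALSE)
  out <- matrix(0, reducer$n_rois, reducer$p)
  for (i in seq_len(reducer$n_rois)) {
    r <- reducer$rois[[i]]
    out[i, ] <- ((F[i, ] - r$mean) %*% r$rotation) / r$scale
  }
  out
}

scott_bandwidth <- function(centers) {
  m <- nrow(centers); p <- ncol(centers)
  sig <- mean(apply(centers, 2L, stats::sd))
  b <- sig * m^(-1 / (p + 4))
  if (!is.finite(b) || b <= 0) {
    warning("zero-variance centers; bandwidth floored at 1e-6")
    b <- 1e-6
  }
  b
}

#' Fit the class-conditional kernel density model of the latent node features
#'
#' Estimates, per class, a Gaussian KDE over reduced node features with
#' Scott's-rule bandwidth `b = sigma_hat * m^(-1/(p+4))`. In `per_roi` mode
#' (default) each ROI keeps its own center set per class, so sampled latent
#' matrices preserve ROI identity; `pooled` mode pools all N*n_Y node
#' features of a class into one density.
#'
#' @param reduced list of N x p matrices (one per training subject).
#' @param labels integer vector of class labels (0/1), one per subject.
#' @param mode `"per_roi"` or `"pooled"`.
#' @return a `label_kde` object.
#' @export
fit_kde <- function(reduced, labels, mode = c("per_roi", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(reduced) == length(labels))
  classes <- sort(unique(labels))
  n <- nrow(reduced[[1]]); p <- ncol(reduced[[1]])
  per_class <- lapply(classes, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L)
      stop("need at least 2 subjects per class to fit the KDE", call. = FALSE)
    if (mode == "per_roi") {
      rois <- lapply(seq_len(n), function(i) {
        centers <- t(vapply(reduced[idx], function(h) h[i, ], numeric(p)))
        list(centers = centers, b = scott_bandwidth(centers))
      })
      list(rois = rois, n_class = length(idx))
    } else {
      centers <- do.call(rbind, reduced[idx])
      list(centers = centers, b = scott_bandwidth(centers), n_class = length(idx))
    }
  })
  names(per_class) <- paste0("class", classes)
  structure(list(classes = classes, per_class = per_class, mode = mode,
                 n_rois = n, p = as.integer(p)),
            class = "label_kde")
}

gauss_kde_density <- function(x, centers, b) {
  p <- ncol(centers)
  d2 <- colSums((t(centers) - x)^2)
  mean(exp(-d2 / (2 * b^2))) / ((sqrt(2 * pi) * b)^p)
}

#' Evaluate the fitted label density at a point
#'
#' Normalized Gaussian kernel sum: `(1/(m b^p)) sum_i K((x - h_i)/b)` with
#' `K` the standard (product) normal kernel; integrates to 1 over R^p.
#'
#' @param kde a [fit_kde()] object.
#' @param x query vector of length p.
#' @param class class label.
#' @param roi ROI index (required in `per_roi` mode).
#' @return density value.
#' @export
kde_density <- function(kde, x, class, roi = NULL) {
  cc <- kde_class(kde, class)
  if (kde$mode == "per_roi") {
    if (is.null(roi)) stop("per_roi mode needs a `roi` index", call. = FALSE)
    r <- cc$rois[[roi]]
    gauss_kde_density(x, r$centers, r$b)
  } else {
    gauss_kde_density(x, cc$centers, cc$b)
  }
}

kde_class <- function(kde, class) {
  key <- paste0("class", class)
  if (!key %in% names(kde$per_class))
    stop("no KDE fitted for class ", class, call. = FALSE)
  kde$per_class[[key]]
}

#' Sample a latent node-feature matrix from the label distribution
#'
#' Draws one N x p matrix: in `per_roi` mode row i comes from ROI i's
#' class-conditional KDE (uniform center choice plus isotropic Gaussian
#' noise of sd b); in `pooled` mode all N rows come from the pooled class
#' KDE. Deterministic given `seed`.
#'
#' @param kde a [fit_kde()] object.
#' @param class class label to condition on.
#' @param seed integer seed.
#' @return N x p matrix.
#' @export
sample_matrix <- function(kde, class, seed) {
  cc <- kde_class(kde, class)
  with_seed(seed, sample_matrix_stream(kde, cc))
}

# Draw from the active RNG stream (no reseeding) — used inside training.
sample_matrix_stream <- function(kde, cc) {
  n <- kde$n_rois; p <- kde$p
  if (kde$mode == "per_roi") {
    m_centers <- nrow(cc$rois[[1]]$centers)
    js <- sample.int(m_centers, n, replace = TRUE)
    x <- matrix(stats::rnorm(n * p), n, p)
    for (i in seq_len(n)) {
      r <- cc$rois[[i]]
      x[i, ] <- r$centers[js[i], ] + x[i, ] * r$b
    }
    x
  } else {
    js <- sample.int(nrow(cc$centers), n, replace = TRUE)
    cc$centers[js, , drop = FALSE] + matrix(stats::rnorm(n * p, sd = cc$b), n, p)
  }
}
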