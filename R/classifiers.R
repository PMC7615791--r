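#' Upper-triangle vectorization of a connectivity matrix
#'
#' @param A symmetric N x N matrix.
#' @return vector of length `N(N-1)/2` (column-major upper triangle).
#' @export
upper_tri_vec <- function(A) A[upper.tri(A)]

check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class", call. = FALSE)
}

#' GCN classifier on BFNs
#'
#' Two graph-convolution layers (32 and 16 hidden units, ReLU), mean
#' pooling over nodes, and a final linear layer to 2 softmax outputs. Node
#' features are the rows of the BFN itself (connectivity profiles), so the
#' classifier applies equally to original and generated networks. Trained
#' full-batch with Adam (lr 1e-4), deterministic given `seed`.
#'
#' @param bfns list of symmetric connectivity matrices.
#' @param labels class labels in \{0, 1\}.
#' @param epochs training epochs (default 1000).
#' @param lr Adam learning rate.
#' @param hidden the two GCN widths.
#' @param seed integer seed.
#' @param warm_start optionally, a fitted `gcn_classifier` whose parameters
#'   seed the optimization (used to fine-tune a classifier trained on
#'   original networks with generated networks mixed in).
#' @return a `gcn_classifier` object.
#' @export
gcn_classifier_fit <- function(bfns, labels, epochs = 1000L, lr = 1e-4,
                               hidden = c(32L, 16L), seed = 1L,
                               warm_start = NULL) {
  check_two_classes(labels)
  n_nodes <- nrow(bfns[[1]])
  nsamp <- length(bfns)
  normas <- lapply(bfns, function(a) norm_adj_fwd(a)$out)
  p1s <- lapply(seq_len(nsamp), function(i) normas[[i]] %*% bfns[[i]])
  y1h <- t(vapply(labels, function(y) if (y == 0L) c(1, 0) else c(0, 1), numeric(2)))
  with_seed(seed, {
    par <- if (!is.null(warm_start)) {
      stopifnot(inherits(warm_start, "gcn_classifier"))
      warm_start$params
    } else
      list(W1 = glorot(n_nodes, hidden[1]), W2 = glorot(hidden[1], hidden[2]),
           W3 = glorot(hidden[2], 2L), b3 = numeric(2))
    opt <- adam_init(par)
    for (ep in seq_len(epochs)) {
      g <- zeros_like(par)
      for (i in seq_len(nsamp)) {
        z1 <- p1s[[i]] %*% par$W1
        a1 <- relu(z1)
        p2 <- normas[[i]] %*% a1
        z2 <- p2 %*% par$W2
        a2 <- relu(z2)
        pool <- colMeans(a2)
        logit <- as.vector(pool %*% par$W3) + par$b3
        pr <- exp(logit - max(logit)); pr <- pr / sum(pr)
        dz <- (pr - y1h[i, ]) / nsamp
        g$W3 <- g$W3 + outer(pool, dz)
        g$b3 <- g$b3 + dz
        dpool <- as.vector(par$W3 %*% dz)
        da2 <- matrix(dpool / n_nodes, n_nodes, hidden[2], byrow = TRUE)
        dz2 <- da2 * (z2 > 0)
        g$W2 <- g$W2 + crossprod(p2, dz2)
        dp2 <- tcrossprod(dz2, par$W2)
        dz1 <- crossprod(normas[[i]], dp2) * (z1 > 0)
        g$W1 <- g$W1 + crossprod(p1s[[i]], dz1)
      }
      stp <- adam_step(par, g, opt, lr)
      par <- stp$params; opt <- stp$state
    }
    structure(list(params = par, hidden = hidden, n_nodes = n_nodes),
              class = "gcn_classifier")
  })
}

#' @rdname gcn_classifier_fit
#' @param object a fitted `gcn_classifier`.
#' @param A a single BFN to classify.
#' @return `gcn_classifier_predict`: probability 2-vector.
#' @export
gcn_classifier_predict <- function(object, A) {
  par <- object$params
  na <- norm_adj_fwd(A)$out
  a1 <- relu(na %*% A %*% par$W1)
  a2 <- relu(na %*% a1 %*% par$W2)
  logit <- as.vector(colMeans(a2) %*% par$W3) + par$b3
  pr <- exp(logit - max(logit))
  pr / sum(pr)
}

#' SVM baseline on vectorized BFNs
#'
#' RBF-kernel support vector machine with probability calibration on
#' upper-triangle edge vectors.
#'
#' @param x matrix of feature vectors (one row per network).
#' @param y labels in \{0, 1\}.
#' @param seed seed for the internal probability-calibration CV.
#' @return fitted `e1071::svm` model.
#' @export
svm_fit <- function(x, y, seed = 1L) {
  check_two_classes(y)
  with_seed(seed,
            e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                       probability = TRUE, scale = FALSE))
}

#' @rdname svm_fit
#' @param object fitted model.
#' @param newx matrix of feature vectors to score.
#' @return `svm_predict`: probability of class 1 per row.
#' @export
svm_predict <- function(object, newx) {
  pr <- stats::predict(object, newx, probability = TRUE)
  attr(pr, "probabilities")[, "1"]
}

#' DNN baseline on vectorized BFNs
#'
#' Feed-forward network 128 -> 32 -> 2 (ReLU hidden, softmax output) on
#' standardized upper-triangle edge vectors, trained full-batch with Adam.
#'
#' @param x feature matrix (one row per network).
#' @param y labels in \{0, 1\}.
#' @param epochs,lr training schedule.
#' @param hidden hidden widths.
#' @param seed integer seed.
#' @return a `dnn_classifier` object.
#' @export
dnn_fit <- function(x, y, epochs = 1000L, lr = 1e-4, hidden = c(128L, 32L),
                    seed = 1L) {
  check_two_classes(y)
  mu <- colMeans(x)
  sd0 <- pmax(apply(x, 2L, stats::sd), 1e-8)
  xs <- sweep(sweep(x, 2L, mu), 2L, sd0, "/")
  y1h <- t(vapply(y, function(v) if (v == 0L) c(1, 0) else c(0, 1), numeric(2)))
  widths <- c(ncol(x), hidden, 2L)
  with_seed(seed, {
    par <- lapply(seq_len(length(widths) - 1L),
                  function(i) init_dense(widths[i], widths[i + 1L]))
    opt <- adam_init(par)
    nl <- length(par)
    for (ep in seq_len(epochs)) {
      acts <- vector("list", nl)
      a <- xs
      for (l in seq_len(nl)) {
        z <- sweep(a %*% par[[l]]$W, 2L, par[[l]]$b, "+")
        if (l < nl) {
          acts[[l]] <- list(x = a, mask = z > 0)
          a <- relu(z)
        } else {
          acts[[l]] <- list(x = a)
          a <- softmax_rows(z)
        }
      }
      dz <- (a - y1h) / nrow(xs)
      g <- vector("list", nl)
      for (l in rev(seq_len(nl))) {
        g[[l]] <- list(W = crossprod(acts[[l]]$x, dz), b = colSums(dz))
        if (l > 1L) dz <- tcrossprod(dz, par[[l]]$W) * acts[[l - 1L]]$mask
      }
      stp <- adam_step(par, g, opt, lr)
      par <- stp$params; opt <- stp$state
    }
    structure(list(params = par, mu = mu, sd = sd0), class = "dnn_classifier")
  })
}

#' @rdname dnn_fit
#' @param object fitted model.
#' @param newx feature matrix to score.
#' @return `dnn_predict`: probability of class 1 per row.
#' @export
dnn_predict <- function(object, newx) {
  a <- sweep(sweep(newx, 2L, object$mu), 2L, object$sd, "/")
  nl <- length(object$params)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% object$params[[l]]$W, 2L, object$params[[l]]$b, "+")
    a <- if (l < nl) relu(z) else softmax_rows(z)
  }
  a[, 2L]
}
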