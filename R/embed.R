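#' 2-D t-SNE embedding of a set of BFNs
#'
#' Exact-gradient t-distributed stochastic neighbour embedding of the
#' vectorized upper triangles, for qualitative overlap checks between
#' original and generated networks. Deterministic given `seed`. The O(n^2)
#' exact formulation is used; the sets embedded here are small (hundreds of
#' networks).
#'
#' @param bfns list of connectivity matrices (at least 5).
#' @param perplexity target perplexity (default `min(30, (n-1)/3)`).
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed for the initialization.
#' @return n x 2 matrix of coordinates.
#' @export
embed_2d <- function(bfns, perplexity = NULL, n_iter = 300L, seed = 1L) {
  n <- length(bfns)
  if (n < 5L) stop("need at least 5 networks to embed", call. = FALSE)
  x <- t(vapply(bfns, upper_tri_vec, numeric(length(upper_tri_vec(bfns[[1]])))))
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  d2 <- as.matrix(stats::dist(x))^2

  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0; pj <- w } else {
        pj <- w / sw
        h <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      }
      if (abs(h - log_u) < 1e-5) break
      if (h > log_u) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p[i, -i] <- pj
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  with_seed(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- y * 0
    gains <- y * 0 + 1
    momentum <- 0.5
    for (it in seq_len(n_iter)) {
      ex <- if (it <= 100) 4 else 1
      d2y <- as.matrix(stats::dist(y))^2
      num <- 1 / (1 + d2y)
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      l <- (ex * p - q) * num
      grad <- 4 * (diag(rowSums(l)) - l) %*% y
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- momentum * inc - 100 * gains * grad
      y <- y + inc
      y <- sweep(y, 2L, colMeans(y))
      if (it == 20) momentum <- 0.8
    }
    y
  })
}
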