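# Brute-force reference implementations for small weighted graphs:
# independent oracles for the weighted graph metrics. All operate on a
# nonnegative weight matrix with zero diagonal; distances are 1/weight.

bf_floyd <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

bf_global_eff <- function(w) {
  d <- bf_floyd(w)
  n <- nrow(w)
  off <- d[row(d) != col(d)]
  sum(1 / off[is.finite(off)]) / (n * (n - 1))
}

bf_onnela <- function(w) {
  n <- nrow(w)
  wh <- (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  ci <- numeric(n)
  for (i in 1:n) {
    acc <- 0
    for (j in 1:n) for (q in 1:n)
      if (j != i && q != i && j != q)
        acc <- acc + wh[i, j] * wh[i, q] * wh[j, q]
    ci[i] <- if (k[i] >= 2) acc / (k[i] * (k[i] - 1)) else 0
  }
  ci
}

# betweenness: enumerate all simple paths between each pair, count shortest
bf_betweenness <- function(w) {
  n <- nrow(w)
  paths <- function(s, t, visited) {
    if (s == t) return(list(t))
    out <- list()
    for (v in which(w[s, ] > 0)) {
      if (!(v %in% visited)) {
        for (p in paths(v, t, c(visited, v)))
          out[[length(out) + 1]] <- c(s, p)
      }
    }
    out
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths(s, t, s)
    if (length(ps) == 0) next
    lens <- vapply(ps, function(p)
      sum(1 / w[cbind(p[-length(p)], p[-1])]), numeric(1))
    sh <- ps[abs(lens - min(lens)) < 1e-12]
    for (v in setdiff(1:n, c(s, t))) {
      cnt <- sum(vapply(sh, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + cnt / length(sh)
    }
  }
  btw   # undirected: each unordered pair counted once
}

# mean local efficiency: average inverse distance between the neighbours of
# each vertex, with shortest paths running through the whole graph minus
# that vertex (paths may leave the neighbourhood)
bf_local_eff <- function(w) {
  n <- nrow(w)
  le <- numeric(n)
  for (i in 1:n) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    d <- bf_floyd(w[-i, -i, drop = FALSE])
    nb2 <- match(nb, setdiff(seq_len(n), i))
    dsub <- d[nb2, nb2, drop = FALSE]
    off <- dsub[row(dsub) != col(dsub)]
    le[i] <- sum(1 / off[is.finite(off)]) / (k * (k - 1))
  }
  mean(le)
}

# exhaustive modularity maximization over all partitions (<= 8 nodes)
bf_best_modularity <- function(w) {
  n <- nrow(w)
  m2 <- sum(w)
  deg <- rowSums(w)
  best <- -Inf
  assign_next <- function(labels, next_label) {
    i <- length(labels) + 1
    if (i > n) {
      q <- 0
      for (a in 1:n) for (b in 1:n)
        if (labels[a] == labels[b])
          q <- q + w[a, b] - deg[a] * deg[b] / m2
      best <<- max(best, q / m2)
      return(invisible())
    }
    for (lab in 1:next_label)
      assign_next(c(labels, lab), max(next_label, lab + 1))
  }
  assign_next(integer(0), 1)
  best
}

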