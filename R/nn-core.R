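# Low-level differentiable primitives used by the model networks. Every
# forward returns (out, cache); every backward consumes (grad, cache) and
# returns input/parameter gradients. Written against tight shapes so the
# finite-difference tests can exercise the full chain.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / rowSums(e)
}

# dS for P = softmax_rows(S)
softmax_rows_bwd <- function(P, dP) P * (dP - rowSums(dP * P))

LN_EPS <- 1e-6

layernorm_fwd <- function(x) {
  st <- layernorm_fwd_cpp(x, LN_EPS)
  list(out = st$y, cache = list(y = st$y, inv = st$inv))
}

layernorm_bwd <- function(dy, cache) {
  layernorm_bwd_cpp(dy, cache$y, cache$inv)
}

# --- multi-head self-attention over the N node tokens ---------------------

head_index <- function(d, heads) {
  dh <- d %/% heads
  lapply(seq_len(heads), function(h) ((h - 1L) * dh + 1L):(h * dh))
}

# `x` may stack `nb` independent token sets; attention runs within a block
# (subjects never attend across subjects), while all weight projections run
# as single large products over the stack. The per-block scaled dot-product
# core (with row softmax) is compiled.
mha_fwd <- function(x, p, heads, nb = 1L) {
  d <- ncol(x)
  scal <- 1 / sqrt(d / heads)
  q <- x %*% p$Wq; k <- x %*% p$Wk; v <- x %*% p$Wv
  at <- attn_fwd_cpp(q, k, v, nb, heads, scal)
  u <- at$o %*% p$Wo
  list(out = u,
       cache = list(x = x, q = q, k = k, v = v, o = at$o, pstore = at$p,
                    scal = scal, heads = heads, nb = nb))
}

mha_bwd <- function(du, cache, p) {
  x <- cache$x
  dWo <- crossprod(cache$o, du)
  do <- tcrossprod(du, p$Wo)
  bk <- attn_bwd_cpp(do, cache$q, cache$k, cache$v, cache$pstore,
                     cache$nb, cache$heads, cache$scal)
  dx <- tcrossprod(bk$dq, p$Wq) + tcrossprod(bk$dk, p$Wk) +
    tcrossprod(bk$dv, p$Wv)
  list(dx = dx,
       grads = list(Wq = crossprod(x, bk$dq), Wk = crossprod(x, bk$dk),
                    Wv = crossprod(x, bk$dv), Wo = dWo))
}

# --- symmetric GCN normalization with self-loops --------------------------
# A_hat = D^{-1/2} (A + I) D^{-1/2}, with D the diagonal of row sums of
# |A| + I. Absolute weights keep the degree positive for signed Pearson
# edges; the signed A itself is propagated.

norm_adj_fwd <- function(a) {
  d <- rowSums(abs(a)) + 1
  s <- 1 / sqrt(d)
  sp <- a
  diag(sp) <- diag(sp) + 1
  list(out = sp * tcrossprod(s), cache = list(a = a, s = s, sp = sp))
}

norm_adj_bwd <- function(dahat, cache) {
  s <- cache$s
  da <- dahat * tcrossprod(s)
  pr <- dahat * cache$sp
  ds <- as.vector(pr %*% s) + as.vector(crossprod(pr, s))
  dd <- -0.5 * s^3 * ds
  da + sign(cache$a) * dd
}

# --- Adam -----------------------------------------------------------------
# Parameters are nested lists of numeric arrays; state mirrors the shape.

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

adam_init <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  # moments are mutated in place by the C kernel; parameters come back fresh
  upd <- function(p, g, m, v) {
    if (is.list(p)) Map(upd, p, g, m, v)
    else adam_kernel(p, g, m, v, lr, beta1, beta2, c1, c2, eps)
  }
  list(params = upd(params, grads, state$m, state$v), state = state)
}

# elementwise sum of two gradient trees
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) Map(grad_add, a, b) else a + b
}
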