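#' Model architecture configuration
#'
#' Fixes every shape in the four networks: the two-layer GCN encoder
#' (T -> `enc_hidden` -> `p`, ReLU then tanh), the N-subnetwork
#' discriminator (p -> 32 -> 64 -> 1 per ROI, sigmoid output averaged over
#' ROIs), the five-layer MLP classifier on the flattened latent matrix, and
#' the transformer generator: CT(p, heads\[1\]) -> DU(p -> `du1_dim`) ->
#' CT(du1_dim, heads\[2\]) -> DU(du1_dim -> T) -> CT(T, heads\[3\]) followed
#' by the inner-product/tanh connectivity head. Head counts must divide
#' their layer widths; violations are configuration errors at build time.
#'
#' @param n_rois N, number of ROIs.
#' @param n_timepoints T, feature length (also the generator output width).
#' @param p latent node dimension.
#' @param enc_hidden hidden width of the first GCN layer.
#' @param dis_hidden the two discriminator hidden widths.
#' @param cla_hidden the four classifier hidden widths (output is 2). The
#'   depth (five layers) and output size follow the architecture; widths
#'   are free choices, sized against cohorts of order 10^2 subjects.
#' @param ct_heads head counts of the three connectivity-transformer layers.
#' @param du1_dim output width of the first dimension-upscaling layer.
#' @param variant generator/model variant: `"full"`, `"no_du"` (CT-only
#'   generator at constant width), `"no_ct"` (the two DU affine layers
#'   only), or the module-removal variants `"no_encoder"`,
#'   `"no_discriminator"`, `"no_classifier"` (full architecture, reduced
#'   losses).
#' @param no_du_heads head counts used by the `no_du` variant (all three CT
#'   layers run at width `p`).
#' @return a `dagae_config` object.
#' @export
dagae_config <- function(n_rois = 90L, n_timepoints = 187L, p = 32L,
                         enc_hidden = 64L, dis_hidden = c(32L, 64L),
                         cla_hidden = c(256L, 128L, 64L, 16L),
                         ct_heads = c(4L, 8L, 11L), du1_dim = 64L,
                         variant = "full", no_du_heads = c(4L, 8L, 8L)) {
  variant <- tolower(variant)
  ok <- c("full", "no_du", "no_ct", "no_encoder", "no_discriminator", "no_classifier")
  if (!variant %in% ok)
    stop("unknown variant '", variant, "'; must be one of ",
         paste(ok, collapse = ", "), call. = FALSE)
  cfg <- list(n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
              p = as.integer(p), enc_hidden = as.integer(enc_hidden),
              dis_hidden = as.integer(dis_hidden), cla_hidden = as.integer(cla_hidden),
              ct_heads = as.integer(ct_heads), du1_dim = as.integer(du1_dim),
              variant = variant, no_du_heads = as.integer(no_du_heads))
  gen_dims <- if (variant == "no_du") rep(cfg$p, 3L) else
    c(cfg$p, cfg$du1_dim, cfg$n_timepoints)
  heads <- if (variant == "no_du") cfg$no_du_heads else cfg$ct_heads
  if (variant != "no_ct") {
    bad <- gen_dims %% heads != 0
    if (any(bad))
      stop("head count must divide the CT layer width (",
           paste(sprintf("%d/%d", gen_dims[bad], heads[bad]), collapse = ", "),
           ")", call. = FALSE)
  }
  cfg$gen_dims <- gen_dims
  cfg$gen_heads <- heads
  class(cfg) <- "dagae_config"
  cfg
}

# The output projection of each attention block starts near zero (0.1 x
# Glorot): each CT layer then opens close to its residual identity, and the
# inner-product tanh head starts inside its active range instead of
# saturating (a saturated tanh has an exactly-zero gradient in double
# precision, which would freeze the generator permanently).
init_ct <- function(d) list(Wq = glorot(d, d), Wk = glorot(d, d),
                            Wv = glorot(d, d), Wo = glorot(d, d) * 0.1)

init_dense <- function(nin, nout) list(W = glorot(nin, nout), b = numeric(nout))

#' Initialize all four networks
#'
#' Glorot-uniform weights, zero biases, deterministic given `seed`.
#'
#' @param config a [dagae_config()].
#' @param seed integer seed.
#' @return a `dagae_model` with components `enc`, `dis`, `cla`, `gen`.
#' @export
dagae_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "dagae_config"))
  with_seed(seed, {
    n <- config$n_rois; p <- config$p
    enc <- list(W1 = glorot(config$n_timepoints, config$enc_hidden),
                W2 = glorot(config$enc_hidden, p))
    h1 <- config$dis_hidden[1]; h2 <- config$dis_hidden[2]
    dis <- list(
      W1 = array(stats::runif(p * h1 * n, -sqrt(6 / (p + h1)), sqrt(6 / (p + h1))), c(p, h1, n)),
      b1 = matrix(0, n, h1),
      W2 = array(stats::runif(h1 * h2 * n, -sqrt(6 / (h1 + h2)), sqrt(6 / (h1 + h2))), c(h1, h2, n)),
      b2 = matrix(0, n, h2),
      W3 = matrix(stats::runif(h2 * n, -sqrt(6 / (h2 + 1)), sqrt(6 / (h2 + 1))), h2, n),
      b3 = numeric(n))
    widths <- c(n * p, config$cla_hidden, 2L)
    cla <- lapply(seq_len(length(widths) - 1L),
                  function(i) init_dense(widths[i], widths[i + 1L]))
    gd <- config$gen_dims
    gen <- if (config$variant == "no_ct") {
      list(du1 = init_dense(p, config$du1_dim),
           du2 = init_dense(config$du1_dim, config$n_timepoints))
    } else if (config$variant == "no_du") {
      list(ct1 = init_ct(gd[1]), ct2 = init_ct(gd[2]), ct3 = init_ct(gd[3]))
    } else {
      list(ct1 = init_ct(gd[1]), du1 = init_dense(gd[1], gd[2]),
           ct2 = init_ct(gd[2]), du2 = init_dense(gd[2], gd[3]),
           ct3 = init_ct(gd[3]))
    }
    structure(list(config = config, enc = enc, dis = dis, cla = cla, gen = gen),
              class = "dagae_model")
  })
}

block_rows <- function(b, n) ((b - 1L) * n + 1L):(b * n)

# --- graph convolution ----------------------------------------------------

#' One graph-convolution layer
#'
#' Computes `activation(A_hat %*% Xin %*% W)` with
#' `A_hat = D^{-1/2} (A + I) D^{-1/2}` and `D` the diagonal of row sums of
#' `|A| + I` (absolute weights keep degrees positive for signed Pearson
#' edges; the signed adjacency is what gets propagated).
#'
#' @param A symmetric adjacency (BFN).
#' @param Xin node-feature matrix (rows are nodes).
#' @param W weight matrix.
#' @param activation `"relu"`, `"tanh"` or `"identity"`.
#' @return node-feature matrix of width `ncol(W)`.
#' @export
gcn_layer <- function(A, Xin, W, activation = c("relu", "tanh", "identity")) {
  activation <- match.arg(activation)
  check_symmetric(A, tol = 1e-8, name = "adjacency")
  z <- norm_adj_fwd(A)$out %*% Xin %*% W
  switch(activation, relu = relu(z), tanh = tanh(z), identity = z)
}

# Batched encoder forward over `nb` subjects stacked row-wise. `p1s` (the
# per-subject A_hat %*% F products) can be precomputed once per cohort.
enc_fwd <- function(enc, normAs, fs, p1s = NULL) {
  nb <- length(normAs)
  if (is.null(p1s)) p1s <- lapply(seq_len(nb), function(b) normAs[[b]] %*% fs[[b]])
  p1 <- if (nb == 1L) p1s[[1]] else do.call(rbind, p1s)
  n <- nrow(normAs[[1]])
  z1 <- p1 %*% enc$W1
  r1 <- relu(z1)
  p2 <- matrix(0, nrow(r1), ncol(r1))
  for (b in seq_len(nb)) {
    rb <- block_rows(b, n)
    p2[rb, ] <- normAs[[b]] %*% r1[rb, , drop = FALSE]
  }
  h <- tanh(p2 %*% enc$W2)
  list(out = h, cache = list(p1 = p1, mask = z1 > 0, r1 = r1, p2 = p2,
                             h = h, normAs = normAs, fs = fs, nb = nb, n = n))
}

# dh (stacked) -> encoder weight grads (+ per-subject d(normA) if asked).
enc_bwd <- function(dh, cache, enc, need_dnormA = FALSE) {
  nb <- cache$nb; n <- cache$n
  dz2 <- dh * (1 - cache$h^2)
  dW2 <- crossprod(cache$p2, dz2)
  dp2 <- tcrossprod(dz2, enc$W2)
  dr1 <- matrix(0, nrow(dp2), ncol(dp2))
  for (b in seq_len(nb)) {
    rb <- block_rows(b, n)
    dr1[rb, ] <- crossprod(cache$normAs[[b]], dp2[rb, , drop = FALSE])
  }
  dz1 <- dr1 * cache$mask
  dW1 <- crossprod(cache$p1, dz1)
  out <- list(grads = list(W1 = dW1, W2 = dW2))
  if (need_dnormA) {
    dp1 <- tcrossprod(dz1, enc$W1)
    out$dnormAs <- lapply(seq_len(nb), function(b) {
      rb <- block_rows(b, n)
      tcrossprod(dp2[rb, , drop = FALSE], cache$r1[rb, , drop = FALSE]) +
        tcrossprod(dp1[rb, , drop = FALSE], cache$fs[[b]])
    })
  }
  out
}

#' Encode a subject to its latent node representation
#'
#' Two GCN layers (ReLU then tanh): `H = tanh(A_hat relu(A_hat F W1) W2)`,
#' an N x p matrix with entries in (-1, 1).
#'
#' @param model a [dagae_init()] model (or checkpoint).
#' @param A subject BFN.
#' @param F subject feature matrix.
#' @return N x p latent matrix.
#' @export
encode <- function(model, A, F) {
  cfg <- model$config
  if (!all(dim(F) == c(cfg$n_rois, cfg$n_timepoints)) ||
      !all(dim(A) == c(cfg$n_rois, cfg$n_rois)))
    stop("A must be N x N and F must be N x T", call. = FALSE)
  check_symmetric(A, tol = 1e-8, name = "A")
  enc_fwd(model$enc, list(norm_adj_fwd(A)$out), list(F))$out
}

# --- discriminator --------------------------------------------------------

# `m_stack`: nb subjects' N x p matrices stacked row-wise. Subnetwork i
# consumes rows i, N+i, 2N+i, ... Returns the nb x N per-subnetwork sigmoid
# outputs; D per sample is the row mean. The per-subnetwork loop is
# compiled (hidden activations cached node-major for the backward pass).
dis_fwd <- function(dis, m_stack, nb) {
  fw <- dis_fwd_cpp(m_stack, dis$W1, dis$b1, dis$W2, dis$b2, dis$W3,
                    dis$b3, nb)
  list(sig = fw$sig, d = rowMeans(fw$sig), a1s = fw$a1s, a2s = fw$a2s,
       m_stack = m_stack, nb = nb, n = dim(dis$W1)[3])
}

# dsig: nb x N gradient wrt the per-subnetwork sigmoid outputs.
dis_bwd <- function(dsig, fw, dis, need_dx = FALSE) {
  bk <- dis_bwd_cpp(dsig, fw$m_stack, fw$sig, fw$a1s, fw$a2s,
                    dis$W1, dis$W2, dis$W3, fw$nb, need_dx)
  list(grads = bk[c("W1", "b1", "W2", "b2", "W3", "b3")],
       dx_stack = if (need_dx) bk$dx else NULL)
}

#' Discriminator output for one latent matrix
#'
#' N per-ROI subnetworks (p -> 32 -> 64 -> 1 perceptrons with sigmoid
#' output); subnetwork i sees only row i. The discriminator output is the
#' mean of the N subnetwork outputs, in \[0, 1\].
#'
#' @param model a `dagae_model`.
#' @param M N x p matrix (latent representation or prior sample).
#' @return scalar in \[0, 1\].
#' @export
discriminate <- function(model, M) {
  if (nrow(M) != dim(model$dis$W1)[3])
    stop("input must have one row per ROI subnetwork", call. = FALSE)
  dis_fwd(model$dis, M, 1L)$d
}

# --- classifier -----------------------------------------------------------

# Row-major flatten of each subject's block in the stack.
flatten_stack <- function(m_stack, nb, n) {
  matrix(as.vector(t(m_stack)), nb, n * ncol(m_stack), byrow = TRUE)
}

cla_fwd <- function(cla, m_stack, nb, n) {
  x <- flatten_stack(m_stack, nb, n)
  caches <- vector("list", length(cla))
  for (i in seq_along(cla)) {
    z <- sweep(x %*% cla[[i]]$W, 2L, cla[[i]]$b, "+")
    if (i < length(cla)) {
      a <- relu(z)
      caches[[i]] <- list(x = x, mask = z > 0)
      x <- a
    } else {
      caches[[i]] <- list(x = x)
      x <- softmax_rows(z)
    }
  }
  list(prob = x, caches = caches, nb = nb, n = n)
}

# dz: nb x 2 gradient wrt the final-layer logits (softmax-CE form).
# Returns the gradient wrt the stacked latent input.
cla_bwd <- function(dz, fw, cla, p) {
  grads <- vector("list", length(cla))
  for (i in rev(seq_along(cla))) {
    cc <- fw$caches[[i]]
    grads[[i]] <- list(W = crossprod(cc$x, dz), b = colSums(dz))
    dz <- tcrossprod(dz, cla[[i]]$W)
    if (i > 1L) dz <- dz * fw$caches[[i - 1L]]$mask
  }
  dstack <- matrix(0, fw$nb * fw$n, p)
  for (b in seq_len(fw$nb))
    dstack[block_rows(b, fw$n), ] <- matrix(dz[b, ], fw$n, p, byrow = TRUE)
  list(grads = grads, dstack = dstack)
}

#' Classify a latent representation
#'
#' Flattens H row-wise and applies the five-layer MLP with softmax output.
#'
#' @param model a `dagae_model`.
#' @param H N x p latent matrix.
#' @return probability 2-vector (sums to 1).
#' @export
classify <- function(model, H) {
  as.vector(cla_fwd(model$cla, H, 1L, nrow(H))$prob)
}

# --- generator ------------------------------------------------------------

ct_fwd <- function(p, m, heads, nb = 1L) {
  ln <- layernorm_fwd(m)
  at <- mha_fwd(ln$out, p, heads, nb)
  list(out = m + at$out, cache = list(ln = ln$cache, at = at$cache))
}

ct_bwd <- function(dout, cache, p) {
  bk <- mha_bwd(dout, cache$at, p)
  dm <- dout + layernorm_bwd(bk$dx, cache$ln)
  list(dm = dm, grads = bk$grads)
}

#' Connectivity-transformer layer
#'
#' Pre-norm multi-head self-attention over the N node tokens with a
#' residual connection: `out = M + MHA(LayerNorm(M))`. Output shape equals
#' input shape; `heads` must divide `ncol(M)`.
#'
#' @param params list with `Wq`, `Wk`, `Wv`, `Wo` (d x d each).
#' @param M N x d token matrix.
#' @param heads number of attention heads.
#' @return N x d matrix.
#' @export
ct_layer <- function(params, M, heads) {
  if (ncol(M) %% heads != 0)
    stop("heads (", heads, ") must divide the token width (", ncol(M), ")",
         call. = FALSE)
  ct_fwd(params, M, heads)$out
}

du_fwd <- function(p, m) {
  z <- sweep(m %*% p$W, 2L, p$b, "+")
  list(out = relu(z), cache = list(m = m, mask = z > 0))
}

du_bwd <- function(dout, cache, p) {
  dz <- dout * cache$mask
  list(dm = tcrossprod(dz, p$W),
       grads = list(W = crossprod(cache$m, dz), b = colSums(dz)))
}

gen_stack <- function(cfg) {
  switch(cfg$variant,
         no_ct = c("du1", "du2"),
         no_du = c("ct1", "ct2", "ct3"),
         c("ct1", "du1", "ct2", "du2", "ct3"))
}

# Batched generator: `m` stacks nb subjects' N x p latents; returns the nb
# generated/reconstructed networks as a list.
gen_fwd <- function(gen, cfg, m, nb = 1L) {
  n <- nrow(m) %/% nb
  stack <- gen_stack(cfg)
  caches <- vector("list", length(stack))
  names(caches) <- stack
  hi <- 0L
  for (nm in stack) {
    if (startsWith(nm, "ct")) {
      hi <- hi + 1L
      st <- ct_fwd(gen[[nm]], m, cfg$gen_heads[hi], nb)
    } else st <- du_fwd(gen[[nm]], m)
    caches[[nm]] <- st$cache
    m <- st$out
  }
  outs <- vector("list", nb)
  a_ts <- vector("list", nb)
  for (b in seq_len(nb)) {
    g <- tcrossprod(m[block_rows(b, n), , drop = FALSE])
    a_t <- tanh(g)
    a <- a_t
    diag(a) <- 1
    a_ts[[b]] <- a_t
    outs[[b]] <- a
  }
  list(outs = outs, cache = list(mp = m, a_ts = a_ts, outs = outs,
                                 caches = caches, nb = nb, n = n))
}

# das: list of nb N x N gradients wrt the generated networks.
gen_bwd <- function(das, cache, gen, cfg) {
  nb <- cache$nb; n <- cache$n
  dm <- matrix(0, nrow(cache$mp), ncol(cache$mp))
  for (b in seq_len(nb)) {
    da <- das[[b]]
    diag(da) <- 0                    # diagonal is overwritten to 1
    dg <- da * (1 - cache$a_ts[[b]]^2)
    rb <- block_rows(b, n)
    dm[rb, ] <- (dg + t(dg)) %*% cache$mp[rb, , drop = FALSE]
  }
  stack <- rev(gen_stack(cfg))
  hi <- sum(startsWith(stack, "ct")) + 1L
  grads <- list()
  for (nm in stack) {
    if (startsWith(nm, "ct")) {
      hi <- hi - 1L
      st <- ct_bwd(dm, cache$caches[[nm]], gen[[nm]])
    } else st <- du_bwd(dm, cache$caches[[nm]], gen[[nm]])
    grads[[nm]] <- st$grads
    dm <- st$dm
  }
  list(dm = dm, grads = grads[names(gen)])
}

#' Generate a BFN from a latent node matrix
#'
#' Runs the transformer generator (CT/DU stack per the model variant) and
#' the inner-product connectivity head `tanh(M' M'^T)`; the diagonal is
#' overwritten to 1 to match the Pearson convention.
#'
#' @param model a `dagae_model`.
#' @param M N x p latent matrix (encoder output or prior sample).
#' @return symmetric N x N matrix with entries in \[-1, 1\], unit diagonal.
#' @export
generate <- function(model, M) {
  cfg <- model$config
  if (!all(dim(M) == c(cfg$n_rois, cfg$p)))
    stop("M must be N x p", call. = FALSE)
  gen_fwd(model$gen, cfg, M, 1L)$outs[[1]]
}
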