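ns <- asNamespace("dagae")

test_that("head-count divisibility is enforced at build time", {
  cfg <- dagae_config()
  expect_equal(cfg$gen_dims %% cfg$gen_heads, c(0L, 0L, 0L))  # 32/4, 64/8, 187/11
  expect_error(dagae_config(p = 30), "divide")
  expect_error(dagae_config(n_timepoints = 100), "divide")
  expect_error(dagae_config(variant = "bogus"), "unknown variant")
})

test_that("gcn_layer matches the explicit normalization and propagation", {
  # isolated nodes: degrees are 2 and A + I has diagonal 2, so A_hat = I
  # and the layer is a plain dense map
  a <- diag(3)
  x <- matrix(rnorm(6), 3)
  w <- matrix(rnorm(4), 2)
  out <- gcn_layer(a, x, w, "identity")
  expect_equal(out, x %*% w, tolerance = 1e-12)

  # brute-force loop oracle on a random symmetric 3-node graph
  set.seed(2)
  a <- matrix(runif(9, -1, 1), 3); a <- (a + t(a)) / 2; diag(a) <- 1
  d <- rowSums(abs(a)) + 1
  ahat <- matrix(0, 3, 3)
  sp <- a + diag(3)
  for (i in 1:3) for (j in 1:3) ahat[i, j] <- sp[i, j] / sqrt(d[i] * d[j])
  manual <- ahat %*% x %*% w
  expect_lt(max(abs(gcn_layer(a, x, w, "identity") - manual)), 1e-10)

  # permutation equivariance
  pm <- diag(3)[c(2, 3, 1), ]
  out1 <- gcn_layer(pm %*% a %*% t(pm), pm %*% x, w, "relu")
  expect_lt(max(abs(out1 - pm %*% gcn_layer(a, x, w, "relu"))), 1e-12)

  expect_error(gcn_layer(matrix(runif(9), 3), x, w), "symmetric")
})

test_that("the normalized adjacency of an identity BFN is the identity", {
  a <- diag(4)
  na <- ns$norm_adj_fwd(a)$out
  expect_equal(na, diag(4), tolerance = 1e-12)
})

test_that("encode has the stated shape and range", {
  cfg <- dagae_config()              # N = 90, p = 32
  m <- dagae_init(cfg, seed = 2)
  spec <- cohort_spec(n_per_class = 2, seed = 5)
  s <- generate_cohort(spec)[[1]]
  h <- encode(m, s$A, s$F)
  expect_equal(dim(h), c(90L, 32L))
  expect_true(all(abs(h) < 1))       # tanh range
  m0 <- m
  m0$enc$W1[] <- 0; m0$enc$W2[] <- 0
  expect_equal(encode(m0, s$A, s$F), matrix(0, 90, 32))
})

test_that("discriminate averages per-ROI sigmoid subnetworks", {
  cfg <- tiny_model_config()
  m <- dagae_init(cfg, seed = 3)
  h <- matrix(rnorm(12), 6, 2)
  # zero weights: every subnetwork outputs sigmoid(0) = 0.5
  m0 <- m
  for (nm in names(m0$dis)) m0$dis[[nm]][] <- 0
  expect_equal(discriminate(m0, h), 0.5, tolerance = 1e-12)
  d <- discriminate(m, h)
  expect_true(d >= 0 && d <= 1)
  expect_error(discriminate(m, h[1:3, ]), "one row per ROI")

  # hand-computed two-subnetwork forward pass
  cfg2 <- dagae_config(n_rois = 2, n_timepoints = 14, p = 2, enc_hidden = 3,
                       cla_hidden = c(4, 4, 4, 4), ct_heads = c(1, 2, 7),
                       du1_dim = 4)
  m2 <- dagae_init(cfg2, seed = 1)
  h2 <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  manual <- numeric(2)
  for (i in 1:2) {
    a1 <- pmax(h2[i, ] %*% m2$dis$W1[, , i] + m2$dis$b1[i, ], 0)
    a2 <- pmax(a1 %*% m2$dis$W2[, , i] + m2$dis$b2[i, ], 0)
    manual[i] <- 1 / (1 + exp(-(a2 %*% m2$dis$W3[, i] + m2$dis$b3[i])))
  }
  expect_equal(discriminate(m2, h2), mean(manual), tolerance = 1e-12)
})

test_that("classify is a proper softmax with the closed form on logits", {
  cfg <- tiny_model_config()
  m <- dagae_init(cfg, seed = 4)
  h <- matrix(rnorm(12), 6, 2)
  pr <- classify(m, h)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr > 0 & pr < 1))
  # zero final layer: uniform output
  m0 <- m
  nl <- length(m0$cla)
  m0$cla[[nl]]$W[] <- 0; m0$cla[[nl]]$b[] <- 0
  expect_equal(classify(m0, h), c(0.5, 0.5), tolerance = 1e-12)
  # bias-only logits (a, b) give the closed-form softmax
  m0$cla[[nl]]$b <- c(0.7, -0.4)
  expect_equal(classify(m0, h),
               exp(c(0.7, -0.4)) / sum(exp(c(0.7, -0.4))), tolerance = 1e-12)
})

test_that("attention weights match the softmax oracle and sum to 1", {
  set.seed(9)
  m <- matrix(rnorm(8 * 4), 8)
  q <- m; k <- m; v <- m       # identity Q, K, V maps
  heads <- 2L; dh <- 2
  at <- ns$attn_fwd_cpp(q, k, v, 1L, heads, 1 / sqrt(dh))
  for (h in 1:heads) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    s <- m[, idx] %*% t(m[, idx]) / sqrt(dh)
    e <- exp(s - apply(s, 1, max))
    oracle <- e / rowSums(e)
    prt <- at$p[((h - 1) * 8 + 1):(h * 8), ]   # stored transposed
    expect_lt(max(abs(t(prt) - oracle)), 1e-8)
    expect_equal(colSums(prt), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("a single-token ct_layer reduces to residual plus mapped value", {
  cfg <- tiny_model_config()
  m <- dagae_init(cfg, seed = 5)
  p <- m$gen$ct1
  x <- matrix(c(0.4, -1.2), 1, 2)
  out <- ct_layer(p, x, heads = 1)
  ln <- (x - mean(x)) / sqrt(mean((x - mean(x))^2) + 1e-6)
  manual <- x + (ln %*% p$Wv) %*% p$Wo   # attention weight is exactly 1
  expect_equal(out, manual, tolerance = 1e-10)
  expect_error(ct_layer(p, matrix(rnorm(9), 3), heads = 2), "divide")
})

test_that("generate produces valid connectivity with orthogonal-row zeroes", {
  cfg <- small_model_config()
  m <- dagae_init(cfg, seed = 6)
  x <- matrix(rnorm(20 * 8), 20)
  a <- generate(m, x)
  expect_equal(max(abs(a - t(a))), 0)
  expect_valid_bfn(a)
  # with weights scaled down the tanh range is strictly open
  m_small <- m
  m_small$gen <- rapply(m$gen, function(w) w * 0.05, how = "replace")
  a_small <- generate(m_small, x * 0.2)
  expect_true(all(abs(a_small[upper.tri(a_small)]) < 1))

  # with every attention output map zeroed (CT = identity via the residual)
  # and no DU layers, generate is tanh(M M^T): orthogonal rows give zero
  # off-diagonal entries
  cfg2 <- dagae_config(n_rois = 4, n_timepoints = 14, p = 4,
                       enc_hidden = 4, cla_hidden = c(4, 4, 4, 4),
                       variant = "no_du", no_du_heads = c(2, 2, 2))
  m2 <- dagae_init(cfg2, seed = 7)
  for (nm in names(m2$gen)) m2$gen[[nm]]$Wo[] <- 0
  x2 <- diag(4) * 0.5                # orthogonal rows
  a2 <- generate(m2, x2)
  expect_equal(a2[upper.tri(a2)], rep(0, 6), tolerance = 1e-12)
  expect_equal(diag(a2), rep(1, 4))
})

test_that("all four mappings are deterministic given parameters and input", {
  cfg <- tiny_model_config()
  m <- dagae_init(cfg, seed = 8)
  s <- tiny_cohort()[[1]]
  h <- encode(m, s$A, s$F)
  expect_identical(h, encode(m, s$A, s$F))
  expect_identical(discriminate(m, h), discriminate(m, h))
  expect_identical(classify(m, h), classify(m, h))
  expect_identical(generate(m, h), generate(m, h))
})

test_that("generate . encode yields valid BFNs for random parameters", {
  cfg <- tiny_model_config()
  s <- tiny_cohort()[[2]]
  for (seed in 1:100) {
    m <- dagae_init(cfg, seed = seed)
    a <- generate(m, encode(m, s$A, s$F))
    expect_true(max(abs(a - t(a))) < 1e-10 && all(abs(a) <= 1) &&
                  all(diag(a) == 1))
  }
})

test_that("analytic gradients of the joint objective match finite differences", {
  coh <- tiny_cohort()
  cfg <- tiny_model_config()
  m <- dagae_init(cfg, seed = 5)
  batch <- coh[c(1, 7)]
  w <- c(enc = 1, cla = 1, rec = 1, nrc = 1)
  jb <- ns$joint_grads(m, batch, w)
  total_loss <- function(mm) {
    j <- ns$joint_grads(mm, batch, w)
    j$l_enc + j$l_cla + j$l_rec + j$l_nrc
  }
  check_leaf <- function(comp, path, gleaf) {
    pleaf <- m[[comp]]
    for (p in path) pleaf <- pleaf[[p]]
    ks <- with_seed(length(path) + nchar(comp),
                    sample(length(pleaf), min(4, length(pleaf))))
    for (kk in ks) {
      mm <- m
      node <- mm[[comp]]
      v0 <- pleaf[kk]
      modify <- function(x, pp, k, val) {
        if (length(pp) == 0) { x[k] <- val; return(x) }
        x[[pp[1]]] <- modify(x[[pp[1]]], pp[-1], k, val)
        x
      }
      mm[[comp]] <- modify(mm[[comp]], path, kk, v0 + 1e-6)
      up <- total_loss(mm)
      mm[[comp]] <- modify(mm[[comp]], path, kk, v0 - 1e-6)
      dn <- total_loss(mm)
      num <- (up - dn) / 2e-6
      ana <- gleaf[kk]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
  walk <- function(comp, g, node, path = character()) {
    if (is.list(node)) {
      nms <- names(node)
      for (i in seq_along(node))
        walk(comp, g[[i]], node[[i]],
             c(path, if (is.null(nms)) i else nms[i]))
    } else check_leaf(comp, path, g)
  }
  walk("enc", jb$enc_g, m$enc)
  walk("cla", jb$cla_g, m$cla)
  walk("gen", jb$gen_g, m$gen)
})

test_that("discriminator gradients match finite differences", {
  coh <- tiny_cohort()
  cfg <- tiny_model_config()
  m <- dagae_init(cfg, seed = 5)
  hs <- do.call(rbind, lapply(coh[c(1, 7)], function(s) encode(m, s$A, s$F)))
  xs <- with_seed(3, matrix(rnorm(12 * 2, sd = 0.5), 12, 2))
  fwF <- ns$dis_fwd(m$dis, hs, 2L)
  fwR <- ns$dis_fwd(m$dis, xs, 2L)
  n_sub <- fwF$n
  dsigF <- matrix(1 / (1 - fwF$d) / 2 / n_sub, 2, n_sub)
  dsigR <- matrix(-1 / fwR$d / 2 / n_sub, 2, n_sub)
  g <- ns$grad_add(ns$dis_bwd(dsigF, fwF, m$dis)$grads,
                   ns$dis_bwd(dsigR, fwR, m$dis)$grads)
  ldis_of <- function(dis) {
    fF <- ns$dis_fwd(dis, hs, 2L); fR <- ns$dis_fwd(dis, xs, 2L)
    loss_dis(fF$d, fR$d)
  }
  for (nm in names(g)) {
    ks <- with_seed(nchar(nm), sample(length(m$dis[[nm]]),
                                      min(4, length(m$dis[[nm]]))))
    for (kk in ks) {
      d2 <- m$dis
      v0 <- d2[[nm]][kk]
      d2[[nm]][kk] <- v0 + 1e-6; up <- ldis_of(d2)
      d2[[nm]][kk] <- v0 - 1e-6; dn <- ldis_of(d2)
      num <- (up - dn) / 2e-6
      expect_lt(abs(num - g[[nm]][kk]) /
                  max(1e-6, abs(num) + abs(g[[nm]][kk])), 1e-3)
    }
  }
})
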