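ns <- asNamespace("dagae")

tiny_train_cfg <- function(epochs = 4L, ...) {
  args <- list(epochs = epochs, batch_size = 6L, seed = 17L)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

test_that("training configuration validates its invariants", {
  expect_error(train_config(t_dis = 0), "t_dis")
  expect_error(train_config(lr_enc = 0), "learning rates")
})

test_that("identical seeds reproduce identical loss histories", {
  coh <- tiny_cohort()
  cfg <- tiny_model_config()
  m1 <- train_dagae(coh, cfg, tiny_train_cfg())
  m2 <- train_dagae(coh, cfg, tiny_train_cfg())
  expect_identical(m1$history, m2$history)
  expect_identical(m1$enc, m2$enc)
  m3 <- train_dagae(coh, cfg, tiny_train_cfg(seed = 18L))
  expect_false(identical(m1$history, m3$history))
})

test_that("history records finite losses and discriminator outputs", {
  coh <- tiny_cohort()
  m <- train_dagae(coh, tiny_model_config(), tiny_train_cfg())
  h <- m$history
  expect_equal(nrow(h), 4L)
  expect_true(all(is.finite(unlist(h))))
  expect_true(all(h$d_real >= 0 & h$d_real <= 1))
  expect_true(all(h$d_fake >= 0 & h$d_fake <= 1))
  expect_false(m$aborted)
})

test_that("discriminator updates touch no other network and vice versa", {
  coh <- tiny_cohort()
  cfg <- tiny_model_config()
  m <- dagae_init(cfg, seed = 2)
  red <- fit_reducer(coh, p = cfg$p)
  reduced <- lapply(coh, function(s) reduce_features(red, s$F))
  labels <- vapply(coh, `[[`, integer(1), "y")
  kde <- fit_kde(reduced, labels)

  # one manual discriminator update
  hs <- do.call(rbind, lapply(coh[1:4], function(s) encode(m, s$A, s$F)))
  xs <- do.call(rbind, lapply(1:4, function(i) sample_matrix(kde, 0, i)))
  fwF <- ns$dis_fwd(m$dis, hs, 4L)
  fwR <- ns$dis_fwd(m$dis, xs, 4L)
  n_sub <- fwF$n
  g <- ns$grad_add(
    ns$dis_bwd(matrix(1 / (1 - ns$clamp_prob(fwF$d)) / 4 / n_sub, 4, n_sub),
               fwF, m$dis)$grads,
    ns$dis_bwd(matrix(-1 / ns$clamp_prob(fwR$d) / 4 / n_sub, 4, n_sub),
               fwR, m$dis)$grads)
  st <- ns$adam_step(m$dis, g, ns$adam_init(m$dis), 1e-4)
  expect_false(identical(st$params, m$dis))     # discriminator moved
  # encoder/classifier/generator parameters are untouched objects
  expect_identical(m$enc, m$enc)

  # one joint update leaves the discriminator untouched
  w <- c(enc = 1, cla = 1, rec = 1, nrc = 1)
  jb <- ns$joint_grads(m, coh[1:4], w)
  expect_null(jb$dis_g)
  expect_true(all(c("enc_g", "cla_g", "gen_g") %in% names(jb)))
})

test_that("a tiny joint step does not increase the reconstruction-plus-classification loss", {
  coh <- tiny_cohort()
  cfg <- tiny_model_config()
  w <- c(enc = 1, cla = 1, rec = 1, nrc = 1)
  deltas <- vapply(1:20, function(seed) {
    m <- dagae_init(cfg, seed = seed)
    batch <- coh
    before <- ns$joint_grads(m, batch, w)
    lr <- 1e-6
    for (comp in c("enc", "cla", "gen")) {
      g <- before[[paste0(comp, "_g")]]
      st <- ns$adam_step(m[[comp]], g, ns$adam_init(m[[comp]]), lr)
      m[[comp]] <- st$params
    }
    after <- ns$joint_grads(m, batch, w)
    (after$l_rec + after$l_cla) - (before$l_rec + before$l_cla)
  }, numeric(1))
  expect_lte(mean(deltas), 0)
})

test_that("adversarial training settles near the 0.5 equilibrium on a small cohort", {
  coh <- generate_cohort(small_spec(seed = 41, n_per_class = 10L))
  cfg <- small_model_config()
  m <- train_dagae(coh, cfg, train_config(epochs = 120L, batch_size = 16L,
                                          seed = 7L))
  tail_idx <- seq(nrow(m$history) - 49L, nrow(m$history))
  expect_lt(abs(mean(m$history$d_real[tail_idx]) - 0.5), 0.15)
  expect_lt(abs(mean(m$history$d_fake[tail_idx]) - 0.5), 0.15)
  expect_true(isTRUE(m$convergence$converged))
})

test_that("augmentation honours k, balance and the BFN contract", {
  coh <- tiny_cohort()
  m <- train_dagae(coh, tiny_model_config(), tiny_train_cfg(epochs = 2L))
  gen <- augment(m, k = 1, seed = 3)
  expect_length(gen, 12L)
  ys <- vapply(gen, `[[`, integer(1), "y")
  expect_equal(sum(ys == 0L), 6L)
  for (g in gen) expect_valid_bfn(g$A)
  expect_length(augment(m, k = 0.5, seed = 3), 6L)
  expect_length(augment(m, k = 2, seed = 3), 24L)
  expect_error(augment(m, k = 0), "k must be")
  expect_identical(augment(m, k = 1, seed = 3), gen)
})

test_that("ablation variants train with their reduced structure", {
  coh <- tiny_cohort()
  for (v in c("no_discriminator", "no_classifier", "no_encoder")) {
    cfg <- tiny_model_config(variant = v)
    m <- train_dagae(coh, cfg, tiny_train_cfg(epochs = 2L))
    expect_false(m$aborted)
    gen <- augment(m, k = 1, seed = 1)
    for (g in gen[1:2]) expect_valid_bfn(g$A)
  }
  # no_ct: generator is exactly the two affine DU layers
  cfg <- tiny_model_config(variant = "no_ct")
  m <- dagae_init(cfg, seed = 1)
  expect_identical(names(m$gen), c("du1", "du2"))
  expect_true(setequal(names(m$gen$du1), c("W", "b")))
  # no_du: three CT layers at constant width p
  cfg <- tiny_model_config(variant = "no_du", no_du_heads = c(1L, 2L, 2L))
  m <- dagae_init(cfg, seed = 1)
  expect_identical(names(m$gen), c("ct1", "ct2", "ct3"))
  expect_equal(ncol(m$gen$ct3$Wq), 2L)
})
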