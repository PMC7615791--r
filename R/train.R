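#' Training configuration
#'
#' Optimizer settings for the alternating adversarial optimization: Adam
#' throughout, encoder learning rate 0.001, discriminator/classifier/
#' generator 0.0001, batch size 16, one discriminator step per iteration.
#'
#' @param epochs number of passes over the training set.
#' @param t_dis discriminator steps per batch iteration (>= 1).
#' @param batch_size minibatch size.
#' @param lr_enc,lr_dis,lr_cla,lr_gen Adam learning rates.
#' @param loss_weights named weights for the joint objective terms
#'   (`enc`, `cla`, `rec`, `nrc`); all 1 by default.
#' @param seed run seed (initialization, shuffling, prior sampling).
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 500L, t_dis = 1L, batch_size = 16L,
                         lr_enc = 1e-3, lr_dis = 1e-4, lr_cla = 1e-4,
                         lr_gen = 1e-4,
                         loss_weights = c(enc = 1, cla = 1, rec = 1, nrc = 1),
                         seed = 1L) {
  if (t_dis < 1L) stop("t_dis must be >= 1", call. = FALSE)
  if (any(c(lr_enc, lr_dis, lr_cla, lr_gen) <= 0))
    stop("all learning rates must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), t_dis = as.integer(t_dis),
                 batch_size = as.integer(batch_size), lr_enc = lr_enc,
                 lr_dis = lr_dis, lr_cla = lr_cla, lr_gen = lr_gen,
                 loss_weights = loss_weights, seed = as.integer(seed)),
            class = "train_config")
}

# Evaluate all loss terms of the joint objective on a set of subjects,
# without updating anything. Used for diagnostics and tests.
#' @rdname train_dagae
#' @param model a trained or initialized `dagae_model`.
#' @export
dagae_losses <- function(model, subjects) {
  cfg <- model$config
  nb <- length(subjects)
  normAs <- lapply(subjects, function(s) norm_adj_fwd(s$A)$out)
  fs <- lapply(subjects, `[[`, "F")
  h_stack <- enc_fwd(model$enc, normAs, fs)$out
  gf <- gen_fwd(model$gen, cfg, h_stack, nb)
  nas_rec <- lapply(gf$outs, function(a) norm_adj_fwd(a)$out)
  h_hat <- enc_fwd(model$enc, nas_rec, fs)$out
  l_rec <- mean(vapply(seq_len(nb), function(b)
    loss_rec(subjects[[b]]$A, gf$outs[[b]]), numeric(1)))
  d <- dis_fwd(model$dis, h_stack, nb)$d
  y <- t(vapply(subjects, function(s) s$y_onehot, numeric(2)))
  prob <- cla_fwd(model$cla, h_stack, nb, cfg$n_rois)$prob
  list(l_enc = loss_enc(d), l_cla = loss_cla(prob, y),
       l_rec = l_rec, l_nrc = loss_nrc(h_stack, h_hat),
       d_fake = mean(d))
}

# One joint forward/backward over a batch: losses of the combined objective
# (L_enc + L_cla + L_rec + L_nrc, weighted) and the gradients for encoder,
# classifier and generator. The discriminator is consumed frozen.
joint_grads <- function(model, batch, w,
                        use_enc = TRUE, use_dis = TRUE, use_cla = TRUE,
                        use_nrc = TRUE, normAs = NULL, p1s = NULL,
                        hs_fixed = NULL, ef = NULL) {
  cfg <- model$config
  bsz <- length(batch)
  n <- cfg$n_rois
  if (is.null(normAs)) normAs <- lapply(batch, function(s) norm_adj_fwd(s$A)$out)
  fs <- lapply(batch, `[[`, "F")
  enc_g <- cla_g <- gen_g <- NULL

  if (use_enc) {
    if (is.null(ef)) ef <- enc_fwd(model$enc, normAs, fs, p1s)
    h_stack <- ef$out
  } else h_stack <- do.call(rbind, hs_fixed)

  gf <- gen_fwd(model$gen, cfg, h_stack, bsz)
  l_rec_b <- mean(vapply(seq_len(bsz), function(b)
    loss_rec(batch[[b]]$A, gf$outs[[b]]), numeric(1)))

  l_nrc_b <- 0
  if (use_nrc) {
    na_recs <- lapply(gf$outs, norm_adj_fwd)
    rf <- enc_fwd(model$enc, lapply(na_recs, `[[`, "out"), fs)
    l_nrc_b <- loss_nrc(h_stack, rf$out)
  }

  dh_stack <- matrix(0, nrow(h_stack), ncol(h_stack))
  l_enc_b <- l_cla_b <- d_fake <- NA_real_

  if (use_dis) {
    fwF <- dis_fwd(model$dis, h_stack, bsz)
    l_enc_b <- loss_enc(fwF$d)
    d_fake <- mean(fwF$d)
    dF <- clamp_prob(fwF$d)
    n_sub <- fwF$n
    dsig <- matrix(w[["enc"]] * (-1 / (1 - dF)) / bsz / n_sub, bsz, n_sub)
    bk <- dis_bwd(dsig, fwF, model$dis, need_dx = TRUE)
    dh_stack <- dh_stack + bk$dx_stack
  }
  if (use_cla) {
    fwC <- cla_fwd(model$cla, h_stack, bsz, n)
    yb <- t(vapply(batch, function(s) s$y_onehot, numeric(2)))
    l_cla_b <- loss_cla(fwC$prob, yb)
    dz <- w[["cla"]] * (fwC$prob - yb) / bsz
    bk <- cla_bwd(dz, fwC, model$cla, cfg$p)
    cla_g <- bk$grads
    dh_stack <- dh_stack + bk$dstack
  }

  np <- n * cfg$p
  das <- vector("list", bsz)
  for (b in seq_len(bsz))
    das[[b]] <- w[["rec"]] * sign(gf$outs[[b]] - batch[[b]]$A) / (n^2 * bsz)
  if (use_nrc) {
    sg <- sign(rf$out - h_stack)
    dh_hat <- w[["nrc"]] * sg / (np * bsz)
    rb <- enc_bwd(dh_hat, rf$cache, model$enc, need_dnormA = TRUE)
    enc_g <- grad_add(enc_g, rb$grads)
    for (b in seq_len(bsz))
      das[[b]] <- das[[b]] + norm_adj_bwd(rb$dnormAs[[b]], na_recs[[b]]$cache)
    dh_stack <- dh_stack - dh_hat
  }
  gb <- gen_bwd(das, gf$cache, model$gen, cfg)
  gen_g <- gb$grads
  dh_stack <- dh_stack + gb$dm
  if (use_enc) {
    eb <- enc_bwd(dh_stack, ef$cache, model$enc)
    enc_g <- grad_add(enc_g, eb$grads)
  }
  list(l_enc = l_enc_b, l_cla = l_cla_b, l_rec = l_rec_b, l_nrc = l_nrc_b,
       d_fake = d_fake, enc_g = enc_g, cla_g = cla_g, gen_g = gen_g)
}

#' Train the adversarial graph autoencoder
#'
#' Alternating optimization: per batch iteration, `t_dis` discriminator
#' updates on `-log D(X) - log(1 - D(H))` against matched-class samples X
#' from the label KDE, then one joint Adam update of encoder, classifier
#' and generator on `L_enc + L_cla + L_rec + L_nrc`. Runs a fixed number of
#' epochs and reports equilibrium diagnostics post hoc, so the procedure is
#' deterministic given the seed.
#'
#' @param subjects training subjects only (the KDE prior is fitted on
#'   exactly these).
#' @param model_config a [dagae_config()]; its variant selects ablations.
#' @param config a [train_config()].
#' @param reducer,kde optionally pre-fitted; fitted on `subjects` when NULL.
#' @param kde_mode KDE granularity when fitting internally.
#' @return a `dagae_model` checkpoint with `history` (per-epoch losses and
#'   discriminator outputs), the fitted `reducer`/`kde`, per-class training
#'   counts and a `convergence` report.
#' @export
train_dagae <- function(subjects, model_config, config = train_config(),
                        reducer = NULL, kde = NULL, kde_mode = "per_roi") {
  stopifnot(inherits(model_config, "dagae_config"), inherits(config, "train_config"))
  cfg <- model_config
  variant <- cfg$variant
  use_enc <- variant != "no_encoder"
  use_dis <- !variant %in% c("no_discriminator", "no_encoder")
  use_cla <- !variant %in% c("no_classifier", "no_encoder")
  use_nrc <- use_enc
  w <- config$loss_weights

  if (is.null(reducer)) reducer <- fit_reducer(subjects, p = cfg$p)
  reduced <- lapply(subjects, function(s) reduce_features(reducer, s$F))
  labels <- vapply(subjects, function(s) s$y, integer(1))
  if (is.null(kde)) kde <- fit_kde(reduced, labels, mode = kde_mode)

  n <- length(subjects)
  nb_cols <- c("l_enc", "l_dis", "l_cla", "l_rec", "l_nrc", "d_real", "d_fake")
  history <- matrix(NA_real_, config$epochs, length(nb_cols),
                    dimnames = list(NULL, nb_cols))

  # per-subject constants
  normAs <- lapply(subjects, function(s) norm_adj_fwd(s$A)$out)
  p1s <- lapply(seq_len(n), function(i) normAs[[i]] %*% subjects[[i]]$F)
  y_onehot <- t(vapply(subjects, function(s) s$y_onehot, numeric(2)))

  with_seed(config$seed, {
    model <- dagae_init(cfg, seed = sample.int(.Machine$integer.max - 1L, 1L))
    opt_enc <- adam_init(model$enc); opt_dis <- adam_init(model$dis)
    opt_cla <- adam_init(model$cla); opt_gen <- adam_init(model$gen)
    last_good <- model
    aborted <- FALSE

    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      starts <- seq(1L, n, by = config$batch_size)
      acc <- c(l_enc = 0, l_dis = 0, l_cla = 0, l_rec = 0, l_nrc = 0,
               d_real = 0, d_fake = 0)
      nb_joint <- 0L; nb_dis <- 0L

      for (st in starts) {
        bi <- ord[st:min(st + config$batch_size - 1L, n)]
        bsz <- length(bi)

        # ---- discriminator steps -------------------------------------
        # the encoder is unchanged between the discriminator steps and the
        # joint step of one iteration, so its forward pass is shared
        ef <- if (use_enc)
          enc_fwd(model$enc, normAs[bi], lapply(subjects[bi], `[[`, "F"),
                  p1s[bi]) else NULL
        if (use_dis) {
          h_stack <- ef$out
          for (td in seq_len(config$t_dis)) {
            x_stack <- do.call(rbind, lapply(bi, function(i)
              sample_matrix_stream(kde, kde_class(kde, subjects[[i]]$y))))
            fwF <- dis_fwd(model$dis, h_stack, bsz)
            fwR <- dis_fwd(model$dis, x_stack, bsz)
            dF <- clamp_prob(fwF$d); dR <- clamp_prob(fwR$d)
            l_d <- loss_dis(fwF$d, fwR$d)
            n_sub <- ncol(fwF$sig)
            dsigF <- matrix(1 / (1 - dF) / bsz / n_sub, bsz, n_sub)
            dsigR <- matrix(-1 / dR / bsz / n_sub, bsz, n_sub)
            g <- grad_add(dis_bwd(dsigF, fwF, model$dis)$grads,
                          dis_bwd(dsigR, fwR, model$dis)$grads)
            stp <- adam_step(model$dis, g, opt_dis, config$lr_dis)
            model$dis <- stp$params; opt_dis <- stp$state
            acc["l_dis"] <- acc["l_dis"] + l_d
            acc["d_real"] <- acc["d_real"] + mean(fwR$d)
            acc["d_fake"] <- acc["d_fake"] + mean(fwF$d)
            nb_dis <- nb_dis + 1L
          }
        }

        # ---- joint encoder / classifier / generator step -------------
        jb <- joint_grads(model, subjects[bi], w,
                          use_enc = use_enc, use_dis = use_dis,
                          use_cla = use_cla, use_nrc = use_nrc,
                          normAs = normAs[bi], p1s = p1s[bi],
                          hs_fixed = if (use_enc) NULL else reduced[bi],
                          ef = ef)
        if (use_enc && !is.null(jb$enc_g)) {
          stp <- adam_step(model$enc, jb$enc_g, opt_enc, config$lr_enc)
          model$enc <- stp$params; opt_enc <- stp$state
        }
        if (use_cla && !is.null(jb$cla_g)) {
          stp <- adam_step(model$cla, jb$cla_g, opt_cla, config$lr_cla)
          model$cla <- stp$params; opt_cla <- stp$state
        }
        if (!is.null(jb$gen_g)) {
          stp <- adam_step(model$gen, jb$gen_g, opt_gen, config$lr_gen)
          model$gen <- stp$params; opt_gen <- stp$state
        }
        acc["l_enc"] <- acc["l_enc"] + if (is.na(jb$l_enc)) 0 else jb$l_enc
        acc["l_cla"] <- acc["l_cla"] + if (is.na(jb$l_cla)) 0 else jb$l_cla
        acc["l_rec"] <- acc["l_rec"] + jb$l_rec
        acc["l_nrc"] <- acc["l_nrc"] + jb$l_nrc
        nb_joint <- nb_joint + 1L
      }

      history[epoch, ] <- c(
        acc["l_enc"] / nb_joint,
        if (nb_dis > 0) acc["l_dis"] / nb_dis else NA_real_,
        acc["l_cla"] / nb_joint, acc["l_rec"] / nb_joint,
        acc["l_nrc"] / nb_joint,
        if (nb_dis > 0) acc["d_real"] / nb_dis else NA_real_,
        if (nb_dis > 0) acc["d_fake"] / nb_dis else NA_real_)

      if (!all(is.finite(history[epoch, c("l_rec", "l_nrc")]))) {
        warning("non-finite loss at epoch ", epoch,
                "; returning last good checkpoint")
        aborted <- TRUE
        model <- last_good
        history <- history[seq_len(epoch - 1L), , drop = FALSE]
        break
      }
      last_good <- model
    }
  })

  history <- as.data.frame(history)
  history$epoch <- seq_len(nrow(history))
  tail_n <- min(50L, nrow(history))
  tail_idx <- seq(nrow(history) - tail_n + 1L, nrow(history))
  convergence <- if (use_dis && tail_n > 0) {
    dr <- mean(history$d_real[tail_idx]); df <- mean(history$d_fake[tail_idx])
    list(d_real_tail = dr, d_fake_tail = df,
         converged = is.finite(dr) && is.finite(df) &&
           abs(dr - 0.5) < 0.15 && abs(df - 0.5) < 0.15,
         tail_epochs = tail_n)
  } else list(d_real_tail = NA_real_, d_fake_tail = NA_real_,
              converged = NA, tail_epochs = tail_n)

  model$history <- history
  model$reducer <- reducer
  model$kde <- kde
  model$n_train_class <- c(`0` = sum(labels == 0L), `1` = sum(labels == 1L))
  model$train_ids <- vapply(subjects, function(s) s$id, character(1))
  model$convergence <- convergence
  model$aborted <- aborted
  model$train_config <- config
  model
}

#' Generate class-conditional augmentation networks
#'
#' For each class, draws `round(k * n_train_class)` latent matrices from the
#' class-conditional KDE and decodes them with the trained generator.
#' Generated networks carry their conditioning label and must only ever be
#' added to training data.
#'
#' @param model a trained [train_dagae()] checkpoint.
#' @param kde label KDE (defaults to the one stored in the checkpoint).
#' @param k augmentation multiple (> 0).
#' @param seed integer seed.
#' @return list of records with `A` (generated BFN), `y`, `kind = "generated"`.
#' @export
augment <- function(model, kde = model$kde, k = 1, seed = 1L) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  if (is.null(kde)) stop("no fitted KDE available", call. = FALSE)
  counts <- model$n_train_class
  out <- list()
  seeds <- derive_seeds(seed, sum(round(k * counts)))
  si <- 0L
  for (cl in c(0L, 1L)) {
    n_gen <- round(k * counts[[as.character(cl)]])
    for (j in seq_len(n_gen)) {
      si <- si + 1L
      x <- sample_matrix(kde, cl, seeds[si])
      out[[length(out) + 1L]] <-
        list(A = generate(model, x), y = cl, kind = "generated")
    }
  }
  out
}
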