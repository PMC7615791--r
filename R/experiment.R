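default_model_config <- function(subjects, variant = "full", p = 32L, ...) {
  dagae_config(n_rois = nrow(subjects[[1]]$F),
               n_timepoints = ncol(subjects[[1]]$F),
               p = p, variant = variant, ...)
}

fit_classifier_on <- function(classifier, bfns, labels, cfg) {
  switch(classifier,
         gcn = gcn_classifier_fit(bfns, labels, epochs = cfg$epochs,
                                  lr = cfg$lr, seed = cfg$seed),
         svm = svm_fit(t(vapply(bfns, upper_tri_vec,
                                numeric(length(upper_tri_vec(bfns[[1]]))))),
                       labels, seed = cfg$seed),
         dnn = dnn_fit(t(vapply(bfns, upper_tri_vec,
                                numeric(length(upper_tri_vec(bfns[[1]]))))),
                       labels, epochs = cfg$epochs, lr = cfg$lr,
                       seed = cfg$seed))
}

predict_classifier_on <- function(classifier, fit, bfns) {
  switch(classifier,
         gcn = vapply(bfns, function(a) gcn_classifier_predict(fit, a)[2L],
                      numeric(1)),
         svm = svm_predict(fit, t(vapply(bfns, upper_tri_vec,
                                         numeric(length(upper_tri_vec(bfns[[1]])))))),
         dnn = dnn_predict(fit, t(vapply(bfns, upper_tri_vec,
                                         numeric(length(upper_tri_vec(bfns[[1]])))))))
}

#' Cross-validated augmentation experiment
#'
#' Stratified 5-fold cross-validation: per fold, the adversarial model is
#' trained on the four training folds only (the KDE prior included), the
#' generator augments the training networks `k`-fold, the downstream
#' classifier is fitted on original-plus-generated training data, and
#' evaluation uses exclusively the held-out original fold. Generated data
#' never enters any test set; a leakage guard asserts no test subject fed
#' the augmentation.
#'
#' @param subjects a balanced two-class cohort.
#' @param classifier `"gcn"`, `"svm"` or `"dnn"`.
#' @param augmenter `"dagae"` or `"none"` (plain CV baseline).
#' @param k augmentation multiple.
#' @param model_config a [dagae_config()]; derived from the data if NULL.
#' @param train_cfg a [train_config()] for the adversarial training.
#' @param classifier_cfg list with `epochs`, `lr`, `seed` for the
#'   downstream classifier.
#' @param folds_seed seed of the stratified split.
#' @param augment_seed seed for generator sampling.
#' @param n_folds number of folds.
#' @return list with `folds` (per-fold metric data.frame), `mean` (named
#'   vector of mean metrics) and `reports`.
#' @export
cv_experiment <- function(subjects, classifier = c("gcn", "svm", "dnn"),
                          augmenter = c("dagae", "none"), k = 1,
                          model_config = NULL, train_cfg = train_config(),
                          classifier_cfg = list(epochs = 1000L, lr = 1e-4, seed = 1L),
                          folds_seed = 1L, augment_seed = 1L, n_folds = 5L) {
  classifier <- match.arg(classifier)
  augmenter <- match.arg(augmenter)
  if (is.null(model_config) && augmenter == "dagae")
    model_config <- default_model_config(subjects)
  folds <- five_fold_split(subjects, folds_seed, n_folds = n_folds)
  reports <- vector("list", length(folds))
  rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(subjects), test_idx)
    tr <- subjects[train_idx]
    bfns <- lapply(tr, `[[`, "A")
    labels <- vapply(tr, `[[`, integer(1), "y")
    gen <- NULL
    if (augmenter == "dagae") {
      model <- train_dagae(tr, model_config, train_cfg)
      test_ids <- vapply(subjects[test_idx], `[[`, character(1), "id")
      if (length(intersect(test_ids, model$train_ids)) > 0)
        stop("leakage: test subject present in augmentation input", call. = FALSE)
      gen <- augment(model, k = k, seed = augment_seed + f)
    }
    if (!is.null(gen) && classifier == "gcn") {
      # the graph classifier is pretrained on the original training
      # networks, then fine-tuned with the generated ones mixed in
      pre <- gcn_classifier_fit(bfns, labels, epochs = classifier_cfg$epochs,
                                lr = classifier_cfg$lr,
                                seed = classifier_cfg$seed)
      fit <- gcn_classifier_fit(c(bfns, lapply(gen, `[[`, "A")),
                                c(labels, vapply(gen, `[[`, integer(1), "y")),
                                epochs = classifier_cfg$epochs,
                                lr = classifier_cfg$lr,
                                seed = classifier_cfg$seed + 1L,
                                warm_start = pre)
    } else {
      if (!is.null(gen)) {
        bfns <- c(bfns, lapply(gen, `[[`, "A"))
        labels <- c(labels, vapply(gen, `[[`, integer(1), "y"))
      }
      fit <- fit_classifier_on(classifier, bfns, labels, classifier_cfg)
    }
    te_bfns <- lapply(subjects[test_idx], `[[`, "A")
    te_lab <- vapply(subjects[test_idx], `[[`, integer(1), "y")
    prob1 <- predict_classifier_on(classifier, fit, te_bfns)
    reports[[f]] <- compute_metrics(prob1, te_lab)
    rows[[f]] <- data.frame(fold = f, ACC = reports[[f]]$ACC,
                            SEN = reports[[f]]$SEN, SPE = reports[[f]]$SPE,
                            AUC = reports[[f]]$AUC)
  }
  folds_df <- do.call(rbind, rows)
  list(folds = folds_df,
       mean = colMeans(folds_df[, c("ACC", "SEN", "SPE", "AUC")], na.rm = TRUE),
       reports = reports)
}

#' Augmentation-multiple sweep
#'
#' For each `k`, the mean cross-validated accuracy with `k`-times
#' augmentation minus the un-augmented baseline accuracy (`DeltaACC`),
#' under identical folds. No monotonicity in `k` is assumed.
#'
#' @inheritParams cv_experiment
#' @param k_values augmentation multiples to evaluate.
#' @param out_csv optional path; the table is written there as CSV.
#' @return data.frame with columns `k`, `acc`, `delta_acc`.
#' @export
k_sweep <- function(subjects, k_values = 1:8, classifier = "gcn",
                    model_config = NULL, train_cfg = train_config(),
                    classifier_cfg = list(epochs = 1000L, lr = 1e-4, seed = 1L),
                    folds_seed = 1L, out_csv = NULL) {
  base <- cv_experiment(subjects, classifier = classifier, augmenter = "none",
                        classifier_cfg = classifier_cfg, folds_seed = folds_seed)
  acc0 <- base$mean[["ACC"]]
  rows <- lapply(k_values, function(k) {
    if (k == 0)            # no generated data: DeltaACC is 0 by definition
      return(data.frame(k = 0, acc = acc0, delta_acc = 0))
    res <- cv_experiment(subjects, classifier = classifier, augmenter = "dagae",
                         k = k, model_config = model_config,
                         train_cfg = train_cfg, classifier_cfg = classifier_cfg,
                         folds_seed = folds_seed)
    data.frame(k = k, acc = res$mean[["ACC"]],
               delta_acc = res$mean[["ACC"]] - acc0)
  })
  out <- do.call(rbind, rows)
  attr(out, "acc0") <- acc0
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Module-removal and generator-variant ablations
#'
#' Trains the reduced model named by `variant` and evaluates it with
#' [cv_experiment()]: `no_du` keeps a CT-only generator at constant width,
#' `no_ct` reduces the generator to the two affine DU layers,
#' `no_encoder` / `no_discriminator` / `no_classifier` drop the module and
#' its loss terms.
#'
#' @inheritParams cv_experiment
#' @param variant one of `full`, `no_encoder`, `no_discriminator`,
#'   `no_classifier`, `no_du`, `no_ct` (case-insensitive).
#' @return the [cv_experiment()] result.
#' @export
ablation_run <- function(subjects, variant = "full", classifier = "gcn",
                         k = 1, train_cfg = train_config(),
                         classifier_cfg = list(epochs = 1000L, lr = 1e-4, seed = 1L),
                         folds_seed = 1L, p = 32L) {
  variant <- tolower(variant)
  mcfg <- default_model_config(subjects, variant = variant, p = p)
  cv_experiment(subjects, classifier = classifier, augmenter = "dagae", k = k,
                model_config = mcfg, train_cfg = train_cfg,
                classifier_cfg = classifier_cfg, folds_seed = folds_seed)
}
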