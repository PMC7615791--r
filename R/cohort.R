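#' Specify a synthetic two-class connectome cohort
#'
#' Defines the generative conditions for a balanced two-class cohort of ROI
#' (region-of-interest) BOLD-like time series. Subjects in both classes share
#' a modular correlation template (strong within-module, weak between-module
#' correlation); class 1 differs from class 0 by an additive shift on a fixed
#' random subset of inter-module edges, emulating disease-related abnormal
#' functional connections.
#'
#' @param n_rois number of ROIs (network nodes).
#' @param n_timepoints number of time points per ROI signal.
#' @param n_per_class subjects per class.
#' @param n_modules number of correlation modules; if it does not divide
#'   `n_rois` the remainder is assigned to the last module.
#' @param within_corr,between_corr template correlation inside / between
#'   modules; must satisfy `0 <= between_corr < within_corr <= 1`.
#' @param effect_edges fraction of inter-module edges altered in class 1.
#' @param effect_size additive correlation shift applied to those edges.
#' @param subject_noise_sd sd of the subject-level jitter added to the
#'   template off-diagonal before sampling.
#' @param seed integer seed governing edge selection and all subject draws.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_rois = 90L, n_timepoints = 187L, n_per_class = 75L,
                        n_modules = 5L, within_corr = 0.5, between_corr = 0.1,
                        effect_edges = 0.2, effect_size = 0.3,
                        subject_noise_sd = 0.05, seed = 1L) {
  spec <- list(n_rois = as.integer(n_rois), n_timepoints = as.integer(n_timepoints),
               n_per_class = as.integer(n_per_class), n_modules = as.integer(n_modules),
               within_corr = within_corr, between_corr = between_corr,
               effect_edges = effect_edges, effect_size = effect_size,
               subject_noise_sd = subject_noise_sd, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_rois < 2L) stop("n_rois must be >= 2", call. = FALSE)
    if (n_timepoints < 3L)
      stop("n_timepoints must be >= 3 (Pearson correlation degenerate)", call. = FALSE)
    if (n_per_class < 2L) stop("n_per_class must be >= 2", call. = FALSE)
    if (n_modules < 1L || n_modules > n_rois)
      stop("n_modules must be in [1, n_rois]", call. = FALSE)
    if (!(between_corr >= 0 && between_corr < within_corr && within_corr <= 1))
      stop("need 0 <= between_corr < within_corr <= 1 (fields: within_corr, between_corr)",
           call. = FALSE)
    if (effect_edges < 0 || effect_edges > 1)
      stop("effect_edges must be a fraction in [0,1]", call. = FALSE)
    if (subject_noise_sd < 0) stop("subject_noise_sd must be >= 0", call. = FALSE)
  })
  invisible(spec)
}

# Module label per ROI: equal blocks, remainder folded into the last module.
module_assignment <- function(n_rois, n_modules) {
  size <- n_rois %/% n_modules
  lab <- rep(seq_len(n_modules), each = size)
  if (length(lab) < n_rois) lab <- c(lab, rep(n_modules, n_rois - length(lab)))
  lab
}

#' Build the class-0 and class-1 correlation templates
#'
#' The class-0 template is block-modular. The class-1 template adds
#' `effect_size` to a seeded random subset (`effect_edges` fraction) of
#' inter-module edges, clips off-diagonal entries to \[-0.95, 0.95\] and
#' repairs both templates to valid correlation matrices.
#'
#' @param spec a [cohort_spec()].
#' @return list with `template0`, `template1`, `modules` (ROI module labels)
#'   and `effect_mask` (logical matrix of altered edges).
#' @export
make_class_templates <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_rois
  mod <- module_assignment(n, spec$n_modules)
  same <- outer(mod, mod, "==")
  t0 <- ifelse(same, spec$within_corr, spec$between_corr)
  diag(t0) <- 1

  inter <- which(upper.tri(t0) & !same)
  n_eff <- round(spec$effect_edges * length(inter))
  pick <- if (n_eff > 0) with_seed(spec$seed, sample(inter, n_eff)) else integer(0)
  mask <- matrix(FALSE, n, n)
  mask[pick] <- TRUE
  mask <- mask | t(mask)

  t1 <- t0
  t1[mask] <- t1[mask] + spec$effect_size
  off <- !diag(n)
  t1[off] <- clamp(t1[off], -0.95, 0.95)

  out <- tryCatch(
    list(template0 = nearest_psd_corr(t0), template1 = nearest_psd_corr(t1)),
    error = function(e) stop(
      "templates not PSD-repairable for fields within_corr/between_corr/effect_size: ",
      conditionMessage(e), call. = FALSE))
  c(out, list(modules = mod, effect_mask = mask))
}

#' Simulate one subject's ROI time-series matrix
#'
#' Columns are iid draws from a zero-mean multivariate normal whose
#' covariance is the class template perturbed by subject-level jitter
#' (off-diagonal Gaussian noise of sd `subject_noise_sd`, re-symmetrized and
#' PSD-repaired). Time points are white: Pearson connectivity is invariant
#' to temporal ordering, so autocorrelation would add nothing here.
#'
#' @param template correlation template for the subject's class.
#' @param spec a [cohort_spec()].
#' @param subject_seed integer seed; the draw is deterministic given it.
#' @return `n_rois x n_timepoints` feature matrix.
#' @export
simulate_subject <- function(template, spec, subject_seed) {
  validate_cohort_spec(spec)
  if (spec$n_timepoints < 3L) stop("n_timepoints must be >= 3", call. = FALSE)
  check_symmetric(template, tol = 1e-8, name = "template")
  with_seed(subject_seed, {
    sigma <- template
    if (spec$subject_noise_sd > 0) {
      jit <- matrix(stats::rnorm(length(sigma), sd = spec$subject_noise_sd),
                    nrow(sigma), ncol(sigma))
      jit <- (jit + t(jit)) / 2
      diag(jit) <- 0
      sigma <- nearest_psd_corr(sigma + jit)
    }
    sample_mvn_cols(spec$n_timepoints, sigma)
  })
}

#' Generate a full balanced synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of subjects; each is a list with `id`, `F` (ROI x time
#'   matrix), `A` (Pearson BFN), `y` (0 = control, 1 = patient) and
#'   `y_onehot`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  tpl <- make_class_templates(spec)
  n_tot <- 2L * spec$n_per_class
  seeds <- derive_seeds(spec$seed, n_tot)
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  lapply(seq_len(n_tot), function(i) {
    tm <- if (labels[i] == 0L) tpl$template0 else tpl$template1
    f <- simulate_subject(tm, spec, seeds[i])
    new_subject(id = sprintf("sub-%03d", i), F = f, A = pearson_bfn(f),
                y = labels[i])
  })
}
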