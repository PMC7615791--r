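# Shared fixtures: small cohorts and model configurations sized so that the
# full forward/backward machinery is exercised in seconds. Head counts must
# divide layer widths, hence the specific T values (divisible by 11).

with_seed <- dagae:::with_seed

tiny_spec <- function(seed = 11, ...) {
  args <- list(n_rois = 6L, n_timepoints = 14L, n_per_class = 6L,
               n_modules = 2L, within_corr = 0.5, between_corr = 0.1,
               effect_edges = 0.5, effect_size = 0.3,
               subject_noise_sd = 0.02, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# p = 2 (1 head), du1 = 4 (2 heads), T = 14 (7 heads)
tiny_model_config <- function(...) {
  args <- list(n_rois = 6L, n_timepoints = 14L, p = 2L, enc_hidden = 5L,
               cla_hidden = c(8L, 6L, 5L, 4L), ct_heads = c(1L, 2L, 7L),
               du1_dim = 4L)
  args[names(list(...))] <- list(...)
  do.call(dagae_config, args)
}

# Cohort/model pair used for the reduced training studies: N = 20, T = 44
# (44 = 4 * 11), p = 8.
small_spec <- function(seed = 21, n_per_class = 12L, effect_size = 0.4, ...) {
  args <- list(n_rois = 20L, n_timepoints = 44L, n_per_class = n_per_class,
               n_modules = 4L, within_corr = 0.5, between_corr = 0.1,
               effect_edges = 0.3, effect_size = effect_size,
               subject_noise_sd = 0.05, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

small_model_config <- function(...) {
  args <- list(n_rois = 20L, n_timepoints = 44L, p = 8L, enc_hidden = 16L,
               cla_hidden = c(64L, 32L, 16L, 8L), ct_heads = c(4L, 8L, 11L),
               du1_dim = 64L)
  args[names(list(...))] <- list(...)
  do.call(dagae_config, args)
}

tiny_cohort_cache <- new.env(parent = emptyenv())

tiny_cohort <- function(seed = 11) {
  key <- paste0("c", seed)
  if (is.null(tiny_cohort_cache[[key]]))
    tiny_cohort_cache[[key]] <- generate_cohort(tiny_spec(seed))
  tiny_cohort_cache[[key]]
}

expect_valid_bfn <- function(A) {
  expect_true(all(is.finite(A)))
  expect_lt(max(abs(A - t(A))), 1e-10)
  expect_equal(unname(diag(A)), rep(1, nrow(A)))
  expect_true(min(A) >= -1 && max(A) <= 1)
}
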