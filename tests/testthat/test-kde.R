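make_subjects <- function(n_subj, n_rois, n_time, seed = 1) {
  with_seed(seed, lapply(seq_len(n_subj), function(i)
    new_subject(id = paste0("s", i),
                F = matrix(rnorm(n_rois * n_time), n_rois), y = i %% 2L)))
}

test_that("the per-ROI PCA reducer behaves like PCA", {
  subs <- make_subjects(12, 3, 5)
  # reconstruction error is non-increasing in p, and zero at p = T
  errs <- vapply(1:5, function(p) {
    red <- fit_reducer(subs, p = p)
    sum(vapply(seq_along(subs), function(si) {
      f <- subs[[si]]$F
      tot <- 0
      for (i in 1:3) {
        r <- red$rois[[i]]
        z <- (f[i, ] - r$mean) %*% r$rotation
        rec <- as.vector(z %*% t(r$rotation)) + r$mean
        tot <- tot + sum((f[i, ] - rec)^2)
      }
      tot
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_lt(errs[5], 1e-16)
  expect_error(fit_reducer(subs, p = 6), "rank")
})

test_that("the first principal axis of collinear 2-D features is the line direction", {
  # one ROI, T = 2, points on the line y = 2x (plus the pearson_bfn
  # constraint is bypassed by passing A explicitly)
  ts <- seq(-1, 1, length.out = 10)
  subs <- lapply(seq_along(ts), function(i)
    new_subject(id = paste0("s", i), F = matrix(c(ts[i], 2 * ts[i]), 1),
                A = matrix(1, 1, 1), y = i %% 2L))
  red <- fit_reducer(subs, p = 1)
  axis <- red$rois[[1]]$rotation[, 1]
  expect_equal(abs(sum(axis * c(1, 2) / sqrt(5))), 1, tolerance = 1e-10)
})

test_that("reduced features live in [-1, 1] on the training set", {
  subs <- make_subjects(10, 4, 12)
  red <- fit_reducer(subs, p = 3)
  for (s in subs) {
    h <- reduce_features(red, s$F)
    expect_true(all(abs(h) <= 1 + 1e-12))
  }
})

test_that("kde density has Gaussian closed forms and integrates to 1", {
  # two symmetric centers +/- a in 1-D
  red1 <- list(matrix(c(0.7, -0.7, 0.7, -0.7), 4, 1))
  kde <- fit_kde(rep(red1, 4), labels = c(0, 0, 1, 1), mode = "pooled")
  b <- kde$per_class$class0$b
  expect_equal(kde_density(kde, 0.7, class = 0),
               kde_density(kde, -0.7, class = 0), tolerance = 1e-12)
  # quadrature over a wide grid
  grid <- seq(-8, 8, by = 0.002)
  dens <- vapply(grid, function(x) kde_density(kde, x, class = 0), numeric(1))
  integral <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(grid))
  expect_equal(integral, 1, tolerance = 1e-3)

  # a single repeated center: density at the center is 1 / (b sqrt(2 pi))
  redc <- rep(list(matrix(0.3, 2, 1)), 4)
  ws <- capture_warnings(
    kdec <- fit_kde(redc, labels = c(0, 0, 1, 1), mode = "pooled"))
  expect_true(length(ws) >= 1 && all(grepl("bandwidth", ws)))
  bc <- kdec$per_class$class0$b
  expect_equal(kde_density(kdec, 0.3, class = 0), 1 / (bc * sqrt(2 * pi)),
               tolerance = 1e-9)
})

test_that("kde sampling is seeded, class-conditional and matches its density", {
  subs <- make_subjects(16, 4, 10, seed = 3)
  red <- fit_reducer(subs, p = 2)
  reduced <- lapply(subs, function(s) reduce_features(red, s$F))
  labels <- vapply(subs, `[[`, integer(1), "y")
  kde <- fit_kde(reduced, labels, mode = "per_roi")
  x1 <- sample_matrix(kde, class = 0, seed = 5)
  expect_identical(x1, sample_matrix(kde, class = 0, seed = 5))
  expect_equal(dim(x1), c(4L, 2L))

  # b -> 0 degenerate kernel: every sampled row equals a stored center
  kde0 <- kde
  for (i in 1:4) kde0$per_class$class0$rois[[i]]$b <- 1e-12
  x0 <- sample_matrix(kde0, class = 0, seed = 9)
  for (i in 1:4) {
    cents <- kde$per_class$class0$rois[[i]]$centers
    d <- min(sqrt(colSums((t(cents) - x0[i, ])^2)))
    expect_lt(d, 1e-9)
  }

  # Monte-Carlo moment check on one ROI
  cc <- kde$per_class$class1
  draws <- with_seed(8, vapply(1:2000, function(i)
    dagae:::sample_matrix_stream(kde, cc)[2, ], numeric(2)))
  ctr_mean <- colMeans(cc$rois[[2]]$centers)
  sd_mix <- sqrt(mean(apply(cc$rois[[2]]$centers, 2, stats::var)) +
                   cc$rois[[2]]$b^2)
  expect_lt(max(abs(rowMeans(draws) - ctr_mean)), 4 * sd_mix / sqrt(2000))
})

test_that("1-D samples reproduce the density curve (total variation)", {
  red1 <- lapply(1:10, function(i) matrix(sin(i), 1, 1))
  kde <- fit_kde(red1, labels = rep(c(0, 1), 5), mode = "pooled")
  cc <- kde$per_class$class0
  n_draw <- 50000
  xs <- with_seed(2, vapply(seq_len(n_draw), function(i)
    dagae:::sample_matrix_stream(kde, cc)[1, 1], numeric(1)))
  breaks <- seq(min(xs) - 0.1, max(xs) + 0.1, length.out = 60)
  hcount <- hist(xs, breaks = breaks, plot = FALSE)$density
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dens <- vapply(mid, function(x) kde_density(kde, x, class = 0), numeric(1))
  bw <- diff(breaks)[1]
  tv <- 0.5 * sum(abs(hcount - dens)) * bw
  expect_lt(tv, 0.05)
})

test_that("class-conditional kdes separate when the cohort classes differ", {
  spec <- small_spec(seed = 31, effect_size = 0.5)
  coh <- generate_cohort(spec)
  red <- fit_reducer(coh, p = 4)
  reduced <- lapply(coh, function(s) reduce_features(red, s$F))
  labels <- vapply(coh, `[[`, integer(1), "y")
  kde <- fit_kde(reduced, labels)
  m0 <- colMeans(do.call(rbind, lapply(1:40, function(i)
    sample_matrix(kde, 0, seed = i))))
  m1 <- colMeans(do.call(rbind, lapply(1:40, function(i)
    sample_matrix(kde, 1, seed = 100 + i))))
  expect_gt(max(abs(m0 - m1)), 0.01)
})
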