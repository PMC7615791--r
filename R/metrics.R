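#' Classification metrics from predicted probabilities
#'
#' Confusion counts with class 1 (patient) as positive: `TL` correctly
#' predicted patients, `TN` correctly predicted controls, `FL` controls
#' predicted as patients, `FN` patients predicted as controls. Then
#' `ACC = (TL+TN)/total`, `SEN = TL/(TL+FN)`, `SPE = TN/(TN+FL)`, and AUC
#' by the rank (Mann-Whitney) statistic on the class-1 probabilities.
#' Metrics with a degenerate denominator (no positives / no negatives) are
#' reported as `NA`, not 0.
#'
#' @param prob1 predicted probability of class 1, one per sample.
#' @param labels true labels in \{0, 1\}.
#' @param threshold decision threshold on `prob1` (default 0.5).
#' @return a `metrics_report` list with ACC, SEN, SPE, AUC and the counts.
#' @export
compute_metrics <- function(prob1, labels, threshold = 0.5) {
  if (length(prob1) != length(labels)) stop("length mismatch", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be in {0,1}", call. = FALSE)
  pred <- as.integer(prob1 >= threshold)
  tl <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fl <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  acc <- if (n1 + n0 > 0) (tl + tn) / (n1 + n0) else NA_real_
  sen <- if (n1 > 0) tl / (tl + fn) else NA_real_
  spe <- if (n0 > 0) tn / (tn + fl) else NA_real_
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(prob1)
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  structure(list(ACC = acc, SEN = sen, SPE = spe, AUC = auc,
                 TL = tl, TN = tn, FL = fl, FN = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.4f  SEN %.4f  SPE %.4f  AUC %.4f  (TL %d TN %d FL %d FN %d)\n",
              x$ACC, x$SEN, x$SPE, x$AUC, x$TL, x$TN, x$FL, x$FN))
  invisible(x)
}
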