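#' Stratified five-fold split
#'
#' Partitions a two-class cohort into five folds with per-fold class counts
#' differing by at most one. Deterministic given `seed`.
#'
#' @param subjects list of [new_subject()] records.
#' @param seed integer seed for the shuffles.
#' @param n_folds number of folds (default 5).
#' @return list of integer index vectors, one per fold.
#' @export
five_fold_split <- function(subjects, seed, n_folds = 5L) {
  y <- vapply(subjects, function(s) s$y, integer(1))
  if (length(unique(y)) < 2L)
    stop("cohort contains a single class; stratified split undefined", call. = FALSE)
  folds <- vector("list", n_folds)
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      assign_to <- rep_len(seq_len(n_folds), length(idx))
      for (f in seq_len(n_folds))
        folds[[f]] <- c(folds[[f]], idx[assign_to == f])
    }
  })
  lapply(folds, sort)
}

fmt_matrix <- function(m) apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))

#' Write a cohort to disk (TSV matrices + CSV manifest)
#'
#' One TSV file per subject per matrix (`<id>_F.tsv`, `<id>_A.tsv`) with
#' 17-significant-digit floats, plus `manifest.csv` with columns
#' `subject_id, label, path_F, path_A` (paths relative to `dir`).
#'
#' @param subjects list of subjects.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(subjects, function(s) {
    pf <- paste0(s$id, "_F.tsv"); pa <- paste0(s$id, "_A.tsv")
    writeLines(fmt_matrix(s$F), file.path(dir, pf))
    writeLines(fmt_matrix(s$A), file.path(dir, pa))
    data.frame(subject_id = s$id, label = s$y, path_F = pf, path_A = pa,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file missing: ", path, call. = FALSE)
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                              colClasses = "numeric"))
}

#' Read a cohort from a manifest
#'
#' Inverse of [write_cohort()]; subject invariants (finite F, symmetric
#' unit-diagonal A in \[-1,1\], label in \{0,1\}) are enforced on read.
#'
#' @param manifest_path path to `manifest.csv`.
#' @return list of subjects.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path_F", "path_A")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    if (!(man$label[i] %in% c(0L, 1L)))
      stop("label outside {0,1} in manifest row ", i, ": ", man$label[i], call. = FALSE)
    f <- read_tsv_matrix(file.path(base, man$path_F[i]))
    a <- read_tsv_matrix(file.path(base, man$path_A[i]))
    if (nrow(a) != nrow(f))
      stop("shape mismatch between F and A for subject ", man$subject_id[i], call. = FALSE)
    dimnames(f) <- dimnames(a) <- NULL
    new_subject(id = man$subject_id[i], F = f, A = a, y = man$label[i])
  })
}
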