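#' Stratified k-fold split
#'
#' Partitions sample indices into `k` disjoint test folds whose per-class
#' counts differ from exact proportionality by at most one sample: within
#' each class, a seeded shuffle is dealt round-robin across folds. The same
#' seed always yields the same folds.
#'
#' @param labels Class label per sample (factor or coercible).
#' @param k Number of folds (>= 2). Reduced, with a warning, to the smallest
#'   class size if some class has fewer than `k` members.
#' @param seed Integer seed for the in-class shuffles.
#' @return List of `k` lists, each with integer vectors `train` and `test`.
#' @export
stratified_kfold <- function(labels, k, seed) {
  labels <- droplevels(as.factor(labels))
  if (k < 2) stop("k must be >= 2")
  min_class <- min(table(labels))
  if (min_class < k) {
    warning("reducing k from ", k, " to smallest class size ", min_class)
    k <- min_class
    if (k < 2) stop("smallest class too small for any split")
  }
  assign_fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(assign_fold != f), test = which(assign_fold == f))
  })
}

#' Build a nested (double) cross-validation plan
#'
#' External folds split all samples; for each external fold, internal folds
#' split that fold's training samples only. External test indices therefore
#' never reach any internal split — the guard that keeps evaluation data out
#' of gene scoring and subset optimization.
#'
#' @param ds An `expression_dataset`.
#' @param k_external Number of external folds (default 3).
#' @param k_internal Number of internal folds (default 3).
#' @param seed Integer master seed; internal splits use derived child seeds.
#' @return Object of class `cv_plan`: list of external folds, each with
#'   `train`, `test`, and `internal` (a list of train/test pairs whose
#'   indices refer to the full sample set).
#' @export
build_cv_plan <- function(ds, k_external = 3, k_internal = 3, seed = 1) {
  ext <- stratified_kfold(ds$labels, k_external, derive_seed(seed, 0))
  folds <- lapply(seq_along(ext), function(f) {
    tr <- ext[[f]]$train
    inner <- stratified_kfold(ds$labels[tr], k_internal, derive_seed(seed, f))
    inner <- lapply(inner, function(p) {
      list(train = tr[p$train], test = tr[p$test])
    })
    list(train = tr, test = ext[[f]]$test, internal = inner)
  })
  structure(list(folds = folds, k_external = k_external,
                 k_internal = k_internal, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("cv_plan:", x$k_external, "external x", x$k_internal,
      "internal stratified folds, seed", x$seed, "\n")
  invisible(x)
}
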