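# Final aggregation: the subsets harvested over genetic-ensemble iterations
# are reduced to a per-gene selection frequency, and the top-ranked genes
# are evaluated on external test folds the selection never saw.

#' Rank genes by selection frequency
#'
#' Counts, for every candidate gene, the number of collected iterations
#' whose best subset contains it (presence per iteration, not slot
#' multiplicity — chromosomes hold distinct genes anyway). Ranking is by
#' descending count, ties broken by integer score (when supplied) and then
#' by original gene order.
#'
#' @param coll A `subset_collection` from [run_ge()].
#' @param gene_ids Candidate gene identifiers the subset indices refer to.
#' @param integer_scores Optional integer scores used as first tie-break.
#' @return Data frame with columns `gene`, `count`, in rank order.
#' @export
selection_frequency <- function(coll, gene_ids, integer_scores = NULL) {
  if (length(coll$subsets) == 0) stop("empty collection")
  counts <- integer(length(gene_ids))
  for (s in coll$subsets) counts[s] <- counts[s] + 1L
  if (is.null(integer_scores)) integer_scores <- integer(length(gene_ids))
  ord <- order(-counts, -integer_scores, seq_along(gene_ids))
  data.frame(gene = gene_ids[ord], count = counts[ord],
             stringsAsFactors = FALSE)
}

#' Evaluate top-ranked genes on held-out data
#'
#' For each `N` in `n_list`, restricts train and test to the top-N ranked
#' genes, fits every bank member on the training slice, and reports
#' balanced accuracy per classifier, their mean, and the majority-voting
#' balanced accuracy on the test slice.
#'
#' @param ranking Data frame from [selection_frequency()] (or any data
#'   frame with a `gene` column in rank order).
#' @param n_list Top-N sizes to evaluate (default 5, 10, 15, 20).
#' @param train,test `expression_dataset` slices; `test` must be data the
#'   ranking never touched.
#' @param bank A [classifier_bank()].
#' @return Data frame with columns `n`, one column per classifier, `mean`,
#'   and `majority_voting`, accuracies in `[0, 1]`.
#' @export
evaluate_top_genes <- function(ranking, n_list = c(5, 10, 15, 20), train,
                               test, bank) {
  if (max(n_list) > nrow(ranking)) {
    stop("n_list exceeds ranking length (", nrow(ranking), ")")
  }
  rows <- lapply(n_list, function(n) {
    top <- ranking$gene[seq_len(n)]
    fv <- evaluate_subset(top, train, test, bank,
                          w1 = 0.5, w2 = 0.5)
    out <- as.list(fv$per_classifier)
    out$mean <- fv$blocking
    out$majority_voting <- fv$voting
    c(list(n = n), out)
  })
  do.call(rbind, lapply(rows, as.data.frame, check.names = FALSE))
}

#' Dataset-level gene ranking across folds and repeats
#'
#' Sums selection counts over every (fold, repeat) ranking of a pipeline
#' run, with summed integer scores as the tie-break, giving one overall
#' top-gene list per dataset — the list a study would report.
#'
#' @param result An `mfge_result` from [run_mfge()].
#' @return Data frame with columns `gene`, `count`, in rank order.
#' @export
overall_ranking <- function(result) {
  counts <- numeric(0)
  scores <- numeric(0)
  for (key in names(result$rankings)) {
    rk <- result$rankings[[key]]
    f <- as.integer(sub("fold(\\d+)_rep\\d+", "\\1", key))
    stab <- result$score_tables[[f]]
    for (g in rk$gene) {
      if (is.na(counts[g])) counts[g] <- 0
      counts[g] <- counts[g] + rk$count[rk$gene == g]
    }
    for (i in seq_len(nrow(stab))) {
      g <- stab$gene[i]
      if (is.na(scores[g])) scores[g] <- 0
      scores[g] <- scores[g] + stab$integer_score[i]
    }
  }
  ids <- names(counts)
  ord <- order(-counts, -scores[ids], seq_along(ids))
  data.frame(gene = ids[ord], count = unname(counts[ord]),
             stringsAsFactors = FALSE)
}

#' Convergence and subset-size comparison of two engines
#'
#' Compares matched runs of the map-enhanced engine against a baseline
#' (e.g. the uniform-map engine) on mean termination generation and mean
#' subset size, with a one-tailed paired t-test of enhanced < baseline per
#' criterion. Runs are paired by position (same seed).
#'
#' @param enhanced,baseline Lists of `subset_collection` objects of equal
#'   length, one per paired run.
#' @return Data frame with one row per criterion (`generation`, `size`):
#'   means of both methods and the one-tailed paired p-value. A degenerate
#'   all-zero-difference pairing reports p = 0.5 (no evidence either way).
#' @export
convergence_summary <- function(enhanced, baseline) {
  if (length(enhanced) != length(baseline)) {
    stop("need equal numbers of paired runs")
  }
  if (length(enhanced) < 2) stop("need >= 2 paired runs")
  one_sided_p <- function(a, b) {
    d <- a - b
    if (sd(d) == 0) {
      return(if (mean(d) == 0) 0.5 else if (mean(d) < 0) 0 else 1)
    }
    t.test(a, b, paired = TRUE, alternative = "less")$p.value
  }
  gen_e <- vapply(enhanced, function(c) mean(c$generation), numeric(1))
  gen_b <- vapply(baseline, function(c) mean(c$generation), numeric(1))
  size_e <- vapply(enhanced, function(c) mean(c$size), numeric(1))
  size_b <- vapply(baseline, function(c) mean(c$size), numeric(1))
  data.frame(
    criterion = c("generation", "size"),
    enhanced_mean = c(mean(gen_e), mean(size_e)),
    baseline_mean = c(mean(gen_b), mean(size_b)),
    p_value = c(one_sided_p(gen_e, gen_b), one_sided_p(size_e, size_b)),
    stringsAsFactors = FALSE
  )
}
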