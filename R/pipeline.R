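# End-to-end selection pipeline under the double cross-validation protocol:
#
#   standardize -> normalize -> external 3-fold split
#   per external fold:
#     BSS/WSS ranking on external-train -> top-k prefilter
#     internal 3-fold split of external-train
#     filter scores on internal-train sets -> softmax fusion -> frequency map
#     genetic ensemble (fitness = mean combined fitness over internal folds)
#     selection-frequency ranking -> top-N evaluation on external test
#
# External test samples are excluded from prefiltering, scoring, and the
# genetic search; they are only ever classified.

#' Full pipeline run configuration
#'
#' Defaults reproduce the reference protocol: five filters, the
#' five-classifier bank, 3x3 stratified double cross-validation, a top-200
#' BSS/WSS prefilter, top-5/10/15/20 evaluation, 5 repeats of the selection
#' stage, and the [ga_config()] defaults.
#'
#' @param filters Filter subset, see [filter_names()].
#' @param classifiers Bank composition, see [classifier_names()].
#' @param k_external,k_internal Stratified fold counts.
#' @param prefilter_k Genes kept by the BSS/WSS prefilter (capped at the
#'   gene count).
#' @param n_list Top-N sizes evaluated on external test folds.
#' @param repeats Independent repeats of the selection stage per fold.
#' @param ga A [ga_config()]; its `seed` is overridden by derived seeds.
#' @param uniform_map If `TRUE`, swap in the uniform frequency map (the
#'   plain genetic-ensemble baseline) instead of the multi-filter map.
#' @param seed Master seed; every stochastic stage draws a seed derived
#'   from it.
#' @return Object of class `mfge_config`.
#' @export
mfge_config <- function(filters = filter_names(),
                        classifiers = classifier_names(),
                        k_external = 3, k_internal = 3, prefilter_k = 200,
                        n_list = c(5, 10, 15, 20), repeats = 5,
                        ga = ga_config(), uniform_map = FALSE, seed = 1) {
  structure(as.list(environment()), class = "mfge_config")
}

zero_fitness <- function(bank) {
  structure(list(blocking = 0, voting = 0, combined = 0,
                 per_classifier = setNames(rep(0, bank$L), bank$names)),
            class = "fitness_value")
}

#' Build the caching wrapper-fitness function for one external fold
#'
#' The fitness of a subset is the mean combined fitness over the fold's
#' internal train/test splits. Results are cached by sorted subset key;
#' the cache persists across generations and genetic-ensemble iterations,
#' and may be shared between engines evaluated on the same fold.
#'
#' @param internal_slices List of internal splits, each a list with
#'   `train` and `test` `expression_dataset` slices (see
#'   [prepare_fold()]).
#' @param bank A [classifier_bank()].
#' @param w1,w2 Blocking and voting contribution weights.
#' @return A function mapping a vector of gene indices to a
#'   `fitness_value`.
#' @export
make_fitness_fn <- function(internal_slices, bank, w1, w2) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(subset) {
    if (length(subset) == 0) return(zero_fitness(bank))
    key <- paste(sort(subset), collapse = ",")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    parts <- lapply(internal_slices, function(sl) {
      evaluate_subset(subset, sl$train, sl$test, bank, w1, w2)
    })
    fv <- structure(
      list(blocking = mean(vapply(parts, `[[`, numeric(1), "blocking")),
           voting = mean(vapply(parts, `[[`, numeric(1), "voting")),
           combined = mean(vapply(parts, `[[`, numeric(1), "combined")),
           per_classifier = rowMeans(vapply(parts, `[[`,
                                            numeric(bank$L),
                                            "per_classifier"))),
      class = "fitness_value")
    assign(key, fv, envir = cache)
    fv
  }
}

#' Prepare one external fold for scoring and selection
#'
#' Ranks genes by BSS/WSS on the fold's training samples only, keeps the
#' top `config$prefilter_k`, and slices the internal splits plus the
#' external train/test sets down to those genes. External test samples
#' never influence the prefilter.
#'
#' @param ds A preprocessed (standardized, normalized)
#'   `expression_dataset`.
#' @param fold One element of `build_cv_plan(...)$folds`.
#' @param config An [mfge_config()].
#' @return List with `genes` (retained ids), `internal` (list of
#'   train/test slice pairs), `train` and `test` slices.
#' @export
prepare_fold <- function(ds, fold, config) {
  train_ds <- slice_dataset(ds, samples = fold$train, check_classes = TRUE)
  scores <- bss_wss_scores(train_ds)
  k <- min(config$prefilter_k, n_genes(ds))
  kept <- prefilter_top_k(train_ds, scores, k)$gene_ids
  internal <- lapply(fold$internal, function(p) {
    list(train = slice_dataset(ds, genes = kept, samples = p$train),
         test = slice_dataset(ds, genes = kept, samples = p$test))
  })
  list(
    genes = kept,
    internal = internal,
    train = slice_dataset(ds, genes = kept, samples = fold$train),
    test = slice_dataset(ds, genes = kept, samples = fold$test)
  )
}

#' Fused filter score table for one prepared fold
#'
#' Raw filter scores are computed on each internal-train set, averaged
#' across the internal folds, then fused by softmax scaling, summation
#' and integer mapping ([combine_scores()]).
#'
#' @param prep A fold from [prepare_fold()].
#' @param config An [mfge_config()] naming the filter set.
#' @param seed Seed for any stochastic filter component.
#' @return A `filter_score_table` with scaled, total and integer columns.
#' @export
fold_score_table <- function(prep, config, seed) {
  raw <- NULL
  for (i in seq_along(prep$internal)) {
    tab <- score_all_filters(prep$internal[[i]]$train,
                             filter_set = config$filters,
                             seed = derive_seed(seed, 10, i))
    if (is.null(raw)) {
      raw <- tab
    } else {
      for (f in setdiff(colnames(tab), "gene")) {
        raw[[f]] <- raw[[f]] + tab[[f]]
      }
    }
  }
  for (f in setdiff(colnames(raw), "gene")) {
    raw[[f]] <- raw[[f]] / length(prep$internal)
  }
  combine_scores(raw)
}

#' Run the multi-filter enhanced genetic-ensemble pipeline
#'
#' Executes the full double cross-validated selection and evaluation
#' protocol on a labelled expression dataset. See the package vignette for
#' the stage-by-stage account.
#'
#' @param ds An `expression_dataset` (raw; standardization and
#'   normalization are applied internally).
#' @param config An [mfge_config()].
#' @return Object of class `mfge_result`: list with
#'   `evaluation` (data frame: fold, repeat, n, per-classifier balanced
#'   accuracies, their mean, majority voting), `convergence` (data frame:
#'   fold, repeat, mean termination generation, mean subset size),
#'   `rankings` (per fold/repeat selection-frequency rankings),
#'   `collections` (per fold/repeat `subset_collection`s),
#'   `score_tables` (per fold fused score tables), and `config`.
#' @export
run_mfge <- function(ds, config = mfge_config()) {
  ds <- normalize_genes(standardize_genes(ds))
  plan <- build_cv_plan(ds, config$k_external, config$k_internal,
                        derive_seed(config$seed, 1))
  eval_rows <- list()
  conv_rows <- list()
  rankings <- list()
  collections <- list()
  score_tables <- list()

  for (f in seq_along(plan$folds)) {
    prep <- prepare_fold(ds, plan$folds[[f]], config)
    stab <- fold_score_table(prep, config, derive_seed(config$seed, 2, f))
    score_tables[[f]] <- stab
    map <- if (config$uniform_map) {
      uniform_frequency_map(stab$gene, seed = derive_seed(config$seed, 3, f))
    } else {
      build_frequency_map(stab, seed = derive_seed(config$seed, 3, f))
    }
    bank <- classifier_bank(config$classifiers,
                            seed = derive_seed(config$seed, 4, f))
    fitness_fn <- make_fitness_fn(prep$internal, bank,
                                  config$ga$w1, config$ga$w2)
    for (r in seq_len(config$repeats)) {
      cfg <- config$ga
      cfg$seed <- derive_seed(config$seed, 5, f, r)
      coll <- run_ge(fitness_fn, map, cfg)
      ranking <- selection_frequency(coll, stab$gene, stab$integer_score)
      key <- sprintf("fold%d_rep%d", f, r)
      collections[[key]] <- coll
      rankings[[key]] <- ranking
      n_ok <- config$n_list[config$n_list <= length(prep$genes)]
      ev <- evaluate_top_genes(ranking, n_ok, prep$train, prep$test, bank)
      ev <- cbind(fold = f, rep = r, ev)
      eval_rows[[key]] <- ev
      conv_rows[[key]] <- data.frame(
        fold = f, rep = r,
        mean_generation = mean(coll$generation),
        mean_size = mean(coll$size)
      )
    }
  }
  structure(
    list(evaluation = do.call(rbind, c(eval_rows, make.row.names = FALSE)),
         convergence = do.call(rbind, c(conv_rows,
                                        make.row.names = FALSE)),
         rankings = rankings, collections = collections,
         score_tables = score_tables, config = config),
    class = "mfge_result"
  )
}

#' Aggregate an `mfge_result` into a report table
#'
#' Grand means over folds and repeats, per top-N size: one row per
#' classifier plus the mean-over-classifiers and majority-voting rows,
#' with the standard deviation across repeats (of fold-averaged values).
#'
#' @param result An `mfge_result`.
#' @return Data frame with columns `n`, `classifier`, `accuracy`, `sd`.
#' @export
mfge_report <- function(result) {
  ev <- result$evaluation
  clf_cols <- setdiff(colnames(ev), c("fold", "rep", "n"))
  out <- list()
  for (n in unique(ev$n)) {
    sub <- ev[ev$n == n, , drop = FALSE]
    # average over folds within repeat, then mean +/- sd across repeats
    for (cc in clf_cols) {
      per_rep <- tapply(sub[[cc]], sub$rep, mean)
      out[[length(out) + 1]] <- data.frame(
        n = n, classifier = cc, accuracy = mean(per_rep),
        sd = if (length(per_rep) > 1) sd(per_rep) else 0
      )
    }
  }
  do.call(rbind, out)
}

#' @export
print.mfge_result <- function(x, ...) {
  cat("mfge_result:", length(x$score_tables), "external folds,",
      x$config$repeats, "repeat(s)\n")
  rep_tab <- mfge_report(x)
  mv <- rep_tab[rep_tab$classifier == "majority_voting", , drop = FALSE]
  for (i in seq_len(nrow(mv))) {
    cat(sprintf("  top-%-2d majority voting: %.3f +/- %.3f\n",
                mv$n[i], mv$accuracy[i], mv$sd[i]))
  }
  cat(sprintf("  mean termination generation %.2f, mean subset size %.2f\n",
              mean(x$convergence$mean_generation),
              mean(x$convergence$mean_size)))
  invisible(x)
}
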