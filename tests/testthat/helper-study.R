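# Shared smoke-scale selection study used by the acceptance suite. One
# computation serves several checks (parameter recovery, paired engine
# comparison), so it is memoised for the session.
#
# Study conditions: the generator defaults (200 genes, 10 informative at
# effect size 1.5, 25 + 25 samples) under the full 3x3 double
# cross-validation protocol; the genetic engine runs at smoke scale
# (population 16 in 2 niches, 12 iterations per fold, generation cap 12).
# The paired uniform-map baseline shares the external fold, score table,
# bank, fitness cache and engine seed, so the frequency map is the only
# difference.

.study_cache <- new.env(parent = emptyenv())

study_ga <- function(seed) {
  ga_config(iterations = 12, population_size = 16, niches = 2,
            max_generations = 12, seed = seed)
}

run_selection_study <- function(seeds) {
  key <- paste0("s", paste(seeds, collapse = "_"))
  hit <- get0(key, envir = .study_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  per_seed <- lapply(seeds, function(s) {
    gen <- generate_synthetic(synthetic_spec(seed = s))
    ds <- normalize_genes(standardize_genes(gen$dataset))
    cfg <- mfge_config(ga = study_ga(s), seed = s)
    plan <- build_cv_plan(ds, 3, 3, derive_seed(s, 1))
    counts <- setNames(numeric(n_genes(ds)), ds$gene_ids)
    scores <- setNames(numeric(n_genes(ds)), ds$gene_ids)
    mf_fold1 <- NULL
    un_fold1 <- NULL
    for (f in seq_along(plan$folds)) {
      prep <- mfge:::prepare_fold(ds, plan$folds[[f]], cfg)
      stab <- mfge:::fold_score_table(prep, cfg, derive_seed(s, 2, f))
      bank <- classifier_bank(seed = derive_seed(s, 4, f))
      fn <- mfge:::make_fitness_fn(prep$internal, bank, 0.5, 0.5)
      ga <- cfg$ga
      ga$seed <- derive_seed(s, 5, f, 1)
      mf <- run_ge(fn, build_frequency_map(stab, 1), ga)
      rk <- selection_frequency(mf, stab$gene, stab$integer_score)
      counts[rk$gene] <- counts[rk$gene] + rk$count
      scores[stab$gene] <- scores[stab$gene] + stab$integer_score
      if (f == 1) {
        mf_fold1 <- mf
        un_fold1 <- run_ge(fn, uniform_frequency_map(stab$gene, 1), ga)
      }
    }
    ord <- order(-counts, -scores, seq_along(counts))
    list(
      recovered = sum(names(counts)[ord][1:20] %in% gen$informative),
      mf = mf_fold1, un = un_fold1
    )
  })

  out <- list(
    recovered = vapply(per_seed, `[[`, numeric(1), "recovered"),
    mf = lapply(per_seed, `[[`, "mf"),
    un = lapply(per_seed, `[[`, "un")
  )
  assign(key, out, envir = .study_cache)
  out
}
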