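test_that("entropy follows the definition with the 0 log 0 convention", {
  expect_equal(entropy(c(0.5, 0.5)), 1)
  expect_equal(entropy(1), 0)
  expect_equal(entropy(c(0.25, 0.75)), 0.811278, tolerance = 1e-6)
  expect_equal(entropy(c(0.5, 0.5, 0)), 1) # zero mass ignored
  expect_error(entropy(c(-0.1, 1.1)), "negative")
  expect_error(entropy(c(0.3, 0.3)), "sum to 1")
})

test_that("MDLP discretization splits separable genes and stops on noise", {
  d <- discretize_supervised(c(0.1, 0.2, 0.8, 0.9), c("A", "A", "B", "B"))
  expect_equal(d$B, 2L)
  expect_length(d$cut_points, 1)
  expect_gt(d$cut_points, 0.2)
  expect_lt(d$cut_points, 0.8)
  expect_equal(d$bins, c(1L, 1L, 2L, 2L))

  # labels all identical: nothing to split on
  expect_equal(discretize_supervised(1:6, rep("A", 6))$B, 1L)
  # constant values: no candidate cuts
  expect_equal(discretize_supervised(rep(2, 6), rep(c("A", "B"), 3))$B, 1L)
  # bin index = 1 + number of cut points strictly below the value
  expect_equal(d$bins, findInterval(c(0.1, 0.2, 0.8, 0.9), d$cut_points) + 1L)
})

test_that("hand-evaluated table scores match the stated values", {
  perfect <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  indep <- matrix(c(5, 5, 5, 5), 2, byrow = TRUE)
  mixed <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  single <- matrix(c(10, 10), 1)

  expect_equal(chi2_score(perfect), 20)
  expect_equal(chi2_score(indep), 0)
  expect_equal(chi2_score(single), 0)

  expect_equal(info_gain(perfect), 1)
  expect_equal(info_gain(indep), 0)
  expect_equal(info_gain(mixed), 0.278072, tolerance = 1e-6)

  expect_equal(gain_ratio(perfect), 1)
  expect_equal(gain_ratio(single), 0)
  expect_equal(gain_ratio(mixed), 0.278072, tolerance = 1e-6)

  expect_equal(symmetrical_uncertainty(perfect), 1)
  expect_equal(symmetrical_uncertainty(indep), 0)
  expect_equal(symmetrical_uncertainty(mixed), 0.278072, tolerance = 1e-6)
})

test_that("table filters agree with brute-force oracles on random tables", {
  for (seed in 1:200) {
    counts <- random_ctab(seed)
    expect_equal(chi2_score(counts), oracle_chi2(counts), tolerance = 1e-9)
    expect_equal(info_gain(counts), oracle_info_gain(counts),
                 tolerance = 1e-9)
    expect_equal(gain_ratio(counts), oracle_gain_ratio(counts),
                 tolerance = 1e-9)
    expect_equal(symmetrical_uncertainty(counts), oracle_su(counts),
                 tolerance = 1e-9)
  }
})

test_that("table filters are invariant under bin and class permutation", {
  for (seed in 1:20) {
    counts <- random_ctab(seed, max_bins = 4, max_classes = 3)
    perm <- withr::with_seed(seed, {
      counts[sample(nrow(counts)), sample(ncol(counts)), drop = FALSE]
    })
    for (f in list(chi2_score, info_gain, gain_ratio,
                   symmetrical_uncertainty)) {
      expect_equal(f(counts), f(perm), tolerance = 1e-12)
    }
    # info gain bounded by class entropy
    expect_lte(info_gain(counts), oracle_entropy(colSums(counts)) + 1e-12)
    expect_gte(symmetrical_uncertainty(counts), 0)
    expect_lte(symmetrical_uncertainty(counts), 1)
  }
})

test_that("ReliefF matches the exhaustive-neighbour oracle", {
  # perfect separator dominating the distance: W = 1
  vals <- rbind(c(0, 0, 1, 1), c(0.01, 0, 0.01, 0))
  ds <- expression_dataset(vals, labels = c("A", "A", "B", "B"))
  expect_equal(relieff_score(ds, 1), 1)

  # constant gene: all diffs equal, W = 0
  dsc <- expression_dataset(rbind(c(0, 0, 1, 1), rep(0.5, 4)),
                            labels = c("A", "A", "B", "B"))
  expect_equal(relieff_score(dsc, 2), 0)

  for (seed in 1:5) {
    ds <- random_dataset(genes = 3, per_class = 3, classes = 2, seed = seed)
    ds <- normalize_genes(ds)
    for (g in 1:3) {
      expect_equal(relieff_score(ds, g),
                   oracle_relieff(ds$values, ds$labels, g))
    }
  }
  # multi-class agreement with the prior-weighted oracle
  ds3 <- normalize_genes(random_dataset(genes = 4, per_class = 4,
                                        classes = 3, seed = 11))
  for (g in 1:4) {
    expect_equal(relieff_score(ds3, g),
                 oracle_relieff(ds3$values, ds3$labels, g))
  }
})

test_that("ReliefF weights stay in [-1, 1] on normalized data", {
  for (seed in 1:5) {
    ds <- normalize_genes(random_dataset(genes = 8, per_class = 5,
                                         seed = seed))
    w <- vapply(1:8, function(g) relieff_score(ds, g), numeric(1))
    expect_true(all(w >= -1 & w <= 1))
  }
})

test_that("score_all_filters builds the full and restricted score tables", {
  ds <- normalize_genes(standardize_genes(
    random_dataset(genes = 12, per_class = 6, seed = 2)))
  tab <- score_all_filters(ds)
  expect_s3_class(tab, "filter_score_table")
  expect_equal(dim(tab), c(12L, 6L)) # gene + five filters
  expect_equal(colnames(tab), c("gene", filter_names()))

  only_ig <- score_all_filters(ds, filter_set = "infogain")
  expect_equal(colnames(only_ig), c("gene", "infogain"))
  expect_error(score_all_filters(ds, filter_set = "tstat"), "unknown")
  expect_error(score_all_filters(ds, filter_set = character(0)),
               "non-empty")
})

test_that("an uninformative gene scores the minimum under every filter", {
  # single-bin gene (all-identical labels per value region collapse to B=1)
  vals <- rbind(sep = c(0, 0.1, 0.9, 1, 0, 0.1, 0.9, 1),
                flat = rep(0.5, 8))
  ds <- expression_dataset(vals, labels = rep(c("A", "B"), each = 4))
  tab <- score_all_filters(ds)
  flat <- tab[tab$gene == "flat", ]
  expect_equal(flat$chi2, 0)
  expect_equal(flat$su, 0)
  expect_equal(flat$infogain, 0)
  expect_equal(flat$gainratio, 0)
  expect_equal(flat$relieff, 0)
})

test_that("a planted separator outranks the median null gene everywhere", {
  gen <- generate_synthetic(synthetic_spec(n_genes = 50, n_informative = 5,
                                           class_sizes = c(12, 12),
                                           effect_size = 3, seed = 5))
  ds <- normalize_genes(standardize_genes(gen$dataset))
  tab <- score_all_filters(ds)
  is_inf <- tab$gene %in% gen$informative
  for (f in filter_names()) {
    planted <- tab[[f]][is_inf]
    null_median <- stats::median(tab[[f]][!is_inf])
    expect_true(all(planted > null_median),
                label = paste("filter", f, "ranks planted genes"))
  }
})
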