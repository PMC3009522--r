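uniform_map20 <- function() uniform_frequency_map(sprintf("g%02d", 1:20))

test_that("ga_config validates its invariants", {
  expect_error(ga_config(population_size = 10, niches = 3), "divisible")
  expect_error(ga_config(p_crossover = 1.5), "probabilities")
  expect_error(ga_config(w1 = -0.1), "weights")
  cfg <- ga_config()
  expect_equal(cfg$population_size, 100)
  expect_equal(cfg$chromosome_size, 15)
})

test_that("initialization saturates, stays valid, and is never empty", {
  map <- uniform_map20()
  withr::with_seed(1, {
    full <- init_chromosome(map, size = 15, fill_prob = 1)
    expect_length(full, 15)
    expect_equal(length(unique(full)), 15) # all distinct, no zeros
    expect_false(any(full == 0L))

    for (i in 1:50) {
      c <- init_chromosome(map, size = 15, fill_prob = 0.05)
      expect_gte(sum(c != 0L), 1) # all-empty redraw rule
      nz <- c[c != 0L]
      expect_equal(anyDuplicated(nz), 0L)
    }
  })
})

test_that("initial subset size matches the fill probability band", {
  map <- uniform_map20()
  sizes <- withr::with_seed(2, {
    replicate(3000, sum(init_chromosome(map, 15, 0.4) != 0L))
  })
  expect_gt(mean(sizes), 2)  # observed band for evolved subsets
  expect_lt(mean(sizes), 10)
  expect_equal(mean(sizes), 6, tolerance = 0.05) # 15 x 0.4
})

test_that("map-biased initialization prefers high-score genes", {
  tab <- data.frame(gene = sprintf("g%02d", 1:20), f = 1:20)
  tab <- combine_scores(tab)
  map <- build_frequency_map(tab, 1)
  hits <- withr::with_seed(3, {
    tabulate(unlist(replicate(3000, {
      c <- init_chromosome(map, 15, 0.3)
      c[c != 0L]
    })), 20)
  })
  expect_gt(stats::cor(hits, tab$integer_score, method = "spearman"), 0.9)
})

test_that("crossover swaps tails, repairs duplicates, respects p_c", {
  a <- c(1L, 2L, 0L, 0L, 0L)
  b <- c(3L, 4L, 5L, 0L, 0L)
  withr::with_seed(1, {
    unchanged <- crossover(a, b, p_c = 0)
    expect_identical(unchanged, list(a, b))
  })
  # force a crossover and check length/content conservation per cut
  withr::with_seed(5, {
    for (i in 1:50) {
      kids <- crossover(a, b, p_c = 1)
      for (k in kids) {
        expect_length(k, 5)
        nz <- k[k != 0L]
        expect_equal(anyDuplicated(nz), 0L)
        expect_true(all(nz %in% c(a, b)))
      }
    }
  })
  # duplicate repair: shared gene on both sides of the cut survives once
  a2 <- c(7L, 1L, 0L)
  b2 <- c(2L, 0L, 7L)
  withr::with_seed(7, {
    for (i in 1:30) {
      kids <- crossover(a2, b2, p_c = 1)
      for (k in kids) expect_lte(sum(k == 7L), 1)
    }
  })
})

test_that("mutation count follows the chained geometric law", {
  map <- uniform_map20()
  c0 <- c(1L, 2L, 3L, rep(0L, 12))
  out0 <- withr::with_seed(1, mutate(c0, map, p_m = 0))
  expect_equal(out0, c0, ignore_attr = TRUE)
  expect_equal(attr(out0, "mutations"), 0L)
  # small-sample check of E[M] = p_m / (1 - p_chain); the full-size
  # empirical check lives in the acceptance suite
  n <- 20000
  muts <- withr::with_seed(11, {
    replicate(n, {
      m <- 0
      if (runif(1) < 0.1) {
        m <- 1
        while (runif(1) < 0.25) m <- m + 1
      }
      m
    })
  })
  expect_equal(mean(muts), 0.1 / 0.75,
               tolerance = 3 * sd(muts) / sqrt(n) / (0.1 / 0.75))
})

test_that("mutation keeps chromosomes valid and can shrink or grow", {
  map <- uniform_map20()
  withr::with_seed(13, {
    c0 <- init_chromosome(map, 15, 0.4)
    sizes <- replicate(400, {
      m <- mutate(c0, map, p_m = 1, p_chain = 0.5, empty_prob = 0.5)
      nz <- m[m != 0L]
      expect_equal(anyDuplicated(nz), 0L)
      expect_length(m, 15)
      length(nz)
    })
    expect_true(any(sizes < sum(c0 != 0L)))
    expect_true(any(sizes > sum(c0 != 0L)))
  })
})

test_that("tournament selection prefers fitness, then smaller subsets", {
  fit <- c(0.5, 0.5, 0.5)
  sizes <- c(5, 2, 7)
  withr::with_seed(1, {
    picks <- replicate(50, tournament_select(fit, sizes, size = 3))
    # with all-equal fitness any tournament containing member 2 returns it
    expect_gt(mean(picks == 2), 0.5)
  })
  # a strictly dominant chromosome wins every tournament it enters
  fit2 <- c(0.9, 0.1, 0.1, 0.1)
  withr::with_seed(2, {
    picks <- replicate(200, tournament_select(fit2, rep(3, 4), size = 3))
    p_in <- 1 - (1 - 1 / 4)^3
    expect_equal(mean(picks == 1), p_in, tolerance = 0.12)
    expect_true(all(picks[picks != 1] %in% 2:4))
  })
})

test_that("population similarity is mean pairwise Jaccard", {
  same <- list(c(1L, 2L, 0L), c(1L, 2L, 0L), c(2L, 1L, 0L))
  expect_equal(population_similarity(same), 1)
  disjoint <- list(c(1L, 2L, 0L), c(3L, 4L, 0L))
  expect_equal(population_similarity(disjoint), 0)
  pair <- list(c(1L, 2L, 0L), c(2L, 3L, 0L)) # Jaccard 1/3
  expect_equal(population_similarity(pair), 1 / 3)
  empties <- list(c(0L, 0L), c(0L, 0L))
  expect_equal(population_similarity(empties), 1)
})

test_that("migration moves each niche's favourite into the other", {
  mk <- function(ids, fits) {
    list(chroms = lapply(seq_along(fits), function(i) c(ids[i], 0L, 0L)),
         fit = lapply(fits, function(f) list(combined = f)))
  }
  a <- mk(c(10L, 11L, 12L), c(0.9, 0.2, 0.1))
  b <- mk(c(20L, 21L, 22L), c(0.5, 0.4, 0.3))
  out <- migrate(list(a, b), count = 1)
  expect_length(out[[1]]$chroms, 3)
  expect_length(out[[2]]$chroms, 3)
  # A's best (gene 10, fit 0.9) lands in B, replacing B's worst
  genes_b <- vapply(out[[2]]$chroms, `[`, integer(1), 1)
  expect_true(10L %in% genes_b)
  expect_false(22L %in% genes_b)
  # B's best lands in A, replacing A's worst
  genes_a <- vapply(out[[1]]$chroms, `[`, integer(1), 1)
  expect_true(20L %in% genes_a)
  expect_false(12L %in% genes_a)
})

test_that("an iteration finds a planted optimum and respects termination", {
  map <- uniform_map20()
  target <- c(3L, 7L, 11L)
  fn <- overlap_fitness(target)
  cfg <- ga_config(iterations = 1, population_size = 20, niches = 2,
                   max_generations = 30, similarity_threshold = 0.95,
                   seed = 1)
  res <- run_iteration(fn, map, cfg, seed = 42)
  expect_lte(res$generation, 30)
  expect_gte(res$fitness$combined, 0.6) # at least 2 of 3 targets found
  # similarity threshold 0 fires after the first generation
  cfg0 <- ga_config(iterations = 1, population_size = 20,
                    similarity_threshold = 0, seed = 1)
  res0 <- run_iteration(fn, map, cfg0, seed = 1)
  expect_equal(res0$generation, 1L)
})

test_that("chromosomes stay valid through random operator sequences", {
  tab <- data.frame(gene = sprintf("g%02d", 1:20),
                    f = withr::with_seed(4, runif(20)))
  map <- build_frequency_map(combine_scores(tab), 1)
  withr::with_seed(21, {
    pool <- replicate(10, init_chromosome(map, 15, 0.4), simplify = FALSE)
    for (step in 1:200) {
      op <- sample(3, 1)
      if (op == 1) {
        i <- sample(10, 1)
        pool[[i]] <- mutate(pool[[i]], map, 0.8, 0.4, 0.5)
      } else if (op == 2) {
        ij <- sample(10, 2)
        kids <- crossover(pool[[ij[1]]], pool[[ij[2]]], 0.9)
        pool[[ij[1]]] <- kids[[1]]
        pool[[ij[2]]] <- kids[[2]]
      } else {
        i <- sample(10, 1)
        pool[[i]] <- init_chromosome(map, 15, 0.4)
      }
    }
    for (c in pool) {
      expect_length(c, 15)
      nz <- c[c != 0L]
      expect_equal(anyDuplicated(nz), 0L)
      expect_true(all(nz >= 1 & nz <= 20))
    }
  })
})

test_that("run_ge collects one subset per iteration, reproducibly", {
  map <- uniform_map20()
  fn <- overlap_fitness(c(2L, 5L))
  cfg <- ga_config(iterations = 4, population_size = 12, niches = 2,
                   max_generations = 8, seed = 77)
  coll1 <- run_ge(fn, map, cfg)
  coll2 <- run_ge(fn, map, cfg)
  expect_length(coll1$subsets, 4)
  expect_identical(coll1$subsets, coll2$subsets)
  expect_identical(coll1$generation, coll2$generation)
  expect_true(all(coll1$generation <= 8))
  expect_true(all(coll1$size >= 1 & coll1$size <= 15))
})

test_that("elite fitness is non-decreasing within a niche", {
  # drive evolve_niche directly and track the running best
  map <- uniform_map20()
  fn <- overlap_fitness(c(1L, 4L, 9L))
  cfg <- ga_config(population_size = 12, niches = 2, seed = 1)
  withr::with_seed(31, {
    niche <- mfge:::new_niche(map, 6, cfg, fn)
    best <- max(vapply(niche$fit, `[[`, numeric(1), "combined"))
    for (g in 1:15) {
      niche <- mfge:::evolve_niche(niche, map, cfg, fn)
      new_best <- max(vapply(niche$fit, `[[`, numeric(1), "combined"))
      expect_gte(new_best, best - 1e-12)
      best <- new_best
    }
  })
})
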