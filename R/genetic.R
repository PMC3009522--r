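# Niched genetic algorithm. A chromosome is a fixed-length integer vector
# (default 15 slots); each slot holds a candidate-gene index or 0 for
# "no gene here", and non-zero entries are kept pairwise distinct, so a
# chromosome decodes to a gene subset of size 0..15. Initialization and
# mutation draw genes from the gene frequency map, which is where the fused
# filter scores steer the search.

#' Genetic-ensemble configuration
#'
#' Defaults reproduce the reference parameterization: 100 genetic-ensemble
#' iterations, population 100 split into 2 niches of 50 evolved separately
#' with an exchange of favourites every 10 generations, chromosome size 15,
#' tournament selection of 3, single-point crossover at 0.7, chained
#' multi-point mutation at 0.1 with continuation probability 0.25,
#' termination at generation 100 or at 90% population similarity, and
#' contribution weights w1 = w2 = 0.5.
#'
#' @param iterations Genetic-ensemble iterations (best subsets collected).
#' @param population_size Total population; must be divisible by `niches`.
#' @param niches Number of subpopulations.
#' @param migration_interval Generations between exchanges of favourites.
#' @param migration_count Favourites exchanged per niche per migration.
#' @param chromosome_size Slots per chromosome.
#' @param p_crossover Single-point crossover probability.
#' @param p_mutation Probability of the first point mutation.
#' @param p_chain Probability that each further mutation follows the
#'   previous one on the same chromosome.
#' @param tournament_size Candidates per tournament.
#' @param max_generations Generation cap per iteration.
#' @param similarity_threshold Mean pairwise Jaccard similarity at which a
#'   niche is declared converged.
#' @param w1,w2 Contribution weights of the blocking and voting fitness
#'   terms.
#' @param fill_prob Per-slot fill probability at initialization; 0.4 gives
#'   an expected initial subset size of 6 on 15 slots, the midpoint of the
#'   2-10 subset-size band the engine settles into.
#' @param elitism Elites carried over per niche per generation.
#' @param seed Master seed.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(iterations = 100, population_size = 100, niches = 2,
                      migration_interval = 10, migration_count = 1,
                      chromosome_size = 15, p_crossover = 0.7,
                      p_mutation = 0.1, p_chain = 0.25, tournament_size = 3,
                      max_generations = 100, similarity_threshold = 0.9,
                      w1 = 0.5, w2 = 0.5, fill_prob = 0.4, elitism = 1,
                      seed = 1) {
  if (population_size %% niches != 0) {
    stop("population_size must be divisible by niches")
  }
  probs <- c(p_crossover, p_mutation, p_chain, similarity_threshold,
             fill_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (w1 < 0 || w2 < 0) stop("weights must be non-negative")
  structure(as.list(environment()), class = "ga_config")
}

decode_subset <- function(slots) slots[slots != 0L]

#' Initialize a chromosome from the frequency map
#'
#' Each slot is independently left empty with probability `1 - fill_prob`,
#' otherwise filled with a map draw excluding genes already on the
#' chromosome. An all-empty result is redrawn, so every chromosome encodes
#' at least one gene. Map exhaustion leaves remaining slots empty.
#'
#' @param map A `gene_frequency_map`.
#' @param size Chromosome length.
#' @param fill_prob Per-slot fill probability.
#' @return Integer vector of gene indices with 0 as the empty marker.
#' @export
init_chromosome <- function(map, size = 15, fill_prob = 0.4) {
  repeat {
    slots <- integer(size)
    for (j in seq_len(size)) {
      if (runif(1) < fill_prob) {
        g <- draw_gene(map, exclude = slots[slots != 0L])
        if (!is.na(g)) slots[j] <- g
      }
    }
    if (any(slots != 0L)) return(slots)
  }
}

#' Single-point crossover with duplicate repair
#'
#' With probability `p_c`, draws one cut point in `1..size-1` and swaps the
#' parents' tails. A gene appearing on both sides of the cut would be
#' duplicated; the later duplicate slot is zeroed. With probability
#' `1 - p_c` the parents are returned unchanged.
#'
#' @param a,b Parent chromosomes (equal length).
#' @param p_c Crossover probability.
#' @return List of two offspring chromosomes.
#' @export
crossover <- function(a, b, p_c = 0.7) {
  if (length(a) != length(b)) stop("parents must have equal length")
  if (runif(1) >= p_c) return(list(a, b))
  cut <- sample.int(length(a) - 1L, 1L)
  tail_idx <- seq.int(cut + 1L, length(a))
  o1 <- a; o1[tail_idx] <- b[tail_idx]
  o2 <- b; o2[tail_idx] <- a[tail_idx]
  list(repair_duplicates(o1), repair_duplicates(o2))
}

repair_duplicates <- function(slots) {
  seen <- integer(0)
  for (j in seq_along(slots)) {
    if (slots[j] == 0L) next
    if (slots[j] %in% seen) slots[j] <- 0L else seen <- c(seen, slots[j])
  }
  slots
}

#' Chained multi-point mutation
#'
#' The number of point mutations follows the chained law: a first mutation
#' occurs with probability `p_m`, and each further one with probability
#' `p_chain`, geometrically (expected count `p_m / (1 - p_chain)`). Each
#' point mutation picks a uniform slot and overwrites it with the empty
#' marker (probability `empty_prob`, the slot-empty rate used at
#' initialization, so subsets can shrink as well as grow) or with a fresh
#' map draw excluding genes already on the chromosome.
#'
#' @param slots Chromosome to mutate.
#' @param map A `gene_frequency_map`.
#' @param p_m First-mutation probability.
#' @param p_chain Continuation probability.
#' @param empty_prob Probability a mutated slot is emptied rather than
#'   refilled.
#' @return Mutated chromosome, with the number of point mutations applied
#'   attached as attribute `"mutations"`.
#' @export
mutate <- function(slots, map, p_m = 0.1, p_chain = 0.25,
                   empty_prob = 0.6) {
  m <- 0L
  if (runif(1) < p_m) {
    repeat {
      m <- m + 1L
      j <- sample.int(length(slots), 1L)
      if (runif(1) < empty_prob) {
        slots[j] <- 0L
      } else {
        g <- draw_gene(map, exclude = slots[slots != 0L])
        if (!is.na(g)) slots[j] <- g
      }
      if (runif(1) >= p_chain) break
    }
  }
  attr(slots, "mutations") <- m
  slots
}

#' Tournament selection within a niche
#'
#' Draws `size` candidates uniformly with replacement and returns the index
#' of the fittest; fitness ties go to the smaller decoded subset, then to
#' the earlier candidate.
#'
#' @param fitness Combined fitness per niche member.
#' @param subset_sizes Decoded subset size per niche member.
#' @param size Tournament size.
#' @return Index of the selected member.
#' @export
tournament_select <- function(fitness, subset_sizes, size = 3) {
  cand <- sample.int(length(fitness), size, replace = TRUE)
  best <- cand[order(-fitness[cand], subset_sizes[cand], cand)[1]]
  best
}

#' Mean pairwise Jaccard similarity of a niche
#'
#' Similarity of two chromosomes is the Jaccard index of their decoded
#' subsets (empty vs empty counts as 1); the niche value is the mean over
#' all unordered pairs. Niches at or above the configured threshold are
#' declared converged.
#'
#' @param chroms List of chromosomes.
#' @return Value in `[0, 1]` (1 for a single-member niche).
#' @export
population_similarity <- function(chroms) {
  k <- length(chroms)
  if (k < 2) return(1)
  subsets <- lapply(chroms, decode_subset)
  total <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      u <- length(union(subsets[[i]], subsets[[j]]))
      total <- total + if (u == 0) 1 else
        length(intersect(subsets[[i]], subsets[[j]])) / u
    }
  }
  total / (k * (k - 1) / 2)
}

# Evaluate a chromosome through the (caching) fitness function.
eval_chrom <- function(slots, fitness_fn) {
  subset <- decode_subset(slots)
  fitness_fn(subset)
}

#' Exchange favourite chromosomes between niches
#'
#' The top `count` members (by combined fitness) of each niche replace the
#' worst `count` members of the other; niche sizes are unchanged.
#'
#' @param niches List of niches, each a list with `chroms` (list of
#'   chromosomes) and `fit` (list of fitness values).
#' @param count Favourites exchanged per niche.
#' @return The updated list of niches.
#' @export
migrate <- function(niches, count = 1) {
  if (length(niches) < 2) stop("migration needs >= 2 niches")
  combined <- lapply(niches, function(n) {
    vapply(n$fit, function(f) f$combined, numeric(1))
  })
  best_idx <- lapply(combined, function(f) order(-f)[seq_len(count)])
  worst_idx <- lapply(combined, function(f) order(f)[seq_len(count)])
  donors <- lapply(seq_along(niches), function(i) {
    list(chroms = niches[[i]]$chroms[best_idx[[i]]],
         fit = niches[[i]]$fit[best_idx[[i]]])
  })
  for (i in seq_along(niches)) {
    src <- if (i == length(niches)) 1L else i + 1L
    niches[[i]]$chroms[worst_idx[[i]]] <- donors[[src]]$chroms
    niches[[i]]$fit[worst_idx[[i]]] <- donors[[src]]$fit
  }
  niches
}

new_niche <- function(map, size, cfg, fitness_fn) {
  chroms <- replicate(size,
                      init_chromosome(map, cfg$chromosome_size,
                                      cfg$fill_prob),
                      simplify = FALSE)
  list(chroms = chroms, fit = lapply(chroms, eval_chrom, fitness_fn))
}

evolve_niche <- function(niche, map, cfg, fitness_fn) {
  k <- length(niche$chroms)
  fit <- vapply(niche$fit, function(f) f$combined, numeric(1))
  sizes <- vapply(niche$chroms, function(c) length(decode_subset(c)),
                  numeric(1))
  elite_idx <- order(-fit, sizes, seq_along(fit))[seq_len(cfg$elitism)]
  chroms <- niche$chroms[elite_idx]
  fits <- niche$fit[elite_idx]
  while (length(chroms) < k) {
    p1 <- tournament_select(fit, sizes, cfg$tournament_size)
    p2 <- tournament_select(fit, sizes, cfg$tournament_size)
    kids <- crossover(niche$chroms[[p1]], niche$chroms[[p2]],
                      cfg$p_crossover)
    for (kid in kids) {
      if (length(chroms) >= k) break
      kid <- mutate(kid, map, cfg$p_mutation, cfg$p_chain,
                    1 - cfg$fill_prob)
      chroms <- c(chroms, list(kid))
      fits <- c(fits, list(eval_chrom(kid, fitness_fn)))
    }
  }
  list(chroms = chroms, fit = fits)
}

#' Run one genetic-ensemble iteration
#'
#' Evolves the configured niches with generational replacement under
#' elitism, exchanging favourites every `migration_interval` generations,
#' until `max_generations` is reached or any niche's similarity reaches the
#' threshold. Returns the best chromosome ever seen and the generation at
#' which evolution stopped.
#'
#' @param fitness_fn Function taking a vector of gene indices and returning
#'   a `fitness_value` (see [evaluate_subset()]); typically a caching
#'   closure over the internal cross-validation folds.
#' @param map A `gene_frequency_map`.
#' @param cfg A [ga_config()].
#' @param seed Seed for this iteration's random stream.
#' @return List with `best` (chromosome), `fitness` (its `fitness_value`),
#'   `generation` (termination generation).
#' @export
run_iteration <- function(fitness_fn, map, cfg, seed = 1) {
  with_seed(seed, {
    niche_size <- cfg$population_size %/% cfg$niches
    niches <- replicate(cfg$niches,
                        new_niche(map, niche_size, cfg, fitness_fn),
                        simplify = FALSE)
    best <- NULL
    best_fit <- NULL
    note_best <- function(chroms, fits) {
      for (i in seq_along(chroms)) {
        f <- fits[[i]]$combined
        sz <- length(decode_subset(chroms[[i]]))
        if (is.null(best) ||
            f > best_fit$combined + 1e-12 ||
            (abs(f - best_fit$combined) <= 1e-12 &&
             sz < length(decode_subset(best)))) {
          best <<- chroms[[i]]
          best_fit <<- fits[[i]]
        }
      }
    }
    for (n in niches) note_best(n$chroms, n$fit)

    gen <- 0L
    while (gen < cfg$max_generations) {
      gen <- gen + 1L
      niches <- lapply(niches, evolve_niche, map, cfg, fitness_fn)
      if (cfg$niches > 1 && gen %% cfg$migration_interval == 0) {
        niches <- migrate(niches, cfg$migration_count)
      }
      for (n in niches) note_best(n$chroms, n$fit)
      sims <- vapply(niches, function(n) population_similarity(n$chroms),
                     numeric(1))
      if (any(sims >= cfg$similarity_threshold)) break
    }
    list(best = best, fitness = best_fit, generation = gen)
  })
}

#' Run the full genetic-ensemble loop
#'
#' Performs `cfg$iterations` independent [run_iteration()] calls (fresh
#' populations, seeds derived from `cfg$seed`), collecting each iteration's
#' best gene subset together with its termination generation, size and
#' fitness.
#'
#' @inheritParams run_iteration
#' @return Object of class `subset_collection`: list with `subsets` (list
#'   of integer gene-index vectors), `generation`, `size`, `fitness`
#'   (combined), `blocking`, `voting` vectors, and `seed`.
#' @details With `options(mfge.verbose = TRUE)` each iteration emits one
#'   machine-parseable tab-delimited line on stderr: iteration index,
#'   termination generation, blocking/voting/combined fitness, subset
#'   size, and the selected gene indices (comma-separated).
#' @export
run_ge <- function(fitness_fn, map, cfg) {
  if (cfg$iterations < 1) stop("need >= 1 iteration")
  recs <- lapply(seq_len(cfg$iterations), function(it) {
    r <- run_iteration(fitness_fn, map, cfg, derive_seed(cfg$seed, 1000, it))
    if (isTRUE(getOption("mfge.verbose"))) {
      subset <- sort(decode_subset(r$best))
      message(sprintf("iter\t%d\t%d\t%.4f\t%.4f\t%.4f\t%d\t%s",
                      it, r$generation, r$fitness$blocking,
                      r$fitness$voting, r$fitness$combined,
                      length(subset), paste(subset, collapse = ",")))
    }
    r
  })
  structure(
    list(
      subsets = lapply(recs, function(r) sort(decode_subset(r$best))),
      generation = vapply(recs, function(r) r$generation, numeric(1)),
      size = vapply(recs, function(r) length(decode_subset(r$best)),
                    numeric(1)),
      fitness = vapply(recs, function(r) r$fitness$combined, numeric(1)),
      blocking = vapply(recs, function(r) r$fitness$blocking, numeric(1)),
      voting = vapply(recs, function(r) r$fitness$voting, numeric(1)),
      seed = cfg$seed
    ),
    class = "subset_collection"
  )
}

#' @export
print.subset_collection <- function(x, ...) {
  cat("subset_collection:", length(x$subsets), "iterations; mean size",
      sprintf("%.2f", mean(x$size)), "; mean termination generation",
      sprintf("%.2f", mean(x$generation)), "\n")
  invisible(x)
}
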