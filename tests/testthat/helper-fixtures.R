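# Shared fixtures and independent brute-force oracles. Oracles are written
# from the definitions directly (double loops, enumeration) and never call
# the implementation paths they check.

tiny_dataset <- function() {
  vals <- matrix(c(0, 0, 2, 2,
                   1, 2, 3, 4,
                   5, 5, 5, 5), nrow = 3, byrow = TRUE)
  expression_dataset(vals, gene_ids = c("gA", "gB", "gC"),
                     sample_ids = paste0("s", 1:4),
                     labels = c("A", "A", "B", "B"))
}

random_dataset <- function(genes = 20, per_class = 6, classes = 2,
                           seed = 1) {
  withr::with_seed(seed, {
    n <- per_class * classes
    vals <- matrix(rnorm(genes * n), genes, n)
    expression_dataset(vals,
                       gene_ids = sprintf("g%03d", seq_len(genes)),
                       sample_ids = sprintf("s%03d", seq_len(n)),
                       labels = rep(LETTERS[seq_len(classes)],
                                    each = per_class))
  })
}

random_ctab <- function(seed, max_bins = 4, max_classes = 3) {
  withr::with_seed(seed, {
    b <- sample(1:max_bins, 1)
    m <- sample(2:max_classes, 1)
    counts <- matrix(rpois(b * m, 4), b, m)
    if (sum(counts) == 0) counts[1, 1] <- 1
    counts
  })
}

# --- oracles -------------------------------------------------------------

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

oracle_chi2 <- function(counts) {
  n <- sum(counts)
  total <- 0
  for (v in seq_len(nrow(counts))) {
    for (i in seq_len(ncol(counts))) {
      e <- sum(counts[v, ]) * sum(counts[, i]) / n
      if (e > 0) total <- total + (counts[v, i] - e)^2 / e
    }
  }
  total
}

oracle_info_gain <- function(counts) {
  n <- sum(counts)
  h_class <- oracle_entropy(colSums(counts))
  cond <- 0
  for (v in seq_len(nrow(counts))) {
    nv <- sum(counts[v, ])
    if (nv > 0) cond <- cond + (nv / n) * oracle_entropy(counts[v, ])
  }
  h_class - cond
}

oracle_gain_ratio <- function(counts) {
  split <- oracle_entropy(rowSums(counts))
  if (split == 0) return(0)
  oracle_info_gain(counts) / split
}

oracle_su <- function(counts) {
  h_c <- oracle_entropy(colSums(counts))
  h_g <- oracle_entropy(rowSums(counts))
  if (h_c + h_g == 0) return(0)
  2 * oracle_info_gain(counts) / (h_c + h_g)
}

# Exhaustive ReliefF over all samples: nearest hit and per-class nearest
# miss by full-pairwise Euclidean distance, lowest-index tie-break,
# prior-weighted miss term.
oracle_relieff <- function(values, labels, gene) {
  labels <- droplevels(as.factor(labels))
  n <- ncol(values)
  lab <- as.integer(labels)
  priors <- as.numeric(table(labels)) / n
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((values[, i] - values[, j])^2))
    }
  }
  total <- 0
  used <- 0
  for (i in seq_len(n)) {
    same <- setdiff(which(lab == lab[i]), i)
    if (length(same) == 0) next
    used <- used + 1
    hit <- same[which.min(d[i, same])]
    hit_diff <- abs(values[gene, i] - values[gene, hit])
    others <- setdiff(unique(lab), lab[i])
    w <- priors[others] / sum(priors[others])
    miss_diff <- 0
    for (k in seq_along(others)) {
      mem <- which(lab == others[k])
      nm <- mem[which.min(d[i, mem])]
      miss_diff <- miss_diff + w[k] * abs(values[gene, i] - values[gene, nm])
    }
    total <- total + miss_diff - hit_diff
  }
  total / used
}

oracle_bss_wss <- function(values, labels) {
  labels <- as.factor(labels)
  out <- numeric(nrow(values))
  for (j in seq_len(nrow(values))) {
    grand <- mean(values[j, ])
    bss <- 0
    wss <- 0
    for (i in seq_len(ncol(values))) {
      cm <- mean(values[j, labels == labels[i]])
      bss <- bss + (cm - grand)^2
      wss <- wss + (values[j, i] - cm)^2
    }
    out[j] <- if (wss == 0) {
      if (bss > 0) Inf else 0
    } else bss / wss
  }
  out
}

# cheap deterministic fitness for genetic-engine tests: rewards overlap
# with a target subset, mildly penalizes size (no classifiers involved)
overlap_fitness <- function(target, penalty = 0.01) {
  function(subset) {
    ov <- length(intersect(subset, target)) / max(1, length(target))
    val <- max(0, ov - penalty * length(subset))
    structure(list(blocking = val, voting = val, combined = val,
                   per_classifier = c(mock = val)),
              class = "fitness_value")
  }
}
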