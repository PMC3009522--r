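# The five filter scoring algorithms. The four discrete-valued filters
# (chi-squared, information gain, gain ratio, symmetrical uncertainty) all
# work from one shared per-gene contingency table of MDLP bins vs classes;
# ReliefF works directly on the normalized continuous matrix.

#' Build a bin-by-class contingency table
#'
#' @param bins Integer bin index per sample (1-based).
#' @param labels Class label per sample.
#' @return Object of class `contingency_table`: integer matrix `counts`
#'   (bins in rows, classes in columns) with marginals `row_marg`,
#'   `col_marg` and total `n`.
#' @export
contingency_table <- function(bins, labels) {
  labels <- droplevels(as.factor(labels))
  counts <- table(factor(bins, levels = sort(unique(bins))), labels)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(list(counts = counts, row_marg = rowSums(counts),
                 col_marg = colSums(counts), n = sum(counts)),
            class = "contingency_table")
}

as_ctab <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  counts <- as.matrix(x)
  structure(list(counts = counts, row_marg = rowSums(counts),
                 col_marg = colSums(counts), n = sum(counts)),
            class = "contingency_table")
}

#' Chi-squared statistic of a gene-value vs class table
#'
#' `sum (N - E)^2 / E` over all (bin, class) cells, with expected counts
#' `E = row_marginal * col_marginal / n`. Cells with `E = 0` are structural
#' zeros and contribute nothing. A single-bin gene scores 0.
#'
#' @param table A `contingency_table` (or plain count matrix).
#' @return Non-negative statistic.
#' @export
chi2_score <- function(table) {
  ct <- as_ctab(table)
  if (ct$n < 1) stop("empty table")
  expected <- outer(ct$row_marg, ct$col_marg) / ct$n
  ok <- expected > 0
  sum((ct$counts[ok] - expected[ok])^2 / expected[ok])
}

#' Information gain of a gene-value vs class table
#'
#' `H(class) - sum_v P(g = v) H(class | g = v)` in bits, from the table's
#' empirical probabilities: the number of bits about the class obtained by
#' observing the (discretized) gene value.
#'
#' @inheritParams chi2_score
#' @return Gain in bits, in `[0, H(class)]`.
#' @export
info_gain <- function(table) {
  ct <- as_ctab(table)
  if (ct$n < 1) stop("empty table")
  h_class <- count_entropy(ct$col_marg)
  cond <- sum(vapply(seq_along(ct$row_marg), function(v) {
    (ct$row_marg[v] / ct$n) * count_entropy(ct$counts[v, ])
  }, numeric(1)))
  h_class - cond
}

#' Gain ratio of a gene-value vs class table
#'
#' Information gain divided by the split information
#' `-sum_v (|S_v|/|S|) log2(|S_v|/|S|)`, which measures how broadly and
#' uniformly the gene's values split the samples. A single-bin gene has zero
#' split information and is defined to score 0.
#'
#' @inheritParams chi2_score
#' @return Dimensionless ratio.
#' @export
gain_ratio <- function(table) {
  ct <- as_ctab(table)
  split_info <- count_entropy(ct$row_marg)
  if (split_info == 0) return(0)
  info_gain(ct) / split_info
}

#' Symmetrical uncertainty of a gene-value vs class table
#'
#' `2 * (H(class) - H(class | g)) / (H(class) + H(g))`, a normalized mutual
#' information in `[0, 1]`. Defined as 0 when both gene and class are
#' constant (zero denominator).
#'
#' @inheritParams chi2_score
#' @return Value in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(table) {
  ct <- as_ctab(table)
  h_class <- count_entropy(ct$col_marg)
  h_gene <- count_entropy(ct$row_marg)
  if (h_class + h_gene == 0) return(0)
  2 * info_gain(ct) / (h_class + h_gene)
}

#' ReliefF weight of one gene
#'
#' For each probed sample, compares the gene's value difference to the
#' nearest same-class sample (hit) and the nearest different-class sample
#' (miss), nearest meaning smallest Euclidean distance over all genes with
#' the probe itself excluded and ties broken by lowest sample index:
#' `W(g) = (1/sample_count) * sum_i [ diff(g, S_i, miss_i) - diff(g, S_i, hit_i) ]`
#' with `diff` the absolute value difference. On data normalized to
#' `[0, 1]` each diff is in `[0, 1]`, so the `1/sample_count` normalization
#' bounds `W` in `[-1, 1]`. With more than two classes the miss term is the
#' prior-weighted average of the per-opposing-class nearest misses, which
#' reduces to the plain two-term form for binary labels.
#'
#' @param ds An `expression_dataset`, expression already normalized to
#'   `[0, 1]`.
#' @param gene Gene index (or id) to score.
#' @param sample_count Number of probe samples; the default `NULL` uses all
#'   samples deterministically. Smaller values draw a seeded random subset.
#' @param seed Seed used only when subsampling probes.
#' @return Weight in `[-1, 1]`.
#' @export
relieff_score <- function(ds, gene, sample_count = NULL, seed = 1) {
  if (is.character(gene)) gene <- match(gene, ds$gene_ids)
  pre <- relieff_precompute(ds)
  relieff_score_pre(pre, gene, sample_count, seed)
}

# Neighbour search is gene-independent, so distances and hit/miss indices are
# shared across all genes scored on the same dataset.
relieff_precompute <- function(ds) {
  v <- ds$values
  n <- ncol(v)
  labels <- droplevels(ds$labels)
  sizes <- table(labels)
  if (any(sizes < 2)) {
    warning("class(es) with a single sample skipped as ReliefF probes: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  d2 <- as.matrix(stats::dist(t(v)))^2
  diag(d2) <- Inf
  lab_int <- as.integer(labels)
  m <- nlevels(labels)
  hit <- integer(n)
  miss <- matrix(NA_integer_, n, m) # nearest sample of each class
  for (i in seq_len(n)) {
    for (cl in seq_len(m)) {
      members <- which(lab_int == cl)
      members <- members[members != i]
      if (length(members) == 0) next
      miss[i, cl] <- members[which.min(d2[i, members])]
    }
    hit[i] <- miss[i, lab_int[i]]
  }
  priors <- as.numeric(sizes) / n
  list(values = v, lab_int = lab_int, m = m, hit = hit, miss = miss,
       priors = priors, n = n)
}

relieff_score_pre <- function(pre, gene, sample_count = NULL, seed = 1) {
  # probes need at least one same-class neighbour (hit is NA otherwise)
  probes <- which(!is.na(pre$hit) & pre$hit > 0)
  if (!is.null(sample_count) && sample_count < length(probes)) {
    probes <- with_seed(seed, sort(sample(probes, sample_count)))
  }
  sc <- length(probes)
  if (sc == 0) return(0)
  g <- pre$values[gene, ]
  total <- 0
  for (i in probes) {
    hit_diff <- abs(g[i] - g[pre$hit[i]])
    # prior-weighted nearest miss over opposing classes
    others <- setdiff(seq_len(pre$m), pre$lab_int[i])
    w <- pre$priors[others]
    w <- w / sum(w)
    md <- 0
    for (j in seq_along(others)) {
      mi <- pre$miss[i, others[j]]
      if (!is.na(mi)) md <- md + w[j] * abs(g[i] - g[mi])
    }
    total <- total + md - hit_diff
  }
  unname(total / sc)
}

#' Names of the built-in filters
#' @return Character vector.
#' @export
filter_names <- function() c("chi2", "relieff", "su", "infogain", "gainratio")

#' Score every gene under a set of filters
#'
#' Runs the requested filters over all genes and returns their raw scores.
#' The four discrete filters share one MDLP discretization per gene;
#' ReliefF probes all samples by default (deterministic).
#'
#' @param ds A preprocessed (standardized, normalized) `expression_dataset`.
#' @param filter_set Subset of [filter_names()]; default all five.
#' @param seed Seed for ReliefF probe subsampling (unused at the
#'   all-samples default).
#' @param relieff_samples Probe count for ReliefF (`NULL` = all).
#' @return A `filter_score_table`: data frame with `gene` plus one raw-score
#'   column per filter, carrying class `filter_score_table`.
#' @export
score_all_filters <- function(ds, filter_set = filter_names(), seed = 1,
                              relieff_samples = NULL) {
  if (length(filter_set) == 0) stop("filter_set must be non-empty")
  unknown <- setdiff(filter_set, filter_names())
  if (length(unknown) > 0) {
    stop("unknown filter(s): ", paste(unknown, collapse = ", "))
  }
  p <- n_genes(ds)
  out <- data.frame(gene = ds$gene_ids, stringsAsFactors = FALSE)

  discrete <- intersect(filter_set, c("chi2", "su", "infogain", "gainratio"))
  if (length(discrete) > 0) {
    tabs <- lapply(seq_len(p), function(j) {
      contingency_table(discretize_supervised(ds$values[j, ], ds$labels)$bins,
                        ds$labels)
    })
    if ("chi2" %in% discrete) {
      out$chi2 <- vapply(tabs, chi2_score, numeric(1))
    }
    if ("relieff" %in% filter_set) out$relieff <- NA_real_ # keep column order
    if ("su" %in% discrete) {
      out$su <- vapply(tabs, symmetrical_uncertainty, numeric(1))
    }
    if ("infogain" %in% discrete) {
      out$infogain <- vapply(tabs, info_gain, numeric(1))
    }
    if ("gainratio" %in% discrete) {
      out$gainratio <- vapply(tabs, gain_ratio, numeric(1))
    }
  }
  if ("relieff" %in% filter_set) {
    pre <- relieff_precompute(ds)
    out$relieff <- vapply(seq_len(p), function(j) {
      relieff_score_pre(pre, j, relieff_samples, derive_seed(seed, j))
    }, numeric(1))
  }
  out <- out[, c("gene", intersect(filter_names(), filter_set)),
             drop = FALSE]
  class(out) <- c("filter_score_table", "data.frame")
  out
}
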