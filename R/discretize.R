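#' Shannon entropy of a probability vector
#'
#' `-sum(p * log2(p))` with the `0 * log 0 = 0` convention, in bits.
#'
#' @param probabilities Non-negative weights summing to 1 (within 1e-9).
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c(0.5, 0.5)) # 1 bit
entropy <- function(probabilities) {
  p <- probabilities
  if (any(p < 0)) stop("negative probability")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Entropy of a class-count vector (unnormalized).
count_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Recursive MDL-accepted binary splitting on one sorted segment.
# vals: sorted numeric; cls: integer class codes aligned with vals.
# Returns accepted cut values (possibly empty).
mdlp_split <- function(vals, cls, n_class_total) {
  n <- length(vals)
  if (n < 2) return(numeric(0))
  tab <- tabulate(cls, n_class_total)
  ent_s <- count_entropy(tab)
  if (ent_s == 0) return(numeric(0))

  # candidate cuts: midpoints between adjacent distinct values
  distinct <- which(diff(vals) > 0)
  if (length(distinct) == 0) return(numeric(0))

  # cumulative class counts for O(1) split entropies
  best <- NULL
  best_e <- Inf
  cum <- vapply(seq_len(n_class_total), function(k) cumsum(cls == k),
                numeric(n))
  for (i in distinct) {
    left <- cum[i, ]
    right <- tab - left
    e <- (i / n) * count_entropy(left) + ((n - i) / n) * count_entropy(right)
    if (e < best_e - 1e-12) {
      best_e <- e
      best <- i
    }
  }
  if (is.null(best)) return(numeric(0))

  left_tab <- cum[best, ]
  right_tab <- tab - left_tab
  gain <- ent_s - best_e
  k <- sum(tab > 0)
  k1 <- sum(left_tab > 0)
  k2 <- sum(right_tab > 0)
  delta <- log2(3^k - 2) -
    (k * ent_s - k1 * count_entropy(left_tab) - k2 * count_entropy(right_tab))
  threshold <- (log2(n - 1) + delta) / n
  if (gain <= threshold) return(numeric(0))

  cut <- (vals[best] + vals[best + 1]) / 2
  li <- seq_len(best)
  ri <- seq.int(best + 1, n)
  c(mdlp_split(vals[li], cls[li], n_class_total),
    cut,
    mdlp_split(vals[ri], cls[ri], n_class_total))
}

#' Supervised discretization of one gene (Fayyad-Irani MDLP)
#'
#' Recursive entropy-minimizing binary splitting with the minimum description
#' length stopping rule. If no cut passes the MDL criterion the gene gets a
#' single bin (`B = 1`), which every discrete filter scores as uninformative.
#'
#' @param values Continuous expression of one gene across samples.
#' @param labels Class label per sample.
#' @return Object of class `discretized_gene`: `bins` (integer bin index per
#'   sample, 1-based), `cut_points` (ascending thresholds), `B` (bin count =
#'   `length(cut_points) + 1`). A value's bin is 1 + the number of cut points
#'   strictly below it.
#' @export
discretize_supervised <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  ord <- order(values)
  cuts <- sort(mdlp_split(values[ord], as.integer(labels)[ord],
                          nlevels(labels)))
  bins <- findInterval(values, cuts) + 1L
  structure(list(bins = bins, cut_points = cuts, B = length(cuts) + 1L),
            class = "discretized_gene")
}
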