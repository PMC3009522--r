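# Pre-processing protocol, applied in a fixed order:
#   standardize -> normalize -> external split -> BSS/WSS on external-train
#   -> top-k prefilter of external-train -> internal split.
# BSS/WSS ranking and the prefilter only ever see external-train samples, so
# external test data stay untouched by every selection stage.

#' Standardize each gene to mean 0, variance 1
#'
#' Per-gene z-scoring with the population variance convention (divide by n).
#' A constant gene has undefined variance and is mapped to an all-zero row
#' with a warning.
#'
#' @param ds An `expression_dataset`.
#' @return A new `expression_dataset` with standardized rows.
#' @export
standardize_genes <- function(ds) {
  v <- ds$values
  mu <- rowMeans(v)
  centered <- v - mu
  sdev <- sqrt(rowMeans(centered^2)) # population sd
  const <- sdev == 0
  if (any(const)) {
    warning(sum(const), " constant gene row(s) mapped to zeros")
    sdev[const] <- 1
  }
  out <- centered / sdev
  out[const, ] <- 0
  ds$values <- out
  ds
}

#' Rescale each gene into [0, 1]
#'
#' Per-gene min-max rescaling; the row minimum maps to 0 and the maximum to
#' 1. Constant rows map to 0.5. Intended to follow [standardize_genes()];
#' ReliefF relies on this range so that per-gene value differences are
#' themselves in [0, 1].
#'
#' @param ds An `expression_dataset`.
#' @return A new `expression_dataset` with rows in [0, 1].
#' @export
normalize_genes <- function(ds) {
  v <- ds$values
  lo <- apply(v, 1, min)
  hi <- apply(v, 1, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  out <- (v - lo) / rng
  out[const, ] <- 0.5
  ds$values <- out
  ds
}

#' Between-group to within-group sum-of-squares ratio per gene
#'
#' The univariate relevance ratio of Dudoit, Fridlyand and Speed: for gene j,
#' `BSS_j = sum_c N_c (xbar_cj - xbar_j)^2` over classes c and
#' `WSS_j = sum_i (x_ij - xbar_{c(i),j})^2` over samples i. A perfect
#' separator (`WSS = 0`, `BSS > 0`) returns `Inf` so it ranks first; a
#' constant gene (0/0) returns 0 so it ranks last.
#'
#' @param ds An `expression_dataset` with at least two classes.
#' @return Named numeric vector of ratios, one per gene.
#' @export
bss_wss_scores <- function(ds) {
  labels <- droplevels(ds$labels)
  if (nlevels(labels) < 2) stop("BSS/WSS needs >= 2 classes")
  v <- ds$values
  grand <- rowMeans(v)
  bss <- numeric(nrow(v))
  wss <- numeric(nrow(v))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    cm <- rowMeans(v[, idx, drop = FALSE])
    bss <- bss + length(idx) * (cm - grand)^2
    wss <- wss + rowSums((v[, idx, drop = FALSE] - cm)^2)
  }
  ratio <- ifelse(wss == 0, ifelse(bss > 0, Inf, 0), bss / wss)
  names(ratio) <- ds$gene_ids
  ratio
}

#' Keep the top-k genes by score
#'
#' Retains the `k` highest-scoring genes. The retained genes keep their
#' original relative order, and score ties are broken by original gene order,
#' so the operation is fully deterministic.
#'
#' @param ds An `expression_dataset`.
#' @param scores Numeric score per gene (same order as `ds$gene_ids`).
#' @param k Number of genes to keep.
#' @return A new `expression_dataset` with `k` genes.
#' @export
prefilter_top_k <- function(ds, scores, k) {
  if (length(scores) != n_genes(ds)) stop("one score per gene required")
  if (k <= 0) stop("k must be positive")
  if (k > n_genes(ds)) stop("k exceeds gene count")
  keep <- sort(order(-scores, seq_along(scores))[seq_len(k)])
  slice_dataset(ds, genes = keep, check_classes = TRUE)
}
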