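# Score fusion: each filter's raw scores are squashed to (0, 1) by softmax
# scaling, summed across filters, scaled by 10 and rounded to an integer
# score (floored at 1 so every candidate gene stays in play). The integer
# score becomes the gene's multiplicity in the gene frequency map, the pool
# the genetic algorithm samples for initialization and mutation. The map is
# built once per external fold, before any genetic iteration.

#' Softmax-scale one filter's raw score vector
#'
#' Standardizes the vector (population standard deviation) and passes it
#' through the logistic: `scaled = 1 / (1 + exp(-(s - mean) / sd))`.
#' Order-preserving, with every output strictly inside (0, 1). A
#' zero-variance vector maps to all 0.5 with a warning.
#'
#' @param scores Raw scores of one filter across genes (length >= 2).
#' @return Scaled vector in (0, 1).
#' @export
softmax_scale <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores")
  finite <- is.finite(scores)
  if (!all(finite)) {
    # infinities (perfect separators) squash to the logistic bound
    out <- numeric(length(scores))
    out[finite] <- softmax_scale_finite(scores[finite])
    out[!finite] <- ifelse(scores[!finite] > 0, 1, 0)
    return(out)
  }
  softmax_scale_finite(scores)
}

softmax_scale_finite <- function(scores) {
  mu <- mean(scores)
  sdev <- sqrt(mean((scores - mu)^2))
  if (sdev == 0) {
    warning("zero-variance score vector; all entries scaled to 0.5")
    return(rep(0.5, length(scores)))
  }
  1 / (1 + exp(-(scores - mu) / sdev))
}

# round-half-up, documented convention for the 10 * total step
round_half_up <- function(x) floor(x + 0.5)

#' Fuse per-filter scores into total and integer scores
#'
#' Adds to a [score_all_filters()] table one `scaled_<filter>` column per
#' filter (softmax scaling across genes), their sum `total`, and
#' `integer_score = max(1, round_half_up(10 * total))`.
#'
#' @param table A `filter_score_table` of raw scores.
#' @return The table extended with scaled, total and integer-score columns.
#' @export
combine_scores <- function(table) {
  fcols <- setdiff(colnames(table), "gene")
  fcols <- fcols[!startsWith(fcols, "scaled_")]
  fcols <- setdiff(fcols, c("total", "integer_score"))
  if (length(fcols) == 0) stop("no filter columns to combine")
  total <- numeric(nrow(table))
  for (f in fcols) {
    scaled <- softmax_scale(table[[f]])
    table[[paste0("scaled_", f)]] <- scaled
    total <- total + scaled
  }
  table$total <- total
  table$integer_score <- pmax(1L, as.integer(round_half_up(10 * total)))
  class(table) <- c("filter_score_table", "data.frame")
  table
}

#' Build the gene frequency map
#'
#' The multiset ("candidate gene pool") in which each gene appears as many
#' times as its integer score; sampling from it is how filter knowledge
#' biases the genetic operators. Since every integer score is at least 1,
#' every candidate gene is present.
#'
#' @param table A `filter_score_table` with `integer_score` populated
#'   (see [combine_scores()]).
#' @param seed Seed for the map's own draw stream.
#' @return Object of class `gene_frequency_map` with elements `gene_ids`,
#'   `scores` (integer multiplicities), `pool` (gene index per pool entry)
#'   and `seed`.
#' @export
build_frequency_map <- function(table, seed = 1) {
  if (nrow(table) == 0) stop("empty score table")
  if (is.null(table$integer_score)) stop("run combine_scores() first")
  scores <- as.integer(table$integer_score)
  stopifnot(all(scores >= 1))
  structure(
    list(gene_ids = table$gene, scores = scores,
         pool = rep.int(seq_along(scores), scores), seed = seed),
    class = "gene_frequency_map"
  )
}

#' Uniform frequency map (plain genetic-ensemble baseline)
#'
#' Every gene with multiplicity 1: the sampling law the genetic engine falls
#' back to when no filter information is fused in. Used as the paired
#' baseline when measuring what the multi-filter map buys.
#'
#' @param gene_ids Candidate gene identifiers.
#' @param seed Seed for the map's draw stream.
#' @return A `gene_frequency_map`.
#' @export
uniform_frequency_map <- function(gene_ids, seed = 1) {
  n <- length(gene_ids)
  if (n == 0) stop("no genes")
  structure(
    list(gene_ids = gene_ids, scores = rep.int(1L, n), pool = seq_len(n),
         seed = seed),
    class = "gene_frequency_map"
  )
}

#' @export
print.gene_frequency_map <- function(x, ...) {
  cat("gene_frequency_map:", length(x$gene_ids), "genes, pool size",
      length(x$pool), "\n")
  invisible(x)
}

#' Draw one gene from the frequency map
#'
#' Uniform draw from the pool (so gene probabilities are proportional to
#' integer scores), rejecting excluded genes by renormalizing over the
#' allowed part of the pool.
#'
#' @param map A `gene_frequency_map`.
#' @param exclude Integer indices (into `map$gene_ids`) to exclude.
#' @return One gene index, or `NA_integer_` if every gene is excluded
#'   (exhaustion; callers must handle it).
#' @export
draw_gene <- function(map, exclude = integer(0)) {
  if (length(exclude) == 0) {
    return(map$pool[sample.int(length(map$pool), 1L)])
  }
  allowed <- map$pool[!(map$pool %in% exclude)]
  if (length(allowed) == 0) return(NA_integer_)
  allowed[sample.int(length(allowed), 1L)]
}
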