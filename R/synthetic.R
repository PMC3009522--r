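# Synthetic expression data with planted differential genes. Emulates the
# microarray regime the selection pipeline targets: many more genes than
# samples, a small informative subset with shifted class means, everything
# else class-independent Gaussian noise.

#' Specification for a synthetic expression dataset
#'
#' @param n_genes Total genes (default 200, the post-prefilter size the
#'   wrapper stage works with).
#' @param class_sizes Samples per class; default `c(25, 25)`. A three-class
#'   layout such as `c(24, 20, 28)` mimics a leukemia-subtype multi-class
#'   task.
#' @param n_informative Number of planted class-informative genes.
#' @param effect_size Class-mean shift of informative genes, in noise-sd
#'   units.
#' @param rho Optional within-block correlation among informative genes
#'   (redundant-gene scenario), in `[0, 1)`.
#' @param noise One of `"gaussian"` (default) or `"t"` (heavy-tailed,
#'   4 degrees of freedom) for robustness checks.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200, class_sizes = c(25, 25),
                           n_informative = 10, effect_size = 1.5,
                           rho = 0, noise = c("gaussian", "t"), seed = 1) {
  noise <- match.arg(noise)
  if (n_informative > n_genes) stop("n_informative exceeds n_genes")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (length(class_sizes) < 2 || any(class_sizes < 2)) {
    stop("need >= 2 classes with >= 2 samples each")
  }
  structure(list(n_genes = n_genes, class_sizes = class_sizes,
                 n_informative = n_informative, effect_size = effect_size,
                 rho = rho, noise = noise, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with planted genes
#'
#' Informative genes receive class-conditional mean shifts of
#' `effect_size` noise-sd units; null genes are class-independent noise.
#' For two classes the shift is `+effect_size/2` vs `-effect_size/2`. With
#' `m > 2` classes, each informative gene is assigned (round-robin) one
#' class pair that it separates by the full effect size, the remaining
#' classes sitting at 0, so every informative gene separates at least one
#' class pair and the two-class parameterization is recovered exactly at
#' `m = 2`. Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (an `expression_dataset`) and `informative`
#'   (character vector of planted gene ids, named `inf01`, `inf02`, ...;
#'   null genes are `null0001`, ...).
#' @export
generate_synthetic <- function(spec) {
  m <- length(spec$class_sizes)
  n <- sum(spec$class_sizes)
  labels <- factor(rep(paste0("C", seq_len(m)), spec$class_sizes))
  inf_ids <- sprintf("inf%02d", seq_len(spec$n_informative))
  null_ids <- sprintf("null%04d",
                      seq_len(spec$n_genes - spec$n_informative))
  gene_ids <- c(inf_ids, null_ids)

  # class-mean matrix for informative genes (genes x classes)
  mu <- matrix(0, spec$n_informative, m)
  if (spec$n_informative > 0) {
    if (m == 2) {
      mu[, 1] <- spec$effect_size / 2
      mu[, 2] <- -spec$effect_size / 2
    } else {
      pairs <- utils::combn(m, 2)
      for (g in seq_len(spec$n_informative)) {
        p <- pairs[, ((g - 1) %% ncol(pairs)) + 1]
        mu[g, p[1]] <- spec$effect_size / 2
        mu[g, p[2]] <- -spec$effect_size / 2
      }
    }
  }

  with_seed(spec$seed, {
    draw <- function(k) {
      if (spec$noise == "gaussian") rnorm(k)
      else stats::rt(k, df = 4) / sqrt(2) # unit-variance t(4)
    }
    vals <- matrix(draw(spec$n_genes * n), spec$n_genes, n)
    if (spec$rho > 0 && spec$n_informative > 1) {
      # equicorrelated informative block: shared factor construction
      shared <- matrix(draw(n), 1, n)
      idx <- seq_len(spec$n_informative)
      vals[idx, ] <- sqrt(spec$rho) * shared[rep(1, length(idx)), ] +
        sqrt(1 - spec$rho) * vals[idx, ]
    }
    if (spec$n_informative > 0) {
      vals[seq_len(spec$n_informative), ] <-
        vals[seq_len(spec$n_informative), , drop = FALSE] +
        mu[, as.integer(labels), drop = FALSE]
    }
  })
  ds <- expression_dataset(vals, gene_ids = gene_ids,
                           sample_ids = sprintf("s%03d", seq_len(n)),
                           labels = labels)
  list(dataset = ds, informative = inf_ids)
}

#' @rdname generate_synthetic
#' @param ... Arguments passed to [synthetic_spec()]; `class_sizes`
#'   defaults to the three-class layout `c(24, 20, 28)`.
#' @export
generate_multiclass <- function(...) {
  args <- list(...)
  if (is.null(args$class_sizes)) args$class_sizes <- c(24, 20, 28)
  generate_synthetic(do.call(synthetic_spec, args))
}
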