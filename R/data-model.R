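#' Construct an expression dataset
#'
#' The universal input container: a genes-by-samples matrix of continuous
#' expression values with a categorical class label per sample.
#'
#' @param values Numeric matrix, one row per gene, one column per sample.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param sample_ids Character vector of unique sample identifiers (columns).
#' @param labels Class label per sample; coerced to factor. At least two
#'   classes, each with at least two samples, are required for the stratified
#'   cross-validation and per-class sensitivity machinery downstream.
#' @param check_classes If `FALSE`, skip the two-samples-per-class check
#'   (used internally when slicing folds).
#' @return An object of class `expression_dataset` with elements `values`,
#'   `gene_ids`, `sample_ids`, `labels`.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values), labels,
                               check_classes = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                       collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (nrow(values) != length(gene_ids)) {
    stop("row count (", nrow(values), ") != number of gene ids (",
         length(gene_ids), ")")
  }
  if (ncol(values) != length(sample_ids)) {
    stop("column count (", ncol(values), ") != number of sample ids (",
         length(sample_ids), ")")
  }
  if (length(labels) != ncol(values)) {
    stop("need one label per sample: got ", length(labels), " labels for ",
         ncol(values), " samples")
  }
  if (anyNA(values)) stop("missing expression values; impute or filter first")
  if (anyNA(labels)) stop("missing class labels")
  labels <- droplevels(as.factor(labels))
  if (check_classes) {
    if (nlevels(labels) < 2) stop("need at least 2 classes")
    sizes <- table(labels)
    if (any(sizes < 2)) {
      stop("every class needs >= 2 samples; too small: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
    }
  }
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples\n")
  cat("classes:", paste(sprintf("%s (%d)", levels(x$labels),
                                tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Number of genes / samples in an expression dataset
#' @param ds An `expression_dataset`.
#' @return Integer count.
#' @export
n_genes <- function(ds) nrow(ds$values)

#' @rdname n_genes
#' @export
n_samples <- function(ds) ncol(ds$values)

#' Subset an expression dataset by genes and/or samples
#'
#' @param ds An `expression_dataset`.
#' @param genes Gene indices or ids to keep (default all).
#' @param samples Sample indices or ids to keep (default all).
#' @param check_classes Passed to [expression_dataset()]; fold slices may
#'   legitimately hold singleton classes.
#' @return A new `expression_dataset`.
#' @export
slice_dataset <- function(ds, genes = NULL, samples = NULL,
                          check_classes = FALSE) {
  gi <- if (is.null(genes)) seq_len(n_genes(ds)) else genes
  si <- if (is.null(samples)) seq_len(n_samples(ds)) else samples
  if (is.character(gi)) gi <- match(gi, ds$gene_ids)
  if (is.character(si)) si <- match(si, ds$sample_ids)
  if (anyNA(gi)) stop("unknown gene id")
  if (anyNA(si)) stop("unknown sample id")
  expression_dataset(ds$values[gi, si, drop = FALSE],
                     gene_ids = ds$gene_ids[gi],
                     sample_ids = ds$sample_ids[si],
                     labels = ds$labels[si],
                     check_classes = check_classes)
}

#' Read a delimited expression table
#'
#' Expects genes as rows: first column gene id, header row of sample ids.
#' Class labels come either from a dedicated label row inside the table
#' (`label_row`, matched against the gene-id column) or from a separate
#' two-column samples-to-labels file (`label_file`).
#'
#' @param path Path to the delimited matrix.
#' @param label_row Name in the first column marking the label row
#'   (default `"class"`). Ignored when `label_file` is given.
#' @param label_file Optional path to a two-column (sample id, label) file.
#' @param sep Field separator (default tab).
#' @param impute_missing If `TRUE`, missing expression cells are replaced by
#'   the per-gene mean; the default is to reject files with missing cells.
#' @return An `expression_dataset`.
#' @export
read_expression_table <- function(path, label_row = "class",
                                  label_file = NULL, sep = "\t",
                                  impute_missing = FALSE) {
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression table needs a gene-id column plus samples")
  ids <- as.character(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  sample_ids <- colnames(body)

  if (is.null(label_file)) {
    hit <- which(ids == label_row)
    if (length(hit) != 1) {
      stop("expected exactly one label row named '", label_row, "' in ", path)
    }
    labels <- as.character(unlist(body[hit, ]))
    if (anyNA(labels) | any(labels == "")) {
      stop("label row '", label_row, "' does not name a class for every sample")
    }
    ids <- ids[-hit]
    body <- body[-hit, , drop = FALSE]
  } else {
    lab <- read.delim(label_file, sep = sep, header = FALSE,
                      stringsAsFactors = FALSE)
    labels <- as.character(lab[[2]])[match(sample_ids, as.character(lab[[1]]))]
    if (anyNA(labels)) {
      stop("label file misses samples: ",
           paste(sample_ids[is.na(labels)], collapse = ", "))
    }
  }

  vals <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)))
  )
  vals <- matrix(vals, nrow = length(ids),
                 dimnames = list(ids, sample_ids))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (!impute_missing) {
      stop("non-numeric or missing cell at gene '", ids[bad[1, 1]],
           "', sample '", sample_ids[bad[1, 2]], "'")
    }
    for (r in unique(bad[, 1])) {
      row <- vals[r, ]
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      vals[r, ] <- row
    }
  }
  expression_dataset(vals, gene_ids = ids, sample_ids = sample_ids,
                     labels = labels)
}

#' Write an expression dataset as delimited text
#'
#' Inverse of [read_expression_table()] (label-row dialect): first column
#' gene id, header of sample ids, with the class labels in a row named
#' `label_row`.
#'
#' @param ds An `expression_dataset`.
#' @param path Output path.
#' @param label_row Name of the label row (default `"class"`).
#' @param sep Field separator (default tab).
#' @export
write_expression_table <- function(ds, path, label_row = "class", sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", ds$sample_ids), collapse = sep), con)
  writeLines(paste(c(label_row, as.character(ds$labels)), collapse = sep), con)
  body <- apply(ds$values, 1, function(r) {
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = sep)
  })
  writeLines(paste(ds$gene_ids, body, sep = sep), con)
  invisible(path)
}
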