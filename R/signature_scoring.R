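#' Construct a two-centroid gene signature
#'
#' The NE signature consists of 50 genes with two reference expression
#' prototypes on log2 scale: the centroid of neuroendocrine (NE) cell lines
#' and the centroid of non-NE cell lines. A test profile's NE score is half
#' the difference of its Pearson correlations with the two centroids.
#'
#' @param gene_ids character vector of unique gene identifiers.
#' @param ne_centroid,non_ne_centroid numeric vectors of log2-scale centroid
#'   expression, same length and order as `gene_ids`.
#' @param name free-text label for the signature.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(gene_ids, ne_centroid, non_ne_centroid,
                           name = "NE signature") {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    stop_validation(sprintf("duplicate gene id(s) in signature: %s",
                            paste(unique(gene_ids[duplicated(gene_ids)]),
                                  collapse = ", ")))
  }
  if (length(gene_ids) != length(ne_centroid) ||
      length(gene_ids) != length(non_ne_centroid)) {
    stop_validation("gene_ids and both centroids must have equal length")
  }
  if (!is.numeric(ne_centroid) || !is.numeric(non_ne_centroid) ||
      anyNA(ne_centroid) || anyNA(non_ne_centroid)) {
    stop_validation("centroid values must be numeric and non-missing")
  }
  if (stats::sd(ne_centroid) == 0) {
    stop_validation("constant centroid: ne_centroid has zero variance")
  }
  if (stats::sd(non_ne_centroid) == 0) {
    stop_validation("constant centroid: non_ne_centroid has zero variance")
  }
  if (isTRUE(all.equal(ne_centroid, non_ne_centroid, tolerance = 0))) {
    stop_validation("ne_centroid and non_ne_centroid are identical; every score would be 0")
  }
  structure(
    list(gene_ids = gene_ids,
         ne_centroid = stats::setNames(as.numeric(ne_centroid), gene_ids),
         non_ne_centroid = stats::setNames(as.numeric(non_ne_centroid), gene_ids),
         name = name),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes, centroid correlation %.3f\n",
              x$name, length(x$gene_ids),
              stats::cor(x$ne_centroid, x$non_ne_centroid)))
  invisible(x)
}

#' Load a two-centroid signature from TSV
#'
#' Expects a UTF-8 TSV with header columns `gene`, `ne_centroid`,
#' `non_ne_centroid` and at least 3 data rows. Duplicate genes, non-numeric
#' centroid entries and constant centroids are rejected.
#'
#' @param path file path.
#' @return A [gene_signature()].
#' @export
load_signature <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("gene", "ne_centroid", "non_ne_centroid")
  if (!all(need %in% colnames(tab))) {
    stop_format(sprintf("signature file must have columns %s (found: %s)",
                        paste(need, collapse = ", "),
                        paste(colnames(tab), collapse = ", ")))
  }
  if (nrow(tab) < 3L) stop_format("signature file needs at least 3 data rows")
  ne <- suppressWarnings(as.numeric(tab$ne_centroid))
  non_ne <- suppressWarnings(as.numeric(tab$non_ne_centroid))
  if (anyNA(ne) || anyNA(non_ne)) {
    stop_validation("non-numeric centroid entries in signature file")
  }
  gene_signature(tab$gene, ne, non_ne, name = basename(path))
}

#' Write a signature to TSV
#' @param signature a [gene_signature()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  tab <- data.frame(gene = signature$gene_ids,
                    ne_centroid = unname(signature$ne_centroid),
                    non_ne_centroid = unname(signature$non_ne_centroid))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute the NE score of a single expression profile
#'
#' `score = (correl_ne - correl_non_ne) / 2`, where `correl_ne` and
#' `correl_non_ne` are the Pearson correlations between the profile and the
#' NE / non-NE centroid over the genes shared between profile and signature.
#' The score lies in [-1, 1]; positive predicts NE identity, negative
#' non-NE, and exactly zero is called indeterminate. `NA` profile values
#' exclude that gene pairwise and decrement `n_genes_used`.
#'
#' @param profile named numeric vector (gene -> log2 expression) for one
#'   sample.
#' @param signature a [gene_signature()].
#' @param min_genes minimum number of signature genes that must be measured
#'   in the profile (default 40 of the 50).
#' @return A one-row data frame with columns `sample`, `correl_ne`,
#'   `correl_non_ne`, `ne_score`, `n_genes_used`, `call`.
#' @export
compute_ne_score <- function(profile, signature, min_genes = 40L) {
  stopifnot(inherits(signature, "gene_signature"))
  assert_count(min_genes, "min_genes", min = 3L)
  if (is.null(names(profile))) {
    if (length(profile) == length(signature$gene_ids)) {
      names(profile) <- signature$gene_ids
    } else {
      stop_validation("'profile' must be a named numeric vector")
    }
  }
  shared <- intersect(names(profile), signature$gene_ids)
  x <- profile[shared]
  shared <- shared[!is.na(x)]
  x <- profile[shared]
  n_used <- length(shared)
  if (n_used < min_genes) {
    stop_overlap(sprintf(
      "only %d of %d signature genes measured (min_genes = %d)",
      n_used, length(signature$gene_ids), min_genes))
  }
  if (stats::sd(x) == 0) {
    stop_degenerate("profile has zero variance over signature genes; Pearson correlation undefined")
  }
  correl_ne <- stats::cor(x, signature$ne_centroid[shared])
  correl_non_ne <- stats::cor(x, signature$non_ne_centroid[shared])
  score <- (correl_ne - correl_non_ne) / 2
  data.frame(
    sample = "sample",
    correl_ne = correl_ne,
    correl_non_ne = correl_non_ne,
    ne_score = score,
    n_genes_used = n_used,
    call = if (score > 0) "NE" else if (score < 0) "non-NE" else "indeterminate",
    stringsAsFactors = FALSE
  )
}

#' NE scores for every sample of an expression matrix
#'
#' Applies [compute_ne_score()] to each column. Samples that fail their
#' preconditions (insufficient signature-gene overlap, zero variance) are
#' kept in the output with `NA` statistics and the failure reason in the
#' `note` column; the run continues. Output rows follow input sample order.
#'
#' @param expr [expression_matrix()] (log2 scale) or named numeric matrix
#'   attested to be log2. Linear-scale input is log2(x+1)-transformed with a
#'   warning.
#' @param signature a [gene_signature()].
#' @param min_genes see [compute_ne_score()].
#' @return Data frame with one row per sample: `sample`, `correl_ne`,
#'   `correl_non_ne`, `ne_score`, `n_genes_used`, `call`, `note`.
#' @export
score_matrix <- function(expr, signature, min_genes = 40L) {
  expr <- as_expression_matrix(expr)
  if (expr$scale == "linear") {
    warning("linear-scale matrix: applying log2(x + 1) before scoring",
            call. = FALSE)
    expr <- log2_transform(expr, offset = 1)
  }
  samples <- sample_ids(expr)
  rows <- lapply(samples, function(s) {
    res <- tryCatch(
      compute_ne_score(expr$values[, s], signature, min_genes = min_genes),
      nescore_error = function(e) e
    )
    if (inherits(res, "condition")) {
      data.frame(sample = s, correl_ne = NA_real_, correl_non_ne = NA_real_,
                 ne_score = NA_real_, n_genes_used = NA_integer_,
                 call = NA_character_, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      res$sample <- s
      res$note <- ""
      res
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  failed <- out$note != ""
  if (all(failed)) {
    stop_overlap(sprintf("no sample scoreable: %s", out$note[1L]))
  }
  if (any(failed)) {
    warning(sprintf("%d sample(s) not scoreable; see the 'note' column",
                    sum(failed)), call. = FALSE)
  }
  out
}

#' Write NE score table to TSV
#' @param scores data frame from [score_matrix()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
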