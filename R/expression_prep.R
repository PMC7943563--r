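#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto a common distribution: the reference is
#' the vector of row means of the column-sorted matrix, and each column's
#' values are replaced by the reference value at their rank. Tied values
#' within a column receive the mean of the reference values at their tied
#' ranks. Row and column identifiers are unchanged.
#'
#' @param expr an [expression_matrix()] or named numeric matrix. Must be
#'   NA-free.
#' @return An `expression_matrix` of the same shape and scale tag.
#' @export
quantile_normalize <- function(expr) {
  expr <- as_expression_matrix(expr)
  v <- expr$values
  if (anyNA(v)) stop_validation("quantile_normalize does not support NA values")
  reference <- rowMeans(apply(v, 2L, sort))
  out <- apply(v, 2L, function(x) {
    mapped <- reference[rank(x, ties.method = "first")]
    # tie groups occupy contiguous ranks; average the reference over each group
    stats::ave(mapped, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, scale = expr$scale, provenance = expr$provenance)
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param expr linear-scale [expression_matrix()] with nonnegative values.
#' @param offset nonnegative pseudocount added before taking log2 (default 1).
#' @return A log2-scale `expression_matrix`.
#' @export
log2_transform <- function(expr, offset = 1) {
  expr <- if (inherits(expr, "expression_matrix")) expr else
    expression_matrix(expr, scale = "linear")
  assert_scalar_number(offset, "offset")
  if (offset < 0) stop_validation("'offset' must be nonnegative")
  if (expr$scale == "log2") {
    stop_validation("matrix is already log2 scale; refusing to double-transform")
  }
  if (any(expr$values < 0, na.rm = TRUE)) {
    stop_validation("negative values present; cannot log2-transform")
  }
  expression_matrix(log2(expr$values + offset), scale = "log2",
                    provenance = expr$provenance)
}

#' Library-size normalize a count matrix
#'
#' Rescales every sample so its column total equals a common target, by
#' default the median of the original column totals.
#'
#' @param counts [expression_matrix()] or matrix of nonnegative values.
#' @param target total to scale each column to; default the median of the
#'   observed column totals.
#' @return An `expression_matrix` on the same scale tag.
#' @export
library_size_normalize <- function(counts, target = NULL) {
  counts <- if (inherits(counts, "expression_matrix")) counts else
    expression_matrix(counts, scale = "linear")
  v <- counts$values
  if (any(v < 0, na.rm = TRUE)) stop_validation("counts must be nonnegative")
  totals <- colSums(v, na.rm = TRUE)
  if (any(totals <= 0)) {
    stop_validation(sprintf("zero-total sample(s): %s",
                            paste(colnames(v)[totals <= 0], collapse = ", ")))
  }
  if (is.null(target)) target <- stats::median(totals)
  assert_scalar_number(target, "target")
  out <- sweep(v, 2L, target / totals, `*`)
  expression_matrix(out, scale = counts$scale, provenance = counts$provenance)
}

#' Z-score standardize along samples or genes
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n - 1
#' convention) along the chosen axis. Constant vectors map to all zeros with
#' a warning rather than failing.
#'
#' @param expr [expression_matrix()] or named numeric matrix.
#' @param axis `"per_sample"` standardizes each column; `"per_gene"` each row.
#' @return An `expression_matrix` of the same shape.
#' @export
zscore_standardize <- function(expr, axis = c("per_sample", "per_gene")) {
  axis <- match.arg(axis)
  expr <- as_expression_matrix(expr)
  v <- expr$values
  n_along <- if (axis == "per_sample") nrow(v) else ncol(v)
  if (n_along < 2L) stop_validation("cannot z-score an axis of length 1")
  zfun <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  }
  if (axis == "per_sample") {
    sds <- apply(v, 2L, stats::sd, na.rm = TRUE)
    out <- apply(v, 2L, zfun)
  } else {
    sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
    out <- t(apply(v, 1L, zfun))
  }
  if (any(sds == 0, na.rm = TRUE)) {
    warning(sprintf("%d constant %s vector(s) mapped to zeros",
                    sum(sds == 0, na.rm = TRUE),
                    if (axis == "per_sample") "sample" else "gene"),
            call. = FALSE)
  }
  dimnames(out) <- dimnames(v)
  expression_matrix(out, scale = expr$scale, provenance = expr$provenance)
}

#' Cluster-average expression with per-gene min-max scaling
#'
#' Pseudobulk summary for single-cell data: averages expression within each
#' cell cluster, drops clusters below a minimum size, then min-max scales
#' each gene across the retained clusters to [0, 1]. Genes constant across
#' clusters map to all zeros with a warning.
#'
#' @param expr [expression_matrix()] with one column per cell.
#' @param cell_to_cluster named character/factor vector mapping every column
#'   of `expr` to a cluster label.
#' @param min_cluster_size clusters with fewer members are dropped (default
#'   10).
#' @return An `expression_matrix` with one column per retained cluster.
#' @export
cluster_average_minmax <- function(expr, cell_to_cluster, min_cluster_size = 10L) {
  expr <- as_expression_matrix(expr)
  assert_count(min_cluster_size, "min_cluster_size")
  v <- expr$values
  if (is.null(names(cell_to_cluster))) {
    if (length(cell_to_cluster) != ncol(v)) {
      stop_validation("cell_to_cluster must be named or match the sample count")
    }
    names(cell_to_cluster) <- colnames(v)
  }
  missing <- setdiff(colnames(v), names(cell_to_cluster))
  if (length(missing)) {
    stop_validation(sprintf("no cluster assignment for: %s",
                            paste(utils::head(missing, 5L), collapse = ", ")))
  }
  cl <- as.character(cell_to_cluster[colnames(v)])
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_cluster_size]
  dropped <- setdiff(names(sizes), keep)
  if (length(dropped)) {
    message(sprintf("dropping %d cluster(s) below %d cells: %s",
                    length(dropped), min_cluster_size,
                    paste(dropped, collapse = ", ")))
  }
  if (length(keep) < 2L) {
    stop_validation("fewer than 2 clusters retained; cannot min-max scale")
  }
  in_keep <- cl %in% keep
  means <- t(rowsum(t(v[, in_keep, drop = FALSE]), group = cl[in_keep])) /
    rep(as.vector(sizes[sort(keep)]), each = nrow(v))
  means <- means[, sort(keep), drop = FALSE]
  rng <- apply(means, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  flat <- span == 0
  span[flat] <- 1
  out <- (means - rng[1L, ]) / span
  out[flat, ] <- 0
  if (any(flat)) {
    warning(sprintf("%d gene(s) constant across clusters mapped to zeros",
                    sum(flat)), call. = FALSE)
  }
  expression_matrix(out, scale = expr$scale,
                    provenance = paste0(expr$provenance, " [pseudobulk]"))
}
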