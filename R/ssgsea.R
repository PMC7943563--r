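#' Single-sample GSEA (ssGSEA) scores
#'
#' Per-sample rank-based score of a gene set's coordinate up-expression.
#' Within each sample, genes are ranked by expression (descending; ties get
#' average ranks, order within ties broken by gene id). Walking down the
#' ranking, the score is the sum over all positions of the difference
#' between the weighted empirical CDF of in-set genes and the unweighted
#' ECDF of out-of-set genes; the in-set weight of the gene at descending
#' position i is its rank-from-the-bottom raised to `alpha`, normalized
#' over the set, so highly expressed genes weigh most. With `alpha = 0` the
#' statistic reduces to the plain ECDF difference. If `normalize` is on,
#' the whole score matrix is divided by its global range.
#'
#' @param expr [expression_matrix()] or named numeric matrix with >= 2 genes.
#' @param sets [gene_set_collection()] or named list of gene vectors; sets
#'   with empty or full intersection with the matrix genes are skipped with
#'   a message.
#' @param alpha rank weighting exponent (default 0.25).
#' @param normalize divide all scores by (global max - global min) so the
#'   output spans one unit (default `TRUE`).
#' @return A samples x sets numeric matrix with attributes `alpha` and
#'   `normalized`.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  expr <- as_expression_matrix(expr)
  assert_scalar_number(alpha, "alpha")
  if (alpha < 0) stop_validation("'alpha' must be >= 0")
  v <- expr$values
  n <- nrow(v)
  if (n < 2L) stop_validation("need at least 2 genes")
  genes <- rownames(v)
  restricted <- lapply(sets, intersect, x = genes)
  usable <- vapply(restricted, function(g) length(g) >= 1L && length(g) < n,
                   logical(1L))
  if (any(!usable)) {
    message(sprintf("skipping %d set(s) with empty or full gene overlap: %s",
                    sum(!usable),
                    paste(names(sets)[!usable], collapse = ", ")))
  }
  restricted <- restricted[usable]
  if (length(restricted) == 0L) stop_validation("no usable gene set")
  hits <- lapply(restricted, function(g) genes %in% g)
  scores <- matrix(NA_real_, nrow = ncol(v), ncol = length(restricted),
                   dimnames = list(colnames(v), names(restricted)))
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    ord <- order(-x, genes)               # descending, deterministic ties
    rank_bottom <- rank(x, ties.method = "average")  # N for the top gene
    w <- rank_bottom[ord]^alpha
    for (s in seq_along(hits)) {
      h <- hits[[s]][ord]
      k <- sum(h)
      in_cdf <- cumsum(w * h) / sum(w[h])
      out_cdf <- cumsum(!h) / (n - k)
      scores[j, s] <- sum(in_cdf - out_cdf)
    }
  }
  if (normalize) {
    spread <- max(scores) - min(scores)
    if (spread > 0) scores <- scores / spread
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  scores
}
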