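#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort p-values ascending,
#' multiply the i-th by m/i, take cumulative minima from the largest, cap at
#' 1 and return in input order. Wraps [stats::p.adjust()] after validating
#' the input range.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || length(pvalues) == 0L) {
    stop_validation("'pvalues' must be a nonempty numeric vector")
  }
  if (anyNA(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues <= 0) || any(pvalues > 1)) {
    stop_validation("p-values must be finite and in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Correlate every gene with the NE score
#'
#' Per-gene Pearson correlation against the NE score vector with
#' pairwise-complete observations, two-sided p-values from the exact t
#' transform (n - 2 degrees of freedom) and BH adjustment over the tested
#' genes. Constant genes and genes with fewer than 3 complete pairs are
#' excluded (count reported).
#'
#' @param expr [expression_matrix()] or named numeric matrix.
#' @param scores per-sample NE scores (named, or aligned with columns).
#' @return Data frame with columns `gene`, `r`, `n`, `pvalue`, `padj`,
#'   ordered by ascending `pvalue`.
#' @export
correlate_genes_with_score <- function(expr, scores) {
  expr <- as_expression_matrix(expr)
  v <- expr$values
  if (!is.null(names(scores))) scores <- scores[colnames(v)]
  if (length(scores) != ncol(v)) {
    stop_validation("'scores' must align with the matrix samples")
  }
  if (ncol(v) < 3L) stop_validation("need at least 3 samples")
  ok_s <- !is.na(scores)
  n <- rowSums(!is.na(v[, ok_s, drop = FALSE]))
  sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
  keep <- n >= 3L & !is.na(sds) & sds > 0
  if (!any(keep)) stop_degenerate("no testable gene (all constant or too few observations)")
  if (any(!keep)) {
    message(sprintf("excluded %d gene(s): constant or < 3 complete pairs",
                    sum(!keep)))
  }
  r <- as.vector(stats::cor(t(v[keep, , drop = FALSE]), scores,
                            use = "pairwise.complete.obs"))
  pv <- cor_pvalue(r, n[keep])
  out <- data.frame(gene = rownames(v)[keep], r = r, n = n[keep],
                    pvalue = pv, padj = bh_adjust(pv),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pvalue, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group comparison by t-test
#'
#' Welch's unequal-variance t-test by default (the pooled-variance Student
#' form is available via `var_equal = TRUE`), two-sided.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance form (default `FALSE` = Welch).
#' @return A list with `t`, `pvalue`, `mean_a`, `mean_b`, `df`.
#' @export
group_compare <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop_validation("each group needs at least 2 values")
  }
  ht <- tryCatch(
    stats::t.test(values_a, values_b, var.equal = var_equal),
    error = function(e) stop_degenerate(paste("t-test undefined:",
                                              conditionMessage(e)))
  )
  list(t = unname(ht$statistic), pvalue = ht$p.value,
       mean_a = mean(values_a), mean_b = mean(values_b),
       df = unname(ht$parameter))
}

#' Sign-proportion enrichment of a gene category
#'
#' Tests whether genes of a category (e.g. innate immune genes) are
#' negatively associated with the NE score more often than the background:
#' builds the 2x2 table (in-set vs background) x (negative r vs nonnegative
#' r) and applies Pearson's chi-squared test without continuity correction
#' (1 df). With `significant_only = TRUE` only genes passing `alpha` on the
#' adjusted p-value count as negative/nonnegative, the rest are excluded.
#'
#' @param associations data frame from [correlate_genes_with_score()].
#' @param set character vector of category gene ids.
#' @param significant_only restrict to genes with `padj <= alpha` before
#'   counting signs (default `FALSE`: sign of r alone).
#' @param alpha significance threshold used when `significant_only` is on.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return A list with the four counts, `prop_neg_in_set`,
#'   `prop_neg_background`, `chi2` and `pvalue`.
#' @export
sign_proportion_test <- function(associations, set, significant_only = FALSE,
                                 alpha = 0.05, correct = FALSE) {
  need <- c("gene", "r", "padj")
  if (!is.data.frame(associations) || !all(need %in% names(associations))) {
    stop_validation("'associations' must have columns gene, r, padj")
  }
  a <- associations
  if (significant_only) a <- a[a$padj <= alpha, , drop = FALSE]
  in_set <- a$gene %in% set
  if (!any(in_set)) stop_validation("category does not intersect the tested genes")
  if (all(in_set)) stop_validation("background is empty (every tested gene is in the category)")
  neg <- a$r < 0
  tab <- matrix(c(sum(in_set & neg), sum(in_set & !neg),
                  sum(!in_set & neg), sum(!in_set & !neg)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("set", "background"),
                                c("negative", "nonnegative")))
  if (any(rowSums(tab) == 0L)) {
    stop_degenerate(sprintf("zero row margin: %s",
                            rownames(tab)[rowSums(tab) == 0L][1L]))
  }
  if (any(colSums(tab) == 0L)) {
    stop_degenerate(sprintf("zero column margin: %s",
                            colnames(tab)[colSums(tab) == 0L][1L]))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(n_neg_in_set = tab[1L, 1L], n_nonneg_in_set = tab[1L, 2L],
       n_neg_background = tab[2L, 1L], n_nonneg_background = tab[2L, 2L],
       prop_neg_in_set = tab[1L, 1L] / sum(tab[1L, ]),
       prop_neg_background = tab[2L, 1L] / sum(tab[2L, ]),
       chi2 = unname(ht$statistic), pvalue = ht$p.value)
}

#' Pairwise Pearson correlation panel
#'
#' All-pairs correlation of a small panel of per-sample variables (NE score,
#' T-cell density, signature scores ...), as displayed in pairwise scatter
#' matrices: a symmetric r matrix with unit diagonal and two-sided p-values
#' from the t transform.
#'
#' @param variables named list of equal-length numeric vectors (length >= 3).
#' @return List of two matrices, `r` and `pvalue` (diagonal p `NA`).
#' @export
pairwise_correlation_panel <- function(variables) {
  if (!is.list(variables) || length(variables) < 2L ||
      is.null(names(variables))) {
    stop_validation("'variables' must be a named list of >= 2 vectors")
  }
  len <- unique(lengths(variables))
  if (length(len) != 1L) stop_validation("all variables must have the same length")
  if (len < 3L) stop_validation("variables need length >= 3")
  m <- do.call(cbind, variables)
  r <- stats::cor(m, use = "pairwise.complete.obs")
  n_pair <- crossprod(!is.na(m))
  pv <- matrix(cor_pvalue(as.vector(r), as.vector(n_pair)),
               nrow = nrow(r), dimnames = dimnames(r))
  diag(r) <- 1
  diag(pv) <- NA_real_
  list(r = r, pvalue = pv)
}
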