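#' Immunohistochemistry H-score
#'
#' Summary of nuclear staining over a region: `3 * %strong + 2 * %moderate +
#' 1 * %weak`, where the percentages are the extent of reactivity at
#' intensity levels 3/2/1 (level 0 is the implicit remainder). Range 0-300.
#'
#' @param pct_strong,pct_moderate,pct_weak percentages in [0, 100] of nuclei
#'   at intensity 3, 2 and 1; vectors are accepted and recycled elementwise.
#' @return Numeric H-score(s) in [0, 300].
#' @export
h_score <- function(pct_strong, pct_moderate, pct_weak) {
  pcts <- cbind(pct_strong, pct_moderate, pct_weak)
  if (anyNA(pcts) || any(!is.finite(pcts))) {
    stop_validation("percentages must be finite")
  }
  if (any(pcts < 0)) stop_validation("percentages must be nonnegative")
  if (any(pcts > 100) || any(rowSums(pcts) > 100 + 1e-9)) {
    stop_validation("intensity percentages must sum to at most 100")
  }
  as.vector(pcts %*% c(3, 2, 1))
}

#' H-scores for a table of intensity breakdowns
#'
#' @param table data frame with columns `sample`, `pct_strong`,
#'   `pct_moderate`, `pct_weak`.
#' @return The table with an `h_score` column appended.
#' @export
h_score_table <- function(table) {
  need <- c("sample", "pct_strong", "pct_moderate", "pct_weak")
  if (!all(need %in% names(table))) {
    stop_format(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  }
  table$h_score <- h_score(table$pct_strong, table$pct_moderate, table$pct_weak)
  table
}

#' Cells per square millimetre of analysed tissue
#'
#' @param count nonnegative cell count(s).
#' @param area_mm2 analysed area(s) in mm^2, strictly positive.
#' @return Cell density, cells/mm^2.
#' @export
cell_density <- function(count, area_mm2) {
  if (any(!is.finite(count)) || any(count < 0)) {
    stop_validation("'count' must be nonnegative and finite")
  }
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0)) {
    stop_validation("'area_mm2' must be positive")
  }
  count / area_mm2
}

#' qPCR relative expression against a parental group
#'
#' Per sample, the target and control (housekeeping, e.g. PPIA) Ct values
#' are each summarized by the median over replicates; the normalized value
#' is `2^(median Ct_control - median Ct_target)`; the fold change divides by
#' the median normalized value of the parental samples. The alternative
#' `mode = "median_dct"` takes the median of per-replicate delta-Ct values
#' instead (identical for odd replicate counts with paired replicates).
#'
#' @param replicates data frame with columns `sample`, `ct_target`,
#'   `ct_control`, one row per replicate.
#' @param parental character vector of sample ids forming the parental
#'   (reference) group; must be nonempty and present in `replicates`.
#' @param mode `"median_ct"` (default) or `"median_dct"`.
#' @return Data frame with columns `sample`, `normalized`, `fold`.
#' @export
qpcr_relative_expression <- function(replicates, parental,
                                     mode = c("median_ct", "median_dct")) {
  mode <- match.arg(mode)
  need <- c("sample", "ct_target", "ct_control")
  if (!is.data.frame(replicates) || !all(need %in% names(replicates))) {
    stop_format(sprintf("replicates must have columns %s",
                        paste(need, collapse = ", ")))
  }
  ct <- c(replicates$ct_target, replicates$ct_control)
  if (anyNA(ct) || any(!is.finite(ct)) || any(ct <= 0)) {
    stop_validation("Ct values must be finite and > 0")
  }
  if (length(parental) == 0L) stop_validation("parental group is empty")
  if (!any(parental %in% replicates$sample)) {
    stop_validation("no parental sample found in the replicate table")
  }
  samples <- unique(replicates$sample)
  normalized <- vapply(samples, function(s) {
    rep_s <- replicates[replicates$sample == s, , drop = FALSE]
    if (mode == "median_ct") {
      2^(stats::median(rep_s$ct_control) - stats::median(rep_s$ct_target))
    } else {
      2^stats::median(rep_s$ct_control - rep_s$ct_target)
    }
  }, numeric(1L))
  parental_median <- stats::median(normalized[samples %in% parental])
  data.frame(sample = samples, normalized = unname(normalized),
             fold = unname(normalized) / parental_median,
             stringsAsFactors = FALSE, row.names = NULL)
}
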