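#' Rank genes by Pearson correlation with the NE score
#'
#' Builds the pre-ranked list that drives GSEA: the ranking metric is each
#' gene's Pearson correlation with the per-sample NE score. Zero-variance
#' genes cannot be correlated and are excluded (count reported). Ties in the
#' metric are broken by ascending gene id, making the ranking deterministic.
#'
#' @param expr [expression_matrix()] or named numeric matrix, samples in
#'   columns.
#' @param scores numeric NE score vector, one per sample; if named, names
#'   are matched to sample ids.
#' @return A data frame of class `ranked_list` with columns `gene` and
#'   `metric`, ordered by non-increasing metric.
#' @export
rank_genes_by_correlation <- function(expr, scores) {
  expr <- as_expression_matrix(expr)
  v <- expr$values
  if (!is.null(names(scores))) {
    missing <- setdiff(colnames(v), names(scores))
    if (length(missing)) {
      stop_validation(sprintf("no score for sample(s): %s",
                              paste(utils::head(missing, 5L), collapse = ", ")))
    }
    scores <- scores[colnames(v)]
  } else if (length(scores) != ncol(v)) {
    stop_validation("'scores' length must equal the sample count")
  }
  if (ncol(v) < 3L) stop_validation("need at least 3 samples to correlate")
  sds <- apply(v, 1L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds > 0
  if (!any(keep)) stop_degenerate("all genes are constant; no ranking possible")
  if (any(!keep)) {
    message(sprintf("excluded %d constant gene(s) from the ranking", sum(!keep)))
  }
  r <- as.vector(stats::cor(t(v[keep, , drop = FALSE]), scores,
                            use = "pairwise.complete.obs"))
  genes <- rownames(v)[keep]
  ord <- order(-r, genes)
  structure(data.frame(gene = genes[ord], metric = r[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

as_ranked_list <- function(ranked) {
  if (inherits(ranked, "ranked_list")) return(ranked)
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ord <- order(-ranked, names(ranked))
    return(structure(data.frame(gene = names(ranked)[ord],
                                metric = unname(ranked)[ord],
                                stringsAsFactors = FALSE),
                     class = c("ranked_list", "data.frame")))
  }
  if (is.data.frame(ranked) && all(c("gene", "metric") %in% names(ranked))) {
    if (is.unsorted(rev(ranked$metric))) {
      stop_validation("'ranked' metric must be non-increasing")
    }
    return(structure(ranked[, c("gene", "metric")],
                     class = c("ranked_list", "data.frame")))
  }
  stop_validation("'ranked' must be a ranked_list, a named numeric vector, or a gene/metric data frame")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating a running sum: at genes in the set
#' ("hits") it increments by `|metric|^p` normalized over the hits, at
#' misses it decrements by `1/(N - N_hit)`. The enrichment score is the
#' signed extreme deviation of the running sum (the extreme of larger
#' absolute value; ties favour the positive extreme). The leading edge is
#' the hits at or before the maximum (at or after the minimum, for a
#' negative score).
#'
#' @param ranked a `ranked_list` (see [rank_genes_by_correlation()]) or
#'   named metric vector.
#' @param set character vector of gene ids; must intersect the ranking in a
#'   nonempty proper subset.
#' @param p weight exponent on `|metric|` (default 1, the classic weighted
#'   statistic; 0 gives the unweighted Kolmogorov-Smirnov form).
#' @return A list with `es`, `running_sum` (length N), `leading_edge`, and
#'   `n_hits`.
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  ranked <- as_ranked_list(ranked)
  assert_scalar_number(p, "p")
  if (p < 0) stop_validation("'p' must be >= 0")
  genes <- ranked$gene
  n <- length(genes)
  hit <- genes %in% set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop_validation("gene set does not intersect the ranked list")
  if (n_hit == n) stop_validation("gene set covers the entire ranked list")
  w <- abs(ranked$metric)^p
  wsum <- sum(w[hit])
  # all-zero hit weights (possible when p > 0 and hit metrics are 0): fall
  # back to equal weights so the statistic stays defined
  inc <- if (wsum > 0) ifelse(hit, w / wsum, 0) else ifelse(hit, 1 / n_hit, 0)
  dec <- ifelse(hit, 0, 1 / (n - n_hit))
  running <- cumsum(inc - dec)
  i_max <- which.max(running)
  i_min <- which.min(running)
  # |max| vs |min| ties resolve to the positive extreme; the 1e-12 slack keeps
  # the choice stable against floating-point accumulation order
  es <- if (abs(running[i_max]) >= abs(running[i_min]) - 1e-12)
    running[i_max] else running[i_min]
  idx <- seq_len(n)
  leading <- if (es >= 0) genes[hit & idx <= i_max] else genes[hit & idx >= i_min]
  list(es = es, running_sum = running, leading_edge = leading, n_hits = n_hit)
}

# ES only, from sorted hit positions: the running sum is piecewise linear so
# its extremes occur just after a hit (maxima), just before a hit or at the
# start/end (minima). O(k) per evaluation; used for the permutation null.
es_from_positions <- function(pos, w_all, n) {
  pos <- sort.int(pos)
  k <- length(pos)
  wh <- w_all[pos]
  wsum <- sum(wh)
  wh <- if (wsum > 0) wh / wsum else rep(1 / k, k)
  dec <- 1 / (n - k)
  cw <- cumsum(wh)
  j <- seq_len(k)
  after <- cw - (pos - j) * dec          # value at each hit position
  before <- c(0, cw[-k]) - (pos - j) * dec  # value just before each hit
  hi <- max(after, -dec)                 # -dec covers a leading all-miss run
  lo <- min(before, 0)                   # 0 covers the terminal value at N
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

#' Pre-ranked GSEA with a gene-label permutation null
#'
#' For each gene set, computes the weighted enrichment score and compares it
#' with a null distribution of scores from size-matched random gene sets
#' drawn from the ranked list (gene-label permutation). The p-value is
#' `(1 + #same-sign null scores at least as extreme) / (1 + #same-sign null
#' scores)` and is therefore never zero; NES is the enrichment score divided
#' by the mean absolute same-sign null score. P-values are
#' Benjamini-Hochberg adjusted across the collection.
#'
#' @param ranked a `ranked_list` or named metric vector.
#' @param sets a [gene_set_collection()] or named list of gene vectors.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed for the permutation draw.
#' @param p weight exponent, see [enrichment_score()].
#' @return Data frame with one row per testable set: `set`, `size`, `es`,
#'   `nes`, `pvalue`, `padj`, `n_more_extreme`, `n_perm`, and a list column
#'   `leading_edge`; sorted by `padj` then `|nes|`. Sets failing the
#'   enrichment-score preconditions are skipped with a message.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000L, seed = 1L, p = 1) {
  ranked <- as_ranked_list(ranked)
  assert_count(n_perm, "n_perm", min = 100L)
  assert_count(seed, "seed", min = -.Machine$integer.max)
  n <- nrow(ranked)
  observed <- lapply(names(sets), function(nm) {
    tryCatch(enrichment_score(ranked, sets[[nm]], p = p),
             nescore_error = function(e) {
               message(sprintf("skipping set '%s': %s", nm, conditionMessage(e)))
               NULL
             })
  })
  names(observed) <- names(sets)
  observed <- Filter(Negate(is.null), observed)
  if (length(observed) == 0L) stop_validation("no testable gene set")
  sizes <- vapply(observed, `[[`, integer(1L), "n_hits")
  w_all <- abs(ranked$metric)^p
  # one shared null per distinct set size, seeded
  null_by_size <- withr::with_seed(seed, {
    lapply(stats::setNames(nm = sort(unique(sizes))), function(k) {
      vapply(seq_len(n_perm), function(i) {
        es_from_positions(sample.int(n, k), w_all, n)
      }, numeric(1L))
    })
  })
  rows <- lapply(names(observed), function(nm) {
    obs <- observed[[nm]]
    null_es <- null_by_size[[as.character(obs$n_hits)]]
    sign_obs <- if (obs$es >= 0) 1 else -1
    same <- null_es[sign(null_es) == sign_obs]
    n_more <- sum(abs(same) >= abs(obs$es))
    pval <- (1 + n_more) / (1 + length(same))
    nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = obs$n_hits, es = obs$es, nes = nes,
               pvalue = pval, n_more_extreme = n_more, n_perm = n_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out$leading_edge <- I(lapply(observed, `[[`, "leading_edge"))
  out <- out[order(out$padj, -abs(out$nes)), , drop = FALSE]
  out <- out[, c("set", "size", "es", "nes", "pvalue", "padj",
                 "n_more_extreme", "n_perm", "leading_edge")]
  rownames(out) <- NULL
  out
}

#' GSEA with a sample-label permutation null
#'
#' Alternative null for cohort data: the NE score vector is permuted across
#' samples, the correlation ranking recomputed, and each set's enrichment
#' score re-evaluated on the permuted ranking. P-value, NES and BH
#' adjustment follow the same estimators as [preranked_gsea()]. Intended for
#' synthetic cohorts where the full expression matrix is available.
#'
#' @inheritParams preranked_gsea
#' @param expr [expression_matrix()] or named numeric matrix.
#' @param scores per-sample NE scores aligned with `expr` columns.
#' @return As [preranked_gsea()].
#' @export
gsea_sample_permutation <- function(expr, scores, sets, n_perm = 1000L,
                                    seed = 1L, p = 1) {
  expr <- as_expression_matrix(expr)
  assert_count(n_perm, "n_perm", min = 100L)
  ranked <- rank_genes_by_correlation(expr, scores)
  observed <- lapply(names(sets), function(nm) {
    tryCatch(enrichment_score(ranked, sets[[nm]], p = p),
             nescore_error = function(e) {
               message(sprintf("skipping set '%s': %s", nm, conditionMessage(e)))
               NULL
             })
  })
  names(observed) <- names(sets)
  observed <- Filter(Negate(is.null), observed)
  if (length(observed) == 0L) stop_validation("no testable gene set")
  sc <- if (is.null(names(scores))) scores else scores[sample_ids(expr)]
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm_ranked <- rank_genes_by_correlation(expr, sample(sc))
      vapply(names(observed), function(nm) {
        enrichment_score(perm_ranked, sets[[nm]], p = p)$es
      }, numeric(1L))
    }, numeric(length(observed)))
  })
  null_es <- matrix(null_es, nrow = length(observed))
  rows <- lapply(seq_along(observed), function(i) {
    obs <- observed[[i]]
    nulls <- null_es[i, ]
    sign_obs <- if (obs$es >= 0) 1 else -1
    same <- nulls[sign(nulls) == sign_obs]
    n_more <- sum(abs(same) >= abs(obs$es))
    data.frame(set = names(observed)[i], size = obs$n_hits, es = obs$es,
               nes = if (length(same)) obs$es / mean(abs(same)) else NA_real_,
               pvalue = (1 + n_more) / (1 + length(same)),
               n_more_extreme = n_more, n_perm = n_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out$leading_edge <- I(lapply(observed, `[[`, "leading_edge"))
  out <- out[order(out$padj, -abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k consensus leading edge across data sets
#'
#' Intersects a gene set's leading edges across data sets, orders the shared
#' genes by the most extreme ranking-metric value in a designated reference
#' data set, and truncates to `k`. When a data set contributes several
#' leading edges (merged libraries, e.g. the two interferon-response sets),
#' pass them as a list: they are unioned per data set before intersecting.
#'
#' @param leading_edges list with one element per data set; each element a
#'   character vector of leading-edge genes, or a list of such vectors to be
#'   unioned.
#' @param reference_metric named numeric vector: the ranking metric of the
#'   reference data set.
#' @param k number of genes to keep (default 25).
#' @return Character vector of at most `k` genes; empty (with a warning) if
#'   the intersection is empty.
#' @export
leading_edge_top_k <- function(leading_edges, reference_metric, k = 25L) {
  assert_count(k, "k")
  if (length(leading_edges) == 0L) stop_validation("no leading edges supplied")
  per_dataset <- lapply(leading_edges, function(le) {
    if (is.list(le)) unique(unlist(le)) else unique(le)
  })
  common <- Reduce(intersect, per_dataset)
  if (length(common) == 0L) {
    warning("leading edges share no genes across data sets", call. = FALSE)
    return(character(0L))
  }
  metric <- reference_metric[common]
  if (anyNA(metric)) {
    warning(sprintf("%d shared gene(s) missing from the reference metric",
                    sum(is.na(metric))), call. = FALSE)
  }
  common <- common[order(-abs(metric), common, na.last = TRUE)]
  utils::head(common, k)
}

#' Write GSEA results to TSV
#' @param results data frame from [preranked_gsea()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gsea <- function(results, path) {
  out <- results
  out$leading_edge <- vapply(results$leading_edge, paste, character(1L),
                             collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
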