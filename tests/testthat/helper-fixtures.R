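# Shared toy fixtures, built in code at test time.

# 4-gene signature with perfectly anti-correlated centroids
toy_signature <- function() {
  gene_signature(paste0("g", 1:4), ne_centroid = c(1, 2, 3, 4),
                 non_ne_centroid = c(4, 3, 2, 1), name = "toy")
}

toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% rownames(m) %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% paste0("s", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force running-sum ES oracle: walks the ranking one
# position at a time, straight from the weighted Kolmogorov-Smirnov
# definition. Kept free of any call into the package's enrichment code.
brute_force_es <- function(metric, hit, p = 1) {
  n <- length(metric)
  n_hit <- sum(hit)
  denom <- sum(abs(metric[hit])^p)
  run <- numeric(n)
  level <- 0
  for (i in seq_len(n)) {
    level <- if (hit[i]) level + abs(metric[i])^p / denom else
      level - 1 / (n - n_hit)
    run[i] <- level
  }
  hi <- max(run); lo <- min(run)
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

# Default synthetic bundle shared by recovery tests (seed fixed up front)
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(synthetic_config(seed = 101L))
    cache
  }
})
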