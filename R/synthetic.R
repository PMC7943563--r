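#' Configuration for the synthetic transcriptome generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: each sample carries a latent neuroendocrine state `s` in
#' [-1, 1]; 50 signature genes interpolate between two anti-correlated
#' centroids as a convex blend in `s`; an immune/interferon program is
#' negatively coupled to `s`, a REST-target program positively coupled; the
#' remaining genes are neutral background. Defaults describe a desk-scale
#' cohort: 200 samples, 100 immune and 100 REST-target genes over 800
#' background genes, per-gene Gaussian noise with standard deviation 1 on
#' log2 scale, and coupling slopes of -2 / +2 log2 units per unit of latent
#' state.
#'
#' @param n_samples number of samples (default 200).
#' @param n_signature_genes signature size (default 50, minimum 4).
#' @param n_immune_genes,n_rest_target_genes,n_background_genes program
#'   sizes (defaults 100 / 100 / 800).
#' @param ne_state_distribution `"uniform"` (U(-1, 1)) or `"two_group"`
#'   (s = +1 with probability `prop_ne`, else -1, jittered by 0.05).
#' @param prop_ne probability of the NE group under `"two_group"`.
#' @param immune_effect slope (<= 0) of the immune program on the latent
#'   state, log2 units.
#' @param rest_effect slope (>= 0) of the REST-target program.
#' @param noise_sd per-gene Gaussian noise standard deviation (> 0).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 200L, n_signature_genes = 50L,
                             n_immune_genes = 100L,
                             n_rest_target_genes = 100L,
                             n_background_genes = 800L,
                             ne_state_distribution = c("uniform", "two_group"),
                             prop_ne = 0.5,
                             immune_effect = -2, rest_effect = 2,
                             noise_sd = 1, seed = 1L) {
  ne_state_distribution <- match.arg(ne_state_distribution)
  assert_count(n_samples, "n_samples", min = 2L)
  assert_count(n_signature_genes, "n_signature_genes", min = 4L)
  assert_count(n_immune_genes, "n_immune_genes")
  assert_count(n_rest_target_genes, "n_rest_target_genes")
  assert_count(n_background_genes, "n_background_genes")
  assert_scalar_number(immune_effect, "immune_effect")
  assert_scalar_number(rest_effect, "rest_effect")
  assert_scalar_number(noise_sd, "noise_sd")
  assert_scalar_number(prop_ne, "prop_ne")
  assert_count(seed, "seed", min = -.Machine$integer.max)
  if (immune_effect > 0) stop_validation("'immune_effect' must be <= 0")
  if (rest_effect < 0) stop_validation("'rest_effect' must be >= 0")
  if (noise_sd <= 0) stop_validation("'noise_sd' must be > 0")
  if (prop_ne <= 0 || prop_ne >= 1) stop_validation("'prop_ne' must be in (0, 1)")
  structure(
    list(n_samples = as.integer(n_samples),
         n_signature_genes = as.integer(n_signature_genes),
         n_immune_genes = as.integer(n_immune_genes),
         n_rest_target_genes = as.integer(n_rest_target_genes),
         n_background_genes = as.integer(n_background_genes),
         ne_state_distribution = ne_state_distribution,
         prop_ne = prop_ne,
         immune_effect = immune_effect, rest_effect = rest_effect,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic two-centroid signature
#'
#' Draws log2-scale NE and non-NE centroids for `n_signature_genes` genes.
#' By default the non-NE centroid is rejection-sampled until its Pearson
#' correlation with the NE centroid is non-positive (anti-correlated
#' prototypes, as in the real signature). With
#' `perfect_anticorrelation = TRUE` the non-NE centroid is the exact mirror
#' of the NE centroid, making their correlation exactly -1 — useful for
#' adversarial bound checks where the centroid profiles must score exactly
#' +1 / -1.
#'
#' @param config a [synthetic_config()].
#' @param perfect_anticorrelation force centroid correlation to exactly -1.
#' @return A [gene_signature()].
#' @export
generate_signature <- function(config, perfect_anticorrelation = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_signature_genes
  withr::with_seed(config$seed, {
    ne <- stats::rnorm(n, mean = 8, sd = 2)
    if (perfect_anticorrelation) {
      non_ne <- max(ne) + min(ne) - ne
    } else {
      repeat {
        non_ne <- stats::rnorm(n, mean = 8, sd = 2)
        if (stats::cor(ne, non_ne) <= 0) break
      }
    }
    gene_signature(sprintf("SIG%03d", seq_len(n)), ne, non_ne,
                   name = sprintf("synthetic NE signature (seed %d)",
                                  config$seed))
  })
}

#' Generate a synthetic expression data set with known truth
#'
#' For sample i with latent state `s_i`: signature genes follow the convex
#' centroid blend `(1 + s)/2 * ne_centroid + (1 - s)/2 * non_ne_centroid`;
#' immune genes follow `baseline + immune_effect * s`; REST-target genes
#' `baseline + rest_effect * s`; background genes stay at baseline. All
#' genes receive independent Gaussian noise of sd `noise_sd`, baselines are
#' drawn once per gene on log2 scale, and everything is driven by
#' `config$seed`. The planted gene sets `IMMUNE_PROGRAM`, `REST_TARGETS`
#' and `RANDOM_K` (a size-matched random draw of background genes) support
#' enrichment recovery tests.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements `expr`
#'   (log2-scale [expression_matrix()]), `truth` (list: `ne_state`,
#'   `gene_program`, `planted_sets`), `signature` and `sets` (same
#'   [gene_set_collection()] as `truth$planted_sets`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sig <- generate_signature(config)
  withr::with_seed(config$seed + 1L, {
    ns <- config$n_samples
    samples <- sprintf("S%03d", seq_len(ns))
    s <- switch(config$ne_state_distribution,
      uniform = stats::runif(ns, -1, 1),
      two_group = ifelse(stats::runif(ns) < config$prop_ne, 1, -1) +
        stats::rnorm(ns, sd = 0.05)
    )
    s <- pmin(1, pmax(-1, s))
    names(s) <- samples

    imm_genes <- sprintf("IMM%03d", seq_len(config$n_immune_genes))
    rest_genes <- sprintf("RST%03d", seq_len(config$n_rest_target_genes))
    bkg_genes <- sprintf("BKG%03d", seq_len(config$n_background_genes))
    genes <- c(sig$gene_ids, imm_genes, rest_genes, bkg_genes)

    sig_block <- outer(sig$ne_centroid, (1 + s) / 2) +
      outer(sig$non_ne_centroid, (1 - s) / 2)
    baseline <- function(k) stats::rnorm(k, mean = 7, sd = 1.5)
    imm_block <- baseline(length(imm_genes)) +
      outer(rep(config$immune_effect, length(imm_genes)), s)
    rest_block <- baseline(length(rest_genes)) +
      outer(rep(config$rest_effect, length(rest_genes)), s)
    bkg_block <- matrix(baseline(length(bkg_genes)), nrow = length(bkg_genes),
                        ncol = ns)
    values <- rbind(sig_block, imm_block, rest_block, bkg_block) +
      matrix(stats::rnorm(length(genes) * ns, sd = config$noise_sd),
             nrow = length(genes))
    dimnames(values) <- list(genes, samples)

    program <- c(
      ifelse(sig$ne_centroid >= sig$non_ne_centroid,
             "signature_ne", "signature_non_ne"),
      rep("immune", length(imm_genes)),
      rep("rest_target", length(rest_genes)),
      rep("background", length(bkg_genes))
    )
    names(program) <- genes

    planted <- gene_set_collection(list(
      IMMUNE_PROGRAM = imm_genes,
      REST_TARGETS = rest_genes,
      RANDOM_K = sample(bkg_genes, min(length(imm_genes), length(bkg_genes)))
    ), source = "planted synthetic programs")

    structure(
      list(expr = expression_matrix(values, scale = "log2",
                                    provenance = sprintf("synthetic (seed %d)",
                                                         config$seed)),
           truth = list(ne_state = s, gene_program = program,
                        planted_sets = planted),
           signature = sig,
           sets = planted,
           config = config),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d samples (seed %d)\n",
              nrow(x$expr$values), ncol(x$expr$values), x$config$seed))
  invisible(x)
}

#' Write a synthetic bundle to plain-text fixtures
#'
#' Emits `expression.tsv`, `signature.tsv`, `planted_sets.gmt` and
#' `truth.tsv` (one row per sample: `sample`, `ne_state`) into a directory.
#' The files round-trip losslessly through [read_expression()],
#' [load_signature()] and [read_gmt()] to float-format tolerance.
#'
#' @param bundle result of [generate_dataset()].
#' @param directory output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(bundle, directory) {
  stopifnot(inherits(bundle, "synthetic_dataset"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) ne_stop(sprintf("cannot create directory: %s", directory),
                     "nescore_io_error")
  }
  paths <- c(
    expression = file.path(directory, "expression.tsv"),
    signature = file.path(directory, "signature.tsv"),
    sets = file.path(directory, "planted_sets.gmt"),
    truth = file.path(directory, "truth.tsv")
  )
  write_expression(bundle$expr, paths[["expression"]])
  write_signature(bundle$signature, paths[["signature"]])
  write_gmt(bundle$truth$planted_sets, paths[["sets"]])
  utils::write.table(
    data.frame(sample = names(bundle$truth$ne_state),
               ne_state = unname(bundle$truth$ne_state),
               stringsAsFactors = FALSE),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
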