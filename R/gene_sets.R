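#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene ids. Names must be
#'   unique; genes are deduplicated within each set; empty sets are dropped
#'   with a warning.
#' @param source free text recording where the collection came from.
#' @return An object of class `gene_set_collection` (a named list of
#'   character vectors with a `source` attribute).
#' @export
gene_set_collection <- function(sets, source = "") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_validation("every gene set needs a name")
  }
  if (anyDuplicated(names(sets))) {
    stop_validation("gene set names must be unique")
  }
  deduped <- lapply(sets, function(g) unique(as.character(g[nzchar(g) & !is.na(g)])))
  n_dup <- sum(lengths(sets) - lengths(deduped))
  if (n_dup > 0L) {
    warning(sprintf("removed %d duplicate/empty gene entr%s within sets",
                    n_dup, if (n_dup == 1L) "y" else "ies"), call. = FALSE)
  }
  empty <- lengths(deduped) == 0L
  if (any(empty)) {
    warning(sprintf("dropping %d empty set(s): %s", sum(empty),
                    paste(names(deduped)[empty], collapse = ", ")),
            call. = FALSE)
    deduped <- deduped[!empty]
  }
  if (length(deduped) == 0L) stop_validation("collection has no nonempty sets")
  structure(deduped, class = "gene_set_collection", source = source)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are deduplicated and empty sets dropped, both with
#' warnings.
#'
#' @param path file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format("empty GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short)) {
    stop_format(sprintf("GMT line %d has fewer than 2 fields", short[1L]))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  gene_set_collection(sets, source = path)
}

#' Write a gene set collection to GMT
#' @param sets a [gene_set_collection()] or named list of gene vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}
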