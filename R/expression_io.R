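#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: a header row of sample ids, first column gene ids. GCT 1.2
#' layout: `#1.2` version line, a dimensions line, then a header with `Name`
#' and `Description` columns followed by sample ids. Duplicate gene rows are
#' collapsed by their mean with a warning; file order of ids is preserved.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`; default guesses from the extension.
#' @param scale scale tag to attach (`"log2"` or `"linear"`); the file format
#'   itself does not record it.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            scale = c("log2", "linear")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3L || !startsWith(lines[1L], "#1.2")) {
      stop_format("not a GCT 1.2 file (missing '#1.2' version line)")
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]))
    if (length(dims) < 2L || any(is.na(dims[1:2]))) {
      stop_format("malformed GCT dimensions line (line 2)")
    }
    body <- parse_delim_matrix(lines[-(1:2)], first_line_number = 3L,
                               n_id_cols = 2L)
    if (nrow(body$values) != dims[1L] || ncol(body$values) != dims[2L]) {
      stop_format(sprintf(
        "GCT dimensions line says %d x %d but body has %d x %d",
        dims[1L], dims[2L], nrow(body$values), ncol(body$values)
      ))
    }
  } else {
    body <- parse_delim_matrix(lines, first_line_number = 1L, n_id_cols = 1L)
  }
  values <- collapse_duplicate_genes(body$values)
  expression_matrix(values, scale = scale, provenance = path)
}

# Shared TSV body parser; reports ragged rows with their 1-based line number.
parse_delim_matrix <- function(lines, first_line_number, n_id_cols) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_format("empty expression matrix")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  widths <- lengths(fields[-1L])
  # allow a headerless corner column in plain TSV (R write.table style)
  if (n_id_cols == 1L && all(widths == n_col + 1L)) {
    header <- c("", header)
    n_col <- n_col + 1L
  }
  bad <- which(lengths(fields[-1L]) != n_col)
  if (length(bad)) {
    stop_format(sprintf("ragged row at line %d (expected %d fields, got %d)",
                        first_line_number + bad[1L], n_col,
                        lengths(fields[-1L])[bad[1L]]))
  }
  sample_names <- header[-seq_len(n_id_cols)]
  if (length(sample_names) == 0L) stop_format("no sample columns")
  rows <- fields[-1L]
  genes <- vapply(rows, `[[`, character(1L), 1L)
  num <- vapply(rows, function(f) {
    suppressWarnings(as.numeric(f[-seq_len(n_id_cols)]))
  }, numeric(length(sample_names)))
  values <- if (is.matrix(num)) t(num) else matrix(num, ncol = length(sample_names))
  dimnames(values) <- list(genes, sample_names)
  list(values = values)
}

collapse_duplicate_genes <- function(values) {
  if (!anyDuplicated(rownames(values))) return(values)
  genes <- rownames(values)
  dup <- unique(genes[duplicated(genes)])
  warning(sprintf("collapsing %d duplicated gene id(s) by mean: %s",
                  length(dup), paste(utils::head(dup, 5L), collapse = ", ")),
          call. = FALSE)
  keep <- unique(genes)
  out <- rowsum(values, group = genes, reorder = FALSE) /
    as.vector(table(factor(genes, levels = unique(genes))))
  out[keep, , drop = FALSE]
}

#' Write an expression matrix to TSV or GCT
#'
#' @param expr an [expression_matrix()] or named numeric matrix.
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  expr <- as_expression_matrix(expr)
  v <- expr$values
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
    header <- paste(c("Name", "Description", colnames(v)), collapse = "\t")
    body <- paste(rownames(v), rownames(v),
                  apply(v, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(c(header, body), con)
  } else {
    tab <- data.frame(gene = rownames(v), v, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
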