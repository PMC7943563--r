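#' Expression matrix container
#'
#' A light S3 wrapper around a genes-by-samples numeric matrix carrying a
#' scale tag (`"linear"` or `"log2"`) and free-text provenance. The scale tag
#' exists because NE scoring and most downstream statistics assume
#' log2-transformed expression; functions that care consult the tag rather
#' than guessing from the values.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names. Values must be finite or `NA`.
#' @param scale `"linear"` or `"log2"`.
#' @param provenance free text recording where the matrix came from.
#' @return An object of class `expression_matrix` with fields `values`,
#'   `scale` and `provenance`.
#' @export
expression_matrix <- function(values, scale = c("log2", "linear"),
                              provenance = "") {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("'values' must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop_validation("expression matrix is empty")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_validation("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop_validation("duplicate gene ids in expression matrix")
  }
  if (anyDuplicated(colnames(values))) {
    stop_validation("duplicate sample ids in expression matrix")
  }
  if (any(is.infinite(values))) {
    stop_validation("expression values must be finite or NA (no +/-Inf)")
  }
  structure(
    list(values = values, scale = scale, provenance = provenance),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d samples [%s scale]\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `expression_matrix`.
#' @return Character vector of identifiers in matrix order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# Accept either an expression_matrix or a bare named matrix (assumed log2
# only when the caller explicitly attests; otherwise require the class).
as_expression_matrix <- function(x, arg = "expr") {
  if (inherits(x, "expression_matrix")) return(x)
  if (is.matrix(x) && is.numeric(x)) {
    return(expression_matrix(x, scale = "log2"))
  }
  stop_validation(sprintf("'%s' must be an expression_matrix or a named numeric matrix", arg))
}
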