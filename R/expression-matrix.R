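#' Expression matrix container
#'
#' Lightweight container for an entities-by-samples expression matrix.
#' Missing measurements are encoded as `NA` in `values`; the missingness
#' mask used by the presence filter and by pairwise correlation is simply
#' `is.na(values)`. The `scale` flag records whether values are linear
#' intensities or log2 intensities; it transitions only via
#' [log2_transform()].
#'
#' @param values Numeric matrix with unique entity rownames and unique
#'   sample colnames. `NA` marks missing entries; all non-missing entries
#'   must be finite.
#' @param scale Either `"linear"` or `"log2"`.
#' @return An object of class `ExpressionMatrix` with elements `values`
#'   and `scale`.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, "linear")
#' em
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry entity rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate entity ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  if (any(!is.na(values) & !is.finite(values)))
    stop("expression values must be finite where not missing")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("ExpressionMatrix: %d entities x %d samples (%s scale)\n",
              nrow(v), ncol(v), x$scale))
  nm <- sum(is.na(v))
  if (nm > 0)
    cat(sprintf("  missing entries: %d (%.1f%%)\n", nm, 100 * nm / length(v)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Entity and sample identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
entity_ids <- function(x) rownames(x$values)

#' @rdname entity_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# internal: coerce ExpressionMatrix or plain matrix to its numeric matrix
as_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an ExpressionMatrix or a numeric matrix")
}
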