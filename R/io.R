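#' Read / write expression matrices as TSV
#'
#' Layout: entities in rows, first column `id`, remaining columns the
#' sample ids; missing entries written as `NA`. Values are written with 17
#' significant digits so that a write/read round trip is numerically
#' exact.
#'
#' @param path File path.
#' @param scale Scale flag for the matrix being read.
#' @return `read_expression_tsv`: an `ExpressionMatrix`.
#'   `write_expression_tsv`: the path, invisibly.
#' @export
read_expression_tsv <- function(path, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  expression_matrix(m, scale)
}

#' @rdname read_expression_tsv
#' @param m An `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  write_matrix_tsv(m$values, path)
}

# internal: deterministic, round-trip-exact numeric matrix TSV
write_matrix_tsv <- function(x, path, id_col = "id") {
  ch <- matrix(ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g")),
               nrow(x), ncol(x))
  lines <- c(paste(c(id_col, colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], ch[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Read / write sample class labels as TSV
#'
#' Two columns: `sample_id`, `class`.
#'
#' @param path File path.
#' @return `read_labels_tsv`: named character vector (sample -> class).
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df$class, df$sample_id)
}

#' @rdname read_labels_tsv
#' @param labels Named character vector.
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels),
                                class = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write DNA/RNA sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path File path.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @export
write_fasta <- function(sequences, path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "DNA") Biostrings::DNAStringSet(sequences)
  else Biostrings::RNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a correlation matrix with its resampling metadata sidecar
#'
#' Writes the gene x miRNA value matrix as TSV and a JSON sidecar
#' (`<path>.json`) recording the resampling protocol.
#'
#' @param c A `CorrelationMatrix`.
#' @param path TSV path.
#' @export
write_correlation_tsv <- function(c, path) {
  stopifnot(inherits(c, "CorrelationMatrix"))
  write_matrix_tsv(c$values, path)
  meta <- list(n_reps = c$n_reps, fraction = c$fraction, seed = c$seed,
               sample_class = c$sample_class)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an SVD profile as JSON
#'
#' Spectrum, variance fractions and score-shape statistics; the singular
#' vectors themselves go to an optional TSV.
#'
#' @param profile An `SvdProfile`.
#' @param path JSON path.
#' @param scores_tsv Optional path for the left (gene-score) vectors.
#' @export
write_svd_json <- function(profile, path, scores_tsv = NULL) {
  stopifnot(inherits(profile, "SvdProfile"))
  jsonlite::write_json(
    list(singular_values = profile$singular_values,
         variance_fractions = profile$variance_fractions,
         shape_stats = profile$shape_stats),
    path, digits = NA, pretty = TRUE, dataframe = "columns")
  if (!is.null(scores_tsv))
    write_matrix_tsv(profile$left_vectors, scores_tsv, id_col = "gene")
  invisible(path)
}
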