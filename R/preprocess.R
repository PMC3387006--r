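#' Collapse probe-level rows to gene-level rows
#'
#' Maps probe identifiers to gene symbols and replaces the probes of each
#' gene by their arithmetic mean per sample, computed on the linear scale
#' (collapse first, log-transform after). Probes without a mapping are
#' dropped. Missing probe measurements are excluded from the mean; a
#' gene-sample cell whose probes are all missing stays missing.
#'
#' @param probe_matrix An `ExpressionMatrix` on the linear scale whose rows
#'   are probe ids.
#' @param probe_to_gene Named character vector (`names` = probe ids,
#'   values = gene symbols) or a two-column data.frame
#'   (`probe_id`, `gene_symbol`). Each probe maps to at most one gene.
#' @return An `ExpressionMatrix` with one row per gene, linear scale.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene) {
  stopifnot(inherits(probe_matrix, "ExpressionMatrix"))
  if (probe_matrix$scale != "linear")
    stop("collapse_probes expects linear-scale values (collapse before log2)")
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2]]),
                           as.character(probe_to_gene[[1]]))
  } else {
    map <- probe_to_gene
  }
  if (length(map) == 0) stop("empty probe-to-gene mapping")
  if (anyDuplicated(names(map)))
    stop("a probe maps to more than one gene")
  genes <- unique(map)
  if (anyDuplicated(toupper(genes)))
    stop("gene symbols that differ only by letter case: ",
         paste(genes[duplicated(toupper(genes))], collapse = ", "))
  v <- probe_matrix$values
  mapped <- intersect(rownames(v), names(map))
  if (length(mapped) == 0) stop("no probe in the matrix is mapped to a gene")
  v <- v[mapped, , drop = FALSE]
  gene_of <- map[mapped]
  out <- rowsum(ifelse(is.na(v), 0, v), gene_of, reorder = FALSE)
  cnt <- rowsum((!is.na(v)) * 1, gene_of, reorder = FALSE)
  out <- out / cnt                      # 0/0 -> NaN where all probes missing
  out[cnt == 0] <- NA_real_
  expression_matrix(out, "linear")
}

#' Log2-transform an expression matrix
#'
#' @param m An `ExpressionMatrix` on the linear scale; all non-missing
#'   values must be strictly positive.
#' @return The matrix on the log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "linear") stop("matrix is already on the log2 scale")
  v <- m$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive value for entity '%s', sample '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  expression_matrix(log2(v), "log2")
}

#' Variability (fold-change) filter
#'
#' Keeps entities whose log2 range (max minus min over non-missing samples)
#' reaches `log2(fold)`. The boundary is inclusive by default. Rows that
#' are entirely missing are dropped with a warning.
#'
#' @param m `ExpressionMatrix`, log2 scale.
#' @param fold Minimum fold change between the highest and lowest intensity
#'   (default 2).
#' @param inclusive Keep entities whose range equals the cutoff exactly
#'   (default `TRUE`).
#' @return Filtered `ExpressionMatrix`, row order preserved.
#' @export
filter_variability <- function(m, fold = 2.0, inclusive = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "log2") stop("variability filter operates on log2 values")
  if (!is.numeric(fold) || fold <= 1) stop("'fold' must exceed 1")
  v <- m$values
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing)) {
    warning(sprintf("dropping %d all-missing entit%s",
                    sum(all_missing), if (sum(all_missing) == 1) "y" else "ies"))
  }
  rng <- apply(v, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0) -Inf else max(r) - min(r)
  })
  cut <- log2(fold)
  keep <- if (inclusive) rng >= cut else rng > cut
  message(sprintf("variability filter (fold=%g): kept %d of %d entities",
                  fold, sum(keep), nrow(v)))
  expression_matrix(v[keep, , drop = FALSE], "log2")
}

#' Presence filter
#'
#' Keeps entities measured (non-missing) in more than `min_fraction` of the
#' samples. The boundary is strict by default, reading "present in over
#' 80% of the samples" literally: an entity present in exactly 80% of the
#' samples is dropped.
#'
#' @param m `ExpressionMatrix`.
#' @param min_fraction Presence fraction that must be exceeded
#'   (default 0.80); must lie in (0, 1].
#' @param strict Use a strict `>` comparison (default `TRUE`); `FALSE`
#'   switches to `>=`.
#' @return Filtered `ExpressionMatrix`, row order preserved.
#' @export
filter_presence <- function(m, min_fraction = 0.80, strict = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("'min_fraction' must lie in (0, 1]")
  v <- m$values
  frac <- rowMeans(!is.na(v))
  keep <- if (strict) frac > min_fraction else frac >= min_fraction
  message(sprintf("presence filter (>%s%g%%): kept %d of %d entities",
                  if (strict) "" else "=", 100 * min_fraction,
                  sum(keep), nrow(v)))
  expression_matrix(v[keep, , drop = FALSE], m$scale)
}
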