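#' Term-to-gene annotation table
#'
#' Container for a GMT-like annotation: each term maps to a description
#' and a gene set, against a fixed background universe. Term gene sets are
#' harmonized (intersected) with the universe; terms left empty after
#' harmonization are dropped with a message.
#'
#' @param gene_sets Named list of character vectors (term id -> genes).
#' @param universe Background gene universe.
#' @param descriptions Optional named character vector of descriptions.
#' @return A `TermTable`.
#' @export
term_table <- function(gene_sets, universe, descriptions = NULL) {
  if (length(universe) == 0) stop("empty gene universe")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop("every term needs an id")
  if (anyDuplicated(names(gene_sets))) stop("duplicate term ids")
  harmonized <- lapply(gene_sets, function(g) intersect(unique(g), universe))
  empty <- lengths(harmonized) == 0
  if (any(empty)) {
    message(sprintf("dropping %d term(s) with no genes in the universe",
                    sum(empty)))
    harmonized <- harmonized[!empty]
  }
  if (length(harmonized) == 0) stop("no non-empty terms")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(harmonized)),
                                    names(harmonized))
  structure(list(gene_sets = harmonized,
                 universe = unique(universe),
                 descriptions = descriptions[names(harmonized)]),
            class = "TermTable")
}

#' @export
print.TermTable <- function(x, ...) {
  cat(sprintf("TermTable: %d terms over a universe of %d genes\n",
              length(x$gene_sets), length(x$universe)))
  invisible(x)
}

#' Read / write GMT annotation files
#'
#' Standard GMT layout: one term per line, tab-separated
#' `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path File path.
#' @param universe Background universe for the resulting [term_table()]
#'   (default: the union of all term genes).
#' @return `read_gmt`: a `TermTable`. `write_gmt`: the path, invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  desc <- stats::setNames(vapply(parts, `[`, character(1), 2), ids)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  if (is.null(universe)) universe <- unique(unlist(sets))
  term_table(sets, universe, desc)
}

#' @rdname read_gmt
#' @param terms A `TermTable`.
#' @export
write_gmt <- function(terms, path) {
  stopifnot(inherits(terms, "TermTable"))
  lines <- vapply(names(terms$gene_sets), function(id) {
    paste(c(id, terms$descriptions[[id]], terms$gene_sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' One-sided Fisher exact test of every term against the background
#' universe, with Benjamini-Hochberg adjustment across all tested terms.
#' This is the local stand-in for web-based annotation enrichment
#' services: the statistic is the same hypergeometric over-representation
#' test, computed against a user-supplied GMT.
#'
#' @param gene_list Non-empty query gene list, a subset of the universe.
#' @param terms A `TermTable`.
#' @param alternative Test alternative (default `"greater"`).
#' @return data.frame sorted by adjusted p then term id, with columns
#'   `term`, `description`, `hits`, `term_size`, `list_size`,
#'   `universe_size`, `odds_ratio`, `p_value`, `adj_p`.
#' @export
overrepresentation <- function(gene_list, terms, alternative = "greater") {
  stopifnot(inherits(terms, "TermTable"))
  if (length(terms$universe) == 0) stop("empty universe")
  gene_list <- unique(gene_list)
  if (length(gene_list) == 0) stop("empty gene list")
  if (!all(gene_list %in% terms$universe))
    stop("gene list contains genes outside the universe")
  N <- length(terms$universe)
  n <- length(gene_list)
  rows <- lapply(names(terms$gene_sets), function(id) {
    tg <- terms$gene_sets[[id]]
    K <- length(tg)
    k <- length(intersect(tg, gene_list))
    ft <- fisher_2x2(k, n - k, K - k, N - K - (n - k), alternative)
    data.frame(term = id, description = terms$descriptions[[id]],
               hits = k, term_size = K, list_size = n, universe_size = N,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  out <- out[order(out$adj_p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are clipped to at
#' most 1 and returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Hierarchical clustering of samples on selected features
#'
#' Clusters the sample columns on the expression of a restricted feature
#' set, with the same distance/linkage arguments as the network
#' clustering (one pipeline-wide meaning of "hierarchical clustering"),
#' and cuts the dendrogram into `k` clusters.
#'
#' Missing feature values are imputed with the feature's mean across
#' samples (clustering distances are undefined for sample pairs without
#' shared observations; mean imputation keeps every sample clusterable
#' while leaving observed values untouched).
#'
#' @param m An `ExpressionMatrix`.
#' @param feature_ids Entities to cluster on (subset of the matrix rows).
#' @param k Number of clusters, `2 <= k <=` number of samples.
#' @param distance,linkage As in [cluster_bipartite()].
#' @return A `Partition`: named integer vector (sample -> cluster label).
#' @export
cluster_samples <- function(m, feature_ids, k,
                            distance = "manhattan", linkage = "ward.D") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!all(feature_ids %in% rownames(m$values)))
    stop("unknown feature ids")
  if (k < 2) stop("'k' must be at least 2")
  v <- m$values[feature_ids, , drop = FALSE]
  if (ncol(v) < k) stop("fewer samples than clusters")
  if (anyNA(v)) {
    message(sprintf("imputing %d missing value(s) with feature means",
                    sum(is.na(v))))
    for (i in seq_len(nrow(v))) {
      miss <- is.na(v[i, ])
      if (any(miss)) v[i, miss] <- mean(v[i, ], na.rm = TRUE)
    }
    if (anyNA(v)) stop("a feature has no observed values")
  }
  hc <- stats::hclust(stats::dist(t(v), method = distance), method = linkage)
  stats::cutree(hc, k = k)
}

#' Chi-square association between two sample partitions
#'
#' Pearson chi-square test (no continuity correction by default) on the
#' label contingency table of two partitions of the same samples.
#'
#' @param a,b Named label vectors over the same sample set, each with at
#'   least two distinct labels.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p_value`, `observed`, `expected`
#'   and `low_expected` (flag: any expected count below 5).
#' @export
partition_association <- function(a, b, correct = FALSE) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("partitions must be named by sample id")
  if (!setequal(names(a), names(b)))
    stop("partitions cover different sample sets")
  b <- b[names(a)]
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("each partition needs at least two distinct labels")
  tab <- table(a, b)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = ct$p.value,
       observed = tab,
       expected = ct$expected,
       low_expected = any(ct$expected < 5))
}
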