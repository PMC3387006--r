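#' Discretize a correlation matrix into a signed bipartite network
#'
#' Marks the top `quantile` of the entries as +1 and the bottom `quantile`
#' as -1; everything else becomes 0. The cut count is
#' `k = floor(quantile * M)` with `M` the total number of entries, so the
#' +1 and -1 counts are exactly equal by construction. Boundary ties are
#' broken lexicographically by (row index, column index) for bit
#' reproducibility; the -1 set is chosen among entries not already taken
#' by the +1 set, preserving the count conservation even under total ties.
#'
#' @param c A `CorrelationMatrix` or a finite numeric matrix.
#' @param quantile Tail fraction per sign, in (0, 0.5) (default 0.01).
#' @return A `SignedNetwork`: list with integer `values` in \{-1, 0, +1\},
#'   the realized `pos_threshold` / `neg_threshold` and `quantile`.
#' @export
discretize <- function(c, quantile = 0.01) {
  x <- if (inherits(c, "CorrelationMatrix")) c$values else as_values(c)
  if (!all(is.finite(x))) stop("matrix contains non-finite entries")
  if (quantile <= 0 || quantile >= 0.5)
    stop("'quantile' must lie in (0, 0.5)")
  M <- length(x)
  k <- floor(quantile * M)
  if (k < 1) stop("matrix too small for quantile")
  v <- as.vector(x)
  ri <- as.vector(row(x))
  ci <- as.vector(col(x))
  pos_idx <- order(-v, ri, ci)[seq_len(k)]
  neg_ord <- order(v, ri, ci)
  neg_idx <- setdiff(neg_ord, pos_idx)[seq_len(k)]
  net <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  net[pos_idx] <- 1L
  net[neg_idx] <- -1L
  structure(list(values = net,
                 pos_threshold = min(x[pos_idx]),
                 neg_threshold = max(x[neg_idx]),
                 quantile = quantile),
            class = "SignedNetwork")
}

#' @export
print.SignedNetwork <- function(x, ...) {
  cat(sprintf("SignedNetwork: %d genes x %d miRNAs; +1: %d, -1: %d\n",
              nrow(x$values), ncol(x$values),
              sum(x$values == 1L), sum(x$values == -1L)))
  invisible(x)
}

#' Condense a signed network against a miRNA whitelist
#'
#' Restricts the columns to the whitelisted miRNAs (original column order
#' preserved), then drops genes that retain fewer than `min_nonzero`
#' non-zero connections — counting either sign — to the remaining miRNAs.
#' The order of operations is fixed: columns first, then rows.
#'
#' @param net A `SignedNetwork`.
#' @param mirna_whitelist Character vector of miRNA ids to keep.
#' @param min_nonzero Minimum non-zero connections per retained gene
#'   (default 2).
#' @return The condensed `SignedNetwork` (thresholds carried over).
#' @export
condense <- function(net, mirna_whitelist, min_nonzero = 2L) {
  stopifnot(inherits(net, "SignedNetwork"))
  if (length(mirna_whitelist) == 0) stop("empty whitelist")
  keep_cols <- colnames(net$values)[colnames(net$values) %in% mirna_whitelist]
  if (length(keep_cols) == 0)
    stop("whitelist does not intersect the network's miRNAs")
  v <- net$values[, keep_cols, drop = FALSE]
  keep_rows <- rowSums(v != 0L) >= min_nonzero
  message(sprintf("condense: %d of %d miRNAs, %d of %d genes retained",
                  length(keep_cols), ncol(net$values),
                  sum(keep_rows), nrow(v)))
  structure(list(values = v[keep_rows, , drop = FALSE],
                 pos_threshold = net$pos_threshold,
                 neg_threshold = net$neg_threshold,
                 quantile = net$quantile),
            class = "SignedNetwork")
}

#' Two-way hierarchical clustering of a signed network
#'
#' Clusters the miRNA columns (observations = signed column vectors) by
#' agglomerative clustering with Manhattan distance and Ward linkage, and
#' cuts the column dendrogram into exactly `k_mirna` clusters. The genes
#' are clustered the same way for display (heatmap row ordering) only;
#' module membership is derived from the connection patterns, not from the
#' gene tree.
#'
#' @param net A `SignedNetwork`.
#' @param k_mirna Number of miRNA clusters to cut (default 5).
#' @param distance Distance for [stats::dist()] (default `"manhattan"`).
#' @param linkage Linkage for [stats::hclust()] (default `"ward.D"`, the
#'   classical Ward update on the given distance; `"ward.D2"` available).
#' @return List with `mirna_clusters` (named integer vector),
#'   `mirna_hclust` and `gene_hclust` dendrograms.
#' @export
cluster_bipartite <- function(net, k_mirna = 5L,
                              distance = "manhattan", linkage = "ward.D") {
  stopifnot(inherits(net, "SignedNetwork"))
  v <- net$values
  if (nrow(v) == 0 || ncol(v) == 0) stop("empty network")
  if (k_mirna < 2 || k_mirna > ncol(v))
    stop("'k_mirna' must lie in [2, number of miRNAs]")
  hc_m <- stats::hclust(stats::dist(t(v), method = distance),
                        method = linkage)
  hc_g <- if (nrow(v) >= 2)
    stats::hclust(stats::dist(v, method = distance), method = linkage)
  list(mirna_clusters = stats::cutree(hc_m, k = k_mirna),
       mirna_hclust = hc_m,
       gene_hclust = hc_g)
}

# internal: iterative pruning of one sign-specific incidence matrix.
# B is a binary gene x miRNA matrix; returns the sub-matrix in which every
# gene and every miRNA keeps >= 2 within-module connections (fixed point),
# or after the single gene-drop pass only (single_pass).
prune_incidence <- function(B, mode = c("fixed_point", "single_pass")) {
  mode <- match.arg(mode)
  B <- B[rowSums(B) >= 2, , drop = FALSE]
  if (mode == "single_pass") return(B)
  repeat {
    B2 <- B[, colSums(B) >= 2, drop = FALSE]
    B2 <- B2[rowSums(B2) >= 2, , drop = FALSE]
    if (identical(dim(B2), dim(B))) break
    B <- B2
  }
  B
}

#' Extract miRNA-mRNA module pairs from a clustered signed network
#'
#' For each miRNA cluster and each sign s in \{+, -\}: collect the genes
#' with at least one s-connection to the cluster miRNAs, drop genes with
#' only one such connection, and (in the default `"fixed_point"` mode)
#' iteratively drop miRNAs with fewer than two s-connections to the
#' remaining genes and genes falling below two, until stable. The fixed
#' point guarantees the module property that every member has at least two
#' within-module connections of that sign. `"single_pass"` performs only
#' the single gene-drop pass (all cluster miRNAs retained), for strict
#' replication of a one-shot workflow.
#'
#' @param net A `SignedNetwork` (typically condensed).
#' @param mirna_clusters Named integer vector mapping every network miRNA
#'   to exactly one cluster (as from [cluster_bipartite()]).
#' @param mode `"fixed_point"` (default) or `"single_pass"`.
#' @return List of `ModulePair` objects, one per cluster id (ascending).
#'   Each has `id`, `cluster`, `mirnas` (the full cluster), and per sign a
#'   list `pos` / `neg` with `mirnas`, `genes`, and the within-module
#'   connection counts `gene_connections`, `mirna_connections`. Empty
#'   modules are permitted.
#' @export
extract_module_pairs <- function(net, mirna_clusters,
                                 mode = c("fixed_point", "single_pass")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "SignedNetwork"))
  v <- net$values
  if (!setequal(names(mirna_clusters), colnames(v)))
    stop("'mirna_clusters' must assign every network miRNA to one cluster")
  out <- lapply(sort(unique(mirna_clusters)), function(cid) {
    mir <- names(mirna_clusters)[mirna_clusters == cid]
    sub <- v[, mir, drop = FALSE]
    one_sign <- function(s) {
      B <- (sub == s) * 1L
      B <- prune_incidence(B, mode)
      # an empty (0 x 0) pruning result loses its dimnames entirely
      genes <- rownames(B); if (is.null(genes)) genes <- character(0)
      mirs <- colnames(B); if (is.null(mirs)) mirs <- character(0)
      list(mirnas = mirs, genes = genes,
           gene_connections = rowSums(B),
           mirna_connections = colSums(B))
    }
    structure(list(id = sprintf("modu-%d", cid), cluster = cid,
                   mirnas = mir,
                   pos = one_sign(1L), neg = one_sign(-1L)),
              class = "ModulePair")
  })
  n_empty <- sum(vapply(out, function(mp)
    length(mp$pos$genes) == 0 && length(mp$neg$genes) == 0, logical(1)))
  if (n_empty > 0)
    message(sprintf("%d cluster(s) yielded empty module pairs", n_empty))
  out
}

#' @export
print.ModulePair <- function(x, ...) {
  cat(sprintf("ModulePair %s: %d miRNAs; +module %d genes (%d miRNAs), -module %d genes (%d miRNAs)\n",
              x$id, length(x$mirnas),
              length(x$pos$genes), length(x$pos$mirnas),
              length(x$neg$genes), length(x$neg$mirnas)))
  invisible(x)
}

#' Tabular summary of a list of module pairs
#'
#' One row per module (sign-specific), mirroring the usual module summary
#' table: module id with a `-ps`/`-ne` extension, gene count and the
#' retained miRNA list.
#'
#' @param module_pairs List of `ModulePair` objects.
#' @param prefix Optional id prefix (e.g. a class label).
#' @return A data.frame with columns `module`, `gene_number`, `mirnas`.
#' @export
module_summary <- function(module_pairs, prefix = "") {
  rows <- lapply(module_pairs, function(mp) {
    data.frame(
      module = paste0(prefix, mp$id, c("-ps", "-ne")),
      gene_number = c(length(mp$pos$genes), length(mp$neg$genes)),
      mirnas = c(paste(mp$pos$mirnas, collapse = ","),
                 paste(mp$neg$mirnas, collapse = ",")),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Module edge list
#'
#' Flattens module pairs into a (mirna, gene, sign, module) edge table,
#' sorted deterministically.
#'
#' @param module_pairs List of `ModulePair` objects.
#' @param net The `SignedNetwork` the modules were extracted from.
#' @return data.frame with columns `module`, `sign`, `mirna`, `gene`.
#' @export
module_edges <- function(module_pairs, net) {
  stopifnot(inherits(net, "SignedNetwork"))
  v <- net$values
  rows <- list()
  for (mp in module_pairs) {
    for (s in c(1L, -1L)) {
      mod <- if (s == 1L) mp$pos else mp$neg
      if (length(mod$genes) == 0 || length(mod$mirnas) == 0) next
      sub <- v[mod$genes, mod$mirnas, drop = FALSE] == s
      idx <- which(sub, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        module = paste0(mp$id, if (s == 1L) "-ps" else "-ne"),
        sign = s,
        mirna = mod$mirnas[idx[, 2]],
        gene = mod$genes[idx[, 1]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(module = character(), sign = integer(),
                      mirna = character(), gene = character()))
  out <- do.call(rbind, rows)
  out[order(out$module, out$mirna, out$gene), , drop = FALSE]
}

#' Heatmap of a signed network
#'
#' Draws the condensed network with the conventional colours: red for the
#' top-quantile positive connections, yellow for the top-quantile negative
#' connections, orange for the unconsidered background. Rows and columns
#' follow the two-way dendrogram order when a clustering is supplied.
#'
#' @param net A `SignedNetwork`.
#' @param clustering Optional result of [cluster_bipartite()].
#' @export
plot_network_heatmap <- function(net, clustering = NULL) {
  stopifnot(inherits(net, "SignedNetwork"))
  v <- net$values
  if (!is.null(clustering)) {
    v <- v[, clustering$mirna_hclust$order, drop = FALSE]
    if (!is.null(clustering$gene_hclust))
      v <- v[clustering$gene_hclust$order, , drop = FALSE]
  }
  graphics::image(t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                  col = c("yellow", "orange", "red"),
                  zlim = c(-1, 1), axes = FALSE,
                  xlab = "miRNAs", ylab = "genes")
  invisible(net)
}
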