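#' Subsample-averaged Pearson correlation matrix
#'
#' Estimates the correlation between every gene and every miRNA by a
#' resampling scheme: in each of `n_reps` replicates a fraction of the
#' samples is drawn without replacement, the Pearson coefficient is
#' computed for every gene-miRNA pair over the non-missing shared samples
#' of that draw, and the final estimate is the arithmetic mean over
#' replicates. A pair whose correlation is undefined in a replicate
#' (fewer than `min_pairs` usable samples, or zero variance in the draw)
#' contributes nothing to that replicate's average for that pair rather
#' than being imputed as zero.
#'
#' With `fraction = 1` every replicate would use the full sample set, so a
#' single exact pass is performed and the result equals the plain
#' full-sample Pearson matrix bit for bit.
#'
#' @param mirna_matrix,gene_matrix `ExpressionMatrix` objects on the log2
#'   scale sharing the sample ids in `sample_ids`.
#' @param sample_ids Samples (e.g. one tumour class) to correlate over;
#'   default: all shared samples.
#' @param n_reps Number of resampling replicates (default 1000).
#' @param fraction Subsample fraction in (0, 1]; the draw size is
#'   `floor(fraction * n)` (default 0.8).
#' @param seed Integer seed; the replicate draws are fully determined by it.
#' @param min_pairs Minimum usable samples for a pair in a replicate
#'   (default 3).
#' @param sample_class Optional label stored in the result metadata.
#' @param keep_replicates If `TRUE`, attach the per-replicate correlation
#'   array (genes x miRNAs x reps) as element `replicates` (memory heavy;
#'   intended for diagnostics at small scale).
#' @return A `CorrelationMatrix`: list with `values` (genes x miRNAs, may
#'   contain `NA` for pairs undefined in every replicate), `n_defined`
#'   (replicate counts per pair) and the resampling metadata
#'   `n_reps`, `fraction`, `seed`, `sample_class`.
#' @export
subsampled_correlation <- function(mirna_matrix, gene_matrix,
                                   sample_ids = NULL,
                                   n_reps = 1000, fraction = 0.8,
                                   seed = 1L, min_pairs = 3L,
                                   sample_class = NA_character_,
                                   keep_replicates = FALSE) {
  stopifnot(inherits(mirna_matrix, "ExpressionMatrix"),
            inherits(gene_matrix, "ExpressionMatrix"))
  if (mirna_matrix$scale != "log2" || gene_matrix$scale != "log2")
    stop("both matrices must be on the log2 scale")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must lie in (0, 1]")
  if (n_reps < 1) stop("'n_reps' must be positive")
  shared <- intersect(colnames(gene_matrix$values),
                      colnames(mirna_matrix$values))
  if (is.null(sample_ids)) sample_ids <- shared
  if (!all(sample_ids %in% shared))
    stop("some requested samples are absent from one of the matrices")
  n <- length(sample_ids)
  if (n < 4) stop("need at least 4 samples")
  m <- floor(fraction * n)
  if (m < 3) stop("floor(fraction * n) must be at least 3")

  G <- gene_matrix$values[, sample_ids, drop = FALSE]
  M <- mirna_matrix$values[, sample_ids, drop = FALSE]

  rep_cor <- function(idx) {
    g <- G[, idx, drop = FALSE]
    mm <- M[, idx, drop = FALSE]
    if (anyNA(g) || anyNA(mm)) {
      r <- suppressWarnings(stats::cor(t(g), t(mm),
                                       use = "pairwise.complete.obs"))
      npair <- (!is.na(g)) %*% t(!is.na(mm))
      r[npair < min_pairs] <- NA_real_
    } else {
      # complete data: plain Pearson (also the exact fraction = 1 path)
      r <- suppressWarnings(stats::cor(t(g), t(mm)))
    }
    r
  }

  if (m == n) {
    # degenerate resampling: every replicate is the full sample set
    r <- rep_cor(seq_len(n))
    out <- structure(list(values = r,
                          n_defined = matrix(as.integer(!is.na(r)),
                                             nrow(r), ncol(r),
                                             dimnames = dimnames(r)),
                          n_reps = as.integer(n_reps), fraction = fraction,
                          seed = as.integer(seed),
                          sample_class = sample_class),
                     class = "CorrelationMatrix")
    if (keep_replicates) out$replicates <- array(r, c(dim(r), 1L))
    return(out)
  }

  acc <- matrix(0, nrow(G), nrow(M))
  cnt <- matrix(0L, nrow(G), nrow(M))
  reps <- if (keep_replicates) array(NA_real_, c(nrow(G), nrow(M), n_reps))
  withr::with_seed(seed, {
    for (b in seq_len(n_reps)) {
      r <- rep_cor(sample.int(n, m))
      ok <- !is.na(r)
      acc[ok] <- acc[ok] + r[ok]
      cnt <- cnt + ok
      if (keep_replicates) reps[, , b] <- r
    }
  })
  vals <- acc / cnt
  vals[cnt == 0L] <- NA_real_
  dimnames(vals) <- list(rownames(G), rownames(M))
  dimnames(cnt) <- dimnames(vals)
  n_excluded <- sum(cnt < n_reps)
  if (n_excluded > 0)
    message(sprintf(
      "%d pair(s) had undefined correlations in some replicates (excluded from their means)",
      n_excluded))
  out <- structure(list(values = vals, n_defined = cnt,
                        n_reps = as.integer(n_reps), fraction = fraction,
                        seed = as.integer(seed), sample_class = sample_class),
                   class = "CorrelationMatrix")
  if (keep_replicates) out$replicates <- reps
  out
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf(
    "CorrelationMatrix: %d genes x %d miRNAs (%d reps, %.0f%% subsample%s)\n",
    nrow(x$values), ncol(x$values), x$n_reps, 100 * x$fraction,
    if (is.na(x$sample_class)) "" else paste0(", class ", x$sample_class)))
  invisible(x)
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Applies z = atanh(r) = 0.5 * log((1 + r) / (1 - r)) entrywise after
#' clipping r to `[-(1 - clip_epsilon), 1 - clip_epsilon]` so that perfect
#' correlations map to finite z values (required for the downstream SVD).
#'
#' @param c A `CorrelationMatrix` or a numeric matrix of correlations in
#'   `[-1, 1]`.
#' @param clip_epsilon Clipping margin (default 1e-6).
#' @return A `ZMatrix`: list with `values` and `clip_epsilon`.
#' @examples
#' fisher_z(matrix(c(0, 0.5, -0.5, 1), 2, 2,
#'          dimnames = list(c("g1", "g2"), c("m1", "m2"))))$values
#' @export
fisher_z <- function(c, clip_epsilon = 1e-6) {
  v <- if (inherits(c, "CorrelationMatrix")) c$values else as_values(c)
  if (any(abs(v) > 1, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  lim <- 1 - clip_epsilon
  v <- pmin(pmax(v, -lim), lim)
  structure(list(values = atanh(v), clip_epsilon = clip_epsilon),
            class = "ZMatrix")
}
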