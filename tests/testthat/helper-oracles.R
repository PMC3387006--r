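# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (explicit loops, closed forms) and separate from the
# package's implementation paths.

rand_named_matrix <- function(nr, nc, seed, rgen = stats::rnorm,
                              row_prefix = "g", col_prefix = "m") {
  withr::with_seed(seed, {
    matrix(rgen(nr * nc), nr, nc,
           dimnames = list(sprintf("%s%03d", row_prefix, seq_len(nr)),
                           sprintf("%s%03d", col_prefix, seq_len(nc))))
  })
}

rand_expression <- function(nr, nc, seed, scale = "log2",
                            row_prefix = "g") {
  m <- rand_named_matrix(nr, nc, seed, row_prefix = row_prefix,
                         col_prefix = "s")
  expression_matrix(m + 8, scale)
}

# full-sort brute-force selection of the k largest / smallest entries with
# (row, column) lexicographic tie-break; -1 chosen among entries not in +1
oracle_signed_topk <- function(x, k) {
  v <- as.vector(x); ri <- as.vector(row(x)); ci <- as.vector(col(x))
  pos <- order(-v, ri, ci)[1:k]
  neg <- setdiff(order(v, ri, ci), pos)[1:k]
  list(pos = sort(pos), neg = sort(neg))
}

# fixed-point pruning of a binary gene x miRNA incidence matrix, written
# as an explicit element-counting recursion
oracle_prune <- function(B) {
  genes <- rownames(B); mirs <- colnames(B)
  # initial pass: a gene survives only with >= 2 connections
  keep_g <- vapply(genes, function(g) sum(B[g, mirs]) >= 2, logical(1))
  genes <- genes[keep_g]
  repeat {
    keep_m <- vapply(mirs, function(m) {
      cnt <- 0
      for (g in genes) cnt <- cnt + B[g, m]
      cnt >= 2
    }, logical(1))
    mirs2 <- mirs[keep_m]
    keep_g <- vapply(genes, function(g) {
      cnt <- 0
      for (m in mirs2) cnt <- cnt + B[g, m]
      cnt >= 2
    }, logical(1))
    genes2 <- genes[keep_g]
    if (length(mirs2) == length(mirs) && length(genes2) == length(genes))
      break
    mirs <- mirs2; genes <- genes2
  }
  list(genes = genes, mirnas = mirs)
}

# Benjamini-Hochberg step-up written from the definition: sort, take
# m * p / rank, enforce monotonicity by a cumulative minimum from the
# largest p downwards, clip at 1, undo the sort
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# one-sided (greater) Fisher p as a direct hypergeometric tail sum:
# P(K >= a) with white = a + c, black = b + d, drawn = a + b
hyper_tail <- function(a, b, c, d) {
  kmax <- min(a + b, a + c)
  sum(stats::dhyper(a:kmax, a + c, b + d, a + b))
}

# hand Pearson chi-square on a contingency table
oracle_chisq <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# independent seed-match construction via character complement tables
oracle_seed_motifs <- function(mature) {
  comp <- c(A = "T", C = "G", G = "C", U = "A", T = "A")
  rc <- function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  s28 <- substr(mature, 2, 8)
  s27 <- substr(mature, 2, 7)
  sort(unique(c(rc(s28), paste0(rc(s27), "A"), paste0(rc(s28), "A"))))
}

# naive O(L * m) sliding-window motif scan; N never matches
oracle_scan <- function(seqs, motif_sets) {
  A <- matrix(0L, length(seqs), length(motif_sets),
              dimnames = list(names(seqs),
                              vapply(motif_sets, `[[`, character(1),
                                     "mirna_id")))
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[[i]], "")[[1]]
    for (j in seq_along(motif_sets)) {
      found <- FALSE
      for (mot in motif_sets[[j]]$motifs$motif) {
        mc <- strsplit(mot, "")[[1]]
        L <- length(s) - length(mc) + 1
        if (L < 1) next
        for (st in seq_len(L)) {
          if (all(s[st:(st + length(mc) - 1)] == mc)) { found <- TRUE; break }
        }
        if (found) break
      }
      A[i, j] <- as.integer(found)
    }
  }
  A
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  exp_idx <- si * sj / ch2(n)
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

jaccard <- function(a, b) {
  if (length(union(a, b)) == 0) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

# small fully-modular synthetic configuration (every non-near-constant
# gene belongs to a module) used by the recovery tests
recovery_config <- function(noise_sd, n_per_class = c(PPC = 60),
                            loading = 3, seed = 11,
                            n_modules = 3, mirnas_per = 3, genes_per = 10,
                            extra_mirnas = 0) {
  synthetic_config(
    n_samples_per_class = n_per_class,
    n_genes = n_modules * 2 * genes_per,
    n_mirnas = n_modules * mirnas_per + extra_mirnas,
    module_specs = replicate(n_modules,
      module_spec(mirnas_per, genes_per, genes_per,
                  loading_strength = loading),
      simplify = FALSE),
    noise_sd = noise_sd, missing_rate = 0,
    near_constant_fraction = 0, seed = seed)
}
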