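#' SVD characterization of a z-transformed correlation matrix
#'
#' Treats the matrix as a pseudo-dataset with genes (rows) as observations
#' and miRNAs (columns) as features and decomposes it by singular value
#' decomposition, without centering: the raw sign structure of the
#' correlations is what produces the characteristic two-peak score
#' distributions, and centering would destroy it. Variance fractions
#' sigma_k^2 / sum_j sigma_j^2 are computed over *all* singular values even
#' when fewer component vectors are returned.
#'
#' Sign convention: each component is flipped, if necessary, so that its
#' left (gene-score) vector has a non-negative sum; an exactly zero sum
#' falls back to making the first nonzero entry positive. This makes the
#' decomposition reproducible across platforms.
#'
#' @param z A `ZMatrix` (see [fisher_z()]) or a finite numeric matrix.
#' @param n_components Number of singular vectors to return (default: all).
#' @return An `SvdProfile`: list with `singular_values`,
#'   `variance_fractions`, `left_vectors` (genes x components),
#'   `right_vectors` (miRNAs x components) and `shape_stats` (a data.frame
#'   of skewness / bimodality per left vector, see [score_shape_stats()]).
#' @export
svd_characterize <- function(z, n_components = NULL) {
  x <- if (inherits(z, "ZMatrix")) z$values else as_values(z)
  if (!all(is.finite(x))) stop("matrix contains non-finite entries")
  r <- min(dim(x))
  if (is.null(n_components)) n_components <- r
  if (n_components < 1 || n_components > r)
    stop("'n_components' must lie in [1, min(dim)]")
  s <- svd(x, nu = n_components, nv = n_components)
  for (k in seq_len(n_components)) {
    sgn <- sum(s$u[, k])
    if (sgn == 0) {
      nz <- which(s$u[, k] != 0)
      sgn <- if (length(nz)) s$u[nz[1], k] else 1
    }
    if (sgn < 0) {
      s$u[, k] <- -s$u[, k]
      s$v[, k] <- -s$v[, k]
    }
  }
  rownames(s$u) <- rownames(x)
  rownames(s$v) <- colnames(x)
  colnames(s$u) <- colnames(s$v) <- paste0("SV", seq_len(n_components))
  fr <- s$d^2 / sum(s$d^2)
  shape <- do.call(rbind, lapply(seq_len(n_components), function(k) {
    st <- tryCatch(score_shape_stats(s$u[, k]),
                   error = function(e) list(skewness = NA_real_,
                                            bimodality_coefficient = NA_real_,
                                            bimodal_leaning = NA))
    data.frame(component = k, skewness = st$skewness,
               bimodality = st$bimodality_coefficient,
               bimodal_leaning = st$bimodal_leaning)
  }))
  structure(list(singular_values = s$d,
                 variance_fractions = fr,
                 left_vectors = s$u,
                 right_vectors = s$v,
                 shape_stats = shape),
            class = "SvdProfile")
}

#' @export
print.SvdProfile <- function(x, ...) {
  cat(sprintf("SvdProfile: %d components returned of %d singular values\n",
              ncol(x$left_vectors), length(x$singular_values)))
  k <- min(5, length(x$variance_fractions))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$variance_fractions[seq_len(k)]), collapse = " "),
      "\n")
  invisible(x)
}

#' Shuffle null for a correlation (z) matrix
#'
#' Destroys the joint row/column structure of the matrix while preserving
#' the multiset of its values exactly. The default (`"entrywise"`) permutes
#' all entries uniformly at random over all positions — the strongest null
#' of this kind; `"rows"` / `"columns"` permute entries within each row or
#' column only.
#'
#' @param z `ZMatrix` or numeric matrix.
#' @param seed Integer seed.
#' @param mode One of `"entrywise"`, `"rows"`, `"columns"`.
#' @return An object of the same class with permuted values.
#' @export
shuffle_null <- function(z, seed, mode = c("entrywise", "rows", "columns")) {
  mode <- match.arg(mode)
  is_z <- inherits(z, "ZMatrix")
  x <- if (is_z) z$values else as_values(z)
  withr::with_seed(seed, {
    if (mode == "entrywise") {
      x[] <- sample(as.vector(x))
    } else if (mode == "rows") {
      for (i in seq_len(nrow(x))) x[i, ] <- sample(x[i, ])
    } else {
      for (j in seq_len(ncol(x))) x[, j] <- sample(x[, j])
    }
  })
  if (is_z) structure(list(values = x, clip_epsilon = z$clip_epsilon),
                      class = "ZMatrix")
  else x
}

#' Shape statistics of a singular-vector score distribution
#'
#' Quantifies the visual impressions "two-peak" and "asymmetric" for a
#' score vector: bias-corrected sample skewness G1 and Sarle's bimodality
#' coefficient with the finite-sample correction,
#' BC = (G1^2 + 1) / (G2 + 3 (n-1)^2 / ((n-2)(n-3))),
#' where G2 is the bias-corrected excess kurtosis. BC above 5/9 (the value
#' attained by the uniform distribution) is flagged "bimodal-leaning".
#'
#' @param v Numeric vector, length >= 4, non-zero variance.
#' @return List with `skewness`, `bimodality_coefficient`,
#'   `bimodal_leaning`.
#' @export
score_shape_stats <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  if (n < 4) stop("need at least 4 values")
  if (stats::sd(v) == 0) stop("zero variance")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  b1 <- m3 / m2^1.5
  g1 <- b1 * sqrt(n * (n - 1)) / (n - 2)
  b2 <- m4 / m2^2
  g2 <- ((n + 1) * (b2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  bc <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  list(skewness = g1, bimodality_coefficient = bc,
       bimodal_leaning = bc > 5 / 9)
}

#' Plot an SVD profile (scree and score histograms)
#'
#' Draws the variance-explained spectrum and the score distributions of
#' the first two left singular vectors, mirroring the standard
#' scree + histogram presentation of correlation-matrix SVD profiles.
#'
#' @param profile An `SvdProfile`.
#' @param n_bars Number of spectrum bars to draw (default 10).
#' @export
plot_svd_profile <- function(profile, n_bars = 10) {
  stopifnot(inherits(profile, "SvdProfile"))
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  k <- min(n_bars, length(profile$variance_fractions))
  graphics::barplot(profile$variance_fractions[seq_len(k)],
                    names.arg = seq_len(k),
                    xlab = "component", ylab = "variance fraction",
                    main = "spectrum")
  for (j in seq_len(min(2, ncol(profile$left_vectors)))) {
    graphics::hist(profile$left_vectors[, j], breaks = 40,
                   xlab = sprintf("scores (left vector %d)", j),
                   main = sprintf("component %d", j))
  }
  invisible(profile)
}
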