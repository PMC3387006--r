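#' One planted module specification
#'
#' Describes a planted miRNA-mRNA module for the synthetic generator: a
#' set of miRNAs and a positively and a negatively loaded gene set, all
#' driven by one shared latent factor. The population correlation between
#' a modular miRNA and a modular gene under the shared-factor model is
#' +/- loading_strength^2 / (loading_strength^2 + noise_sd^2).
#'
#' @param mirna_count,pos_gene_count,neg_gene_count Positive member counts.
#' @param loading_strength Factor loading lambda > 0 (default 3, which with
#'   unit noise gives planted |r| = 0.9).
#' @param classes Optional character vector of sample classes in which the
#'   module is active; `NULL` (default) means all classes.
#' @return A `module_spec` list.
#' @export
module_spec <- function(mirna_count, pos_gene_count, neg_gene_count,
                        loading_strength = 3, classes = NULL) {
  counts <- c(mirna_count, pos_gene_count, neg_gene_count)
  if (any(counts < 1) || any(counts != floor(counts)))
    stop("module member counts must be positive integers")
  if (loading_strength <= 0) stop("'loading_strength' must be positive")
  structure(list(mirna_count = as.integer(mirna_count),
                 pos_gene_count = as.integer(pos_gene_count),
                 neg_gene_count = as.integer(neg_gene_count),
                 loading_strength = loading_strength,
                 classes = classes),
            class = "module_spec")
}

# default module profile: the study-like module-size spectrum scaled to a
# desk-sized dataset (miRNA counts 5,4,8,3,7; gene counts ~1/10 scale)
default_module_specs <- function() {
  list(module_spec(5, 54, 11), module_spec(4, 47, 9),
       module_spec(8, 23, 6), module_spec(3, 35, 4),
       module_spec(7, 15, 62))
}

#' Synthetic study configuration
#'
#' Defines a fully synthetic two-class (plus normal) expression study with
#' planted correlated miRNA-gene module blocks of both signs, a missing
#' pattern on the miRNA side to exercise the presence filter, and a
#' near-constant gene fraction to exercise the variability filter. The
#' seed fully determines every generated artifact.
#'
#' Default class sizes are 98 primary-like, 13 metastatic-like and 28
#' normal samples, mirroring the cohort structure the pipeline is designed
#' for; tests use scaled-down configurations.
#'
#' @param n_samples_per_class Named positive integer vector of class sizes.
#' @param n_genes,n_mirnas Total entity counts.
#' @param module_specs List of [module_spec()] objects. Modular gene sets
#'   are disjoint across modules by construction; the total modular miRNA
#'   and gene counts must fit within `n_mirnas` / `n_genes`.
#' @param noise_sd Standard deviation of the i.i.d. entity noise
#'   (default 1).
#' @param missing_rate Probability that a miRNA measurement is missing,
#'   in \[0, 1) (default 0.05).
#' @param near_constant_fraction Fraction of genes generated almost
#'   constant so the variability filter has a non-trivial pass/fail mix
#'   (default 0.1).
#' @param near_constant_sd Noise of the near-constant genes (default 0.05).
#' @param baseline_mean,baseline_sd Entity baseline distribution on the
#'   log2 scale (defaults 8 and 1.5, a typical microarray intensity range).
#' @param utr_length 3'UTR length in nt (default 800, near the human
#'   median).
#' @param seed Integer seed.
#' @return A validated `SyntheticConfig`.
#' @export
synthetic_config <- function(n_samples_per_class = c(PPC = 98, MPC = 13,
                                                     normal = 28),
                             n_genes = 400, n_mirnas = 60,
                             module_specs = default_module_specs(),
                             noise_sd = 1, missing_rate = 0.05,
                             near_constant_fraction = 0.1,
                             near_constant_sd = 0.05,
                             baseline_mean = 8, baseline_sd = 1.5,
                             utr_length = 800, seed = 1L) {
  if (is.null(names(n_samples_per_class)) ||
      any(names(n_samples_per_class) == ""))
    stop("'n_samples_per_class' must be a named vector")
  if (any(n_samples_per_class < 1)) stop("class sizes must be positive")
  if (n_genes < 1 || n_mirnas < 1) stop("entity counts must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  if (near_constant_fraction < 0 || near_constant_fraction >= 1)
    stop("'near_constant_fraction' must lie in [0, 1)")
  if (utr_length < 8) stop("'utr_length' must be at least 8 nt")
  lapply(module_specs, function(sp) {
    if (!inherits(sp, "module_spec")) stop("module_specs must be module_spec objects")
    if (!is.null(sp$classes) &&
        !all(sp$classes %in% names(n_samples_per_class)))
      stop("module classes must be declared sample classes")
  })
  n_mod_mirnas <- sum(vapply(module_specs, `[[`, integer(1), "mirna_count"))
  n_mod_genes <- sum(vapply(module_specs, function(sp)
    sp$pos_gene_count + sp$neg_gene_count, integer(1)))
  if (n_mod_mirnas > n_mirnas)
    stop("modular miRNA counts exceed 'n_mirnas'")
  n_nc <- floor(near_constant_fraction * n_genes)
  if (n_mod_genes + n_nc > n_genes)
    stop("modular plus near-constant gene counts exceed 'n_genes'")
  structure(list(n_samples_per_class = n_samples_per_class,
                 n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 module_specs = module_specs,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 near_constant_fraction = near_constant_fraction,
                 near_constant_sd = near_constant_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 utr_length = as.integer(utr_length),
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate paired synthetic expression matrices
#'
#' Shared-latent-factor model: per module one latent factor per sample is
#' drawn i.i.d. standard normal; modular miRNAs and positive-module genes
#' load +lambda, negative-module genes load -lambda. Every entity adds an
#' entity-specific baseline (drawn once) and i.i.d. Gaussian noise.
#' Non-modular entities are pure baseline + noise, except for the
#' near-constant gene tail which gets `near_constant_sd` noise instead.
#' miRNA entries are masked missing i.i.d. at `missing_rate`. Values are
#' on the log2 scale.
#'
#' @param config A `SyntheticConfig`.
#' @return List with `mirna` and `gene` (`ExpressionMatrix`, log2),
#'   `labels` (named character vector sample -> class) and `truth` (a
#'   `GroundTruth`: `mirna_module`, `gene_module`, `gene_sign` — named
#'   integer vectors, 0 = background — plus `near_constant` gene ids).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cls <- config$n_samples_per_class
  n <- sum(cls)
  sample_idv <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(rep(names(cls), cls), sample_idv)
  specs <- config$module_specs
  nmod <- length(specs)
  gene_idv <- sprintf("G%04d", seq_len(config$n_genes))
  mirna_idv <- sprintf("mir%03d", seq_len(config$n_mirnas))

  mirna_module <- stats::setNames(integer(config$n_mirnas), mirna_idv)
  gene_module <- stats::setNames(integer(config$n_genes), gene_idv)
  gene_sign <- stats::setNames(integer(config$n_genes), gene_idv)
  i_m <- 1L; i_g <- 1L
  for (m in seq_len(nmod)) {
    sp <- specs[[m]]
    mirna_module[i_m:(i_m + sp$mirna_count - 1L)] <- m
    i_m <- i_m + sp$mirna_count
    gene_module[i_g:(i_g + sp$pos_gene_count - 1L)] <- m
    gene_sign[i_g:(i_g + sp$pos_gene_count - 1L)] <- 1L
    i_g <- i_g + sp$pos_gene_count
    gene_module[i_g:(i_g + sp$neg_gene_count - 1L)] <- m
    gene_sign[i_g:(i_g + sp$neg_gene_count - 1L)] <- -1L
    i_g <- i_g + sp$neg_gene_count
  }
  n_nc <- floor(config$near_constant_fraction * config$n_genes)
  near_constant <- if (n_nc > 0)
    gene_idv[(config$n_genes - n_nc + 1L):config$n_genes]
  else character(0)

  withr::with_seed(config$seed, {
    factors <- if (nmod > 0)
      matrix(stats::rnorm(nmod * n), nmod, n)
    else matrix(0, 0, n)
    gene_base <- stats::rnorm(config$n_genes, config$baseline_mean,
                              config$baseline_sd)
    mirna_base <- stats::rnorm(config$n_mirnas, config$baseline_mean,
                               config$baseline_sd)
    gvals <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                    config$n_genes, n,
                    dimnames = list(gene_idv, sample_idv))
    if (n_nc > 0)
      gvals[near_constant, ] <- stats::rnorm(n_nc * n, 0,
                                             config$near_constant_sd)
    mvals <- matrix(stats::rnorm(config$n_mirnas * n, 0, config$noise_sd),
                    config$n_mirnas, n,
                    dimnames = list(mirna_idv, sample_idv))
    for (m in seq_len(nmod)) {
      sp <- specs[[m]]
      active <- if (is.null(sp$classes)) rep(1, n)
                else as.numeric(labels %in% sp$classes)
      f <- factors[m, ] * active * sp$loading_strength
      gm <- which(gene_module == m)
      gvals[gm, ] <- gvals[gm, ] +
        outer(gene_sign[gm], f)        # +/- lambda * factor
      mm <- which(mirna_module == m)
      mvals[mm, ] <- sweep(mvals[mm, , drop = FALSE], 2, f, `+`)
    }
    gvals <- gvals + gene_base
    mvals <- mvals + mirna_base
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(mvals)) < config$missing_rate
      mvals[mask] <- NA_real_
    }
  })

  truth <- structure(list(mirna_module = mirna_module,
                          gene_module = gene_module,
                          gene_sign = gene_sign,
                          near_constant = near_constant),
                     class = "GroundTruth")
  list(mirna = expression_matrix(mvals, "log2"),
       gene = expression_matrix(gvals, "log2"),
       labels = labels,
       truth = truth)
}

#' Generate 3'UTR sequences with planted seed-match motifs
#'
#' Background sequences are i.i.d. uniform A/C/G/T. Every (gene, miRNA)
#' pair marked 1 in the plant matrix receives at least one verbatim motif
#' insertion at a recorded position (insertions never overlap each other);
#' every pair marked 0 is guaranteed clean: the whole sequence is
#' rejection-sampled (bounded retries) until it contains none of that
#' miRNA's motifs. The guarantee applies to the miRNAs present as columns
#' of `plant` — the set whose affinity ground truth must be exact.
#'
#' @param plant Binary gene x miRNA matrix (rownames = genes, colnames =
#'   miRNA ids present in `motif_sets`).
#' @param motif_sets Named list of `SeedMotifSet` objects covering the
#'   plant columns.
#' @param utr_length Sequence length in nt; must fit all motifs.
#' @param seed Integer seed.
#' @param max_retries Whole-sequence rejection cap per gene (default 1000).
#' @return List with `sequences` (named character vector of DNA) and
#'   `positions` (data.frame `gene`, `mirna`, `motif`, `start`).
#' @export
generate_utr_fasta <- function(plant, motif_sets, utr_length, seed,
                               max_retries = 1000L) {
  if (!is.matrix(plant) || is.null(rownames(plant)) ||
      (ncol(plant) > 0 && is.null(colnames(plant))))
    stop("'plant' must be a matrix with gene rownames and miRNA colnames")
  if (!all(plant %in% c(0, 1))) stop("'plant' must be binary")
  if (!all(colnames(plant) %in% names(motif_sets)))
    stop("motif_sets must cover all plant columns")
  motif_sets <- motif_sets[colnames(plant)]
  max_len <- if (ncol(plant) > 0)
    max(vapply(motif_sets, function(ms)
      max(nchar(ms$motifs$motif)), integer(1)))
  else 0L
  if (max_len > utr_length) stop("motifs longer than 'utr_length'")
  alphabet <- c("A", "C", "G", "T")
  genes <- rownames(plant)
  seqs <- stats::setNames(character(length(genes)), genes)
  pos_rows <- list()
  withr::with_seed(seed, {
    for (g in genes) {
      planted_j <- colnames(plant)[plant[g, ] == 1]
      zero_j <- colnames(plant)[plant[g, ] == 0]
      zero_motifs <- unique(unlist(lapply(motif_sets[zero_j],
                                          function(ms) ms$motifs$motif)))
      done <- FALSE
      for (try in seq_len(max_retries)) {
        s <- paste(sample(alphabet, utr_length, replace = TRUE),
                   collapse = "")
        recs <- list()
        occupied <- matrix(numeric(0), ncol = 2)
        placed_all <- TRUE
        for (j in planted_j) {
          mot_tab <- motif_sets[[j]]$motifs
          mot <- mot_tab$motif[sample.int(nrow(mot_tab), 1)]
          len <- nchar(mot)
          placed <- FALSE
          for (attempt in 1:50) {
            st <- sample.int(utr_length - len + 1, 1)
            en <- st + len - 1
            if (nrow(occupied) == 0 ||
                all(en < occupied[, 1] | st > occupied[, 2])) {
              substr(s, st, en) <- mot
              occupied <- rbind(occupied, c(st, en))
              recs[[length(recs) + 1]] <-
                data.frame(gene = g, mirna = j, motif = mot, start = st,
                           stringsAsFactors = FALSE)
              placed <- TRUE
              break
            }
          }
          if (!placed) { placed_all <- FALSE; break }
        }
        if (!placed_all) next
        clean <- length(zero_motifs) == 0 ||
          !any(vapply(zero_motifs, function(m) grepl(m, s, fixed = TRUE),
                      logical(1)))
        if (clean) {
          seqs[[g]] <- s
          pos_rows <- c(pos_rows, recs)
          done <- TRUE
          break
        }
      }
      if (!done)
        stop(sprintf(
          "could not satisfy motif constraints for gene '%s' in %d retries (motif density too high for utr_length?)",
          g, max_retries))
    }
  })
  positions <- if (length(pos_rows)) do.call(rbind, pos_rows)
  else data.frame(gene = character(), mirna = character(),
                  motif = character(), start = integer())
  list(sequences = seqs, positions = positions)
}

#' Generate a random term-to-gene annotation table with one planted term
#'
#' Random terms draw their gene sets uniformly from the gene universe;
#' one term, if requested, is exactly equal to a planted gene subset so
#' that over-representation of that subset is recoverable by construction.
#'
#' @param genes Gene universe.
#' @param n_terms Number of random terms.
#' @param planted_term Optional list `list(id =, genes =)`; `genes` must
#'   be a non-empty subset of the universe.
#' @param size_range Random term sizes, inclusive (default 5 to 50).
#' @param seed Integer seed.
#' @return A `TermTable`.
#' @export
generate_term_table <- function(genes, n_terms, planted_term = NULL,
                                size_range = c(5, 50), seed = 1L) {
  if (length(genes) == 0) stop("empty gene universe")
  if (!is.null(planted_term)) {
    if (length(planted_term$genes) == 0) stop("planted gene subset is empty")
    if (!all(planted_term$genes %in% genes))
      stop("planted genes must lie in the universe")
  }
  size_range <- pmin(size_range, length(genes))
  sets <- withr::with_seed(seed, {
    stats::setNames(lapply(seq_len(n_terms), function(i) {
      k <- sample(size_range[1]:size_range[2], 1)
      sample(genes, k)
    }), sprintf("T%03d", seq_len(n_terms)))
  })
  desc <- stats::setNames(rep("random term", n_terms), names(sets))
  if (!is.null(planted_term)) {
    sets[[planted_term$id]] <- planted_term$genes
    desc[planted_term$id] <- "planted term"
  }
  term_table(sets, genes, desc)
}

#' Random mature miRNA sequences
#'
#' Uniform i.i.d. RNA sequences, regenerated on (vanishingly rare) seed
#' collisions so all sequences are distinct.
#'
#' @param mirna_ids Names for the sequences.
#' @param length Sequence length in nt (default 22, a typical mature
#'   miRNA).
#' @param seed Integer seed.
#' @return Named character vector of RNA sequences.
#' @export
random_mature_sequences <- function(mirna_ids, length = 22L, seed = 1L) {
  withr::with_seed(seed, {
    draw <- function() paste(sample(c("A", "C", "G", "U"), length,
                                    replace = TRUE), collapse = "")
    out <- vapply(mirna_ids, function(i) draw(), character(1))
    while (anyDuplicated(out)) {
      dup <- which(duplicated(out))
      out[dup] <- vapply(dup, function(i) draw(), character(1))
    }
    out
  })
}
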