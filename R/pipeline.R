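#' Pipeline configuration
#'
#' Collects the file inputs and tuning parameters of the end-to-end
#' study flow: preprocessing, per-class subsample-averaged correlation,
#' SVD characterization, signed-network discretization, whitelist
#' condensation, two-way clustering, module-pair extraction, target-site
#' enrichment and gene-set over-representation.
#'
#' @param gene_tsv,mirna_tsv Expression TSVs (log2 scale; see
#'   [read_expression_tsv()]).
#' @param labels_tsv Sample class labels TSV.
#' @param whitelist Text file, one cancer-miRNA id per line.
#' @param utr_fasta 3'UTR FASTA (optional; enables the affinity stage).
#' @param mature_fasta Mature miRNA FASTA (optional; with `utr_fasta`).
#' @param gmt Term annotation GMT (optional; enables term enrichment).
#' @param driver_genes Text file of genes for the sample-partition
#'   association stage (optional).
#' @param classes Sample classes analysed as parallel networks
#'   (default `c("PPC", "MPC")`).
#' @param n_reps,fraction Correlation resampling protocol
#'   (defaults 1000 and 0.8).
#' @param quantile Signed-network tail fraction (default 0.01).
#' @param k_mirna miRNA cluster count (default 5).
#' @param min_nonzero Condensation row threshold (default 2).
#' @param fold,presence Preprocessing filter parameters (defaults 2, 0.8).
#' @param clip_epsilon Fisher-z clipping margin (default 1e-6).
#' @param n_components SVD components to store (default 10).
#' @param k_sample_clusters Clusters for the partition-association stage
#'   (default 2).
#' @param extraction_mode Module pruning mode (see
#'   [extract_module_pairs()]).
#' @param seed Master seed; per-stage seeds are split from it
#'   deterministically.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(gene_tsv, mirna_tsv, labels_tsv, whitelist,
                            utr_fasta = NULL, mature_fasta = NULL,
                            gmt = NULL, driver_genes = NULL,
                            classes = c("PPC", "MPC"),
                            n_reps = 1000, fraction = 0.8,
                            quantile = 0.01, k_mirna = 5,
                            min_nonzero = 2, fold = 2.0, presence = 0.80,
                            clip_epsilon = 1e-6, n_components = 10,
                            k_sample_clusters = 2,
                            extraction_mode = "fixed_point",
                            seed = 1L) {
  paths <- list(gene_tsv = gene_tsv, mirna_tsv = mirna_tsv,
                labels_tsv = labels_tsv, whitelist = whitelist,
                utr_fasta = utr_fasta, mature_fasta = mature_fasta,
                gmt = gmt, driver_genes = driver_genes)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input '%s' does not exist: %s", nm, p))
  }
  if (quantile <= 0 || quantile >= 0.5) stop("'quantile' out of range")
  if (fraction <= 0 || fraction > 1) stop("'fraction' out of range")
  structure(c(paths,
              list(classes = classes, n_reps = n_reps, fraction = fraction,
                   quantile = quantile, k_mirna = k_mirna,
                   min_nonzero = min_nonzero, fold = fold,
                   presence = presence, clip_epsilon = clip_epsilon,
                   n_components = n_components,
                   k_sample_clusters = k_sample_clusters,
                   extraction_mode = extraction_mode,
                   seed = as.integer(seed))),
            class = "PipelineConfig")
}

# internal: deterministic per-stage seed split, kept below 2^31
stage_seed <- function(seed, stage_index) {
  as.integer((as.double(seed) * 48271 + 7919 * stage_index) %% 2147483647)
}

#' Run the end-to-end study flow
#'
#' Executes preprocess -> correlation (per class) -> SVD profile ->
#' discretize -> condense -> cluster -> module extraction ->
#' target-site enrichment -> gene-set over-representation, writing every
#' artifact under `outdir` together with a manifest (input hashes,
#' parameters, seeds, output hashes). With `resume = TRUE`, stages whose
#' output files already exist are loaded from disk instead of recomputed,
#' so deleting a late-stage artifact and re-running recomputes only the
#' downstream stages.
#'
#' @param config A `PipelineConfig`.
#' @param outdir Output directory (created if needed).
#' @param resume Reuse existing stage outputs (default `FALSE`).
#' @return Invisibly, a list with the per-class results (`correlation`,
#'   `svd`, `network`, `condensed`, `clusters`, `module_pairs`, `edges`)
#'   and the `manifest` path.
#' @export
run_pipeline <- function(config, outdir, resume = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("preprocess", "correlation", "svd", "network", "modules",
              "enrichment"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  pj <- function(...) file.path(outdir, ...)
  fresh <- function(...) !resume || !all(file.exists(pj(...)))

  ## --- preprocess ------------------------------------------------------
  gene_f <- pj("preprocess", "gene_filtered.tsv")
  mirna_f <- pj("preprocess", "mirna_filtered.tsv")
  if (fresh(file.path("preprocess", c("gene_filtered.tsv",
                                      "mirna_filtered.tsv")))) {
    gene <- filter_variability(read_expression_tsv(config$gene_tsv),
                               fold = config$fold)
    mirna <- filter_presence(read_expression_tsv(config$mirna_tsv),
                             min_fraction = config$presence)
    write_expression_tsv(gene, gene_f)
    write_expression_tsv(mirna, mirna_f)
  } else {
    message("preprocess: reusing cached artifacts")
    gene <- read_expression_tsv(gene_f)
    mirna <- read_expression_tsv(mirna_f)
  }
  labels <- read_labels_tsv(config$labels_tsv)
  whitelist <- readLines(config$whitelist)

  results <- list()
  for (ci in seq_along(config$classes)) {
    cl <- config$classes[ci]
    cl_samples <- names(labels)[labels == cl]
    cl_samples <- intersect(cl_samples, sample_ids(gene))

    ## --- correlation ---------------------------------------------------
    cor_f <- pj("correlation", sprintf("%s_correlation.tsv", cl))
    if (fresh(file.path("correlation", basename(cor_f)))) {
      cm <- subsampled_correlation(
        mirna, gene, sample_ids = cl_samples,
        n_reps = config$n_reps, fraction = config$fraction,
        seed = stage_seed(config$seed, 10 + ci), sample_class = cl)
      write_correlation_tsv(cm, cor_f)
    } else {
      message(sprintf("correlation[%s]: reusing cached artifact", cl))
      cm <- structure(list(values = read_matrix_tsv(cor_f),
                           n_reps = config$n_reps,
                           fraction = config$fraction,
                           seed = stage_seed(config$seed, 10 + ci),
                           sample_class = cl),
                      class = "CorrelationMatrix")
    }
    cvals <- cm$values
    if (anyNA(cvals)) {
      message(sprintf(
        "correlation[%s]: %d pair(s) undefined in every replicate, treated as 0",
        cl, sum(is.na(cvals))))
      cvals[is.na(cvals)] <- 0
    }

    ## --- SVD profile (whitelist-restricted, as in the study design) ----
    svd_f <- pj("svd", sprintf("%s_svd.json", cl))
    wl_cols <- intersect(colnames(cvals), whitelist)
    zsub <- fisher_z(cvals[, wl_cols, drop = FALSE],
                     clip_epsilon = config$clip_epsilon)
    prof <- svd_characterize(
      zsub, n_components = min(config$n_components, min(dim(zsub$values))))
    write_svd_json(prof, svd_f)

    ## --- network: discretize + condense --------------------------------
    net_f <- pj("network", sprintf("%s_condensed.tsv", cl))
    net <- discretize(cvals, quantile = config$quantile)
    cnet <- condense(net, whitelist, min_nonzero = config$min_nonzero)
    write_matrix_tsv(cnet$values, net_f)

    ## --- modules --------------------------------------------------------
    edges_f <- pj("modules", sprintf("%s_edges.tsv", cl))
    summary_f <- pj("modules", sprintf("%s_summary.tsv", cl))
    k_use <- min(config$k_mirna, ncol(cnet$values))
    clu <- cluster_bipartite(cnet, k_mirna = k_use)
    mps <- extract_module_pairs(cnet, clu$mirna_clusters,
                                mode = config$extraction_mode)
    edges <- module_edges(mps, cnet)
    utils::write.table(edges, edges_f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(module_summary(mps, prefix = paste0(cl, "-")),
                       summary_f, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    ## --- target-site enrichment ----------------------------------------
    enr <- NULL
    if (!is.null(config$utr_fasta) && !is.null(config$mature_fasta)) {
      mature <- read_mature_fasta(config$mature_fasta)
      motif_sets <- lapply(names(mature), function(id)
        seed_motifs(mature[[id]], id))
      names(motif_sets) <- names(mature)
      A <- scan_utr(config$utr_fasta, motif_sets)
      enr_rows <- list()
      for (mp in mps) {
        genes_ne <- intersect(mp$neg$genes, rownames(A))
        mir_ne <- intersect(mp$neg$mirnas, colnames(A))
        if (length(genes_ne) < 1 || length(mir_ne) < 1) next
        r <- module_target_enrichment(A, genes_ne, mir_ne)
        r <- cbind(module = paste0(cl, "-", mp$id, "-ne"), r)
        enr_rows[[length(enr_rows) + 1]] <- r
      }
      if (length(enr_rows)) {
        enr <- do.call(rbind, enr_rows)
        utils::write.table(
          enr, pj("enrichment", sprintf("%s_target_enrichment.tsv", cl)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    ## --- gene-set over-representation ----------------------------------
    terms_res <- NULL
    if (!is.null(config$gmt)) {
      terms <- read_gmt(config$gmt, universe = entity_ids(gene))
      term_rows <- list()
      for (mp in mps) {
        for (s in c("ps", "ne")) {
          gl <- intersect(if (s == "ps") mp$pos$genes else mp$neg$genes,
                          terms$universe)
          if (length(gl) < 2) next
          r <- overrepresentation(gl, terms)
          term_rows[[length(term_rows) + 1]] <-
            cbind(module = paste0(cl, "-", mp$id, "-", s), r)
        }
      }
      if (length(term_rows)) {
        terms_res <- do.call(rbind, term_rows)
        utils::write.table(
          terms_res,
          pj("enrichment", sprintf("%s_term_enrichment.tsv", cl)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    results[[cl]] <- list(correlation = cm, svd = prof, network = net,
                          condensed = cnet, clusters = clu,
                          module_pairs = mps, edges = edges,
                          target_enrichment = enr,
                          term_enrichment = terms_res)
  }

  ## --- sample-partition association ------------------------------------
  if (!is.null(config$driver_genes)) {
    drivers <- intersect(readLines(config$driver_genes), entity_ids(gene))
    cl1 <- config$classes[1]
    mps1 <- results[[cl1]]$module_pairs
    neg_sizes <- vapply(mps1, function(mp) length(mp$neg$genes), integer(1))
    mir_feats <- if (length(mps1))
      intersect(mps1[[which.max(neg_sizes)]]$neg$mirnas, entity_ids(mirna))
    else character(0)
    cl_samples <- intersect(names(labels)[labels == cl1], sample_ids(gene))
    if (length(mir_feats) >= 2 && length(drivers) >= 2 &&
        length(cl_samples) >= config$k_sample_clusters) {
      sub_m <- expression_matrix(
        mirna$values[, cl_samples, drop = FALSE], "log2")
      sub_g <- expression_matrix(
        gene$values[, cl_samples, drop = FALSE], "log2")
      pa <- partition_association(
        cluster_samples(sub_m, mir_feats, config$k_sample_clusters),
        cluster_samples(sub_g, drivers, config$k_sample_clusters))
      jsonlite::write_json(
        list(statistic = pa$statistic, df = pa$df, p_value = pa$p_value,
             low_expected = pa$low_expected),
        pj("enrichment", "partition_association.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      results$partition_association <- pa
    }
  }

  ## --- manifest ---------------------------------------------------------
  manifest_f <- pj("manifest.json")
  out_files <- sort(setdiff(
    list.files(outdir, recursive = TRUE), "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(outdir, out_files)))
  names(hashes) <- out_files
  in_paths <- Filter(Negate(is.null),
                     config[c("gene_tsv", "mirna_tsv", "labels_tsv",
                              "whitelist", "utr_fasta", "mature_fasta",
                              "gmt", "driver_genes")])
  in_hashes <- lapply(in_paths, function(p) unname(tools::md5sum(p)))
  params <- config[c("classes", "n_reps", "fraction", "quantile",
                     "k_mirna", "min_nonzero", "fold", "presence",
                     "clip_epsilon", "n_components", "k_sample_clusters",
                     "extraction_mode", "seed")]
  jsonlite::write_json(
    list(package = "mirModNet",
         version = as.character(utils::packageVersion("mirModNet")),
         parameters = params, inputs = in_hashes, outputs = hashes),
    manifest_f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest_f
  invisible(results)
}

#' Write a complete synthetic study to disk
#'
#' Generates a synthetic dataset from a [synthetic_config()] and writes
#' every file input the pipeline needs: expression TSVs, labels, a miRNA
#' whitelist (the planted modular miRNAs plus a sample of background
#' miRNAs, mirroring a literature cancer-miRNA list that is wider than
#' the modules it contains), 3'UTR and mature-sequence FASTA with planted
#' seed-match motifs for the negative-module gene sets, a GMT with one
#' term planted on the largest negative module, a driver-gene list, and
#' the ground truth as JSON.
#'
#' @param config A `SyntheticConfig`.
#' @param dir Target directory.
#' @param whitelist_extra Number of non-modular miRNAs added to the
#'   whitelist (default: half the modular count, capped by availability).
#' @return Invisibly, a list with the file `paths`, the generated `data`
#'   and the `truth` (with `plant` and `positions` added).
#' @export
simulate_study <- function(config, dir, whitelist_extra = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data <- generate_expression(config)
  truth <- data$truth
  modular <- names(truth$mirna_module)[truth$mirna_module > 0]
  background <- names(truth$mirna_module)[truth$mirna_module == 0]
  if (is.null(whitelist_extra))
    whitelist_extra <- min(length(background), ceiling(length(modular) / 2))
  whitelist <- withr::with_seed(stage_seed(config$seed, 91), {
    c(modular, sample(background, whitelist_extra))
  })

  mature <- random_mature_sequences(names(truth$mirna_module),
                                    seed = stage_seed(config$seed, 92))
  motif_sets <- lapply(names(mature), function(id)
    seed_motifs(mature[[id]], id))
  names(motif_sets) <- names(mature)

  # plant matrix: negative-module genes carry the target sites of their
  # modular miRNAs; constrained columns = the modular miRNAs
  genes <- names(truth$gene_module)
  plant <- matrix(0L, length(genes), length(modular),
                  dimnames = list(genes, modular))
  for (g in genes) {
    m <- truth$gene_module[[g]]
    if (m > 0 && truth$gene_sign[[g]] == -1L) {
      mm <- modular[truth$mirna_module[modular] == m]
      plant[g, mm] <- 1L
    }
  }
  utr <- generate_utr_fasta(plant, motif_sets[modular], config$utr_length,
                            seed = stage_seed(config$seed, 93))

  # planted annotation term: the largest negative-module gene set
  neg_sizes <- vapply(seq_along(config$module_specs), function(m)
    sum(truth$gene_module == m & truth$gene_sign == -1L), integer(1))
  m_big <- which.max(neg_sizes)
  planted_genes <- genes[truth$gene_module == m_big &
                           truth$gene_sign == -1L]
  terms <- generate_term_table(genes, n_terms = 50,
                               planted_term = list(id = "T_planted",
                                                   genes = planted_genes),
                               seed = stage_seed(config$seed, 94))

  # driver stand-ins: positive genes of the same module (shared factor)
  drivers <- utils::head(genes[truth$gene_module == m_big &
                                 truth$gene_sign == 1L], 34)

  paths <- list(
    gene_tsv = file.path(dir, "gene_expression.tsv"),
    mirna_tsv = file.path(dir, "mirna_expression.tsv"),
    labels_tsv = file.path(dir, "labels.tsv"),
    whitelist = file.path(dir, "mirna_whitelist.txt"),
    utr_fasta = file.path(dir, "utr.fasta"),
    mature_fasta = file.path(dir, "mature_mirna.fasta"),
    gmt = file.path(dir, "terms.gmt"),
    driver_genes = file.path(dir, "driver_genes.txt"),
    truth_json = file.path(dir, "truth.json"))
  write_expression_tsv(data$gene, paths$gene_tsv)
  write_expression_tsv(data$mirna, paths$mirna_tsv)
  write_labels_tsv(data$labels, paths$labels_tsv)
  writeLines(whitelist, paths$whitelist)
  write_fasta(utr$sequences, paths$utr_fasta, "DNA")
  write_fasta(mature, paths$mature_fasta, "RNA")
  write_gmt(terms, paths$gmt)
  writeLines(drivers, paths$driver_genes)
  jsonlite::write_json(
    list(mirna_module = as.list(truth$mirna_module),
         gene_module = as.list(truth$gene_module),
         gene_sign = as.list(truth$gene_sign),
         near_constant = truth$near_constant,
         whitelist = whitelist,
         planted_term_genes = planted_genes),
    paths$truth_json, auto_unbox = TRUE, digits = NA)

  truth$plant <- plant
  truth$positions <- utr$positions
  invisible(list(paths = paths, data = data, truth = truth,
                 whitelist = whitelist, motif_sets = motif_sets,
                 terms = terms))
}
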