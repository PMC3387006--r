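test_that("configuration invariants are enforced", {
  expect_error(module_spec(0, 5, 5), "positive")
  expect_error(module_spec(2, 5, 5, loading_strength = -1), "positive")
  expect_error(synthetic_config(n_mirnas = 3,
                                module_specs = list(module_spec(4, 5, 5))),
               "miRNA counts")
  expect_error(synthetic_config(n_genes = 10, n_mirnas = 10,
                                module_specs = list(module_spec(2, 50, 50))),
               "gene counts")
  expect_error(synthetic_config(missing_rate = 1), "missing_rate")
  cfg <- synthetic_config()
  # defaults mirror the cohort structure the pipeline targets
  expect_identical(cfg$n_samples_per_class,
                   c(PPC = 98, MPC = 13, normal = 28))
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- recovery_config(noise_sd = 1, seed = 120)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$gene$values, b$gene$values)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$labels, b$labels)
  cfg2 <- recovery_config(noise_sd = 1, seed = 121)
  expect_false(identical(generate_expression(cfg2)$gene$values,
                         a$gene$values))
})

test_that("zero noise gives exact unit within-module correlations", {
  cfg <- recovery_config(noise_sd = 0, n_per_class = c(PPC = 20), seed = 122,
                         n_modules = 1, mirnas_per = 2, genes_per = 3)
  d <- generate_expression(cfg)
  r <- stats::cor(t(d$gene$values), t(d$mirna$values))
  pos <- names(d$truth$gene_sign)[d$truth$gene_sign == 1L]
  neg <- names(d$truth$gene_sign)[d$truth$gene_sign == -1L]
  mod_mir <- names(d$truth$mirna_module)[d$truth$mirna_module == 1L]
  expect_equal(unname(r[pos, mod_mir]), matrix(1, 3, 2), tolerance = 1e-12)
  expect_equal(unname(r[neg, mod_mir]), matrix(-1, 3, 2), tolerance = 1e-12)
})

test_that("without planted modules all pairwise correlations stay small", {
  cfg <- synthetic_config(n_samples_per_class = c(PPC = 100),
                          n_genes = 50, n_mirnas = 10,
                          module_specs = list(), missing_rate = 0,
                          near_constant_fraction = 0, seed = 123)
  d <- generate_expression(cfg)
  r <- stats::cor(t(d$gene$values), t(d$mirna$values))
  expect_lt(max(abs(r)), 0.5)
})

test_that("planted |r| matches the shared-factor closed form lambda^2/(lambda^2+sigma^2)", {
  # lambda = 1, sigma = 1 -> population |r| = 1/2. 100 modules of one
  # miRNA plus one positive and one negative gene give 200 planted pairs
  # driven by 100 independent latent factors, so the mean of |r-hat| at
  # n = 100 concentrates tightly around 1/2.
  cfg <- synthetic_config(n_samples_per_class = c(PPC = 100),
                          n_genes = 200, n_mirnas = 100,
                          module_specs = replicate(100,
                            module_spec(1, 1, 1, loading_strength = 1),
                            simplify = FALSE),
                          noise_sd = 1, missing_rate = 0,
                          near_constant_fraction = 0, seed = 124)
  d <- generate_expression(cfg)
  r <- stats::cor(t(d$gene$values), t(d$mirna$values))
  mir_of_mod <- stats::setNames(names(d$truth$mirna_module),
                                d$truth$mirna_module)
  planted <- vapply(names(d$truth$gene_module), function(g)
    r[g, mir_of_mod[[as.character(d$truth$gene_module[[g]])]]],
    numeric(1))
  expect_identical(length(planted), 200L)
  expect_lt(abs(mean(abs(planted)) - 0.5), 0.05)
})

test_that("realized missingness tracks missing_rate within 2%", {
  cfg <- synthetic_config(n_samples_per_class = c(PPC = 100),
                          n_genes = 10, n_mirnas = 100,
                          module_specs = list(), missing_rate = 0.1,
                          near_constant_fraction = 0, seed = 125)
  d <- generate_expression(cfg)
  expect_identical(length(d$mirna$values), 10000L)
  expect_lt(abs(mean(is.na(d$mirna$values)) - 0.1), 0.02)
})

test_that("near-constant genes fail the variability filter, modular genes pass", {
  cfg <- synthetic_config(n_samples_per_class = c(PPC = 60),
                          n_genes = 60, n_mirnas = 6,
                          module_specs = list(module_spec(3, 10, 10)),
                          noise_sd = 1, missing_rate = 0,
                          near_constant_fraction = 0.3, seed = 126)
  d <- generate_expression(cfg)
  expect_identical(length(d$truth$near_constant), 18L)
  kept <- entity_ids(suppressMessages(filter_variability(d$gene)))
  expect_false(any(d$truth$near_constant %in% kept))
  modular <- names(d$truth$gene_module)[d$truth$gene_module > 0]
  expect_true(all(modular %in% kept))
})

test_that("class-restricted modules correlate only within their classes", {
  cfg <- synthetic_config(
    n_samples_per_class = c(PPC = 60, MPC = 60),
    n_genes = 20, n_mirnas = 4,
    module_specs = list(module_spec(2, 5, 5, classes = "PPC"),
                        module_spec(2, 5, 5, classes = "MPC")),
    noise_sd = 1, missing_rate = 0, near_constant_fraction = 0,
    seed = 127)
  d <- generate_expression(cfg)
  ppc <- names(d$labels)[d$labels == "PPC"]
  mpc <- names(d$labels)[d$labels == "MPC"]
  g1 <- names(d$truth$gene_module)[d$truth$gene_module == 1 &
                                     d$truth$gene_sign == 1][1]
  m1 <- names(d$truth$mirna_module)[d$truth$mirna_module == 1][1]
  r_in <- stats::cor(d$gene$values[g1, ppc], d$mirna$values[m1, ppc])
  r_out <- stats::cor(d$gene$values[g1, mpc], d$mirna$values[m1, mpc])
  expect_gt(r_in, 0.7)
  expect_lt(abs(r_out), 0.5)
})

test_that("background motif counts match the uniform-sequence expectation", {
  # expected count of a fixed 7-mer in an unconstrained uniform sequence
  # of length L is (L - 6) * 4^-7
  empty_plant <- matrix(0L, 1000, 0,
                        dimnames = list(sprintf("g%04d", 1:1000), NULL))
  utr <- generate_utr_fasta(empty_plant, list(), utr_length = 2000,
                            seed = 128)
  motif <- "ACGTACG"
  counts <- Biostrings::vcountPattern(
    motif, Biostrings::DNAStringSet(utr$sequences))
  expected <- (2000 - 6) / 4^7
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("simulate_study writes a complete, deterministic file bundle", {
  cfg <- synthetic_config(n_samples_per_class = c(PPC = 12, MPC = 8),
                          n_genes = 40, n_mirnas = 8,
                          module_specs = list(module_spec(2, 5, 5)),
                          utr_length = 300, seed = 129)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  st1 <- suppressMessages(simulate_study(cfg, d1))
  st2 <- suppressMessages(simulate_study(cfg, d2))
  for (p in names(st1$paths)) {
    expect_true(file.exists(st1$paths[[p]]))
    expect_identical(readLines(st1$paths[[p]]), readLines(st2$paths[[p]]))
  }
  # the planted affinity truth is recoverable from the written FASTA
  mature <- read_mature_fasta(st1$paths$mature_fasta)
  sets <- lapply(names(mature), function(id) seed_motifs(mature[[id]], id))
  names(sets) <- names(mature)
  modular <- colnames(st1$truth$plant)
  A <- scan_utr(st1$paths$utr_fasta, sets[modular])
  expect_identical(unclass(A)[, ], st1$truth$plant[, ])
})
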