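test_that("discretize marks floor(quantile * M) entries of each sign", {
  x <- rand_named_matrix(10, 10, seed = 61)
  net <- discretize(x, quantile = 0.01)     # k = floor(1) = 1
  expect_identical(sum(net$values == 1L), 1L)
  expect_identical(sum(net$values == -1L), 1L)
  expect_equal(x[which(net$values == 1L)], max(x))
  expect_equal(x[which(net$values == -1L)], min(x))
})

test_that("discretize agrees with a full-sort oracle and records thresholds", {
  for (s in 1:5) {
    x <- rand_named_matrix(100, 40, seed = 600 + s)
    net <- discretize(x, quantile = 0.01)
    k <- floor(0.01 * length(x))
    oracle <- oracle_signed_topk(x, k)
    expect_identical(sort(which(net$values == 1L)), oracle$pos)
    expect_identical(sort(which(net$values == -1L)), oracle$neg)
    expect_true(all(x[net$values == 1L] >= net$pos_threshold))
    expect_true(all(x[net$values == -1L] <= net$neg_threshold))
    expect_true(all(x[net$values == 0L] < net$pos_threshold &
                      x[net$values == 0L] > net$neg_threshold))
  }
})

test_that("discretize breaks total ties deterministically, conserving counts", {
  x <- matrix(0.3, 8, 5, dimnames = list(sprintf("g%d", 1:8),
                                         sprintf("m%d", 1:5)))
  n1 <- discretize(x, quantile = 0.1)   # k = 4
  n2 <- discretize(x, quantile = 0.1)
  expect_identical(n1$values, n2$values)
  expect_identical(sum(n1$values == 1L), 4L)
  expect_identical(sum(n1$values == -1L), 4L)
  expect_error(discretize(rand_named_matrix(5, 5, seed = 62),
                          quantile = 0.01), "too small")
})

test_that("condense restricts columns then drops weakly-connected rows", {
  v <- matrix(0L, 4, 4, dimnames = list(paste0("g", 1:4), paste0("m", 1:4)))
  v["g1", c("m1", "m2")] <- c(1L, -1L)  # two connections, mixed sign
  v["g2", "m1"] <- 1L                   # single connection
  v["g3", c("m3", "m4")] <- 1L          # connections outside whitelist
  net <- structure(list(values = v, pos_threshold = 0.5,
                        neg_threshold = -0.5, quantile = 0.01),
                   class = "SignedNetwork")
  out <- suppressMessages(condense(net, c("m1", "m2")))
  expect_identical(rownames(out$values), "g1")   # mixed signs count
  expect_identical(colnames(out$values), c("m1", "m2"))
  expect_error(condense(net, "nope"), "intersect")
  expect_error(condense(net, character(0)), "empty")
})

test_that("condense equals a naive per-row non-zero count on a random fixture", {
  v <- matrix(sample(c(-1L, 0L, 0L, 0L, 1L), 200, replace = TRUE), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("m%02d", 1:10)))
  net <- structure(list(values = v, pos_threshold = 1, neg_threshold = -1,
                        quantile = 0.01), class = "SignedNetwork")
  wl <- sprintf("m%02d", c(1, 3, 5, 7, 9))
  out <- suppressMessages(condense(net, wl, min_nonzero = 2))
  naive <- rownames(v)[vapply(rownames(v), function(g)
    sum(v[g, wl] != 0L) >= 2, logical(1))]
  expect_identical(rownames(out$values), naive)
})

test_that("cluster_bipartite recovers duplicate-column groups and planted blocks", {
  a <- c(1L, 1L, 0L, -1L, 0L); b <- c(0L, -1L, 1L, 1L, 1L)
  v <- cbind(m1 = a, m2 = a, m3 = b, m4 = b)
  rownames(v) <- paste0("g", 1:5)
  net <- structure(list(values = v, pos_threshold = 1, neg_threshold = -1,
                        quantile = 0.1), class = "SignedNetwork")
  cl <- cluster_bipartite(net, k_mirna = 2)
  expect_identical(cl$mirna_clusters[["m1"]], cl$mirna_clusters[["m2"]])
  expect_identical(cl$mirna_clusters[["m3"]], cl$mirna_clusters[["m4"]])
  expect_false(cl$mirna_clusters[["m1"]] == cl$mirna_clusters[["m3"]])
  # maximal cut: singletons
  cl4 <- cluster_bipartite(net, k_mirna = 4)
  expect_identical(length(unique(cl4$mirna_clusters)), 4L)
  expect_error(cluster_bipartite(net, k_mirna = 5), "k_mirna")
})

test_that("planted three-block networks are clustered with ARI = 1", {
  truth <- rep(1:3, each = 4)
  v <- withr::with_seed(63, {
    blocks <- matrix(0L, 60, 12)
    for (j in 1:12) {
      rows <- ((truth[j] - 1) * 20 + 1):(truth[j] * 20)
      blocks[rows, j] <- sample(c(1L, -1L), 20, replace = TRUE)
    }
    blocks
  })
  dimnames(v) <- list(sprintf("g%02d", 1:60), sprintf("m%02d", 1:12))
  net <- structure(list(values = v, pos_threshold = 1, neg_threshold = -1,
                        quantile = 0.1), class = "SignedNetwork")
  cl <- cluster_bipartite(net, k_mirna = 3)
  expect_equal(ari(cl$mirna_clusters, truth), 1)
})

test_that("extract_module_pairs drops single-connection genes", {
  v <- matrix(0L, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("m1", "m2")))
  v["g1", ] <- 1L              # connected to both
  v["g2", "m1"] <- 1L          # only one positive connection
  v["g3", ] <- c(-1L, -1L)
  net <- structure(list(values = v, pos_threshold = 1, neg_threshold = -1,
                        quantile = 0.1), class = "SignedNetwork")
  clusters <- c(m1 = 1L, m2 = 1L)
  # the single gene-drop pass keeps g1 and discards g2
  mps <- extract_module_pairs(net, clusters, mode = "single_pass")
  expect_identical(mps[[1]]$pos$genes, "g1")
  expect_identical(mps[[1]]$neg$genes, "g3")
  # the fixed point additionally empties these modules: with one gene
  # left, each miRNA has a single within-module connection
  fp <- suppressMessages(extract_module_pairs(net, clusters))
  expect_length(fp[[1]]$pos$genes, 0)
  expect_length(fp[[1]]$neg$genes, 0)
  # a cluster with no connections yields empty modules
  v0 <- matrix(0L, 3, 2, dimnames = dimnames(v))
  net0 <- structure(list(values = v0, pos_threshold = 1,
                         neg_threshold = -1, quantile = 0.1),
                    class = "SignedNetwork")
  mps0 <- suppressMessages(extract_module_pairs(net0, clusters))
  expect_length(mps0[[1]]$pos$genes, 0)
  expect_length(mps0[[1]]$neg$genes, 0)
})

test_that("fixed-point extraction matches the pruning oracle on random networks", {
  for (s in 1:20) {
    v <- withr::with_seed(700 + s, {
      matrix(sample(c(-1L, 0L, 1L), 180, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25)), 30, 6)
    })
    dimnames(v) <- list(sprintf("g%02d", 1:30), sprintf("m%d", 1:6))
    net <- structure(list(values = v, pos_threshold = 1,
                          neg_threshold = -1, quantile = 0.1),
                     class = "SignedNetwork")
    clusters <- stats::setNames(rep(1:2, each = 3), colnames(v))
    mps <- suppressMessages(extract_module_pairs(net, clusters))
    for (mp in mps) {
      mir <- names(clusters)[clusters == mp$cluster]
      for (s2 in c(1L, -1L)) {
        mod <- if (s2 == 1L) mp$pos else mp$neg
        ref <- oracle_prune((v[, mir, drop = FALSE] == s2) * 1L)
        expect_setequal(mod$genes, ref$genes)
        expect_setequal(mod$mirnas, ref$mirnas)
        # every member keeps >= 2 within-module connections
        if (length(mod$genes) > 0) {
          sub <- v[mod$genes, mod$mirnas, drop = FALSE] == s2
          expect_true(all(rowSums(sub) >= 2))
          expect_true(all(colSums(sub) >= 2))
        }
      }
    }
  }
})

test_that("single-pass mode keeps all cluster miRNAs and weaker genes", {
  # g1-g2 connect to m1 twice; m2 has a single connection (via g1)
  v <- matrix(0L, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("m1", "m2")))
  v["g1", ] <- 1L
  v["g2", "m1"] <- 1L
  v["g3", "m1"] <- 1L
  net <- structure(list(values = v, pos_threshold = 1, neg_threshold = -1,
                        quantile = 0.1), class = "SignedNetwork")
  clusters <- c(m1 = 1L, m2 = 1L)
  single <- suppressMessages(
    extract_module_pairs(net, clusters, mode = "single_pass"))
  fixed <- suppressMessages(extract_module_pairs(net, clusters))
  expect_setequal(single[[1]]$pos$mirnas, c("m1", "m2"))
  expect_identical(single[[1]]$pos$genes, "g1")
  # the fixed point then removes m2 (one connection) and with it g1's
  # second connection, leaving nothing with >= 2 connections
  expect_length(fixed[[1]]$pos$genes, 0)
})

test_that("raising min_nonzero never adds genes to any module", {
  v <- withr::with_seed(64, {
    matrix(sample(c(-1L, 0L, 1L), 300, replace = TRUE,
                  prob = c(0.2, 0.5, 0.3)), 50, 6)
  })
  dimnames(v) <- list(sprintf("g%02d", 1:50), sprintf("m%d", 1:6))
  net <- structure(list(values = v, pos_threshold = 1, neg_threshold = -1,
                        quantile = 0.1), class = "SignedNetwork")
  genes_at <- lapply(c(2, 3, 4), function(mn) {
    cn <- suppressMessages(condense(net, colnames(v), min_nonzero = mn))
    rownames(cn$values)
  })
  expect_true(all(genes_at[[2]] %in% genes_at[[1]]))
  expect_true(all(genes_at[[3]] %in% genes_at[[2]]))
})

test_that("module_edges and module_summary are consistent with the pairs", {
  v <- matrix(0L, 4, 3, dimnames = list(paste0("g", 1:4), paste0("m", 1:3)))
  v[c("g1", "g2"), c("m1", "m2")] <- 1L
  v[c("g3", "g4"), c("m1", "m2")] <- -1L
  net <- structure(list(values = v, pos_threshold = 1, neg_threshold = -1,
                        quantile = 0.1), class = "SignedNetwork")
  clusters <- c(m1 = 1L, m2 = 1L, m3 = 2L)
  mps <- suppressMessages(extract_module_pairs(net, clusters))
  edges <- module_edges(mps, net)
  expect_identical(nrow(edges), 8L)
  expect_setequal(unique(edges$module), c("modu-1-ps", "modu-1-ne"))
  summ <- module_summary(mps)
  expect_identical(summ$gene_number[summ$module == "modu-1-ps"], 2L)
  expect_identical(summ$gene_number[summ$module == "modu-1-ne"], 2L)
})
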