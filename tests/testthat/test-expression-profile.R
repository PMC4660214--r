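test_that("gene filter equals the brute-force predicate on a planted matrix", {
  set.seed(81)
  n <- 1000
  mat <- matrix(rexp(n * 8, rate = 0.4), n, 8,
                dimnames = list(sprintf("G%04d", 1:n), paste0("S", 1:8)))
  # plant clear pass/fail genes
  mat[1, ] <- c(10, 30, 5, 40, 12, 3, 25, 8)       # high mean, high CV: pass
  mat[2, ] <- rep(100, 8)                          # CV 0: fail
  mat[3, ] <- rep(c(0.1, 0.4), 4)                  # mean below 1.5: fail
  kept <- filter_genes(mat)
  manual <- rownames(mat)[sapply(seq_len(n), function(i) {
    mu <- mean(mat[i, ]); s <- sd(mat[i, ])
    mu > 1.5 && s / mu > 0.3
  })]
  expect_equal(rownames(kept), manual)
  expect_true("G0001" %in% rownames(kept))
  expect_false(any(c("G0002", "G0003") %in% rownames(kept)))
  # idempotence
  expect_identical(filter_genes(kept), kept)
})

test_that("filter boundaries are strict and ribosomal genes droppable", {
  mat <- rbind(
    exact_mean = c(1.0, 2.0, 1.0, 2.0),  # mean exactly 1.5: strict > rejects
    low_cv = c(9, 10, 11, 10),           # high mean, CV ~0.08: rejected
    RPL1 = c(10, 30, 5, 40),
    RPS9 = c(10, 30, 5, 40),
    KEEP = c(10, 30, 5, 40))
  expect_false("exact_mean" %in% rownames(filter_genes(mat)))
  expect_false("low_cv" %in% rownames(filter_genes(mat)))
  out <- filter_genes(mat, drop_ribosomal = TRUE)
  expect_equal(rownames(out), "KEEP")
  out2 <- filter_genes(mat, drop_ribosomal = FALSE)
  expect_true(all(c("RPL1", "RPS9", "KEEP") %in% rownames(out2)))
  expect_error(filter_genes(mat[, 1, drop = FALSE]), "2 samples")
})

test_that("Spearman distance is a proper profile dissimilarity", {
  set.seed(82)
  mat <- matrix(rexp(50 * 6), 50, 6, dimnames = list(NULL, paste0("S", 1:6)))
  mat[, 2] <- mat[, 1]  # identical samples
  d <- spearman_distance(mat)
  expect_equal(d[1, 2], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
  matz <- mat; matz[, 3] <- 5
  expect_error(spearman_distance(matz), "S3")
})

test_that("three-sample UPGMA matches the hand computation", {
  # X = (1,2,3,4), Y = (1,2,4,3), Z = (4,3,2,1)
  # rho(X,Y) = 1 - 6*2/60 = 0.8    -> d = 0.2
  # rho(X,Z) = -1 -> d = 2; rho(Y,Z) = 1 - 6*18/60 = -0.8 -> d = 1.8
  # UPGMA: merge {X,Y} at 0.2, then with Z at (2 + 1.8)/2 = 1.9
  mat <- cbind(X = c(1, 2, 3, 4), Y = c(1, 2, 4, 3), Z = c(4, 3, 2, 1))
  hc <- cluster_samples(mat)
  expect_equal(hc$linkage$a[1], "X")
  expect_equal(hc$linkage$b[1], "Y")
  expect_equal(hc$linkage$height, c(0.2, 1.9), tolerance = 1e-12)
  expect_equal(hc$linkage$size, c(2L, 3L))
  expect_equal(sort(stats::cutree(hc, 2)[c("X", "Y")]), c(X = 1L, Y = 1L))
})

test_that("UPGMA agrees with hclust average linkage on random matrices", {
  set.seed(83)
  for (i in 1:5) {
    mat <- matrix(rexp(80 * 7), 80, 7, dimnames = list(NULL, paste0("S", 1:7)))
    d <- spearman_distance(mat)
    ours <- cluster_samples(mat)
    ref <- stats::hclust(as.dist(d), method = "average")
    expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-12)
    expect_equal(stats::cophenetic(ours), stats::cophenetic(ref),
                 tolerance = 1e-12)
  }
})

test_that("planted two-group structure is recovered across seeded runs", {
  hits <- 0L
  for (s in 1:100) {
    sim <- simulate_fpkm_matrix(seed = s, n_genes = 60, n_per_group = 4,
                                n_de = 20, effect = 3, noise_sd = 0.5)
    hc <- cluster_samples(sim$mat)
    grp <- stats::cutree(hc, 2)
    if (length(unique(grp[sim$labels == "A"])) == 1 &&
        length(unique(grp[sim$labels == "B"])) == 1 &&
        grp[1] != grp[8]) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("dendrograms export as Newick", {
  sim <- simulate_fpkm_matrix(seed = 5, n_genes = 60, n_per_group = 3)
  hc <- cluster_samples(sim$mat)
  nwk <- as_newick(hc)
  expect_true(grepl("^\\(.*\\);$", nwk))
  expect_true(all(vapply(colnames(sim$mat), grepl, TRUE, x = nwk,
                         fixed = TRUE)))
  tf <- file.path(tempdir(), "tree.nwk")
  as_newick(hc, tf)
  expect_identical(readLines(tf), nwk)
})

test_that("signal-to-noise scores rank planted genes with the documented floor", {
  sim <- simulate_fpkm_matrix(seed = 6, n_genes = 100, n_per_group = 4,
                              n_de = 1, effect = 6, noise_sd = 0.2)
  rk <- signal_to_noise_rank(sim$mat, sim$labels, phenotype = "A")
  expect_equal(rk$gene[1], sim$de_genes)
  # identical expression across phenotypes scores zero
  mat0 <- rbind(flat = rep(3, 8))
  rk0 <- signal_to_noise_rank(mat0, rep(c("A", "B"), each = 4))
  expect_equal(rk0$score, 0)
  # sd floor: constant classes score (mA - mB) / (0.2 * (|mA| + |mB|))
  matc <- rbind(g = c(10, 10, 10, 5, 5, 5))
  rkc <- signal_to_noise_rank(matc, rep(c("A", "B"), each = 3))
  expect_equal(rkc$score, 5 / (0.2 * 15), tolerance = 1e-12)
  # antisymmetry under label swap
  rk_swap <- signal_to_noise_rank(sim$mat, sim$labels, phenotype = "B")
  both <- merge(rk, rk_swap, by = "gene")
  expect_equal(both$score.x, -both$score.y, tolerance = 1e-12)
  expect_error(signal_to_noise_rank(sim$mat, c("A", rep("B", 7))),
               "at least 2")
})

test_that("ranking is invariant to common affine rescaling of a gene", {
  sim <- simulate_fpkm_matrix(seed = 8, n_genes = 30, n_per_group = 4)
  rk1 <- signal_to_noise_rank(sim$mat, sim$labels)
  mat2 <- sim$mat * 2          # common positive scaling of every gene
  rk2 <- signal_to_noise_rank(mat2, sim$labels)
  expect_equal(rk2$score, rk1$score, tolerance = 1e-12)
  expect_equal(rk2$gene, rk1$gene)
})

test_that("expression matrices round-trip as TSV", {
  sim <- simulate_fpkm_matrix(seed = 9, n_genes = 20, n_per_group = 3)
  tf <- file.path(tempdir(), "expr.tsv")
  write_expression_tsv(sim$mat, tf)
  back <- read_expression_tsv(tf)
  expect_equal(back, sim$mat, tolerance = 1e-9)
})
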