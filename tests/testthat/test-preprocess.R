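make_meta_cm <- function(nucleosome = 0.5, tss = 3, mito = 0.01, n = 6) {
  m <- matrix(rpois(20 * n, 5) + 1L, 20, n,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:n)))
  meta <- data.frame(cell_id = colnames(m), sample = "s", timepoint = "t",
                     condition = "control",
                     pct_mito = rep_len(mito, n),
                     tss_enrichment = rep_len(tss, n),
                     nucleosome_signal = rep_len(nucleosome, n),
                     total_atac = 1000L)
  cell_matrix(m, meta = meta)
}

test_that("qc_filter applies the chromatin thresholds and is idempotent", {
  cm <- make_meta_cm(nucleosome = c(0.5, 2.5, 1.0, 0.9, 1.1, 0.4))
  out <- qc_filter(cm, qc_thresholds(min_total_counts = 0, min_total_atac = 0))
  expect_false("c02" %in% out$cm$cell_ids)  # nucleosome 2.5 > 2
  expect_equal(out$report$n_removed, 1L)
  again <- qc_filter(out$cm, qc_thresholds(min_total_counts = 0,
                                           min_total_atac = 0))
  expect_identical(again$cm$cell_ids, out$cm$cell_ids)
  expect_equal(again$report$n_removed, 0L)

  # thresholds at their 0/Inf-equivalents act as the identity filter
  all_pass <- qc_filter(cm, qc_thresholds(min_total_counts = 0,
                                          min_total_atac = 0,
                                          max_pct_mito = 1,
                                          max_nucleosome = Inf, min_tss = 0))
  expect_identical(all_pass$cm$cell_ids, cm$cell_ids)
  expect_error(qc_thresholds(max_nucleosome = NA), "NA")
})

test_that("qc_filter removes exactly the truth-recorded failing cells", {
  sim <- simulate_hindbrain(config_13hpf(), seed = 7)[["13hpf"]]
  out <- qc_filter(sim$rna)
  truth <- sim$truth$cells
  expect_setequal(out$report$removed_cells, truth$cell_id[truth$qc_fail])
  expect_gt(sum(truth$qc_fail_planted), 0)
  expect_error(
    qc_filter(sim$rna, qc_thresholds(min_total_counts = 10^9)),
    "every cell")
})

test_that("normalize_log matches its formula and a two-loop reference", {
  m <- matrix(c(1L, 3L, 0L, 2L, 0L, 2L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  nm <- normalize_log(cell_matrix(m))
  expect_equal(nm$values["a", "x"], log(1 + 1e4 * 1 / 4), tolerance = 1e-12)
  expect_equal(nm$values["c", "x"], 0)

  cm <- random_cell_matrix(40, 25, seed = 3)
  nm <- normalize_log(cm, scale_factor = 500)
  ref <- matrix(0, 40, 25)
  cnt <- as.matrix(cm$counts)
  for (j in 1:25) {
    tot <- sum(cnt[, j])
    for (i in 1:40) ref[i, j] <- log(1 + 500 * cnt[i, j] / tot)
  }
  expect_lt(max(abs(as.matrix(nm$values) - ref)), 1e-12)

  # duplicating a cell leaves its normalised column unchanged
  dup <- cbind(cnt, dup = cnt[, 1])
  colnames(dup)[26] <- "dup"
  nm2 <- normalize_log(cell_matrix(dup), scale_factor = 500)
  expect_identical(unname(as.matrix(nm2$values)[, "dup"]),
                   unname(as.matrix(nm$values)[, 1]))

  zero <- cbind(cnt, z = 0L)
  colnames(zero)[26] <- "zcell"
  expect_error(normalize_log(cell_matrix(zero)), "zcell")
})

test_that("pca_embed agrees with a dense eigendecomposition", {
  set.seed(5)
  cnt <- matrix(rpois(20 * 50, 4), 20, 50,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("c%02d", 1:50)))
  nm <- normalize_log(cell_matrix(cnt))
  emb <- pca_embed(nm, n_components = 5, n_hvg = 20, clip = 1e6)
  x <- as.matrix(nm$values)
  x <- (x - rowMeans(x)) / apply(x, 1, sd)
  eig <- eigen(cov(t(x)) * (49 / 49))
  ref <- t(x) %*% eig$vectors[, 1:5]
  for (j in 1:5) {
    agree <- max(abs(emb$coords[, j] - ref[, j]))
    flip <- max(abs(emb$coords[, j] + ref[, j]))
    expect_lt(min(agree, flip), 1e-8)
  }
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
})

test_that("pca_embed degenerate inputs behave as specified", {
  cnt <- matrix(2L, 5, 10, dimnames = list(paste0("g", 1:5),
                                           paste0("c", 1:10)))
  nm <- normalize_log(cell_matrix(cnt))
  expect_error(pca_embed(nm, n_components = 2), "constant")

  # variation along one gene only: PC1 carries essentially all variance
  set.seed(1)
  cnt[1, ] <- rpois(10, 50) + 1L
  nm <- normalize_log(cell_matrix(cnt))
  emb <- pca_embed(nm, n_components = 2, n_hvg = 5)
  expect_gt(emb$explained_variance[1] /
              sum(emb$explained_variance), 0.95)
})

test_that("lsi first component tracks depth, supporting drop_first", {
  sim <- simulate_hindbrain(config_13hpf(), seed = 11)[["13hpf"]]
  lsi_all <- lsi_embed(sim$atac, drop_first = FALSE)
  depth <- log1p(Matrix::colSums(sim$atac$counts))
  expect_gt(abs(cor(lsi_all$coords[, 1], depth)), 0.9)
  lsi <- lsi_embed(sim$atac)
  expect_lt(abs(cor(lsi$coords[, 1], depth)), 0.5)
  expect_equal(ncol(lsi$coords), 30)
})

test_that("lsi rejects degenerate accessibility matrices", {
  m <- matrix(1L, 40, 8)
  peaks <- data.frame(chrom = "c", start = 0:39 * 100L, end = 0:39 * 100L + 50L)
  mem <- matrix(1, 40, 1, dimnames = list(NULL, "M1"))
  pd <- peak_data(m, peaks, paste0("c", 1:8), mem)
  expect_error(lsi_embed(pd, n_components = 3), "identical")
  pd2 <- random_peak_data(10, 8)
  expect_error(lsi_embed(pd2, n_components = 30), "informative peaks")
})

test_that("knn graph matches a brute-force neighbour search", {
  set.seed(9)
  coords <- matrix(rnorm(200 * 5), 200, 5,
                   dimnames = list(sprintf("c%03d", 1:200), NULL))
  emb <- coords_embedding(coords)
  g <- bimodal_knn_graph(emb, k = 10, alpha = 1)
  expect_true(all(g$edges$weight > 0 & g$edges$weight <= 1))
  # brute force: squared distances via explicit loops over pairs
  d2 <- matrix(0, 200, 200)
  for (i in 1:200) for (j in 1:200) d2[i, j] <- sum((coords[i, ] - coords[j, ])^2)
  nn_ref <- t(vapply(1:200, function(i) {
    ord <- order(d2[i, ])
    ord[ord != i][1:10]
  }, integer(10)))
  nn_pkg <- hindseg:::knn_from_dist(
    hindseg:::zscale_dist(as.matrix(dist(coords))), 10)
  expect_identical(nn_pkg, nn_ref)
  expect_error(bimodal_knn_graph(emb, k = 200), "k = 200")
})

test_that("alpha = 1 reduces the bimodal graph to the RNA graph", {
  set.seed(2)
  emb_r <- coords_embedding(matrix(rnorm(50 * 4), 50, 4,
                                   dimnames = list(paste0("c", 1:50), NULL)))
  emb_a <- coords_embedding(matrix(rnorm(50 * 4), 50, 4,
                                   dimnames = list(paste0("c", 1:50), NULL)))
  g1 <- bimodal_knn_graph(emb_r, emb_a, k = 5, alpha = 1)
  g2 <- bimodal_knn_graph(emb_r, k = 5, alpha = 1)
  expect_identical(g1$edges, g2$edges)
})

test_that("graph clustering recovers planted blobs deterministically", {
  set.seed(4)
  coords <- rbind(matrix(rnorm(100 * 3), 100, 3),
                  matrix(rnorm(100 * 3, mean = 10), 100, 3))
  rownames(coords) <- sprintf("c%03d", 1:200)
  emb <- coords_embedding(coords)
  g <- bimodal_knn_graph(emb, k = 15, alpha = 1)
  # volumetric Gaussians fragment at high resolution (the usual modularity
  # behaviour); a coarse resolution recovers the planted partition exactly
  ca <- cluster_graph(g, resolution = 0.1, seed = 3)
  truth <- rep(c(0, 1), each = 100)
  expect_equal(length(unique(ca$cluster_of)), 2L)
  expect_equal(ari(ca$cluster_of, truth), 1)
  ca2 <- cluster_graph(g, resolution = 0.1, seed = 3)
  expect_identical(ca$cluster_of, ca2$cluster_of)
  # resolution -> 0 collapses a connected graph to one community
  set.seed(8)
  cloud <- matrix(rnorm(150 * 3), 150, 3,
                  dimnames = list(sprintf("d%03d", 1:150), NULL))
  g1 <- bimodal_knn_graph(coords_embedding(cloud), k = 15, alpha = 1)
  ca0 <- cluster_graph(g1, resolution = 1e-4, seed = 3)
  expect_equal(length(unique(ca0$cluster_of)), 1L)
})
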