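two_group_nm <- function(n_genes = 30, n_per = 60, boost_gene = 1,
                         boost = 6, seed = 1) {
  set.seed(seed)
  cnt <- matrix(rpois(n_genes * 2 * n_per, 2), n_genes, 2 * n_per,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%03d", seq_len(2 * n_per))))
  cnt[boost_gene, seq_len(n_per)] <- rpois(n_per, 2 * 2^boost)
  list(nm = normalize_log(cell_matrix(cnt)),
       ca = cluster_assignment(setNames(rep(0:1, each = n_per),
                                        colnames(cnt))))
}

test_that("cluster_markers finds planted markers and handles flat genes", {
  fx <- two_group_nm(boost = 3)
  mt <- cluster_markers(fx$nm, fx$ca)
  row <- mt[mt$cluster == 0 & mt$gene == "g001", ]
  expect_lt(row$p_adj, 0.01)
  expect_gt(row$log2fc, 1)

  # a constant nonzero gene: p = 1, log2fc = 0
  cnt <- matrix(3L, 10, 12, dimnames = list(sprintf("g%02d", 1:10),
                                            sprintf("c%02d", 1:12)))
  nm <- normalize_log(cell_matrix(cnt))
  ca <- cluster_assignment(setNames(rep(0:1, 6), colnames(cnt)))
  mt2 <- cluster_markers(nm, ca)
  expect_true(all(mt2$p_value == 1))
  expect_true(all(abs(mt2$log2fc) < 1e-12))

  # clusters below 3 cells are skipped with a warning
  ca3 <- cluster_assignment(setNames(c(0L, 0L, rep(1L, 10)),
                                     colnames(cnt)))
  expect_warning(cluster_markers(nm, ca3), "< 3")
})

test_that("rank-sum p-values agree with stats::wilcox.test on both paths", {
  set.seed(7)
  # exact path (4 vs 4, tie-free)
  for (i in 1:20) {
    x <- sample(seq(1, 200), 8)
    g <- rep(c(TRUE, FALSE), each = 4)
    p_pkg <- hindseg:::rank_sum_exact_p(x, g)
    p_ref <- wilcox.test(x[g], x[!g], exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
  # normal-approximation path with ties and continuity correction
  x <- matrix(rpois(5 * 60, 3), 5, 60)
  g <- rep(c(TRUE, FALSE), each = 30)
  p_pkg <- hindseg:::rank_sum_p(x, g)
  p_ref <- apply(x, 1, function(r)
    suppressWarnings(wilcox.test(r[g], r[!g], exact = FALSE,
                                 correct = TRUE)$p.value))
  expect_equal(unname(p_pkg), unname(p_ref), tolerance = 1e-10)
})

test_that("marker p-values are uniform under the global null", {
  set.seed(21)
  cnt <- matrix(rnbinom(2000 * 120, mu = 1, size = 2), 2000, 120,
                dimnames = list(sprintf("g%04d", 1:2000),
                                sprintf("c%03d", 1:120)))
  keep <- colSums(cnt) > 0
  cnt <- cnt[, keep]
  nm <- normalize_log(cell_matrix(cnt))
  ca <- cluster_assignment(setNames(rep_len(0:1, ncol(cnt)), colnames(cnt)))
  mt <- cluster_markers(nm, ca, min_pct = 0.05)
  p <- mt$p_value[mt$cluster == 0]
  # heavy ties make exact uniformity unattainable; KS on the mid-p-ish
  # distribution still detects systematic bias
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("top_markers applies the documented ranking and tie rules", {
  mt <- data.frame(
    cluster = 0L,
    gene = c("gB", "gA", "gC", "gD", "gE"),
    log2fc = c(2, 3, -1, 3, 1),
    p_value = c(0.01, 0.01, 0.001, 0.01, 0.2),
    p_adj = c(0.02, 0.02, 0.002, 0.02, 0.4),
    pct_in = 1, pct_out = 0)
  top <- top_markers(mt, n = 5)[["0"]]
  # gC excluded (negative fc); gA/gD (higher fc) precede gB; gA before gD
  expect_identical(top, c("gA", "gD", "gB", "gE"))
  expect_length(top_markers(mt, n = 2)[["0"]], 2L)
})

test_that("top markers on synthetic clusters are planted markers", {
  sim <- simulate_hindbrain(config_13hpf(qc_fail_fraction = 0),
                            seed = 15)[["13hpf"]]
  nm <- normalize_log(sim$rna)
  ca <- truth_assignment(sim$truth$cells)
  mt <- cluster_markers(nm, ca)
  top <- top_markers(mt, n = 5)
  cfg <- config_13hpf()
  sets <- lapply(cfg$timepoints[[1]]$clusters, `[[`, "marker_genes")
  names(sets) <- vapply(cfg$timepoints[[1]]$clusters, `[[`, "", "label")
  for (k in names(top)) {
    lab <- ca$labels[[k]]
    planted <- sim$rna$gene_ids[sets[[lab]]]
    expect_true(all(top[[k]] %in% planted),
                label = sprintf("top-5 of %s within planted set", lab))
  }
})

test_that("identity assignment labels planted rhombomeres correctly", {
  sim <- simulate_hindbrain(config_13hpf(qc_fail_fraction = 0),
                            seed = 16)[["13hpf"]]
  nm <- normalize_log(sim$rna)
  ca <- truth_assignment(sim$truth$cells)
  truth_label <- ca$labels
  ca$labels <- NULL
  res <- assign_identities(nm, ca)
  got <- cluster_labels(res$ca)
  for (r in paste0("r", 1:6)) {
    k <- names(truth_label)[truth_label == r]
    cells <- names(ca$cluster_of)[ca$cluster_of == as.integer(k)]
    expect_identical(unique(unname(got[cells])), r)
  }
  expect_true(all(res$margins > 0))

  # invariance to cell order
  perm <- sample(length(nm$cell_ids))
  nm_p <- nm
  nm_p$values <- nm$values[, perm]
  nm_p$cell_ids <- nm$cell_ids[perm]
  res_p <- assign_identities(nm_p, ca)
  expect_equal(res_p$scores, res$scores, tolerance = 1e-12)
})

test_that("identity scoring handles ties and missing panels", {
  cnt <- matrix(rpois(10 * 30, 2), 10, 30,
                dimnames = list(c("mk", sprintf("g%02d", 2:10)),
                                sprintf("c%02d", 1:30)))
  cnt["mk", 1:10] <- 20L
  nm <- normalize_log(cell_matrix(cnt))
  ca <- cluster_assignment(setNames(rep(0:2, each = 10), colnames(cnt)))
  res <- assign_identities(nm, ca, panel = list(hit = "mk"))
  expect_identical(unname(res$ca$labels["0"]), "hit")
  expect_warning(
    assign_identities(nm, ca, panel = list(hit = "mk", gone = "absent")),
    "missing")
  expect_error(
    suppressWarnings(assign_identities(nm, ca, panel = list(gone = "absent"))),
    "no usable")

  # clusters with identical profiles receive identical score columns, and
  # equally-scoring labels tie to the lexicographically smallest label
  cnt2 <- cbind(cnt[, 1:10], cnt[, 1:10], cnt[, 21:30])
  colnames(cnt2) <- sprintf("d%02d", 1:30)
  nm2 <- normalize_log(cell_matrix(cnt2))
  ca2 <- cluster_assignment(setNames(rep(0:2, each = 10), colnames(cnt2)))
  res2 <- assign_identities(nm2, ca2, panel = list(hit = "mk"))
  expect_equal(res2$scores[, "0"], res2$scores[, "1"], tolerance = 1e-12)
  w <- capture_warnings(
    res3 <- assign_identities(nm2, ca2, panel = list(zB = "mk", zA = "mk")))
  expect_match(w, "tie", all = TRUE)
  expect_identical(unname(res3$ca$labels["0"]), "zA")
})

test_that("cluster dendrograms reflect centroid geometry", {
  coords <- rbind(matrix(rnorm(20 * 2, 0, 0.05), 20, 2),
                  matrix(rnorm(20 * 2, 0.5, 0.05), 20, 2),
                  matrix(rnorm(20 * 2, 10, 0.05), 20, 2))
  rownames(coords) <- sprintf("c%02d", 1:60)
  emb <- coords_embedding(coords)
  ca <- cluster_assignment(setNames(rep(0:2, each = 20), rownames(coords)),
                           labels = c("0" = "A", "1" = "B", "2" = "C"))
  nwk <- cluster_dendrogram(emb, ca)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  coph <- ape::cophenetic.phylo(phy)
  expect_lt(coph["A", "B"], coph["A", "C"])

  ca1 <- cluster_assignment(setNames(rep(0L, 60), rownames(coords)))
  expect_error(cluster_dendrogram(emb, ca1), "at least 2")
})

test_that("r3 and r5 are dendrogram siblings on shared-marker data", {
  cfg <- config_13hpf(qc_fail_fraction = 0)
  # deepen the r3/r5 marker overlap so their centroids are unambiguously
  # the nearest pair, as in hindbrain data where they share a regulator
  r3 <- cfg$timepoints[[1]]$clusters[[3]]$marker_genes
  cfg$timepoints[[1]]$clusters[[5]]$marker_genes <-
    unique(c(cfg$timepoints[[1]]$clusters[[5]]$marker_genes, r3[1:20]))
  sim <- simulate_hindbrain(cfg, seed = 18)[["13hpf"]]
  truth <- sim$truth$cells
  rh_cells <- truth$cell_id[truth$true_cluster %in% paste0("r", 1:6)]
  cm <- subset_cells(sim$rna, rh_cells)
  nm <- normalize_log(cm)
  emb <- pca_embed(nm)
  ca <- truth_assignment(truth[truth$cell_id %in% rh_cells, ])
  nwk <- cluster_dendrogram(emb, ca)
  phy <- ape::read.tree(text = nwk)
  coph <- ape::cophenetic.phylo(phy)
  expect_equal(unname(coph["r3", "r5"]), min(coph[coph > 0]),
               tolerance = 1e-9)
})

test_that("the shipped panel file matches the built-in panel", {
  path <- system.file("extdata", "rhombomere_panel.json", package = "hindseg")
  expect_true(nzchar(path))
  panel <- read_identity_panel(path)
  expect_equal(panel, default_identity_panel())
})
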