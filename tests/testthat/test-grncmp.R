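test_that("peak-gene correlations match a naive two-pass computation", {
  fx <- grn_fixture(seed = 3, n = 120)
  links <- link_peaks_to_genes(fx$pd, fx$nm, r_min = 0.2)
  v <- as.matrix(fx$nm$values)
  p <- as.matrix(fx$pd$counts)
  for (i in seq_len(min(nrow(links), 20))) {
    x <- p[links$peak[i], ]
    y <- v[links$gene[i], ]
    mx <- mean(x); my <- mean(y)
    r_ref <- sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
    expect_equal(links$r[i], r_ref, tolerance = 1e-12)
  }
  # a peak identical to a gene's expression correlates perfectly
  cnt <- matrix(rpois(4 * 50, 3), 4, 50,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:50)))
  nm <- normalize_log(cell_matrix(cnt))
  pk <- matrix(as.matrix(nm$values)[1, ], 1, 50)
  pd <- peak_data(round(pk * 10), data.frame(chrom = "c", start = 0L,
                                             end = 100L),
                  paste0("c", 1:50),
                  matrix(1, 1, 1, dimnames = list(NULL, "M1")))
  l2 <- link_peaks_to_genes(pd, nm)
  expect_gte(l2$r[l2$gene == "g1"], 0.99)
})

test_that("independent peaks and genes are not retained at n = 500", {
  set.seed(17)
  n <- 500
  cnt <- matrix(rpois(40 * n, 3), 40, n,
                dimnames = list(sprintf("g%02d", 1:40),
                                sprintf("c%03d", 1:n)))
  nm <- normalize_log(cell_matrix(cnt))
  pk <- matrix(rpois(40 * n, 2), 40, n)
  pd <- peak_data(pk, data.frame(chrom = "c", start = (1:40) * 100L,
                                 end = (1:40) * 100L + 50L),
                  colnames(cnt),
                  matrix(1, 40, 1, dimnames = list(NULL, "M1")))
  links <- link_peaks_to_genes(pd, nm)
  # null P(|r| >= 0.3) at n = 500 is ~3e-11; 1600 pairs should yield none
  expect_equal(nrow(links), 0L)

  pk[1, ] <- 2L
  pd0 <- peak_data(pk, pd$peaks, colnames(cnt), pd$motif_membership)
  expect_warning(link_peaks_to_genes(pd0, nm), "zero-variance")
})

test_that("build_grn recovers the planted regulatory plan", {
  fx <- grn_fixture()
  links <- link_peaks_to_genes(fx$pd, fx$nm)
  ca <- cluster_assignment(setNames(rep(0L, length(fx$nm$cell_ids)),
                                    fx$nm$cell_ids),
                           labels = c("0" = "all"))
  net <- build_grn(links, fx$pd, fx$catalog, fx$nm, ca, "all")
  planted <- paste(fx$planted$source, fx$planted$target)
  got <- paste(net$edges$source, net$edges$target)
  expect_gte(mean(planted %in% got), 0.8)
  expect_gte(mean(got %in% planted), 0.8)

  # a TF below the detection floor has no outgoing edges
  nm0 <- fx$nm
  v <- as.matrix(nm0$values)
  v["tf1", ] <- 0
  nm0$values <- as(v, "CsparseMatrix")
  net0 <- build_grn(links, fx$pd, fx$catalog, nm0, ca, "all")
  expect_false("tf1" %in% net0$edges$source)

  expect_error(build_grn(links, fx$pd, list(), fx$nm, ca, "all"),
               "empty TF catalog")

  # invariance to cell order
  perm <- sample(length(fx$nm$cell_ids))
  nm_p <- fx$nm
  nm_p$values <- fx$nm$values[, perm]
  nm_p$cell_ids <- fx$nm$cell_ids[perm]
  pd_p <- fx$pd
  pd_p$counts <- fx$pd$counts[, perm]
  pd_p$cell_ids <- fx$pd$cell_ids[perm]
  links_p <- link_peaks_to_genes(pd_p, nm_p)
  net_p <- build_grn(links_p, pd_p, fx$catalog, nm_p, ca, "all")
  expect_equal(net_p$edges, net$edges, tolerance = 1e-12)
})

test_that("first-neighbour extraction matches an adjacency scan", {
  set.seed(29)
  edges <- expand.grid(source = paste0("n", 1:10),
                       target = paste0("n", 1:50),
                       stringsAsFactors = FALSE)
  edges <- edges[edges$source != edges$target, ]
  edges <- edges[sample(nrow(edges), 120), ]
  edges$weight <- runif(120)
  edges$sign <- "+"
  net <- grn_network(edges)
  for (v in c("n1", "n5", "n30")) {
    fn <- first_neighbors(net, v)
    nbrs <- unique(c(v, edges$target[edges$source == v],
                     edges$source[edges$target == v]))
    expect_setequal(fn$nodes$id, nbrs)
    keep <- edges$source %in% nbrs & edges$target %in% nbrs
    expect_equal(nrow(fn$edges), sum(keep))
    # idempotence
    fn2 <- first_neighbors(fn, v)
    expect_setequal(fn2$nodes$id, fn$nodes$id)
    expect_equal(nrow(fn2$edges), nrow(fn$edges))
  }
  iso <- grn_network(data.frame(source = "a", target = "b", weight = 1,
                                sign = "+"),
                     nodes = data.frame(id = c("a", "b", "lone"),
                                        kind = c("TF", "gene", "gene")))
  expect_identical(first_neighbors(iso, "lone")$nodes$id, "lone")
  star <- grn_network(data.frame(source = "hub", target = paste0("g", 1:6),
                                 weight = 1, sign = "+"))
  expect_equal(nrow(first_neighbors(star, "hub")$edges), 6)
  expect_error(first_neighbors(star, "nope"), "not in network")
})

test_that("node overlap reports all denominators symmetrically", {
  a <- grn_network(data.frame(source = "a", target = c("b", "c"),
                              weight = 1, sign = "+"))
  b <- grn_network(data.frame(source = "b", target = c("c", "d"),
                              weight = 1, sign = "+"))
  ov <- node_overlap(a, b)
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$jaccard, 0.5)
  expect_equal(ov$frac_of_a, 2 / 3)
  rev <- node_overlap(b, a)
  expect_equal(rev$jaccard, ov$jaccard)
  expect_equal(rev$frac_of_b, ov$frac_of_a)
  expect_equal(node_overlap(a, a)$jaccard, 1)
  c_net <- grn_network(data.frame(source = "x", target = "y",
                                  weight = 1, sign = "+"))
  expect_equal(node_overlap(a, c_net)$jaccard, 0)
})
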