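# Shared fixtures, all built in code at test time.

# cluster_assignment from a sim_truth cell table (true labels as clusters)
truth_assignment <- function(truth_cells) {
  f <- factor(truth_cells$true_cluster)
  cluster_assignment(
    setNames(as.integer(f) - 1L, truth_cells$cell_id),
    labels = setNames(levels(f), seq_along(levels(f)) - 1L))
}

# small random cell_matrix with sparse counts
random_cell_matrix <- function(n_genes = 50, n_cells = 30, density = 0.2,
                               seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n_genes, n_cells)
  nz <- round(density * length(m))
  m[sample(length(m), nz)] <- rpois(nz, 3) + 1L
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("c%03d", seq_len(n_cells)))
  cell_matrix(m)
}

random_peak_data <- function(n_peaks = 30, n_cells = 20, n_motifs = 4,
                             seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_peaks * n_cells, 0.8), n_peaks, n_cells)
  peaks <- data.frame(chrom = "chr1",
                      start = (seq_len(n_peaks) - 1L) * 500L,
                      end = (seq_len(n_peaks) - 1L) * 500L + 200L)
  mem <- matrix(rbinom(n_peaks * n_motifs, 1, 0.3), n_peaks, n_motifs,
                dimnames = list(NULL, sprintf("M%03d", seq_len(n_motifs))))
  peak_data(m, peaks, sprintf("c%03d", seq_len(n_cells)), mem)
}

# latent-factor multiome fixture with a planted TF -> target regulatory
# plan: three TFs, four targets each, one motif-bearing peak per target,
# plus stable background genes so cell totals are flat
grn_fixture <- function(seed = 42, n = 400) {
  set.seed(seed)
  tfs <- paste0("tf", 1:3)
  z <- matrix(rnorm(n * 3), n, 3)
  genes <- c(tfs, paste0("tg", 1:12), sprintf("bg%02d", 1:60))
  cnt <- matrix(0L, length(genes), n,
                dimnames = list(genes, sprintf("c%03d", seq_len(n))))
  for (t in 1:3) cnt[t, ] <- rpois(n, exp(0.8 + 1.2 * z[, t]))
  for (j in 1:12) {
    t <- ((j - 1) %/% 4) + 1
    cnt[3 + j, ] <- rpois(n, exp(0.8 + 1.2 * z[, t]))
  }
  for (b in 1:60) cnt[15 + b, ] <- rpois(n, 3)
  pk <- matrix(0L, 12, n)
  for (j in 1:12) {
    t <- ((j - 1) %/% 4) + 1
    pk[j, ] <- rpois(n, exp(0.6 + 1.2 * z[, t]))
  }
  peaks <- data.frame(chrom = "chr1", start = (1:12) * 1000L,
                      end = (1:12) * 1000L + 400L)
  mem <- matrix(0, 12, 3, dimnames = list(NULL, c("MA", "MB", "MC")))
  for (j in 1:12) mem[j, ((j - 1) %/% 4) + 1] <- 1
  # tg3/tg4 are co-regulated: their peaks also carry tf2's motif, so the
  # tf1 and tf2 first-neighbour networks share nodes
  mem[3:4, 2] <- 1
  list(pd = peak_data(pk, peaks, colnames(cnt), mem),
       nm = normalize_log(cell_matrix(cnt)),
       catalog = list(tf1 = "MA", tf2 = "MB", tf3 = "MC"),
       planted = data.frame(
         source = c(rep(tfs, each = 4), "tf2", "tf2"),
         target = c(paste0("tg", 1:12), "tg3", "tg4")))
}

# embedding object built directly from coordinates
coords_embedding <- function(coords) {
  hindseg:::new_embedding(coords, "fixture")
}

ari <- function(a, b) hindseg:::adjusted_rand_index(a, b)

# independent brute-force reimplementation of both screens, per gene
brute_periodicity <- function(nm, labels, min_frac = 0.1) {
  even <- c("r2", "r4", "r6"); odd <- c("r1", "r3", "r5")
  v <- as.matrix(nm$values)
  flag_e <- flag_o <- logical(nrow(v))
  for (g in seq_len(nrow(v))) {
    mns <- sapply(c(even, odd), function(l) mean(v[g, labels == l]))
    det <- sapply(c(even, odd), function(l) mean(v[g, labels == l] > 0))
    flag_e[g] <- all(det[even] >= min_frac) &&
      mean(mns[even]) > mean(mns[odd])
    flag_o[g] <- all(det[odd] >= min_frac) &&
      mean(mns[odd]) > mean(mns[even])
  }
  list(even = nm$gene_ids[flag_e], odd = nm$gene_ids[flag_o])
}

brute_pair <- function(nm, labels, pair, min_frac = 0.1, fold = 2) {
  v <- as.matrix(nm$values)
  rh <- paste0("r", 1:6)
  keep <- logical(nrow(v))
  for (g in seq_len(nrow(v))) {
    mns <- sapply(rh, function(l) mean(v[g, labels == l]))
    det <- sapply(pair, function(l) mean(v[g, labels == l] > 0))
    keep[g] <- all(det >= min_frac) &&
      min(mns[pair]) >= fold * max(mns[setdiff(rh, pair)])
  }
  nm$gene_ids[keep]
}

random_rh_instance <- function(seed, n_genes = 120, n_per = 25) {
  set.seed(seed)
  labels <- rep(paste0("r", 1:6), each = n_per)
  cnt <- matrix(rnbinom(n_genes * length(labels), mu = 0.6, size = 1),
                n_genes, length(labels),
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("c%03d", seq_along(labels))))
  cnt[1, ] <- cnt[1, ] + 1L  # guard against zero-total cells
  nm <- normalize_log(cell_matrix(cnt))
  ca <- cluster_assignment(setNames(as.integer(factor(labels)) - 1L,
                                    colnames(cnt)),
                           labels = setNames(levels(factor(labels)), 0:5))
  list(nm = nm, ca = ca, labels = labels)
}

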