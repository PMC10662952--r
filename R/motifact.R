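#' Per-cell motif accessibility deviation scores
#'
#' For motif m and cell c the observed signal `o` is the cell's total
#' fragment count in motif-bearing peaks and the expected signal `e` is the
#' cell depth times the motif peak set's share of total fragment mass;
#' `raw_dev = (o - e) / e`. Each motif's raw deviation is z-scored against
#' `n_background` random peak sets matched peak-for-peak to the motif's
#' peaks by mean-accessibility bin (deciles by default).
#'
#' @param pd a [peak_data()].
#' @param n_background background peak sets per motif.
#' @param n_bins accessibility-matching bins.
#' @param seed integer seed (background sampling).
#' @return a `motif_deviation`: matrices `z` and `raw_dev`
#'   (motifs x cells), `n_background`, `seed`.
#' @export
motif_deviation_scores <- function(pd, n_background = 50, n_bins = 10,
                                   seed = 1L) {
  stopifnot(inherits(pd, "peak_data"))
  counts <- as(pd$counts, "CsparseMatrix")
  peak_mass <- Matrix::rowSums(counts)
  keep <- peak_mass > 0
  counts <- counts[keep, , drop = FALSE]
  membership <- pd$motif_membership[keep, , drop = FALSE]
  peak_mass <- peak_mass[keep]
  n_peaks <- nrow(counts)
  depth <- Matrix::colSums(counts)
  zero_depth <- depth == 0
  if (any(zero_depth)) {
    warnf("%d cell(s) have no fragments in informative peaks; scores set to 0",
          sum(zero_depth))
    depth[zero_depth] <- 1  # placeholder; these columns are zeroed below
  }
  total <- sum(peak_mass)
  mean_acc <- peak_mass / ncol(counts)
  bins <- cut(rank(mean_acc, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  bin_members <- split(seq_len(n_peaks), bins)

  n_motifs <- length(pd$motif_ids)
  n_cells <- ncol(counts)
  z <- raw <- matrix(0, n_motifs, n_cells,
                     dimnames = list(pd$motif_ids, pd$cell_ids))
  with_seed(seed, {
    for (mi in seq_len(n_motifs)) {
      peaks <- which(membership[, mi] > 0)
      if (!length(peaks)) {
        warnf("motif %s has no peaks with counts; scores set to 0",
              pd$motif_ids[mi])
        next
      }
      o <- Matrix::colSums(counts[peaks, , drop = FALSE])
      frac <- sum(peak_mass[peaks]) / total
      e <- depth * frac
      dev <- (o - e) / e
      # backgrounds matched by accessibility bin, sampled per motif peak
      pb <- bins[peaks]
      bg_dev <- matrix(0, n_background, n_cells)
      for (b in seq_len(n_background)) {
        bg <- vapply(pb, function(bb) {
          cand <- bin_members[[bb]]
          cand[sample.int(length(cand), 1L)]
        }, 1L)
        o_bg <- Matrix::colSums(counts[bg, , drop = FALSE])
        e_bg <- depth * sum(peak_mass[bg]) / total
        bg_dev[b, ] <- (o_bg - e_bg) / e_bg
      }
      mu_bg <- colMeans(bg_dev)
      sd_bg <- apply(bg_dev, 2L, sd)
      zi <- (dev - mu_bg) / sd_bg
      if (any(sd_bg == 0)) {
        warnf("motif %s: zero background s.d. for %d cell(s); z set to 0",
              pd$motif_ids[mi], sum(sd_bg == 0))
        zi[sd_bg == 0] <- 0
      }
      dev[zero_depth] <- 0
      zi[zero_depth] <- 0
      raw[mi, ] <- dev
      z[mi, ] <- zi
    }
  })
  structure(list(z = z, raw_dev = raw, n_background = n_background,
                 seed = seed), class = "motif_deviation")
}

print.motif_deviation <- function(x, ...) {
  cat(sprintf("motif_deviation: %d motifs x %d cells (%d background sets)\n",
              nrow(x$z), ncol(x$z), x$n_background))
  invisible(x)
}

#' Differential motif activity per cluster
#'
#' One-vs-rest rank-sum test on per-cell deviation z-scores, BH-adjusted
#' within each cluster and ranked by the mean z difference.
#'
#' @param md a [motif_deviation_scores()] result.
#' @param ca a [cluster_assignment()] over the same cells.
#' @return data.frame (cluster, motif, mean_diff, p, p_adj), sorted within
#'   cluster by decreasing mean_diff.
#' @export
differential_motif_activity <- function(md, ca) {
  stopifnot(inherits(md, "motif_deviation"),
            inherits(ca, "cluster_assignment"))
  cl <- ca$cluster_of[colnames(md$z)]
  if (anyNA(cl)) stopf("assignment is missing %d cells", sum(is.na(cl)))
  clusters <- sort(unique(cl))
  if (length(clusters) < 2L) stopf("need at least 2 clusters")
  out <- list()
  for (k in clusters) {
    in_group <- cl == k
    if (sum(in_group) < 3L) {
      warnf("cluster %s has %d cells (< 3); skipped", k, sum(in_group))
      next
    }
    p <- rank_sum_p(md$z, in_group)
    mean_diff <- rowMeans(md$z[, in_group, drop = FALSE]) -
      rowMeans(md$z[, !in_group, drop = FALSE])
    d <- data.frame(cluster = k, motif = rownames(md$z),
                    mean_diff = mean_diff, p = p,
                    p_adj = p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
    out[[as.character(k)]] <- d[order(-d$mean_diff), ]
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
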