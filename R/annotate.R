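#' One-vs-rest cluster marker detection
#'
#' For every cluster of size >= 3, each gene detected (value > 0) in at
#' least `min_pct` of cells inside or outside the cluster is tested with a
#' two-sided Wilcoxon rank-sum test (exact for tiny groups, normal
#' approximation with tie and continuity correction otherwise). Log2 fold
#' changes are computed on `expm1` of mean normalised values with a
#' pseudocount of 1; p-values are Benjamini-Hochberg adjusted within each
#' cluster's test set.
#'
#' @param nm a [normalize_log()] result.
#' @param ca a [cluster_assignment()] over the same cells.
#' @param min_pct minimum detection fraction in either group.
#' @return a `marker_table` data.frame with columns cluster, gene, log2fc,
#'   p_value, p_adj, pct_in, pct_out.
#' @export
cluster_markers <- function(nm, ca, min_pct = 0.1) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(ca, "cluster_assignment"))
  cl <- ca$cluster_of[nm$cell_ids]
  if (anyNA(cl)) stopf("assignment is missing %d cells", sum(is.na(cl)))
  clusters <- sort(unique(cl))
  if (length(clusters) < 2L) stopf("need at least 2 clusters")
  v <- nm$values
  n <- ncol(v)
  dense <- as_dense(v)
  ranks <- t(apply(dense, 1L, rank))
  tie_term <- apply(ranks, 1L, function(r) {
    t <- tabulate(match(r, unique(r)))
    sum(t^3 - t)
  })
  ev <- v
  ev@x <- expm1(ev@x)
  det <- v
  det@x <- as.numeric(det@x > 0)

  out <- vector("list", length(clusters))
  for (idx in seq_along(clusters)) {
    k <- clusters[idx]
    in_group <- cl == k
    n1 <- sum(in_group)
    n2 <- n - n1
    if (n1 < 3L) {
      warnf("cluster %s has %d cells (< 3); tests skipped", k, n1)
      next
    }
    pct_in <- as.vector(det %*% in_group) / n1
    pct_out <- as.vector(det %*% (!in_group)) / n2
    tested <- pct_in >= min_pct | pct_out >= min_pct
    if (!any(tested)) next
    mean_in <- as.vector(ev %*% in_group) / n1
    mean_out <- as.vector(ev %*% (!in_group)) / n2
    if (n1 <= 8L && n2 <= 8L) {
      p <- apply(dense[tested, , drop = FALSE], 1L, rank_sum_exact_p,
                 in_group = in_group)
    } else {
      w <- as.vector(ranks[tested, , drop = FALSE] %*% in_group) -
        n1 * (n1 + 1) / 2
      sigma2 <- (n1 * n2 / 12) *
        ((n + 1) - tie_term[tested] / (n * (n - 1)))
      z <- w - n1 * n2 / 2
      p <- 2 * pnorm(-abs((z - sign(z) * 0.5) /
                            sqrt(pmax(sigma2, .Machine$double.eps))))
      p[sigma2 == 0] <- 1
      p <- pmin(p, 1)
    }
    out[[idx]] <- data.frame(
      cluster = k,
      gene = nm$gene_ids[tested],
      log2fc = log2fc_expm1(mean_in[tested], mean_out[tested]),
      p_value = p,
      p_adj = p.adjust(p, "BH"),
      pct_in = pct_in[tested],
      pct_out = pct_out[tested],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(cluster = integer(0), gene = character(0),
                                      log2fc = numeric(0), p_value = numeric(0),
                                      p_adj = numeric(0), pct_in = numeric(0),
                                      pct_out = numeric(0))
  class(res) <- c("marker_table", "data.frame")
  res
}

#' Top positive markers per cluster
#'
#' Genes with positive log2 fold change ranked by ascending adjusted
#' p-value, ties broken by descending log2 fold change, then lexicographic
#' gene id.
#'
#' @param mt a [cluster_markers()] table.
#' @param n markers per cluster (shorter lists allowed).
#' @return named list cluster -> character vector of gene ids.
#' @export
top_markers <- function(mt, n = 5) {
  stopifnot(inherits(mt, "data.frame"))
  out <- lapply(split(as.data.frame(mt), mt$cluster), function(d) {
    d <- d[d$log2fc > 0, , drop = FALSE]
    d <- d[order(d$p_adj, -d$log2fc, d$gene), , drop = FALSE]
    head(d$gene, n)
  })
  out
}

#' Assign biological identities to clusters from a marker panel
#'
#' Scores each (cluster, label) pair as the mean, over the label's panel
#' genes, of the cluster's mean expression z-scored across clusters; each
#' cluster receives the argmax label (ties resolved to the
#' lexicographically smallest label, with a warning). The margin between
#' the best and second-best score is reported per cluster.
#'
#' @param nm a [normalize_log()] result.
#' @param ca a [cluster_assignment()].
#' @param panel named list label -> marker gene ids (see
#'   [default_identity_panel()]).
#' @return `list(ca, scores, margins)`: the relabelled assignment, the
#'   label x cluster score matrix, and per-cluster margins.
#' @export
assign_identities <- function(nm, ca, panel = default_identity_panel()) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(ca, "cluster_assignment"))
  cl <- ca$cluster_of[nm$cell_ids]
  clusters <- sort(unique(cl))
  ind <- vapply(clusters, function(k) cl == k,
                logical(length(cl)))
  sizes <- colSums(ind)
  cl_means <- as_dense(nm$values %*% ind) %*% diag(1 / sizes, length(sizes))
  mu <- rowMeans(cl_means)
  sdv <- apply(cl_means, 1L, sd)
  z <- (cl_means - mu) / ifelse(sdv == 0, 1, sdv)
  rownames(z) <- nm$gene_ids

  labels <- names(panel)
  scores <- matrix(NA_real_, length(labels), length(clusters),
                   dimnames = list(labels, as.character(clusters)))
  for (lab in labels) {
    genes <- intersect(panel[[lab]], nm$gene_ids)
    missing <- setdiff(panel[[lab]], nm$gene_ids)
    if (!length(genes)) {
      warnf("all panel genes for label '%s' missing; label skipped", lab)
      next
    }
    if (length(missing)) {
      warnf("label '%s': panel genes missing from data: %s", lab,
            paste(missing, collapse = ", "))
    }
    scores[lab, ] <- colMeans(z[genes, , drop = FALSE])
  }
  scores <- scores[!apply(is.na(scores), 1L, all), , drop = FALSE]
  if (!nrow(scores)) stopf("no usable identity panel labels")

  assigned <- character(ncol(scores))
  margins <- numeric(ncol(scores))
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    best <- max(s)
    winners <- sort(rownames(scores)[s == best])
    if (length(winners) > 1L) {
      warnf("cluster %s: identity score tie between %s",
            colnames(scores)[j], paste(winners, collapse = ", "))
    }
    assigned[j] <- winners[1]
    margins[j] <- if (length(s) > 1L) best - max(s[s < best], -Inf) else Inf
  }
  names(margins) <- colnames(scores)
  label_map <- setNames(assigned, colnames(scores))
  ca$labels <- label_map
  list(ca = ca, scores = scores, margins = margins)
}

#' Dendrogram of cluster centroids
#'
#' Average-linkage hierarchical clustering of cluster centroids in
#' embedding space (Euclidean distance); leaves carry cluster labels.
#'
#' @param emb an `embedding` over the assignment's cells.
#' @param ca a [cluster_assignment()].
#' @return newick string (one leaf per cluster); the `phylo` tree is
#'   attached as attribute `"phylo"`.
#' @export
cluster_dendrogram <- function(emb, ca) {
  stopifnot(inherits(emb, "embedding"), inherits(ca, "cluster_assignment"))
  labels <- cluster_labels(ca)[rownames(emb$coords)]
  uniq <- sort(unique(labels))
  if (length(uniq) < 2L) stopf("need at least 2 clusters for a dendrogram")
  centroids <- t(vapply(uniq, function(l)
    colMeans(emb$coords[labels == l, , drop = FALSE]),
    numeric(ncol(emb$coords))))
  hc <- hclust(dist(centroids), method = "average")
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  attr(nwk, "phylo") <- phy
  nwk
}
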