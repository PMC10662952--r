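#' Correlation-based peak-to-gene linking
#'
#' Pearson correlation of peak fragment counts against gene expression
#' across shared cells, retained when `|r| >= r_min`. Candidate pairs may
#' be supplied (e.g. from a proximity table); by default every
#' (peak, gene) pair is tested, which is intended for modest instances.
#'
#' @param pd a [peak_data()].
#' @param nm a [normalize_log()] result over the same cells.
#' @param candidates optional data.frame (peak_id, gene) restricting the
#'   tested pairs.
#' @param r_min absolute-correlation threshold.
#' @return a `peak_gene_links` data.frame (peak, gene, r, n_cells);
#'   zero-variance peaks or genes are skipped with a warning.
#' @export
link_peaks_to_genes <- function(pd, nm, candidates = NULL, r_min = 0.3) {
  stopifnot(inherits(pd, "peak_data"), inherits(nm, "normalized_matrix"))
  cells <- intersect(pd$cell_ids, nm$cell_ids)
  if (!length(cells)) stopf("no shared cells")
  pmat <- t(as_dense(pd$counts[, cells, drop = FALSE]))
  gmat <- t(as_dense(nm$values[, cells, drop = FALSE]))
  pvar <- apply(pmat, 2L, var)
  gvar <- apply(gmat, 2L, var)
  if (is.null(candidates)) {
    if (any(pvar == 0) || any(gvar == 0)) {
      warnf("%d zero-variance peak(s) and %d gene(s) skipped",
            sum(pvar == 0), sum(gvar == 0))
    }
    pk <- which(pvar > 0)
    gn <- which(gvar > 0)
    r <- cor(pmat[, pk, drop = FALSE], gmat[, gn, drop = FALSE])
    idx <- which(abs(r) >= r_min, arr.ind = TRUE)
    out <- data.frame(peak = colnames(pmat)[pk][idx[, 1]],
                      gene = colnames(gmat)[gn][idx[, 2]],
                      r = r[idx], n_cells = rep(length(cells), nrow(idx)),
                      stringsAsFactors = FALSE)
  } else {
    candidates <- as.data.frame(candidates)
    pi <- match(candidates$peak_id, colnames(pmat))
    gi <- match(candidates$gene, colnames(gmat))
    if (anyNA(pi) || anyNA(gi)) stopf("candidate pair references unknown ids")
    ok <- pvar[pi] > 0 & gvar[gi] > 0
    if (any(!ok)) warnf("%d candidate pair(s) with zero variance skipped",
                        sum(!ok))
    r <- vapply(which(ok), function(i)
      cor(pmat[, pi[i]], gmat[, gi[i]]), 1)
    keep <- abs(r) >= r_min
    out <- data.frame(peak = candidates$peak_id[ok][keep],
                      gene = candidates$gene[ok][keep],
                      r = r[keep], n_cells = rep(length(cells), sum(keep)),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$peak, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("peak_gene_links", "data.frame")
  out
}

#' Build a cluster regulatory network from links and motifs
#'
#' Draws an edge TF -> gene when the TF's motif occurs in at least one
#' peak linked to the gene and the TF is detected in at least
#' `min_tf_frac` of the cluster's cells. The edge weight is the largest
#' absolute link correlation among supporting links; its sign is the sign
#' of that correlation.
#'
#' @param links a [link_peaks_to_genes()] table.
#' @param pd the [peak_data()] carrying motif membership.
#' @param tf_catalog named list TF gene id -> motif id(s).
#' @param nm a [normalize_log()] result.
#' @param ca a [cluster_assignment()].
#' @param cluster label (or id as character) of the cluster to model.
#' @param min_tf_frac TF detection floor within the cluster.
#' @return a [grn_network()].
#' @export
build_grn <- function(links, pd, tf_catalog, nm, ca, cluster,
                      min_tf_frac = 0.1) {
  if (!length(tf_catalog)) stopf("empty TF catalog")
  labels <- cluster_labels(ca)
  cells <- names(labels)[labels == as.character(cluster)]
  if (!length(cells)) stopf("cluster '%s' has no cells", cluster)
  det <- flag_expressed(nm)
  edges <- list()
  for (tf in names(tf_catalog)) {
    if (!tf %in% rownames(det)) next
    frac <- mean(det[tf, cells] > 0)
    if (frac < min_tf_frac) next
    motifs <- intersect(tf_catalog[[tf]], colnames(pd$motif_membership))
    if (!length(motifs)) next
    tf_peaks <- rownames(pd$motif_membership)[
      Matrix::rowSums(pd$motif_membership[, motifs, drop = FALSE]) > 0]
    sup <- links[links$peak %in% tf_peaks & links$gene != tf, , drop = FALSE]
    if (!nrow(sup)) next
    for (g in unique(sup$gene)) {
      rr <- sup$r[sup$gene == g]
      best <- rr[which.max(abs(rr))]
      edges[[length(edges) + 1L]] <- data.frame(
        source = tf, target = g, weight = abs(best),
        sign = if (best >= 0) "+" else "-", stringsAsFactors = FALSE)
    }
  }
  if (!length(edges)) {
    return(grn_network(data.frame(source = character(0), target = character(0),
                                  weight = numeric(0), sign = character(0))))
  }
  grn_network(do.call(rbind, edges))
}

#' First-neighbour subnetwork of a node
#'
#' The induced subnetwork on the node and its direct in/out neighbours,
#' keeping all edges among the selected nodes.
#'
#' @param net a [grn_network()].
#' @param node node id.
#' @return a [grn_network()].
#' @export
first_neighbors <- function(net, node) {
  stopifnot(inherits(net, "grn_network"))
  if (!node %in% net$nodes$id) stopf("node '%s' not in network", node)
  e <- net$edges
  nbrs <- unique(c(node, e$target[e$source == node], e$source[e$target == node]))
  keep_e <- e[e$source %in% nbrs & e$target %in% nbrs, , drop = FALSE]
  keep_n <- net$nodes[net$nodes$id %in% nbrs, , drop = FALSE]
  rownames(keep_e) <- rownames(keep_n) <- NULL
  grn_network(keep_e, keep_n)
}

#' Node overlap between two networks
#'
#' Because the denominator behind a "shared nodes" percentage is
#' ambiguous, the Jaccard index and both directional fractions are all
#' reported.
#'
#' @param net_a,net_b [grn_network()]s with non-empty node sets.
#' @return list (n_shared, jaccard, frac_of_a, frac_of_b).
#' @export
node_overlap <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "grn_network"), inherits(net_b, "grn_network"))
  a <- unique(net_a$nodes$id)
  b <- unique(net_b$nodes$id)
  if (!length(a) || !length(b)) stopf("networks must be non-empty")
  shared <- intersect(a, b)
  list(n_shared = length(shared),
       jaccard = length(shared) / length(union(a, b)),
       frac_of_a = length(shared) / length(a),
       frac_of_b = length(shared) / length(b))
}
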