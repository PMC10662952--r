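#' Combine normalised matrices with per-batch gene centring
#'
#' Restricts every batch to the shared gene set and subtracts each gene's
#' batch mean, removing additive batch effects while preserving
#' within-batch pairwise cell differences exactly.
#'
#' @param nms list of [normalize_log()] results; list names (or each
#'   matrix's timepoint metadata) identify the batches.
#' @param batch_labels optional character vector of batch names, one per
#'   matrix.
#' @return a `combined_matrix`: dense centred `values` (shared genes x all
#'   cells), `gene_ids`, `cell_ids`, per-cell `batch`, and row-bound
#'   metadata.
#' @export
center_by_batch <- function(nms, batch_labels = NULL) {
  stopifnot(length(nms) >= 1L,
            all(vapply(nms, inherits, TRUE, "normalized_matrix")))
  batch_labels <- batch_labels %||% names(nms) %||%
    vapply(nms, function(nm) nm$meta$timepoint[1], "")
  genes <- Reduce(intersect, lapply(nms, `[[`, "gene_ids"))
  if (!length(genes)) stopf("no shared genes between batches")
  parts <- lapply(nms, function(nm) {
    x <- as_dense(nm$values[genes, , drop = FALSE])
    x - rowMeans(x)
  })
  values <- do.call(cbind, parts)
  cells <- unlist(lapply(nms, `[[`, "cell_ids"), use.names = FALSE)
  if (anyDuplicated(cells)) stopf("cell ids collide across batches")
  colnames(values) <- cells
  batch <- rep(batch_labels, vapply(nms, function(nm) length(nm$cell_ids), 1L))
  meta <- do.call(rbind, lapply(nms, function(nm) nm$meta))
  rownames(meta) <- cells
  structure(list(values = values, gene_ids = genes, cell_ids = cells,
                 batch = setNames(batch, cells), meta = meta),
            class = "combined_matrix")
}

#' Joint embedding and clustering of integrated data
#'
#' PCA of the batch-centred matrix, followed by the shared-nearest-
#' neighbour graph and modularity clustering from the preprocessing stage.
#'
#' @param combined a [center_by_batch()] result.
#' @param n_components,k,resolution,seed as in [pca_embed()],
#'   [bimodal_knn_graph()] and [cluster_graph()].
#' @return `list(ca, embedding)`.
#' @export
joint_embed_cluster <- function(combined, n_components = 30, k = 20,
                                resolution = 1.0, seed = 1L) {
  stopifnot(inherits(combined, "combined_matrix"))
  x <- combined$values - rowMeans(combined$values)
  if (!any(is.finite(x))) stopf("combined matrix has no finite values")
  n_components <- min(n_components, min(dim(x)) - 1L)
  s <- partial_svd(t(x), n_components)
  o <- orient_svd(s$u, s$v)
  coords <- o$u %*% diag(s$d, n_components)
  rownames(coords) <- combined$cell_ids
  colnames(coords) <- paste0("PC", seq_len(n_components))
  loadings <- o$v
  rownames(loadings) <- combined$gene_ids
  emb <- new_embedding(coords, "integrated_pca",
                       explained_variance = s$d^2 / sum(x^2),
                       loadings = loadings, features = combined$gene_ids)
  g <- bimodal_knn_graph(emb, k = k, alpha = 1)
  ca <- cluster_graph(g, resolution = resolution, seed = seed)
  list(ca = ca, embedding = emb)
}

#' Contribution cross-tabulation of integrated clusters
#'
#' For every integrated cluster, the fraction of its cells originating
#' from each source group (e.g. timepoint, or timepoint x source cluster).
#'
#' @param ca integrated [cluster_assignment()].
#' @param source_labels character vector named by cell id.
#' @return a `contribution_table`: row-stochastic `fraction` matrix
#'   (clusters x sources) and the matching `counts`.
#' @export
contribution_table <- function(ca, source_labels) {
  stopifnot(inherits(ca, "cluster_assignment"))
  src <- source_labels[names(ca$cluster_of)]
  if (anyNA(src)) stopf("source labels missing for %d cells", sum(is.na(src)))
  counts <- table(cluster = ca$cluster_of, source = src)
  counts <- matrix(counts, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  fraction <- counts / rowSums(counts)
  structure(list(fraction = fraction, counts = counts),
            class = "contribution_table")
}

print.contribution_table <- function(x, ...) {
  cat("contribution_table (fractions):\n")
  print(round(x$fraction, 3))
  invisible(x)
}

#' Flag residual (earliest-timepoint-only) integrated clusters
#'
#' An integrated cluster dominated by the earliest timepoint indicates
#' cells whose profile matches no later cluster.
#'
#' @param ct a [contribution_table()] whose sources are timepoints.
#' @param earliest the earliest timepoint's column name.
#' @param rho dominance threshold.
#' @return character vector of flagged cluster ids.
#' @export
residual_cluster_detect <- function(ct, earliest, rho = 0.9) {
  stopifnot(inherits(ct, "contribution_table"))
  if (!earliest %in% colnames(ct$fraction)) {
    stopf("'%s' is not a source column", earliest)
  }
  rownames(ct$fraction)[ct$fraction[, earliest] >= rho]
}

#' Map query cells onto a labelled reference embedding
#'
#' Query expression is restricted to the genes shared with the reference
#' embedding's feature set, standardised with the reference centres and
#' scales, projected through the reference loadings, and each query cell
#' is labelled by majority vote of its `k` nearest reference cells
#' (Euclidean distance in the embedding). Deterministic: ties go to the
#' lexicographically smallest label and are flagged.
#'
#' @param ref_emb reference [pca_embed()] result (loadings retained).
#' @param ref_ca labelled reference [cluster_assignment()].
#' @param query_nm query [normalize_log()] result.
#' @param k reference neighbours per query cell.
#' @param min_genes minimum shared-gene floor.
#' @param clip cap for standardised query values (as in [pca_embed()]).
#' @return data.frame (cell_id, predicted, confidence, tie).
#' @export
reference_map <- function(ref_emb, ref_ca, query_nm, k = 15,
                          min_genes = 200, clip = 10) {
  stopifnot(inherits(ref_emb, "embedding"),
            inherits(ref_ca, "cluster_assignment"),
            inherits(query_nm, "normalized_matrix"))
  if (is.null(ref_emb$loadings)) stopf("reference embedding lacks loadings")
  genes <- intersect(ref_emb$features, query_nm$gene_ids)
  if (length(genes) < min_genes) {
    stopf("only %d shared genes (floor %d)", length(genes), min_genes)
  }
  sel <- match(genes, ref_emb$features)
  x <- as_dense(query_nm$values[genes, , drop = FALSE])
  if (!is.null(ref_emb$center)) x <- x - ref_emb$center[sel]
  if (!is.null(ref_emb$scale)) x <- x / ref_emb$scale[sel]
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  coords_q <- t(x) %*% ref_emb$loadings[sel, , drop = FALSE]

  ref_coords <- ref_emb$coords
  labels <- cluster_labels(ref_ca)[rownames(ref_coords)]
  # squared distances query x reference via the expansion trick
  d2 <- outer(rowSums(coords_q^2), rowSums(ref_coords^2), "+") -
    2 * coords_q %*% t(ref_coords)
  pred <- character(nrow(coords_q))
  conf <- numeric(nrow(coords_q))
  tie <- logical(nrow(coords_q))
  for (i in seq_len(nrow(coords_q))) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- sort(table(labels[nn]), decreasing = TRUE)
    winners <- sort(names(votes)[votes == votes[1]])
    pred[i] <- winners[1]
    conf[i] <- votes[1] / k
    tie[i] <- length(winners) > 1L
  }
  data.frame(cell_id = query_nm$cell_ids, predicted = pred,
             confidence = conf, tie = tie,
             row.names = NULL, stringsAsFactors = FALSE)
}
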