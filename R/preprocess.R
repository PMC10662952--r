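#' Quality-control thresholds
#'
#' Cells are retained when total RNA counts and total ATAC fragments are at
#' least their minima, the mitochondrial fraction is at most its maximum,
#' the nucleosome signal is at most 2 and the TSS enrichment at least 1
#' (defaults).
#'
#' @param min_total_counts,min_total_atac minimum per-cell totals.
#' @param max_pct_mito maximum mitochondrial fraction (0-1).
#' @param max_nucleosome,min_tss chromatin QC bounds.
#' @return a `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_total_counts = 100L, min_total_atac = 10L,
                          max_pct_mito = 0.25, max_nucleosome = 2,
                          min_tss = 1) {
  th <- list(min_total_counts = min_total_counts,
             min_total_atac = min_total_atac,
             max_pct_mito = max_pct_mito,
             max_nucleosome = max_nucleosome,
             min_tss = min_tss)
  if (anyNA(vapply(th, as.numeric, 1))) stopf("thresholds must not be NA")
  structure(th, class = "qc_thresholds")
}

#' Filter cells on QC covariates
#'
#' @param cm a [cell_matrix()] with populated metadata.
#' @param thresholds a [qc_thresholds()].
#' @return `list(cm, report)`: the filtered matrix and a report with
#'   per-criterion removal counts (a cell failing several criteria is
#'   counted under each).
#' @export
qc_filter <- function(cm, thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "cell_matrix"), inherits(thresholds, "qc_thresholds"))
  m <- cm$meta
  fail <- cbind(
    low_total_counts = m$total_counts < thresholds$min_total_counts,
    low_total_atac = m$total_atac < thresholds$min_total_atac,
    high_pct_mito = m$pct_mito > thresholds$max_pct_mito,
    high_nucleosome = m$nucleosome_signal > thresholds$max_nucleosome,
    low_tss = m$tss_enrichment < thresholds$min_tss)
  keep <- !apply(fail, 1L, any)
  if (!any(keep)) {
    stopf("qc_filter removed every cell; review the thresholds")
  }
  report <- list(n_input = length(keep), n_kept = sum(keep),
                 n_removed = sum(!keep),
                 removed_by_criterion = colSums(fail),
                 removed_cells = cm$cell_ids[!keep])
  list(cm = subset_cells(cm, cm$cell_ids[keep]), report = report)
}

#' Depth-normalised log transform
#'
#' `value = ln(1 + scale_factor * count / cell_total)`. Zeros map to zero
#' and the within-cell rank order of genes is preserved.
#'
#' @param cm a [cell_matrix()].
#' @param scale_factor target depth (default 1e4).
#' @return a `normalized_matrix`: sparse `values` (genes x cells) plus the
#'   source axes and per-cell metadata.
#' @export
normalize_log <- function(cm, scale_factor = 1e4) {
  stopifnot(inherits(cm, "cell_matrix"), scale_factor > 0)
  totals <- Matrix::colSums(cm$counts)
  if (any(totals == 0)) {
    stopf("cell '%s' has zero total counts; filter before normalising",
          cm$cell_ids[which(totals == 0)[1]])
  }
  v <- as(cm$counts, "CsparseMatrix")
  per_entry <- rep.int(totals, diff(v@p))
  v@x <- log1p(scale_factor * v@x / per_entry)
  structure(list(values = v, scale_factor = scale_factor,
                 gene_ids = cm$gene_ids, cell_ids = cm$cell_ids,
                 meta = cm$meta), class = "normalized_matrix")
}

print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d cells (scale %g)\n",
              length(x$gene_ids), length(x$cell_ids), x$scale_factor))
  invisible(x)
}

new_embedding <- function(coords, method, explained_variance = NULL,
                          loadings = NULL, center = NULL, scale = NULL,
                          features = NULL) {
  structure(list(coords = coords, method = method,
                 explained_variance = explained_variance,
                 loadings = loadings, center = center, scale = scale,
                 features = features), class = "embedding")
}

print.embedding <- function(x, ...) {
  cat(sprintf("embedding (%s): %d cells x %d dims\n", x$method,
              nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

# Orient each component so its largest-magnitude loading is positive.
orient_svd <- function(u, v) {
  flip <- vapply(seq_len(ncol(v)), function(j) {
    v[which.max(abs(v[, j])), j] < 0
  }, TRUE)
  u[, flip] <- -u[, flip, drop = FALSE]
  v[, flip] <- -v[, flip, drop = FALSE]
  list(u = u, v = v)
}

partial_svd <- function(x, n_components) {
  if (n_components >= min(dim(x)) - 1L || min(dim(x)) < 50L) {
    s <- svd(x, nu = n_components, nv = n_components)
    list(u = s$u, d = s$d[seq_len(n_components)], v = s$v)
  } else {
    # irlba's random initialisation is pinned so embeddings are reproducible
    s <- with_seed(760613L, irlba::irlba(x, nv = n_components))
    list(u = s$u, d = s$d, v = s$v)
  }
}

#' PCA embedding of normalised expression
#'
#' Selects the `n_hvg` most variable genes, centres and scales them (scaled
#' values clipped at `clip`), and computes a truncated PCA. Components are
#' ordered by decreasing explained variance and oriented so the
#' largest-magnitude gene loading is positive. Loadings, centres and scales
#' are retained so query data can be projected ([reference_map()]).
#'
#' @param nm a [normalize_log()] result.
#' @param n_components number of components.
#' @param n_hvg number of highly-variable genes to use.
#' @param clip cap for scaled values.
#' @return an `embedding`.
#' @export
pca_embed <- function(nm, n_components = 30, n_hvg = 2000, clip = 10) {
  stopifnot(inherits(nm, "normalized_matrix"))
  n_cells <- length(nm$cell_ids)
  if (n_components >= min(length(nm$gene_ids), n_cells)) {
    stopf("n_components must be below min(genes, cells)")
  }
  v <- nm$values
  means <- Matrix::rowMeans(v)
  vars <- Matrix::rowMeans(v^2) - means^2
  vars <- vars * n_cells / max(n_cells - 1, 1)
  if (all(vars < .Machine$double.eps)) stopf("matrix is constant; no variance")
  hvg <- order(vars, decreasing = TRUE)[seq_len(min(n_hvg, sum(vars > 0)))]
  x <- as_dense(v[hvg, , drop = FALSE])
  ctr <- means[hvg]
  scl <- sqrt(vars[hvg])
  x <- (x - ctr) / scl
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  s <- partial_svd(t(x), n_components)
  o <- orient_svd(s$u, s$v)
  coords <- o$u %*% diag(s$d, n_components)
  rownames(coords) <- nm$cell_ids
  colnames(coords) <- paste0("PC", seq_len(n_components))
  loadings <- o$v
  rownames(loadings) <- nm$gene_ids[hvg]
  ev <- s$d^2 / sum(x^2)
  new_embedding(coords, "pca", explained_variance = ev, loadings = loadings,
                center = ctr, scale = scl, features = nm$gene_ids[hvg])
}

#' Latent semantic indexing of chromatin accessibility
#'
#' TF-IDF weighting of the (by default binarised) peak matrix -- term
#' frequency per cell, log-scaled as `log1p(tf * 1e4)`, times
#' `log(1 + n_cells / document frequency)` -- followed by truncated SVD.
#' The first component tracks sequencing depth and is dropped by default.
#'
#' @param pd a [peak_data()].
#' @param n_components components returned (after any drop).
#' @param drop_first drop the depth-correlated first component.
#' @param binarize use peak presence/absence rather than fragment counts.
#' @return an `embedding`.
#' @export
lsi_embed <- function(pd, n_components = 30, drop_first = TRUE,
                      binarize = TRUE) {
  stopifnot(inherits(pd, "peak_data"))
  x <- as(pd$counts, "CsparseMatrix")
  if (binarize) x@x <- as.numeric(x@x > 0)
  keep <- Matrix::rowSums(x) > 0
  x <- x[keep, , drop = FALSE]
  n_cells <- ncol(x)
  n_comp_raw <- n_components + as.integer(drop_first)
  if (nrow(x) <= n_comp_raw) {
    stopf("only %d informative peaks for %d components", nrow(x), n_comp_raw)
  }
  totals <- Matrix::colSums(x)
  if (any(totals == 0)) stopf("cell '%s' has no accessible peaks",
                              pd$cell_ids[which(totals == 0)[1]])
  tf <- x %*% Matrix::Diagonal(x = 1 / totals)
  tf@x <- log1p(tf@x * 1e4)
  idf <- log(1 + n_cells / Matrix::rowSums(x > 0))
  xw <- Matrix::Diagonal(x = idf) %*% tf
  if (identical_columns(xw)) stopf("all cells are identical; no variance")
  s <- partial_svd(t(as_dense(xw)), n_comp_raw)
  o <- orient_svd(s$u, s$v)
  coords <- o$u %*% diag(s$d, n_comp_raw)
  ev <- s$d^2 / sum(xw^2)
  keep_dims <- if (drop_first) 2:n_comp_raw else 1:n_comp_raw
  coords <- coords[, keep_dims, drop = FALSE]
  rownames(coords) <- pd$cell_ids
  colnames(coords) <- paste0("LSI", seq_len(ncol(coords)))
  loadings <- o$v[, keep_dims, drop = FALSE]
  rownames(loadings) <- rownames(x)
  new_embedding(coords, "lsi", explained_variance = ev[keep_dims],
                loadings = loadings, features = rownames(x))
}

identical_columns <- function(m) {
  if (ncol(m) < 2L) return(FALSE)
  first <- m[, 1L]
  for (j in 2:ncol(m)) if (any(m[, j] != first)) return(FALSE)
  TRUE
}

euclidean_dist <- function(coords) {
  as.matrix(dist(coords))
}

zscale_dist <- function(d) {
  vals <- d[upper.tri(d)]
  s <- sd(vals)
  if (s == 0) return(d * 0)
  (d - mean(vals)) / s
}

#' Bimodal shared-nearest-neighbour graph
#'
#' Combines per-modality z-scaled Euclidean distances as
#' `alpha * d_rna + (1 - alpha) * d_atac` (RNA only when no chromatin
#' embedding is given), takes each cell's `k` nearest neighbours, and
#' weights edges by the Jaccard overlap of the two cells' neighbour sets
#' (each set includes the cell itself). The result is symmetric.
#'
#' @param emb_rna,emb_atac `embedding`s over the same cells (`emb_atac`
#'   optional).
#' @param k neighbours per cell.
#' @param alpha RNA weight in `[0, 1]`.
#' @return a `neighbor_graph` with an edge table `(i, j, weight)` indexed
#'   into `cell_ids`.
#' @export
bimodal_knn_graph <- function(emb_rna, emb_atac = NULL, k = 20, alpha = 0.5) {
  stopifnot(inherits(emb_rna, "embedding"))
  n <- nrow(emb_rna$coords)
  if (k >= n) stopf("k = %d but only %d cells", k, n)
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  d <- zscale_dist(euclidean_dist(emb_rna$coords))
  if (!is.null(emb_atac) && alpha < 1) {
    stopifnot(inherits(emb_atac, "embedding"))
    if (!identical(rownames(emb_rna$coords), rownames(emb_atac$coords))) {
      stopf("embeddings must share the cell axis")
    }
    d <- alpha * d + (1 - alpha) * zscale_dist(euclidean_dist(emb_atac$coords))
  }
  nn <- knn_from_dist(d, k)
  # shared-nearest-neighbour Jaccard weights; neighbour sets include self
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1L),
    j = as.vector(t(cbind(seq_len(n), nn))),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn))
  inter <- shared[cbind(ii, jj)]
  w <- inter / (2 * (k + 1L) - inter)
  lo <- pmin(ii, jj)
  hi <- pmax(ii, jj)
  key <- paste(lo, hi)
  keep <- !duplicated(key)
  edges <- data.frame(i = lo[keep], j = hi[keep], weight = w[keep])
  structure(list(k = k, alpha = alpha, edges = edges,
                 cell_ids = rownames(emb_rna$coords), n = n),
            class = "neighbor_graph")
}

knn_from_dist <- function(d, k) {
  n <- nrow(d)
  nn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    nn[i, ] <- ord[ord != i][seq_len(k)]
  }
  nn
}

print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d cells, k = %d, %d undirected edges\n",
              x$n, x$k, nrow(x$edges)))
  invisible(x)
}

#' Modularity clustering of the neighbour graph
#'
#' Weighted Louvain community detection; the partition is deterministic for
#' a fixed seed (tie-breaking is delegated to the seeded RNG).
#'
#' @param g a [bimodal_knn_graph()] result.
#' @param resolution modularity resolution (smaller = fewer clusters).
#' @param seed integer seed.
#' @return a `cluster_assignment`: per-cell cluster ids contiguous from 0,
#'   an optional id -> label map, and the resolution/seed used.
#' @export
cluster_graph <- function(g, resolution = 1.0, seed = 1L) {
  stopifnot(inherits(g, "neighbor_graph"))
  if (g$n == 0L) stopf("empty graph")
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(g$n)))
  comm <- with_seed(seed, igraph::cluster_louvain(
    ig, weights = g$edges$weight, resolution = resolution))
  member <- igraph::membership(comm)
  cluster <- as.integer(member[as.character(seq_len(g$n))]) - 1L
  cluster_assignment(setNames(cluster, g$cell_ids),
                     resolution = resolution, seed = seed)
}

#' Per-cell cluster assignment
#'
#' @param cluster_of named integer vector (cell id -> cluster id);
#'   ids are re-coded to be contiguous from 0.
#' @param labels optional named character vector mapping cluster id (as
#'   character) -> biological label.
#' @param resolution,seed provenance of the partition.
#' @return a `cluster_assignment`.
#' @export
cluster_assignment <- function(cluster_of, labels = NULL, resolution = NA,
                               seed = NA) {
  if (is.null(names(cluster_of))) stopf("cluster_of must be named by cell id")
  ids <- sort(unique(cluster_of))
  recoded <- setNames(match(cluster_of, ids) - 1L, names(cluster_of))
  if (!is.null(labels)) {
    labels <- setNames(unname(labels[as.character(ids)]),
                       as.character(seq_along(ids) - 1L))
  }
  structure(list(cluster_of = recoded, labels = labels,
                 resolution = resolution, seed = seed),
            class = "cluster_assignment")
}

print.cluster_assignment <- function(x, ...) {
  tab <- table(x$cluster_of)
  cat(sprintf("cluster_assignment: %d cells in %d clusters\n",
              length(x$cluster_of), length(tab)))
  if (!is.null(x$labels)) {
    cat("  labels:", paste(sprintf("%s=%s", names(x$labels), x$labels),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Per-cell biological labels of an assignment
#'
#' @param ca a [cluster_assignment()].
#' @return character vector named by cell id: the mapped label where one
#'   exists, otherwise the cluster id as character.
#' @export
cluster_labels <- function(ca) {
  stopifnot(inherits(ca, "cluster_assignment"))
  ids <- as.character(ca$cluster_of)
  if (!is.null(ca$labels)) {
    mapped <- ca$labels[ids]
    ids[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  setNames(ids, names(ca$cluster_of))
}

# indirection so sim_config's qc_thresholds argument can default cleanly
default_qc_thresholds <- function() qc_thresholds()
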