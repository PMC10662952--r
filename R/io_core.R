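#' @import Matrix
NULL

META_COLUMNS <- c("sample", "timepoint", "condition", "total_counts",
                  "pct_mito", "tss_enrichment", "nucleosome_signal",
                  "total_atac")

meta_default <- function(column, n_cells, counts = NULL) {
  switch(column,
    sample            = rep("sample1", n_cells),
    timepoint         = rep("NA", n_cells),
    condition         = rep("control", n_cells),
    total_counts      = if (is.null(counts)) rep(0L, n_cells) else
                          as.integer(round(Matrix::colSums(counts))),
    pct_mito          = rep(0, n_cells),
    tss_enrichment    = rep(Inf, n_cells),
    nucleosome_signal = rep(0, n_cells),
    total_atac        = rep(.Machine$integer.max, n_cells),
    stopf("unknown metadata column '%s'", column))
}

#' Gene-by-cell count container
#'
#' Bundles a sparse non-negative integer count matrix (genes in rows, cells
#' in columns) with one row of per-cell metadata per cell. Metadata columns
#' not supplied are filled with declared defaults and recorded in the
#' `defaulted` attribute so silent gaps stay visible.
#'
#' @param counts matrix or sparse Matrix of non-negative counts
#'   (genes x cells).
#' @param gene_ids,cell_ids unique identifier vectors matching the matrix
#'   dimensions. Taken from `dimnames(counts)` when omitted.
#' @param meta optional per-cell data.frame; rows are matched to `cell_ids`
#'   by a `cell_id` column when present, otherwise by order.
#' @return An object of class `cell_matrix` with elements `counts`
#'   (dgCMatrix), `gene_ids`, `cell_ids`, `meta` and attribute `defaulted`.
#' @export
cell_matrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts), meta = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stopf("gene_ids and cell_ids are required when counts has no dimnames")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    stopf("counts is %d x %d but %d gene ids and %d cell ids were given",
          nrow(counts), ncol(counts), length(gene_ids), length(cell_ids))
  }
  for (what in list(c("gene", "gene_ids"), c("cell", "cell_ids"))) {
    ids <- get(what[2])
    if (anyDuplicated(ids)) {
      stopf("duplicate %s ids: %s", what[1],
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }
  if (any(counts@x < 0) || any(!is.finite(counts@x))) {
    stopf("counts must be finite and non-negative")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  n <- length(cell_ids)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if ("cell_id" %in% names(meta)) {
      idx <- match(cell_ids, meta$cell_id)
      if (anyNA(idx)) stopf("meta is missing rows for %d cells", sum(is.na(idx)))
      meta <- meta[idx, setdiff(names(meta), "cell_id"), drop = FALSE]
    } else if (nrow(meta) != n) {
      stopf("meta has %d rows for %d cells", nrow(meta), n)
    }
  } else {
    meta <- data.frame(row.names = seq_len(n))
  }
  defaulted <- setdiff(META_COLUMNS, names(meta))
  for (col in defaulted) meta[[col]] <- meta_default(col, n, counts)
  meta <- meta[, META_COLUMNS, drop = FALSE]
  rownames(meta) <- cell_ids
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 meta = meta),
            defaulted = defaulted, class = "cell_matrix")
}

print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (%d nonzero counts)\n",
              length(x$gene_ids), length(x$cell_ids),
              Matrix::nnzero(x$counts)))
  cat(sprintf("  timepoints: %s | conditions: %s\n",
              paste(unique(x$meta$timepoint), collapse = ", "),
              paste(unique(x$meta$condition), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell_matrix by cell ids
#'
#' @param cm a [cell_matrix()].
#' @param cells character vector of cell ids (or logical/integer index).
#' @return a `cell_matrix` restricted to the selected cells.
#' @export
subset_cells <- function(cm, cells) {
  if (is.character(cells)) {
    missing <- setdiff(cells, cm$cell_ids)
    if (length(missing)) stopf("unknown cell ids: %s",
                               paste(head(missing, 5), collapse = ", "))
  }
  counts <- cm$counts[, cells, drop = FALSE]
  meta <- cm$meta[colnames(counts), , drop = FALSE]
  meta$cell_id <- rownames(meta)
  cell_matrix(counts, meta = meta)
}

#' Peak-by-cell accessibility container
#'
#' @param counts sparse non-negative matrix (peaks x cells).
#' @param peaks data.frame with columns `chrom`, `start`, `end`
#'   (0-based, half-open) and optionally `peak_id`.
#' @param cell_ids unique cell identifiers.
#' @param motif_membership binary (peaks x motifs) matrix; values > 0 are
#'   binarised to 1 with a warning when the input is not already 0/1.
#' @param motif_ids unique motif identifiers.
#' @return An object of class `peak_data`.
#' @export
peak_data <- function(counts, peaks, cell_ids = colnames(counts),
                      motif_membership, motif_ids = colnames(motif_membership)) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  }
  if (nrow(peaks) != nrow(counts)) {
    stopf("%d peaks for a %d-row count matrix", nrow(peaks), nrow(counts))
  }
  bad <- which(peaks$start >= peaks$end)
  if (length(bad)) stopf("peak %d has start >= end (%d >= %d)",
                         bad[1], peaks$start[bad[1]], peaks$end[bad[1]])
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stopf("duplicate cell ids")
  membership <- as(as(motif_membership, "CsparseMatrix"), "dMatrix")
  if (nrow(membership) != nrow(counts)) {
    stopf("membership has %d peak rows, counts has %d",
          nrow(membership), nrow(counts))
  }
  if (any(membership@x != 0 & membership@x != 1)) {
    warnf("non-binary motif membership values binarised to {0,1}")
    membership@x <- as.numeric(membership@x > 0)
    membership <- Matrix::drop0(membership)
  }
  motif_ids <- as.character(motif_ids %||% sprintf("M%03d", seq_len(ncol(membership))))
  dimnames(counts) <- list(peaks$peak_id, cell_ids)
  dimnames(membership) <- list(peaks$peak_id, motif_ids)
  structure(list(counts = counts, peaks = peaks, cell_ids = cell_ids,
                 motif_membership = membership, motif_ids = motif_ids),
            class = "peak_data")
}

print.peak_data <- function(x, ...) {
  cat(sprintf("peak_data: %d peaks x %d cells, %d motifs\n",
              nrow(x$counts), ncol(x$counts), length(x$motif_ids)))
  invisible(x)
}

#' Directed TF-to-target network
#'
#' @param edges data.frame with columns `source`, `target`, `weight`,
#'   `sign` (`"+"` or `"-"`). Sources are taken to be transcription factors.
#' @param nodes optional data.frame with columns `id`, `kind`
#'   (`"TF"`/`"gene"`); inferred from the edges when omitted.
#' @return object of class `grn_network`.
#' @export
grn_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target", "weight", "sign") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  edges$sign <- as.character(edges$sign)
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stopf("duplicate edge %s -> %s", sub("\r.*", "", d), sub(".*\r", "", d))
  }
  if (any(!is.finite(edges$weight))) stopf("edge weights must be finite")
  if (!all(edges$sign %in% c("+", "-"))) stopf("edge sign must be '+' or '-'")
  rownames(edges) <- NULL
  if (is.null(nodes)) {
    tf <- unique(edges$source)
    gene <- setdiff(unique(edges$target), tf)
    nodes <- data.frame(id = c(tf, gene),
                        kind = c(rep("TF", length(tf)),
                                 rep("gene", length(gene))),
                        stringsAsFactors = FALSE)
  } else {
    nodes <- as.data.frame(nodes)
    missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(missing)) stopf("edge endpoints missing from nodes: %s",
                               paste(head(missing, 5), collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges), class = "grn_network")
}

print.grn_network <- function(x, ...) {
  cat(sprintf("grn_network: %d nodes (%d TFs), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "TF"), nrow(x$edges)))
  invisible(x)
}

read_id_file <- function(path, what) {
  lines <- readLines(path)
  if (!length(lines)) return(character(0))
  ids <- read.table(text = lines, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)[[1]]
  if (anyDuplicated(ids)) {
    stopf("duplicate %s ids in %s: %s", what, path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  as.character(ids)
}

#' Read a cell matrix from Matrix Market triplet files
#'
#' Reads `matrix.mtx` alongside one-id-per-line feature and barcode files
#' (10x-style triplet layout) plus an optional tab-separated metadata table.
#'
#' @param matrix_path Matrix Market coordinate file (genes x cells).
#' @param features_path,barcodes_path one id per line.
#' @param meta_path optional TSV with a header and a `cell_id` column.
#' @return a [cell_matrix()]; the load report (defaulted metadata columns,
#'   dimensions) is in `attr(, "load_report")`.
#' @export
read_cell_matrix <- function(matrix_path, features_path, barcodes_path,
                             meta_path = NULL) {
  m <- Matrix::readMM(matrix_path)
  genes <- read_id_file(features_path, "gene")
  cells <- read_id_file(barcodes_path, "cell")
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stopf(paste0("dimension mismatch: matrix is %d x %d but there are ",
                 "%d features and %d barcodes"),
          nrow(m), ncol(m), length(genes), length(cells))
  }
  meta <- if (!is.null(meta_path)) {
    read.table(meta_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  cm <- cell_matrix(m, genes, cells, meta)
  attr(cm, "load_report") <- list(
    n_genes = length(genes), n_cells = length(cells),
    n_nonzero = Matrix::nnzero(cm$counts),
    defaulted_meta_columns = attr(cm, "defaulted"))
  cm
}

#' Write a cell matrix as Matrix Market triplet files
#'
#' Emits `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `meta.tsv` into
#' `out_dir`; [read_cell_matrix()] on the output reproduces the input
#' exactly.
#'
#' @param cm a [cell_matrix()].
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_cell_matrix <- function(cm, out_dir) {
  stopifnot(inherits(cm, "cell_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                                "meta.tsv"))
  Matrix::writeMM(cm$counts, paths[1])
  writeLines(cm$gene_ids, paths[2])
  writeLines(cm$cell_ids, paths[3])
  meta <- cbind(cell_id = cm$cell_ids, cm$meta)
  write.table(meta, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

read_bed3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- vapply(parts, length, 1L)
  if (any(n_col < 3)) stopf("BED line %d has fewer than 3 fields",
                            which(n_col < 3)[1])
  peaks <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 2L)),
    end = as.integer(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  bad <- which(peaks$start >= peaks$end)
  if (length(bad)) stopf("BED line %d: start >= end (%d >= %d)",
                         bad[1], peaks$start[bad[1]], peaks$end[bad[1]])
  peaks
}

read_membership <- function(path, n_peaks) {
  first <- readLines(path, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    m <- Matrix::readMM(path)
    if (nrow(m) != n_peaks) {
      stopf("membership has %d peak rows for %d peaks", nrow(m), n_peaks)
    }
    return(m)
  }
  # triplet TSV: peak_index (1-based), motif_id, value
  trip <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE,
                     col.names = c("peak_index", "motif_id", "value"))
  if (any(trip$peak_index < 1 | trip$peak_index > n_peaks)) {
    stopf("membership references unknown peak index %d",
          trip$peak_index[which(trip$peak_index < 1 |
                                trip$peak_index > n_peaks)[1]])
  }
  motifs <- sort(unique(trip$motif_id))
  Matrix::sparseMatrix(i = trip$peak_index,
                       j = match(trip$motif_id, motifs),
                       x = as.numeric(trip$value),
                       dims = c(n_peaks, length(motifs)),
                       dimnames = list(NULL, motifs))
}

#' Read peak accessibility data
#'
#' @param matrix_path Matrix Market file of fragment counts (peaks x cells).
#' @param peaks_bed_path BED3+ file (0-based, half-open) in matrix row order.
#' @param barcodes_path one cell id per line.
#' @param membership_path motif membership, Matrix Market (peaks x motifs)
#'   or triplet TSV `(peak_index, motif_id, value)`.
#' @return a [peak_data()].
#' @export
read_peak_data <- function(matrix_path, peaks_bed_path, barcodes_path,
                           membership_path) {
  m <- Matrix::readMM(matrix_path)
  peaks <- read_bed3(peaks_bed_path)
  cells <- read_id_file(barcodes_path, "cell")
  if (nrow(m) != nrow(peaks) || ncol(m) != length(cells)) {
    stopf("dimension mismatch: matrix %d x %d, %d peaks, %d barcodes",
          nrow(m), ncol(m), nrow(peaks), length(cells))
  }
  membership <- read_membership(membership_path, nrow(peaks))
  peak_data(m, peaks, cells, membership)
}

#' Write peak accessibility data
#'
#' @param pd a [peak_data()].
#' @param out_dir output directory.
#' @return invisibly, the paths written.
#' @export
write_peak_data <- function(pd, out_dir) {
  stopifnot(inherits(pd, "peak_data"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("atac_matrix.mtx", "peaks.bed",
                                "atac_barcodes.tsv", "membership.mtx",
                                "motifs.tsv"))
  Matrix::writeMM(pd$counts, paths[1])
  write.table(pd$peaks[, c("chrom", "start", "end")], paths[2],
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(pd$cell_ids, paths[3])
  Matrix::writeMM(pd$motif_membership, paths[4])
  writeLines(pd$motif_ids, paths[5])
  invisible(paths)
}

#' Read a TF-target network from an edge-list TSV
#'
#' @param path TSV with header columns `source`, `target`, `weight`, `sign`.
#' @return a [grn_network()].
#' @export
read_network <- function(path) {
  edges <- read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  grn_network(edges)
}

#' Write a TF-target network as an edge-list TSV
#'
#' @param net a [grn_network()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "grn_network"))
  write.table(net$edges[, c("source", "target", "weight", "sign")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
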