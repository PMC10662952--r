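#' Control-vs-treated cluster composition
#'
#' Cell counts per cluster and condition, converted to within-condition
#' proportions (normalising for different sample sizes) and their ratio.
#'
#' @param ca a [cluster_assignment()] (labels used when present).
#' @param condition character vector named by cell id
#'   (`"control"`/`"treated"`).
#' @return a `composition_result` data.frame with columns cluster,
#'   n_control, n_treated, prop_control, prop_treated, ratio
#'   (`Inf` when a cluster is absent from controls).
#' @export
cluster_composition <- function(ca, condition) {
  stopifnot(inherits(ca, "cluster_assignment"))
  labels <- cluster_labels(ca)
  cond <- condition[names(labels)]
  if (anyNA(cond)) stopf("condition missing for %d cells", sum(is.na(cond)))
  for (lev in c("control", "treated")) {
    if (!any(cond == lev)) stopf("no cells with condition '%s'", lev)
  }
  clusters <- sort(unique(labels))
  n_ctrl <- vapply(clusters, function(l) sum(labels == l & cond == "control"), 1L)
  n_trt <- vapply(clusters, function(l) sum(labels == l & cond == "treated"), 1L)
  prop_ctrl <- n_ctrl / sum(n_ctrl)
  prop_trt <- n_trt / sum(n_trt)
  res <- data.frame(cluster = clusters, n_control = n_ctrl,
                    n_treated = n_trt, prop_control = prop_ctrl,
                    prop_treated = prop_trt,
                    ratio = ifelse(prop_ctrl == 0, Inf,
                                   prop_trt / prop_ctrl),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("composition_result", "data.frame")
  res
}

#' Call clusters missing from the treated condition
#'
#' Flags clusters that are well represented in controls
#' (`prop_control >= min_control_prop`) but essentially absent from the
#' treated sample (`prop_treated < epsilon`).
#'
#' @param cr a [cluster_composition()] result.
#' @param min_control_prop control-representation floor.
#' @param epsilon treated-proportion ceiling.
#' @return character vector of flagged cluster labels.
#' @export
missing_cluster_call <- function(cr, min_control_prop = 0.02,
                                 epsilon = 0.001) {
  stopifnot(inherits(cr, "composition_result"))
  cr$cluster[cr$prop_control >= min_control_prop &
             cr$prop_treated < epsilon]
}

#' Per-cluster treated-vs-control differential expression
#'
#' Within each cluster having at least 3 cells per condition, every gene
#' is tested treated vs control with the rank-sum test; fold changes are
#' computed on `expm1` means with pseudocount 1. A gene is reported when
#' `|log2fc| >= log2(fc_threshold)` and the raw p-value is below
#' `p_threshold` (the raw threshold is the headline filter; BH-adjusted
#' p-values are emitted alongside for audit).
#'
#' @param nm a [normalize_log()] result covering both conditions.
#' @param ca a [cluster_assignment()].
#' @param condition character vector named by cell id.
#' @param fc_threshold fold-change threshold (linear scale).
#' @param p_threshold raw p-value threshold.
#' @return `list(hits, stats)`: `hits` is a named list cluster -> data
#'   frame of passing genes; `stats` holds all tested genes.
#' @export
condition_de <- function(nm, ca, condition, fc_threshold = 2.0,
                         p_threshold = 1e-5) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(ca, "cluster_assignment"))
  labels <- cluster_labels(ca)[nm$cell_ids]
  cond <- condition[nm$cell_ids]
  if (anyNA(labels) || anyNA(cond)) stopf("labels/condition missing for cells")
  ev <- nm$values
  ev@x <- expm1(ev@x)
  stats_out <- list()
  hits <- list()
  for (l in sort(unique(labels))) {
    cells <- which(labels == l)
    trt <- cond[cells] == "treated"
    if (sum(trt) < 3L || sum(!trt) < 3L) {
      warnf("cluster %s: fewer than 3 cells in a condition; skipped", l)
      next
    }
    vals <- as_dense(nm$values[, cells, drop = FALSE])
    p <- rank_sum_p(vals, trt)
    mean_trt <- Matrix::rowSums(ev[, cells[trt], drop = FALSE]) / sum(trt)
    mean_ctl <- Matrix::rowSums(ev[, cells[!trt], drop = FALSE]) / sum(!trt)
    lfc <- log2fc_expm1(mean_trt, mean_ctl)
    d <- data.frame(cluster = l, gene = nm$gene_ids, log2fc = lfc,
                    p_value = p, p_adj = p.adjust(p, "BH"),
                    mean_treated = mean_trt, mean_control = mean_ctl,
                    row.names = NULL, stringsAsFactors = FALSE)
    stats_out[[l]] <- d
    pass <- abs(d$log2fc) >= log2(fc_threshold) & d$p_value < p_threshold
    hits[[l]] <- d[pass, , drop = FALSE]
  }
  list(hits = hits, stats = do.call(rbind, c(stats_out,
                                             list(make.row.names = FALSE))))
}

#' Summarise per-cluster differential-expression hits
#'
#' Reports, per cluster, the number of passing genes and the number after
#' removing genes shared with any other cluster's list (both counts are
#' informative when responses are broadly shared across clusters).
#'
#' @param de a [condition_de()] result.
#' @return data.frame (cluster, n_de, n_de_unique).
#' @export
condition_de_summary <- function(de) {
  gene_lists <- lapply(de$hits, `[[`, "gene")
  all_genes <- unlist(gene_lists, use.names = FALSE)
  shared <- unique(all_genes[duplicated(all_genes)])
  data.frame(
    cluster = names(gene_lists),
    n_de = vapply(gene_lists, length, 1L),
    n_de_unique = vapply(gene_lists, function(g)
      sum(!g %in% shared), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}
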