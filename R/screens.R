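#' Flag expressed (detected) genes per cell
#'
#' A gene counts as expressed in a cell when its normalised value is
#' strictly greater than `threshold` (default 0, so exactly the cells with
#' a nonzero count).
#'
#' @param nm a [normalize_log()] result (or a [cell_matrix()], in which
#'   case raw counts are thresholded).
#' @param threshold strict lower bound.
#' @return sparse 0/1 matrix (genes x cells).
#' @export
flag_expressed <- function(nm, threshold = 0) {
  v <- if (inherits(nm, "normalized_matrix")) nm$values
       else if (inherits(nm, "cell_matrix")) nm$counts
       else stopf("flag_expressed needs a normalized_matrix or cell_matrix")
  f <- as(v, "CsparseMatrix")
  f@x <- as.numeric(f@x > threshold)
  Matrix::drop0(f)
}

rhombomere_summaries <- function(nm, ca) {
  labels <- cluster_labels(ca)[nm$cell_ids]
  rh <- paste0("r", 1:6)
  missing <- setdiff(rh, labels)
  if (length(missing)) stopf("missing rhombomere label(s): %s",
                             paste(missing, collapse = ", "))
  ind <- vapply(rh, function(l) labels == l, logical(length(labels)))
  sizes <- colSums(ind)
  det <- flag_expressed(nm)
  means <- as_dense(nm$values %*% ind) %*% diag(1 / sizes, 6)
  fracs <- as_dense(det %*% ind) %*% diag(1 / sizes, 6)
  dimnames(means) <- dimnames(fracs) <- list(nm$gene_ids, rh)
  list(means = means, fracs = fracs)
}

#' Odd/even rhombomere periodicity screen
#'
#' A gene is even-patterned when it is detected in at least `min_frac` of
#' cells in each of r2, r4 and r6 and the mean of those three cluster means
#' exceeds the mean of the r1/r3/r5 cluster means (odd-patterned is the
#' mirror image). With `strict = TRUE` the aggregate comparison is replaced
#' by per-rhombomere dominance (every even mean above every odd mean).
#'
#' @param nm a [normalize_log()] result.
#' @param ca a [cluster_assignment()] whose labels include r1..r6.
#' @param min_frac detection floor defining "expressed in" a rhombomere.
#' @param strict use the per-rhombomere dominance variant.
#' @return a `periodicity_result`: `even_genes` / `odd_genes` (flagged ids)
#'   and a per-gene `stats` table (means and detection fractions per
#'   rhombomere, aggregate means, flags).
#' @export
periodicity_screen <- function(nm, ca, min_frac = 0.1, strict = FALSE) {
  s <- rhombomere_summaries(nm, ca)
  even <- c("r2", "r4", "r6")
  odd <- c("r1", "r3", "r5")
  mean_even <- rowMeans(s$means[, even])
  mean_odd <- rowMeans(s$means[, odd])
  det_even <- apply(s$fracs[, even] >= min_frac, 1L, all)
  det_odd <- apply(s$fracs[, odd] >= min_frac, 1L, all)
  if (strict) {
    gt_even <- apply(s$means[, even], 1L, min) > apply(s$means[, odd], 1L, max)
    gt_odd <- apply(s$means[, odd], 1L, min) > apply(s$means[, even], 1L, max)
  } else {
    gt_even <- mean_even > mean_odd
    gt_odd <- mean_odd > mean_even
  }
  flag_even <- det_even & gt_even
  flag_odd <- det_odd & gt_odd
  stats <- data.frame(gene = nm$gene_ids, mean_even = mean_even,
                      mean_odd = mean_odd, flag_even = flag_even,
                      flag_odd = flag_odd, stringsAsFactors = FALSE)
  stats <- cbind(stats, s$means, setNames(as.data.frame(s$fracs),
                                          paste0("det_", colnames(s$fracs))))
  structure(list(even_genes = nm$gene_ids[flag_even],
                 odd_genes = nm$gene_ids[flag_odd],
                 min_frac = min_frac, strict = strict, stats = stats),
            class = "periodicity_result")
}

print.periodicity_result <- function(x, ...) {
  cat(sprintf("periodicity screen: %d even-patterned, %d odd-patterned genes\n",
              length(x$even_genes), length(x$odd_genes)))
  invisible(x)
}

#' Adjacent-pair co-expression screen
#'
#' Flags genes detected in at least `min_frac` of cells of both named
#' rhombomeres whose smaller of the two pair means is at least `fold`
#' times the largest mean among the other four rhombomeres.
#'
#' @param nm a [normalize_log()] result.
#' @param ca labelled [cluster_assignment()] including r1..r6.
#' @param pair character vector of two adjacent rhombomere labels.
#' @param min_frac detection floor.
#' @param fold exclusivity fold versus the other rhombomeres.
#' @return data.frame of flagged genes with their statistics.
#' @export
pair_screen <- function(nm, ca, pair, min_frac = 0.1, fold = 2.0) {
  if (length(pair) != 2L || pair[1] == pair[2]) {
    stopf("pair must name two distinct rhombomeres")
  }
  s <- rhombomere_summaries(nm, ca)
  others <- setdiff(colnames(s$means), pair)
  min_pair <- pmin(s$means[, pair[1]], s$means[, pair[2]])
  max_other <- apply(s$means[, others], 1L, max)
  detected <- s$fracs[, pair[1]] >= min_frac & s$fracs[, pair[2]] >= min_frac
  flagged <- detected & min_pair >= fold * max_other
  data.frame(gene = nm$gene_ids[flagged],
             mean_a = s$means[flagged, pair[1]],
             mean_b = s$means[flagged, pair[2]],
             max_other = max_other[flagged],
             det_a = s$fracs[flagged, pair[1]],
             det_b = s$fracs[flagged, pair[2]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the pair screen over all five adjacent rhombomere pairs
#'
#' @inheritParams pair_screen
#' @return named list `"r1|r2"` ... `"r5|r6"` of [pair_screen()] tables.
#' @export
pair_screen_all <- function(nm, ca, min_frac = 0.1, fold = 2.0) {
  rh <- paste0("r", 1:6)
  pairs <- Map(c, rh[1:5], rh[2:6])
  out <- lapply(pairs, function(p) pair_screen(nm, ca, p, min_frac, fold))
  names(out) <- paste(rh[1:5], rh[2:6], sep = "|")
  out
}

#' Per-cell co-expression statistics for an anchor gene
#'
#' Within a cell subset, counts the anchor-positive cells and, for each
#' target gene, the percentage of them that are also target-positive, plus
#' the percentage positive for any target (`pct_either`). Because the
#' choice of denominator can be ambiguous, percentages over all subset
#' cells are reported alongside the anchor-positive denominators.
#'
#' @param flags binary detection matrix from [flag_expressed()].
#' @param anchor anchor gene id.
#' @param targets character vector of target gene ids.
#' @param cells optional cell ids restricting the subset (default: all).
#' @return a `coexpr_result`: n_cells, n_anchor, per-target table
#'   (n_both, pct, pct_of_all), n_either, pct_either and `undefined`
#'   (TRUE when no anchor-positive cells exist; percentages are then NA).
#' @export
coexpression_stats <- function(flags, anchor, targets, cells = NULL) {
  if (!anchor %in% rownames(flags)) stopf("anchor '%s' not found", anchor)
  missing <- setdiff(targets, rownames(flags))
  if (length(missing)) stopf("target(s) not found: %s",
                             paste(missing, collapse = ", "))
  if (!is.null(cells)) flags <- flags[, cells, drop = FALSE]
  n_cells <- ncol(flags)
  a <- as.vector(flags[anchor, ]) > 0
  n_anchor <- sum(a)
  tmat <- as_dense(flags[targets, , drop = FALSE]) > 0
  n_both <- as.vector(tmat %*% a)
  either <- colSums(tmat) > 0
  n_either <- sum(either & a)
  undefined <- n_anchor == 0L
  pct <- if (undefined) rep(NA_real_, length(targets)) else
    100 * n_both / n_anchor
  structure(list(
    anchor = anchor, n_cells = n_cells, n_anchor = n_anchor,
    targets = data.frame(target = targets, n_both = n_both, pct = pct,
                         pct_of_all = 100 * n_both / n_cells,
                         stringsAsFactors = FALSE),
    n_either = n_either,
    pct_either = if (undefined) NA_real_ else 100 * n_either / n_anchor,
    pct_either_of_all = 100 * n_either / n_cells,
    undefined = undefined), class = "coexpr_result")
}

print.coexpr_result <- function(x, ...) {
  cat(sprintf("coexpression: anchor %s positive in %d/%d cells\n",
              x$anchor, x$n_anchor, x$n_cells))
  for (i in seq_len(nrow(x$targets))) {
    cat(sprintf("  %s: %d co-positive (%.1f%% of anchor+)\n",
                x$targets$target[i], x$targets$n_both[i], x$targets$pct[i]))
  }
  cat(sprintf("  any target: %.1f%%\n", x$pct_either))
  invisible(x)
}
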