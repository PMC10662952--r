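#' Simulation configuration for synthetic hindbrain multiome data
#'
#' Describes a multi-timepoint synthetic study: cluster structure with
#' planted marker panels, negative-binomial RNA counts with lognormal
#' library-size factors, per-cell mixed-identity (co-expression) programs,
#' progenitor-to-rhombomere lineages, dorsoventral covariate genes, planted
#' odd/even-periodic and adjacent-pair genes, cluster-restricted chromatin
#' accessibility with planted motif enrichments, and QC covariates with a
#' planted failure fraction.
#'
#' @param n_genes,n_peaks,n_motifs feature-space sizes.
#' @param timepoints list of timepoints, each
#'   `list(name, clusters = list(list(label, n_cells, marker_genes,
#'   marker_log2fc, fate_labels, mix_fraction)))`. `fate_labels` names
#'   descendant clusters (defined at a later timepoint) whose panels a
#'   progenitor cell can express: each cell commits to one primary fate
#'   (uniform) expressed at full strength, and activates each remaining
#'   descendant panel independently with probability `mix_fraction`.
#' @param baseline_mean mean count of a non-marker gene at size factor 1.
#' @param nb_dispersion negative-binomial size parameter (smaller = noisier).
#' @param libsize_meanlog,libsize_sdlog lognormal cell size-factor
#'   parameters.
#' @param coexpression list of
#'   `list(cluster_label, secondary_panels = list(list(name, genes,
#'   fraction, log2fc)))`; each listed panel is activated independently per
#'   cell of that cluster with probability `fraction` (whole-panel
#'   activation).
#' @param lineage_map named list progenitor label -> descendant labels;
#'   must agree with the clusters' `fate_labels`.
#' @param dv_genes,dv_amplitude indices of dorsoventral covariate genes and
#'   the log-scale amplitude of their within-cluster gradient (each cell
#'   draws a uniform axis coordinate).
#' @param periodic_planted `list(even_genes, odd_genes, pair_genes,
#'   base_mean, log2fc)`: planted screen targets. Even/odd genes have mean
#'   `base_mean` in all rhombomere clusters and `base_mean * 2^log2fc` in
#'   the even (r2/r4/r6) or odd (r1/r3/r5) ones; `pair_genes` is a named
#'   list `"rA|rB" -> gene indices` expressed at `base_mean * 2^log2fc` in
#'   the two named clusters only.
#' @param atac `list(p_open_in, p_open_out, frag_mean, cluster_peaks,
#'   motif_assignment, planted_motif_enrichment, enrichment_boost)`:
#'   cluster-restricted accessibility (Bernoulli open gate times Poisson
#'   fragment count) and planted motif enrichments
#'   (`list(list(motif, cluster))`, multiplying the open probability of the
#'   motif's peaks by `enrichment_boost` in that cluster's cells).
#' @param qc_fail_fraction fraction of cells planted to violate one QC
#'   threshold (mitochondrial fraction, nucleosome signal or TSS
#'   enrichment, chosen uniformly).
#' @param qc_thresholds a [qc_thresholds()] object the planted failures are
#'   defined against.
#' @param core_overlap multiplier in (0, 1] applied to a progenitor
#'   cluster's own (core) marker log2 fold change; controls how strongly
#'   progenitor cells differ from their descendants and hence how hard
#'   cross-timepoint integration is.
#' @param gene_aliases,motif_aliases named character vectors mapping
#'   feature index -> readable id (e.g. gene 25 -> "egr2b").
#' @return a `sim_config` object (validated list).
#' @export
sim_config <- function(n_genes, n_peaks, n_motifs, timepoints,
                       baseline_mean = 0.5, nb_dispersion = 2,
                       libsize_meanlog = 0, libsize_sdlog = 0.3,
                       coexpression = list(), lineage_map = list(),
                       dv_genes = integer(0), dv_amplitude = 0.5,
                       periodic_planted = list(even_genes = integer(0),
                                               odd_genes = integer(0),
                                               pair_genes = list(),
                                               base_mean = 0.5, log2fc = 2),
                       atac = list(), qc_fail_fraction = 0.05,
                       qc_thresholds = NULL,
                       core_overlap = 0.5,
                       gene_aliases = character(0),
                       motif_aliases = character(0)) {
  if (!length(timepoints)) stopf("at least one timepoint is required")
  atac_defaults <- list(p_open_in = 0.35, p_open_out = 0.03, frag_mean = 2,
                        depth_sdlog = 0.5, cluster_peaks = list(),
                        motif_assignment = list(),
                        planted_motif_enrichment = list(),
                        enrichment_boost = 3)
  atac <- utils::modifyList(atac_defaults, atac)
  pp_defaults <- list(even_genes = integer(0), odd_genes = integer(0),
                      pair_genes = list(), base_mean = 0.5, log2fc = 2)
  periodic_planted <- utils::modifyList(pp_defaults, periodic_planted)
  qc_thresholds <- qc_thresholds %||% default_qc_thresholds()
  cfg <- structure(list(
    n_genes = as.integer(n_genes), n_peaks = as.integer(n_peaks),
    n_motifs = as.integer(n_motifs), timepoints = timepoints,
    baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
    libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
    coexpression = coexpression, lineage_map = lineage_map,
    dv_genes = as.integer(dv_genes), dv_amplitude = dv_amplitude,
    periodic_planted = periodic_planted, atac = atac,
    qc_fail_fraction = qc_fail_fraction, qc_thresholds = qc_thresholds,
    core_overlap = core_overlap, gene_aliases = gene_aliases,
    motif_aliases = motif_aliases), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  all_labels <- character(0)
  for (tp in cfg$timepoints) {
    if (is.null(tp$name)) stopf("every timepoint needs a name")
    if (!length(tp$clusters)) stopf("timepoint '%s' has no clusters", tp$name)
    for (cl in tp$clusters) {
      if (is.null(cl$label) || is.null(cl$n_cells)) {
        stopf("clusters need label and n_cells")
      }
      if (length(cl$marker_genes) &&
          (max(cl$marker_genes) > cfg$n_genes || min(cl$marker_genes) < 1)) {
        stopf("cluster '%s' marker index out of range", cl$label)
      }
      all_labels <- c(all_labels, cl$label)
    }
  }
  for (prog in names(cfg$lineage_map)) {
    unknown <- setdiff(cfg$lineage_map[[prog]], all_labels)
    if (length(unknown)) {
      stopf("lineage for '%s' references unknown labels: %s", prog,
            paste(unknown, collapse = ", "))
    }
    if (!prog %in% all_labels) stopf("lineage progenitor '%s' is not a cluster",
                                     prog)
  }
  for (co in cfg$coexpression) {
    for (p in co$secondary_panels) {
      if (p$fraction < 0 || p$fraction > 1) {
        stopf("co-expression fractions must lie in [0,1]")
      }
    }
  }
  if (cfg$qc_fail_fraction < 0 || cfg$qc_fail_fraction > 1) {
    stopf("qc_fail_fraction must lie in [0,1]")
  }
  if (cfg$atac$p_open_in <= cfg$atac$p_open_out) {
    warnf("p_open_in <= p_open_out: accessibility signal is inverted")
  }
  for (cp in cfg$atac$cluster_peaks) {
    if (length(cp) && (max(cp) > cfg$n_peaks || min(cp) < 1)) {
      stopf("cluster peak index out of range")
    }
  }
  invisible(cfg)
}

print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d peaks, %d motifs, %d timepoint(s)\n",
              x$n_genes, x$n_peaks, x$n_motifs, length(x$timepoints)))
  for (tp in x$timepoints) {
    cat(sprintf("  %s: %s\n", tp$name,
                paste(vapply(tp$clusters, function(cl)
                  sprintf("%s(%d)", cl$label, cl$n_cells), ""),
                  collapse = " ")))
  }
  invisible(x)
}

feature_ids <- function(prefix, n, aliases, width = 4L) {
  ids <- sprintf(paste0("%s%0", width, "d"), prefix, seq_len(n))
  if (length(aliases)) ids[as.integer(names(aliases))] <- unname(aliases)
  ids
}

# label -> list(genes, log2fc) over every timepoint (first definition wins)
panel_map <- function(cfg) {
  out <- list()
  for (tp in cfg$timepoints) {
    for (cl in tp$clusters) {
      if (is.null(out[[cl$label]])) {
        out[[cl$label]] <- list(genes = cl$marker_genes,
                                log2fc = cl$marker_log2fc %||% 2)
      }
    }
  }
  out
}

EVEN_RHOMBOMERES <- c("r2", "r4", "r6")
ODD_RHOMBOMERES <- c("r1", "r3", "r5")

# Generate one timepoint. Assumes the RNG is already seeded by the caller.
gen_timepoint <- function(cfg, tp, condition = "control",
                          perturbation = NULL) {
  clusters <- tp$clusters
  n_cells_per <- vapply(clusters, function(cl) as.integer(cl$n_cells), 1L)
  n <- sum(n_cells_per)
  labels <- vapply(clusters, function(cl) cl$label, "")
  true_cluster <- rep(labels, n_cells_per)
  tag <- if (condition == "control") tp$name else paste0(tp$name, ".", condition)
  cell_ids <- sprintf("%s_c%05d", tag, seq_len(n))
  panels <- panel_map(cfg)

  base <- cfg$baseline_mean
  mu <- matrix(base, cfg$n_genes, n)
  bump <- function(genes, cells, log2fc, from = base) {
    if (!length(genes) || !length(cells)) return()
    mu[genes, cells] <<- pmax(mu[genes, cells], from * 2^log2fc)
  }

  primary_fate <- rep(NA_character_, n)
  coexpr_rec <- vector("list", n)

  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    cells <- which(true_cluster == cl$label)
    lfc <- cl$marker_log2fc %||% 2
    has_fates <- length(cl$fate_labels %||% character(0)) > 0
    own_lfc <- if (has_fates) lfc * cfg$core_overlap else lfc
    bump(cl$marker_genes, cells, own_lfc)
    if (has_fates) {
      fates <- cl$fate_labels
      prim <- fates[sample.int(length(fates), length(cells), replace = TRUE)]
      primary_fate[cells] <- prim
      mixf <- cl$mix_fraction %||% 0
      for (f in fates) {
        pan <- panels[[f]]
        if (is.null(pan)) stopf("fate label '%s' has no panel", f)
        on <- prim == f
        if (mixf > 0) {
          on <- on | (runif(length(cells)) < mixf)
        }
        bump(pan$genes, cells[on], pan$log2fc)
        for (i in which(on & prim != f)) {
          coexpr_rec[[cells[i]]] <- c(coexpr_rec[[cells[i]]], f)
        }
      }
    }
  }

  for (co in cfg$coexpression) {
    cells <- which(true_cluster == co$cluster_label)
    if (!length(cells)) next
    for (p in co$secondary_panels) {
      on <- runif(length(cells)) < p$fraction
      bump(p$genes, cells[on], p$log2fc %||% 2)
      pname <- p$name %||% "panel"
      for (i in cells[on]) coexpr_rec[[i]] <- c(coexpr_rec[[i]], pname)
    }
  }

  pp <- cfg$periodic_planted
  if (length(pp$even_genes) || length(pp$odd_genes) || length(pp$pair_genes)) {
    rh_cells <- which(true_cluster %in% c(EVEN_RHOMBOMERES, ODD_RHOMBOMERES))
    for (genes in list(pp$even_genes, pp$odd_genes)) {
      if (length(genes)) mu[genes, rh_cells] <- pmax(mu[genes, rh_cells],
                                                     pp$base_mean)
    }
    bump(pp$even_genes, which(true_cluster %in% EVEN_RHOMBOMERES),
         pp$log2fc, from = pp$base_mean)
    bump(pp$odd_genes, which(true_cluster %in% ODD_RHOMBOMERES),
         pp$log2fc, from = pp$base_mean)
    for (pair in names(pp$pair_genes)) {
      lab <- strsplit(pair, "|", fixed = TRUE)[[1]]
      bump(pp$pair_genes[[pair]], which(true_cluster %in% lab),
           pp$log2fc, from = pp$base_mean)
    }
  }

  if (length(cfg$dv_genes)) {
    axis <- runif(n)
    mod <- exp(cfg$dv_amplitude * (axis - 0.5))
    mu[cfg$dv_genes, ] <- mu[cfg$dv_genes, ] *
      rep(mod, each = length(cfg$dv_genes))
  }

  size_factor <- rlnorm(n, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu <- mu * rep(size_factor, each = cfg$n_genes)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                   cfg$n_genes, n)

  # ATAC: Bernoulli open gate x Poisson fragment count
  a <- cfg$atac
  p_open <- matrix(a$p_open_out, cfg$n_peaks, n)
  for (lab in names(a$cluster_peaks)) {
    cells <- which(true_cluster == lab)
    if (length(cells)) p_open[a$cluster_peaks[[lab]], cells] <- a$p_open_in
  }
  for (enr in a$planted_motif_enrichment) {
    cells <- which(true_cluster == enr$cluster)
    pk <- a$motif_assignment[[enr$motif]]
    if (length(cells) && length(pk)) {
      p_open[pk, cells] <- pmin(p_open[pk, cells] *
                                  (enr$boost %||% a$enrichment_boost), 0.95)
    }
  }
  # per-cell depth effect: open probabilities scale with a lognormal
  # factor (complement-power transform keeps them in (0, 1))
  if ((a$depth_sdlog %||% 0) > 0) {
    atac_depth <- rlnorm(n, 0, a$depth_sdlog)
    p_open <- 1 - (1 - p_open)^rep(atac_depth, each = cfg$n_peaks)
  }
  open <- matrix(rbinom(length(p_open), 1L, p_open), cfg$n_peaks, n)
  atac_counts <- open * matrix(rpois(length(p_open), a$frag_mean),
                               cfg$n_peaks, n)

  # QC covariates; a planted fraction violates exactly one threshold
  th <- cfg$qc_thresholds
  qc_fail <- runif(n) < cfg$qc_fail_fraction
  reason <- rep(NA_character_, n)
  reason[qc_fail] <- sample(c("pct_mito", "nucleosome", "tss"),
                            sum(qc_fail), replace = TRUE)
  pct_mito <- runif(n, 0, 0.5 * th$max_pct_mito)
  tss <- th$min_tss + abs(stats::rnorm(n, 3, 1))
  nucleosome <- runif(n, 0.2, 0.8 * th$max_nucleosome)
  i <- which(reason == "pct_mito")
  pct_mito[i] <- runif(length(i), 1.2 * th$max_pct_mito,
                       min(2.5 * th$max_pct_mito, 1))
  i <- which(reason == "nucleosome")
  nucleosome[i] <- runif(length(i), 1.05 * th$max_nucleosome,
                         2 * th$max_nucleosome)
  i <- which(reason == "tss")
  tss[i] <- runif(length(i), 0, 0.9 * th$min_tss)

  gene_ids <- feature_ids("g", cfg$n_genes, cfg$gene_aliases)
  motif_ids <- feature_ids("M", cfg$n_motifs, cfg$motif_aliases, width = 3L)
  dimnames(counts) <- list(gene_ids, cell_ids)

  meta <- data.frame(
    cell_id = cell_ids,
    sample = tag,
    timepoint = tp$name,
    condition = condition,
    total_counts = colSums(counts),
    pct_mito = pct_mito,
    tss_enrichment = tss,
    nucleosome_signal = nucleosome,
    total_atac = colSums(atac_counts),
    stringsAsFactors = FALSE)
  rna <- cell_matrix(counts, meta = meta)

  membership <- matrix(0, cfg$n_peaks, cfg$n_motifs,
                       dimnames = list(NULL, motif_ids))
  for (m in names(a$motif_assignment)) {
    membership[a$motif_assignment[[m]], m] <- 1
  }
  peak_len <- 400L
  peaks <- data.frame(chrom = "chrS",
                      start = (seq_len(cfg$n_peaks) - 1L) * 1000L,
                      end = (seq_len(cfg$n_peaks) - 1L) * 1000L + peak_len)
  atac <- peak_data(atac_counts, peaks, cell_ids, membership, motif_ids)

  # truth records actual threshold violations: the planted covariate
  # failures plus any incidental depth failure from the count model itself
  low_rna <- meta$total_counts < th$min_total_counts
  low_atac <- meta$total_atac < th$min_total_atac
  actual_fail <- qc_fail | low_rna | low_atac
  reason[!qc_fail & low_rna] <- "low_total_counts"
  reason[!qc_fail & !low_rna & low_atac] <- "low_total_atac"
  truth <- data.frame(
    cell_id = cell_ids, timepoint = tp$name, condition = condition,
    true_cluster = true_cluster, primary_fate = primary_fate,
    coexpr_panels = vapply(coexpr_rec, function(x)
      paste(unique(x), collapse = ","), ""),
    qc_fail = actual_fail, qc_fail_planted = qc_fail,
    qc_fail_reason = reason,
    stringsAsFactors = FALSE)
  truth_obj <- structure(list(
    cells = truth,
    lineage_map = cfg$lineage_map,
    planted = cfg$periodic_planted,
    motif_enrichments = cfg$atac$planted_motif_enrichment,
    perturbation = perturbation), class = "sim_truth")

  structure(list(rna = rna, atac = atac, truth = truth_obj,
                 timepoint = tp$name, condition = condition),
            class = "sim_dataset")
}

print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset '%s' (%s): %d cells, %d clusters\n",
              x$timepoint, x$condition, nrow(x$truth$cells),
              length(unique(x$truth$cells$true_cluster))))
  invisible(x)
}

#' Simulate a synthetic hindbrain multiome study
#'
#' Draws RNA counts from a negative binomial with lognormal cell size
#' factors (marker genes of a cell's cluster, of a committed fate, and of
#' any co-activated secondary panel boosted by their log2 fold change),
#' chromatin counts from a Bernoulli-Poisson model with cluster-restricted
#' open probabilities and planted motif enrichments, and QC covariates with
#' a planted failing fraction. Fully reproducible for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return named list (one element per timepoint) of `sim_dataset` objects,
#'   each with elements `rna` ([cell_matrix()]), `atac` ([peak_data()]) and
#'   `truth` (`sim_truth`: per-cell table plus planted structure).
#' @export
simulate_hindbrain <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    out <- lapply(config$timepoints, function(tp) gen_timepoint(config, tp))
    names(out) <- vapply(config$timepoints, function(tp) tp$name, "")
    out
  })
}

#' Simulate a lineage-removal / expansion perturbation
#'
#' Regenerates one timepoint with the listed clusters deleted and the
#' remaining clusters' cell numbers multiplied (rounded) by their expansion
#' factor; the condition column is set to `"treated"`.
#'
#' @param config a [sim_config()].
#' @param removed_labels cluster labels absent from the treated sample.
#' @param expansion_factors named numeric vector label -> factor (> 0);
#'   unlisted clusters keep their size.
#' @param seed integer seed.
#' @param timepoint which configured timepoint to perturb (default first).
#' @return a `sim_dataset` with `condition = "treated"` and the
#'   perturbation recorded in its truth.
#' @export
simulate_perturbation <- function(config, removed_labels = character(0),
                                  expansion_factors = numeric(0), seed = 1L,
                                  timepoint = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tp_names <- vapply(config$timepoints, function(tp) tp$name, "")
  timepoint <- timepoint %||% tp_names[1]
  tp <- config$timepoints[[match(timepoint, tp_names)]]
  labels <- vapply(tp$clusters, function(cl) cl$label, "")
  unknown <- setdiff(removed_labels, labels)
  if (length(unknown)) stopf("cannot remove unknown clusters: %s",
                             paste(unknown, collapse = ", "))
  if (any(expansion_factors <= 0)) stopf("expansion factors must be > 0")
  keep <- !labels %in% removed_labels
  if (!any(keep)) stopf("perturbation removes every cluster")
  clusters <- tp$clusters[keep]
  for (i in seq_along(clusters)) {
    f <- expansion_factors[clusters[[i]]$label]
    if (!is.na(f) && length(f)) {
      clusters[[i]]$n_cells <- as.integer(round(clusters[[i]]$n_cells * f))
    }
  }
  tp$clusters <- clusters
  record <- list(removed = removed_labels,
                 expansion_factors = expansion_factors)
  with_seed(seed, gen_timepoint(config, tp, condition = "treated",
                                perturbation = record))
}

#' Simulate an ordered developmental timecourse
#'
#' As [simulate_hindbrain()], after checking that the configured lineage
#' map is consistent: every progenitor's descendants exist as clusters and
#' match its `fate_labels`, so descendant panels are the resolved single
#' programs of the progenitor's mixed panel set.
#'
#' @inheritParams simulate_hindbrain
#' @return named list of `sim_dataset` objects in timepoint order.
#' @export
simulate_timecourse <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(config$lineage_map)) stopf("config has no lineage_map")
  for (tp in config$timepoints) {
    for (cl in tp$clusters) {
      fates <- cl$fate_labels %||% character(0)
      if (length(fates) && !identical(sort(fates),
                                      sort(config$lineage_map[[cl$label]] %||%
                                           character(0)))) {
        stopf("fate_labels of '%s' disagree with lineage_map", cl$label)
      }
    }
  }
  simulate_hindbrain(config, seed)
}
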