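# Preset study configurations. Gene space is laid out in 12-gene marker
# blocks per cluster; a few indices are aliased to zebrafish gene names so
# that the shipped rhombomere identity panel applies to simulated data.

MARKER_BLOCK <- 40L

marker_block <- function(i) ((i - 1L) * MARKER_BLOCK + 1L):(i * MARKER_BLOCK)

# aliased positions: offset within each rhombomere block
rhombomere_aliases <- local({
  pos <- function(i, off) (i - 1L) * MARKER_BLOCK + off
  ids <- c(irx1b = pos(1L, 1L),
           vgll3 = pos(2L, 1L), tgfbr2b = pos(2L, 2L),
           egr2b = pos(3L, 1L), nab1b = pos(3L, 2L),
           fgf3 = pos(4L, 1L), cyp26b1 = pos(4L, 2L), hoxb1a = pos(4L, 3L),
           dusp2 = pos(4L, 4L), ppp1r14ab = pos(4L, 5L),
           sema3ab = pos(5L, 1L),
           mafba = pos(6L, 1L), crabp2a = pos(6L, 2L))
  setNames(names(ids), ids)
})

alias_index <- function(name) {
  as.integer(names(rhombomere_aliases)[rhombomere_aliases == name])
}

# r1..r6 marker sets; egr2b and nab1b are shared r3/r5 markers and mafba is
# shared r5/r6, mirroring the biology the identity panel encodes.
rhombomere_marker_sets <- function() {
  sets <- lapply(1:6, marker_block)
  names(sets) <- paste0("r", 1:6)
  sets$r5 <- c(sets$r5, alias_index("egr2b"), alias_index("nab1b"),
               alias_index("mafba"))
  sets
}

cluster_spec <- function(label, n_cells, marker_genes, marker_log2fc = 2,
                         fate_labels = NULL, mix_fraction = 0) {
  list(label = label, n_cells = n_cells, marker_genes = marker_genes,
       marker_log2fc = marker_log2fc, fate_labels = fate_labels,
       mix_fraction = mix_fraction)
}

# Deterministic random motif->peak assignment; a planted motif draws half
# of its peaks from the target cluster's accessible block.
motif_layout <- function(n_peaks, n_motifs, peaks_per_motif = 30L,
                         planted = NULL, planted_block = NULL,
                         layout_seed = 42L) {
  with_seed(layout_seed, {
    ids <- sprintf("M%03d", seq_len(n_motifs))
    assignment <- lapply(ids, function(m)
      sort(sample.int(n_peaks, peaks_per_motif)))
    names(assignment) <- ids
    if (!is.null(planted)) {
      k <- peaks_per_motif %/% 2L
      inside <- sample(planted_block, min(k, length(planted_block)))
      outside <- sample(setdiff(seq_len(n_peaks), planted_block),
                        peaks_per_motif - length(inside))
      assignment[[planted]] <- sort(c(inside, outside))
    }
    assignment
  })
}

#' Default single-timepoint hindbrain analog (13 hpf-like)
#'
#' Ten clusters (r1-r6, MHB, CHB, SC.1, SC.2) with 12-gene marker panels at
#' a log2 fold change of 2, dorsoventral covariate genes, cluster-restricted
#' accessibility, and one planted motif enrichment (motif M001 in r4, open
#' rate x3).
#'
#' @param n_cells cells per cluster (scalar) or named vector per label.
#' @param marker_log2fc marker panel contrast.
#' @param qc_fail_fraction planted QC-failure fraction.
#' @return a [sim_config()] with one timepoint named `"13hpf"`.
#' @export
config_13hpf <- function(n_cells = 200, marker_log2fc = 2,
                         qc_fail_fraction = 0.05) {
  labels <- c(paste0("r", 1:6), "MHB", "CHB", "SC.1", "SC.2")
  sizes <- if (length(n_cells) == 1L) setNames(rep(n_cells, 10L), labels)
           else n_cells[labels]
  sets <- rhombomere_marker_sets()
  for (i in 7:10) sets[[labels[i]]] <- marker_block(i)
  clusters <- lapply(labels, function(l)
    cluster_spec(l, sizes[[l]], sets[[l]], marker_log2fc))
  n_peaks <- 500L
  cluster_peaks <- lapply(seq_along(labels), function(i)
    ((i - 1L) * 40L + 1L):(i * 40L))
  names(cluster_peaks) <- labels
  sim_config(
    n_genes = 1000L, n_peaks = n_peaks, n_motifs = 12L,
    timepoints = list(list(name = "13hpf", clusters = clusters)),
    dv_genes = 421:440, dv_amplitude = 0.5,
    atac = list(cluster_peaks = cluster_peaks,
                motif_assignment = motif_layout(n_peaks, 12L,
                                                planted = "M001",
                                                planted_block =
                                                  cluster_peaks$r4),
                planted_motif_enrichment = list(list(motif = "M001",
                                                     cluster = "r4"))),
    qc_fail_fraction = qc_fail_fraction,
    gene_aliases = rhombomere_aliases)
}

#' Perturbation-study configuration
#'
#' Like [config_13hpf()] but with unequal, anatomy-motivated cluster sizes:
#' individual rhombomeres are small (150 cells) relative to the midbrain-
#' hindbrain boundary and caudal hindbrain pools (250) and the spinal cord
#' clusters (400). Used for control-vs-treated composition analysis.
#'
#' @inheritParams config_13hpf
#' @return a [sim_config()].
#' @export
config_perturbstudy <- function(marker_log2fc = 2, qc_fail_fraction = 0) {
  sizes <- c(setNames(rep(150, 6), paste0("r", 1:6)),
             MHB = 250, CHB = 250, SC.1 = 400, SC.2 = 400)
  config_13hpf(n_cells = sizes, marker_log2fc = marker_log2fc,
               qc_fail_fraction = qc_fail_fraction)
}

#' Periodicity / adjacent-pair screen configuration
#'
#' Six rhombomere clusters over a sparse background (baseline mean 0.02,
#' so background genes sit below the 10% detection floor), with planted
#' screen targets at 4-fold contrast: 20 even-patterned genes, 20
#' odd-patterned genes, and 5 genes per adjacent rhombomere pair.
#'
#' @param n_cells cells per rhombomere.
#' @return a [sim_config()] with one timepoint named `"16hpf"`.
#' @export
config_periodicity <- function(n_cells = 150) {
  labels <- paste0("r", 1:6)
  sets <- rhombomere_marker_sets()
  clusters <- lapply(labels, function(l) cluster_spec(l, n_cells, sets[[l]]))
  pairs <- paste(labels[1:5], labels[2:6], sep = "|")
  pair_genes <- lapply(seq_along(pairs), function(i)
    (280L + (i - 1L) * 5L + 1L):(280L + i * 5L))
  names(pair_genes) <- pairs
  cluster_peaks <- lapply(seq_along(labels), function(i)
    ((i - 1L) * 40L + 1L):(i * 40L))
  names(cluster_peaks) <- labels
  sim_config(
    n_genes = 600L, n_peaks = 240L, n_motifs = 6L,
    timepoints = list(list(name = "16hpf", clusters = clusters)),
    baseline_mean = 0.02,
    periodic_planted = list(even_genes = 241:260, odd_genes = 261:280,
                            pair_genes = pair_genes,
                            base_mean = 0.5, log2fc = 2),
    atac = list(cluster_peaks = cluster_peaks,
                motif_assignment = motif_layout(240L, 6L)),
    qc_fail_fraction = 0,
    gene_aliases = rhombomere_aliases)
}

#' Mixed-identity progenitor (HB.1 analog) configuration
#'
#' A single progenitor cluster whose cells all express a primary marker
#' panel (anchored by vgll3) and activate a secondary panel (anchored by
#' egr2b) with probability `p_co`. Markers are effectively on/off (very low
#' baseline, high contrast) so that detection noise is negligible relative
#' to the planted co-expression fraction.
#'
#' @param p_co planted per-cell co-expression probability.
#' @param n_cells cluster size (approximately the anchor-positive count).
#' @return a [sim_config()] with one timepoint named `"10hpf"`.
#' @export
config_coexpr <- function(p_co = 0.74, n_cells = 500) {
  clusters <- list(cluster_spec("HB.1", n_cells, 1:6, marker_log2fc = 14))
  sim_config(
    n_genes = 40L, n_peaks = 60L, n_motifs = 4L,
    timepoints = list(list(name = "10hpf", clusters = clusters)),
    baseline_mean = 0.005,
    coexpression = list(list(
      cluster_label = "HB.1",
      secondary_panels = list(list(name = "r3", genes = 7:12,
                                   fraction = p_co, log2fc = 14)))),
    atac = list(cluster_peaks = list(HB.1 = 1:20),
                motif_assignment = motif_layout(60L, 4L,
                                                peaks_per_motif = 15L)),
    qc_fail_fraction = 0,
    gene_aliases = c("1" = "vgll3", "2" = "tgfbr2b",
                     "7" = "egr2b", "8" = "nab1b"))
}

#' Three-timepoint lineage (timecourse) configuration
#'
#' 10 hpf progenitor domains HB.1 -> {r1,r2,r3}, HB.2 -> {r5,r6} and
#' HB.3 -> {r4} whose cells commit to one descendant panel and mix in
#' additional descendant panels with probability `mix_fraction`; 13 and 16
#' hpf carry the six resolved rhombomere clusters. An optional unresolved
#' progenitor subpopulation (HB.X) carries its own program only and should
#' surface as the residual, progenitor-only integrated cluster.
#'
#' @param mix_fraction per-cell probability of activating each non-primary
#'   descendant panel in a progenitor cluster.
#' @param core_overlap strength of the progenitor core program relative to
#'   descendant panels (see [sim_config()]).
#' @param include_unresolved add the HB.X subpopulation.
#' @return a [sim_config()] with timepoints `"10hpf"`, `"13hpf"`, `"16hpf"`.
#' @export
config_timecourse <- function(mix_fraction = 0.1, core_overlap = 0.5,
                              include_unresolved = TRUE) {
  sets <- rhombomere_marker_sets()
  rh <- function(n_cells) lapply(paste0("r", 1:6), function(l)
    cluster_spec(l, n_cells, sets[[l]]))
  prog <- list(
    cluster_spec("HB.1", 300, 241:252, fate_labels = c("r1", "r2", "r3"),
                 mix_fraction = mix_fraction),
    cluster_spec("HB.2", 200, 253:264, fate_labels = c("r5", "r6"),
                 mix_fraction = mix_fraction),
    cluster_spec("HB.3", 150, 265:276, fate_labels = "r4",
                 mix_fraction = mix_fraction))
  if (include_unresolved) {
    prog <- c(prog, list(cluster_spec("HB.X", 120, 277:300)))
  }
  labels10 <- vapply(prog, function(cl) cl$label, "")
  all_labels <- c(labels10, paste0("r", 1:6))
  cluster_peaks <- lapply(seq_along(all_labels), function(i)
    ((i - 1L) * 30L + 1L):(i * 30L))
  names(cluster_peaks) <- all_labels
  sim_config(
    n_genes = 600L, n_peaks = 360L, n_motifs = 8L,
    timepoints = list(
      list(name = "10hpf", clusters = prog),
      list(name = "13hpf", clusters = rh(150)),
      list(name = "16hpf", clusters = rh(150))),
    lineage_map = list(HB.1 = c("r1", "r2", "r3"), HB.2 = c("r5", "r6"),
                       HB.3 = "r4"),
    core_overlap = core_overlap,
    atac = list(cluster_peaks = cluster_peaks,
                motif_assignment = motif_layout(360L, 8L)),
    qc_fail_fraction = 0,
    gene_aliases = rhombomere_aliases)
}

#' Default rhombomere identity panel
#'
#' Marker panel used to assign rhombomere identities to clusters:
#' r1: irx1b; r2: vgll3, tgfbr2b; r3: egr2b, nab1b; r4: fgf3, cyp26b1,
#' hoxb1a, dusp2, ppp1r14ab; r5: egr2b, sema3ab, mafba; r6: mafba, crabp2a.
#'
#' @return named list label -> character vector of marker genes.
#' @export
default_identity_panel <- function() {
  list(r1 = "irx1b",
       r2 = c("vgll3", "tgfbr2b"),
       r3 = c("egr2b", "nab1b"),
       r4 = c("fgf3", "cyp26b1", "hoxb1a", "dusp2", "ppp1r14ab"),
       r5 = c("egr2b", "sema3ab", "mafba"),
       r6 = c("mafba", "crabp2a"))
}

#' Read an identity panel from JSON
#'
#' @param path JSON file mapping label -> array of marker gene ids.
#' @return named list of character vectors.
#' @export
read_identity_panel <- function(path) {
  panel <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(panel, as.character)
}
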