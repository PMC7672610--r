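#' Run the full cell-cycle isolation pipeline
#'
#' Orchestrates the whole analysis on a raw count matrix: expression
#' filtering, per-batch marker-based phase assignment, removal of flagged
#' cells and a second filtering pass, per-batch variable-gene selection and
#' combination, normalization, PCA, cluster/marker scores, detection of
#' cell-cycle-significant components, the sequence of three-dimensional
#' rotations into dynamical components, and division-anchored pseudotime.
#'
#' @param x a [cc_counts] object (raw counts; batch labels honored).
#' @param markers named list of five marker gene vectors (default the
#'   bundled list).
#' @param cyclic_reference character vector of known cyclic genes for the
#'   marker score; defaults to the union of all marker genes.
#' @param min_cells,min_genes expression filter thresholds (defaults 5 and
#'   500).
#' @param min_corr,doublet_q2,min_q phase assignment thresholds (defaults
#'   0.2, 0.3, 0.75).
#' @param max_components cluster-score outlier search cap (default 100).
#' @param n_coarse viewing-axis grid size (default 10000).
#' @param bin_size UMI-course bin size (default 30).
#' @param phase_lengths phase duration table for boundaries (default
#'   bundled).
#' @param verbose print stage messages (default TRUE).
#' @return Object of class `cc_pipeline`: list with `counts` (final
#'   filtered), `phases` (per-cell tibble for retained cells), `gene_sets`,
#'   `normalized`, `pca`, `cluster_scores`, `marker_scores`
#'   (+ `marker_baseline`), `cc_components`, `dc_space`, `coords`, and
#'   `report` (thresholds and rotation steps).
#' @export
run_cycle_pipeline <- function(x, markers = default_markers(),
                               cyclic_reference = NULL,
                               min_cells = 5, min_genes = 500,
                               min_corr = 0.2, doublet_q2 = 0.3,
                               min_q = 0.75, max_components = 100,
                               n_coarse = 10000, bin_size = 30,
                               phase_lengths = default_phase_lengths(),
                               verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stopifnot(inherits(x, "cc_counts"))
  say("filtering: >= ", min_cells, " cells/gene, >= ", min_genes, " genes/cell")
  x1 <- filter_matrix(x, min_cells, min_genes)
  say("  ", nrow(x1$counts), " genes x ", ncol(x1$counts), " cells retained")

  say("phase assignment over ", length(markers), " marker buckets")
  pa <- assign_phases(x1, markers, min_corr = min_corr,
                      doublet_q2 = doublet_q2, min_q = min_q)
  kept <- pa$cells$cell_id[pa$cells$keep]
  say("  ", length(kept), " cells kept (",
      sum(pa$cells$doublet), " doublets, ",
      sum(pa$cells$low_confidence), " low-confidence removed)")
  x2 <- filter_matrix(subset_cells(x1, kept), min_cells, min_genes)
  phases <- pa$cells[match(colnames(x2$counts), pa$cells$cell_id), ]

  say("variable genes per batch")
  gs <- variable_genes(x2)
  if (is.null(cyclic_reference)) cyclic_reference <- unique(unlist(markers))
  gs <- cc_marker_subset(gs, cyclic_reference)
  say("  ", length(gs$vg_all), " combined variable genes (Q = ",
      signif(gs$Q, 3), "), ", length(gs$vg_cc), " cyclic markers")

  lf <- log_fractions(scaled_fractions(x2))
  n <- normalize_genes(lf, gs$vg_all)
  say("PCA on ", nrow(n$values), " genes x ", ncol(n$values), " cells")
  pca <- pca_decompose(n)

  sig <- cluster_scores(pca$scores, phases$phase)
  ms <- marker_scores(pca$weights, gs$vg_cc)
  ccc <- score_outliers(sig, max_components = max_components)
  say("cell-cycle-significant components: {",
      paste(ccc, collapse = ", "), "}")

  dc <- sequential_rotation(pca, ccc, phases$phase, n_coarse = n_coarse)
  say(length(dc$steps), " rotation step(s) applied")

  coords <- cycle_coordinates(dc, phases$phase,
                              total_umis(x2)[dc$cell_ids],
                              bin_size = bin_size,
                              phase_lengths = phase_lengths)
  say("division aligned; pseudotime over ", nrow(coords$cells), " cells")

  report <- list(
    thresholds = list(min_cells = min_cells, min_genes = min_genes,
                      min_corr = min_corr, doublet_q2 = doublet_q2,
                      min_q = min_q, max_components = max_components,
                      n_coarse = n_coarse, bin_size = bin_size),
    n_genes = nrow(x2$counts), n_cells = ncol(x2$counts),
    Q = gs$Q, n_variable = length(gs$vg_all), n_cc = length(gs$vg_cc),
    cc_components = dc$cc_components,
    rotation_steps = dc$steps,
    division_angle = coords$division_angle,
    cluster_scores = sig, marker_scores = ms$scores,
    marker_baseline = ms$baseline
  )
  structure(list(counts = x2, phases = phases, gene_sets = gs,
                 normalized = n, lf = lf, pca = pca,
                 cluster_scores = sig, marker_scores = ms$scores,
                 marker_baseline = ms$baseline,
                 cc_components = ccc, dc_space = dc, coords = coords,
                 report = report),
            class = "cc_pipeline")
}

#' @export
print.cc_pipeline <- function(x, ...) {
  cat(sprintf("<cc_pipeline> %d genes x %d cells; %d variable genes; cc components {%s}\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              length(x$gene_sets$vg_all),
              paste(x$cc_components, collapse = ", ")))
  cat(sprintf("  division at angle %.3f; DC1/DC2 cluster scores %.3g / %.3g\n",
              x$coords$division_angle,
              cluster_scores(x$dc_space$dc_scores[1:2, , drop = FALSE],
                             x$phases$phase)[1],
              cluster_scores(x$dc_space$dc_scores[1:2, , drop = FALSE],
                             x$phases$phase)[2]))
  invisible(x)
}

#' Write the pipeline run report as JSON
#'
#' @param pipeline a `cc_pipeline` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(pipeline, path) {
  stopifnot(inherits(pipeline, "cc_pipeline"))
  rep <- pipeline$report
  rep$rotation_steps <- lapply(rep$rotation_steps, function(s) {
    list(dims = s$dims, omega = s$omega, alpha = s$alpha, beta = s$beta,
         score = s$score)
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
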