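#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA decomposition
#'
#' @param x a `cc_pca` object.
#' @param ... unused.
#' @return A tibble with one row per component: `component`, `eigenvalue`,
#'   `explained`.
#' @method tidy cc_pca
#' @export
tidy.cc_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 explained = x$explained)
}

#' @rdname tidy.cc_pca
#' @method glance cc_pca
#' @export
glance.cc_pca <- function(x, ...) {
  tibble::tibble(n_genes = length(x$gene_ids),
                 n_cells = length(x$cell_ids),
                 n_components = length(x$eigenvalues),
                 total_variance = sum(x$eigenvalues))
}

#' Tidy a DC space
#'
#' @param x a `cc_dc_space` object.
#' @param n_components how many leading DC score rows to return (default 3).
#' @param ... unused.
#' @return A tibble with one row per cell: `cell_id` and `DC1..DCk`.
#' @method tidy cc_dc_space
#' @export
tidy.cc_dc_space <- function(x, n_components = 3, ...) {
  k <- min(n_components, nrow(x$dc_scores))
  out <- tibble::as_tibble(t(x$dc_scores[seq_len(k), , drop = FALSE]))
  dplyr::bind_cols(tibble::tibble(cell_id = x$cell_ids), out)
}

#' @rdname tidy.cc_dc_space
#' @method glance cc_dc_space
#' @export
glance.cc_dc_space <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$dc_scores),
                 n_steps = length(x$steps),
                 cc_components = paste(x$cc_components, collapse = ","),
                 rotation_det = det(x$rotation))
}

#' Tidy a phase assignment
#'
#' @param x a `cc_phase_assignment` object.
#' @param ... unused.
#' @return The per-cell assignment tibble.
#' @method tidy cc_phase_assignment
#' @export
tidy.cc_phase_assignment <- function(x, ...) x$cells

#' @rdname tidy.cc_phase_assignment
#' @method glance cc_phase_assignment
#' @export
glance.cc_phase_assignment <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells),
                 n_kept = sum(x$cells$keep),
                 n_doublet = sum(x$cells$doublet),
                 n_low_confidence = sum(x$cells$low_confidence))
}

#' Tidy cycle coordinates
#'
#' @param x a `cc_cycle_coordinates` object.
#' @param ... unused.
#' @return The per-cell coordinate tibble.
#' @method tidy cc_cycle_coordinates
#' @export
tidy.cc_cycle_coordinates <- function(x, ...) x$cells

#' @rdname tidy.cc_cycle_coordinates
#' @method glance cc_cycle_coordinates
#' @export
glance.cc_cycle_coordinates <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells),
                 division_angle = x$division_angle,
                 flipped = x$flipped)
}

#' Tidy a full pipeline run
#'
#' @param x a `cc_pipeline` object.
#' @param ... unused.
#' @return Per-cell tibble joining coordinates and phase assignment.
#' @method tidy cc_pipeline
#' @export
tidy.cc_pipeline <- function(x, ...) {
  dplyr::left_join(x$coords$cells,
                   dplyr::select(x$phases, "cell_id", "q", "q2",
                                 "phase2"),
                   by = "cell_id")
}

#' @rdname tidy.cc_pipeline
#' @method glance cc_pipeline
#' @export
glance.cc_pipeline <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$counts$counts),
                 n_cells = ncol(x$counts$counts),
                 n_variable = length(x$gene_sets$vg_all),
                 n_cc_markers = length(x$gene_sets$vg_cc),
                 Q = x$gene_sets$Q,
                 n_cc_components = length(x$cc_components),
                 division_angle = x$coords$division_angle)
}
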