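#' Remove cell-cycle components from the normalized matrix
#'
#' Because U is orthogonal, the normalized data decompose exactly as
#' \eqn{N = U^T \cdot DC = \sum_i U^T_{\cdot i} \, DC_{i \cdot}}. Subtracting
#' the DC1 and DC2 terms removes the cell-cycle plane from the data while
#' leaving every other component untouched:
#' \eqn{\tilde N = N - \sum_{i \in components} U^T_{\cdot i} DC_{i\cdot}}.
#'
#' @param n a `cc_transformed` object at stage `"normalized"` (the matrix
#'   the decomposition was computed from).
#' @param dc_space a `cc_dc_space` object.
#' @param components integer vector of DC indices to remove (default
#'   `c(1, 2)`). Removing none returns N; removing all returns (numerically)
#'   the zero matrix.
#' @return Object of class `cc_cleaned`: list with `values` (genes x cells
#'   matrix), `removed_components`, and the stage/statistics of `n`.
#' @export
remove_components <- function(n, dc_space, components = c(1, 2)) {
  stopifnot(inherits(n, "cc_transformed"), n$stage == "normalized",
            inherits(dc_space, "cc_dc_space"))
  k <- nrow(dc_space$dc_scores)
  components <- as.integer(components)
  if (any(components < 1 | components > k)) {
    stop2("component index out of range 1..", k)
  }
  stopifnot(identical(rownames(n$values), dc_space$gene_ids))
  v <- n$values
  if (length(components)) {
    u_t <- t(dc_space$rotated_weights[components, , drop = FALSE])  # genes x r
    v <- v - u_t %*% dc_space$dc_scores[components, , drop = FALSE]
  }
  structure(list(values = v, removed_components = components,
                 kappa = n$kappa, gene_means = n$gene_means,
                 gene_sds = n$gene_sds),
            class = "cc_cleaned")
}

#' @export
print.cc_cleaned <- function(x, ...) {
  cat(sprintf("<cc_cleaned> %d genes x %d cells, removed DC {%s}\n",
              nrow(x$values), ncol(x$values),
              paste(x$removed_components, collapse = ", ")))
  invisible(x)
}

#' Verify that cell-cycle removal worked
#'
#' Re-runs PCA on the cleaned matrix and reports: (i) cluster and marker
#' scores of the cleaned data's PCs (expected small, below the outlier
#' fence); (ii) variance decompositions of the cleaned PCs against the
#' cyclic gene set and against a size-matched random gene set (expected
#' indistinguishable); (iii) the correlation matrix between cleaned-PC
#' weight vectors and the original DC weight vectors (expected a
#' one-to-one diagonal shifted by the number of removed components).
#'
#' @param cleaned a `cc_cleaned` object.
#' @param dc_space the `cc_dc_space` the removal used.
#' @param phases per-cell phase labels.
#' @param cc_genes character vector of cyclic gene ids.
#' @param n_components number of leading components to report on
#'   (default 10).
#' @param seed seed for the random comparison gene set (logged in the
#'   output).
#' @return List with `pca` (of the cleaned data), `cluster_scores`,
#'   `marker_scores`, `score_outliers`, `decomposition_cc`,
#'   `decomposition_random`, `random_genes`, `weight_correlation`
#'   (cleaned PCs x original DCs), `seed`.
#' @export
verify_removal <- function(cleaned, dc_space, phases, cc_genes,
                           n_components = 10, seed = 1L) {
  stopifnot(inherits(cleaned, "cc_cleaned"), inherits(dc_space, "cc_dc_space"))
  n_obj <- new_transformed(cleaned$values, "normalized", cleaned$kappa,
                           cleaned$gene_means, cleaned$gene_sds)
  pca <- pca_decompose(n_obj)
  k <- min(n_components, nrow(pca$scores))
  sig <- cluster_scores(pca$scores, phases)
  ms <- marker_scores(pca$weights, cc_genes)
  out <- score_outliers(sig, max_components = min(100, length(sig)))
  dec_cc <- variance_decomposition(n_obj, pca$weights, cc_genes,
                                   components = seq_len(k))
  genes <- rownames(cleaned$values)
  set.seed(seed)
  rnd <- sample(genes, length(intersect(cc_genes, genes)))
  dec_rnd <- variance_decomposition(n_obj, pca$weights, rnd,
                                    components = seq_len(k))
  n_dc <- min(nrow(dc_space$rotated_weights), nrow(pca$weights))
  wc <- stats::cor(t(pca$weights[seq_len(min(k, n_dc)), , drop = FALSE]),
                   t(dc_space$rotated_weights[seq_len(n_dc), , drop = FALSE]))
  rownames(wc) <- paste0("cleanPC", seq_len(nrow(wc)))
  list(pca = pca, cluster_scores = sig, marker_scores = ms,
       score_outliers = out, decomposition_cc = dec_cc,
       decomposition_random = dec_rnd, random_genes = rnd,
       weight_correlation = wc, seed = seed)
}
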