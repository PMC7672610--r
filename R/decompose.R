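#' Principal component analysis of the normalized matrix
#'
#' Eigendecomposition of the gene-gene covariance matrix
#' \eqn{\frac{1}{n-1} N N^T} of the normalized (per-gene z-scored) matrix,
#' computed via SVD of N for numerical stability. Rows of the weight matrix
#' \eqn{W^T} are the orthonormal eigenvectors (loadings); PC scores are
#' \eqn{P = W^T N}. Eigenvalues are returned in descending order; for a
#' z-scored input they sum to the number of genes. Sign convention: in each
#' weight row the entry of largest magnitude is positive.
#'
#' @param n a `cc_transformed` object at stage `"normalized"`.
#' @return Object of class `cc_pca`: list with `weights` (components x
#'   genes), `eigenvalues`, `scores` (components x cells), `explained`
#'   (eigenvalue fractions), `gene_ids`, `cell_ids`, and the normalization
#'   statistics carried over from `n`.
#' @export
pca_decompose <- function(n) {
  stopifnot(inherits(n, "cc_transformed"))
  if (n$stage != "normalized") stop2("pca_decompose expects stage 'normalized'")
  v <- n$values
  if (any(!is.finite(v))) stop2("non-finite entries in normalized matrix")
  if (nrow(v) < 2 || ncol(v) < 2) stop2("need >= 2 genes and >= 2 cells")
  k <- min(dim(v))
  sv <- svd(v, nu = k, nv = k)
  lambda <- sv$d[seq_len(k)]^2 / (ncol(v) - 1)
  w <- t(sv$u)                                  # components x genes
  scores <- w %*% v                             # components x cells
  # deterministic signs: largest-magnitude weight in each row positive
  flip <- vapply(seq_len(k), function(i) {
    row <- w[i, ]
    sign(row[which.max(abs(row))]) < 0
  }, logical(1))
  w[flip, ] <- -w[flip, , drop = FALSE]
  scores[flip, ] <- -scores[flip, , drop = FALSE]
  rownames(w) <- paste0("PC", seq_len(k)); colnames(w) <- rownames(v)
  rownames(scores) <- paste0("PC", seq_len(k)); colnames(scores) <- colnames(v)
  structure(list(weights = w, eigenvalues = lambda, scores = scores,
                 explained = lambda / sum(lambda),
                 gene_ids = rownames(v), cell_ids = colnames(v),
                 gene_means = n$gene_means, gene_sds = n$gene_sds,
                 kappa = n$kappa),
            class = "cc_pca")
}

#' @export
print.cc_pca <- function(x, ...) {
  cat(sprintf("<cc_pca> %d components over %d genes x %d cells; top eigenvalues: %s\n",
              length(x$eigenvalues), length(x$gene_ids), length(x$cell_ids),
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Eigenvalue outliers by the interquartile-range fence
#'
#' An eigenvalue is a major outlier (and its component significant) if it
#' exceeds Q3 + `fence` * IQR over all eigenvalues. Quartiles use the
#' standard linear-interpolation quantile.
#'
#' @param lambdas numeric vector of eigenvalues (descending).
#' @param fence IQR multiplier (default 3.5).
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @return Integer vector of outlier component indices (a prefix of the
#'   descending order).
#' @export
eigenvalue_outliers <- function(lambdas, fence = 3.5, quantile_type = 7) {
  stopifnot(length(lambdas) >= 4)
  qs <- stats::quantile(lambdas, c(0.25, 0.75), type = quantile_type,
                        names = FALSE)
  cut <- qs[2] + fence * (qs[2] - qs[1])
  unname(which(lambdas > cut))
}

#' Cell cycle cluster score of a component
#'
#' Splits the cells into the five phase clusters and takes the standard
#' deviation (population convention, 1/5 denominator) of the five per-phase
#' mean scores. A component untouched by the cell cycle has similar cluster
#' means, hence a score near zero.
#'
#' @param score_row numeric vector of per-cell component scores.
#' @param phases per-cell phase labels (factor or character, the five
#'   [cc_phases()] levels); every phase must be represented.
#' @return The cluster score (non-negative scalar).
#' @export
cluster_score <- function(score_row, phases) {
  mu <- phase_cluster_means(rbind(score_row), phases)
  pop_sd(as.numeric(mu))
}

# 5 x components matrix of per-phase mean scores (components in rows of
# `scores`); errors if a phase is missing.
phase_cluster_means <- function(scores, phases) {
  phases <- factor(as.character(phases), levels = cc_phases())
  missing <- cc_phases()[!cc_phases() %in% phases]
  if (length(missing)) {
    stop2("phase(s) absent from data: ", paste(missing, collapse = ", "))
  }
  mu <- vapply(cc_phases(), function(ph) {
    rowMeans(scores[, phases == ph, drop = FALSE])
  }, numeric(nrow(scores)))
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1, dimnames = list(NULL, cc_phases()))
  t(mu)    # vapply gives components x 5; return 5 x components
}

#' Cluster scores for all components
#'
#' @param scores components x cells score matrix.
#' @param phases per-cell phase labels.
#' @return Numeric vector of cluster scores, one per component row.
#' @export
cluster_scores <- function(scores, phases) {
  mu <- phase_cluster_means(scores, phases)   # 5 x components
  apply(mu, 2, pop_sd)
}

#' Cell cycle marker score of a component
#'
#' The summed squared weights of the known cyclic genes in a unit-norm
#' loading row; lies in \[0, 1\]. For a component with no preference for
#' cyclic genes the expected value is the baseline `#VGcc / #VGall`.
#'
#' @param weight_row unit-norm numeric loading vector (named by gene).
#' @param cc_genes character vector of cyclic gene ids (or integer index).
#' @return The marker score.
#' @export
marker_score <- function(weight_row, cc_genes) {
  if (is.character(cc_genes)) {
    cc_genes <- which(names(weight_row) %in% cc_genes)
  }
  sum(weight_row[cc_genes]^2)
}

#' Marker scores for all components
#'
#' @param weights components x genes weight matrix (rows unit-norm, columns
#'   named by gene).
#' @param cc_genes cyclic gene ids.
#' @return List with `scores` (per-component marker score) and `baseline`
#'   (`#cc_genes present / #genes`).
#' @export
marker_scores <- function(weights, cc_genes) {
  idx <- which(colnames(weights) %in% cc_genes)
  list(scores = rowSums(weights[, idx, drop = FALSE]^2),
       baseline = length(idx) / ncol(weights))
}

#' Cluster-score outliers among the leading components
#'
#' Over the first `max_components` cluster scores, flags components whose
#' score exceeds the mean by more than `n_sd` sample standard deviations.
#' These are the components the cell cycle significantly influences.
#'
#' @param sigmas per-component cluster scores (descending component order).
#' @param max_components cap on the components considered (default 100).
#' @param n_sd outlier fence in sample SDs (default 2).
#' @return Integer vector of outlier component indices (warns when empty:
#'   no cell-cycle signal detected).
#' @export
score_outliers <- function(sigmas, max_components = 100, n_sd = 2) {
  stopifnot(length(sigmas) >= 3)
  k <- seq_len(min(max_components, length(sigmas)))
  s <- sigmas[k]
  out <- unname(which(s - mean(s) > n_sd * sample_sd(s)))
  if (length(out) == 0) warn2("no cell-cycle signal detected (no score outliers)")
  out
}

#' Variance decomposition of components along a gene set
#'
#' Splits each component's score row into the contribution of a chosen gene
#' set and of the remaining genes, \eqn{P_i = P_i^{set} + P_i^{rest}}, and
#' decomposes the component variance into the directly explained fraction
#' `cc` = Var(P^set)/Var(P), the `unexplained` fraction Var(P^rest)/Var(P),
#' and the cross-covariance (`implied`) fraction 2 Cov(P^set, P^rest)/Var(P).
#' The three sum to one; `implied` may be negative, in which case the row is
#' flagged.
#'
#' @param n a `cc_transformed` object at stage `"normalized"`.
#' @param transform components x genes transform matrix (PCA weights
#'   \eqn{W^T} or rotated weights U), columns named by gene.
#' @param gene_set character vector of gene ids (subset of the genes of `n`).
#' @param components integer vector of component rows to decompose
#'   (default all).
#' @return A tibble with columns `component`, `cc`, `implied`,
#'   `unexplained`, `negative_implied`.
#' @export
variance_decomposition <- function(n, transform, gene_set,
                                   components = seq_len(nrow(transform))) {
  stopifnot(inherits(n, "cc_transformed"), n$stage == "normalized")
  genes <- rownames(n$values)
  stopifnot(identical(colnames(transform), genes))
  bad <- setdiff(gene_set, genes)
  if (length(bad)) stop2("gene_set not in matrix: ", bad[1])
  in_set <- genes %in% gene_set
  tr <- transform[components, , drop = FALSE]
  p_set <- tr[, in_set, drop = FALSE] %*% n$values[in_set, , drop = FALSE]
  p_rest <- tr[, !in_set, drop = FALSE] %*% n$values[!in_set, , drop = FALSE]
  p <- p_set + p_rest
  nc <- ncol(p)
  center <- function(m) m - rowMeans(m)
  p_set_c <- center(p_set); p_rest_c <- center(p_rest); p_c <- center(p)
  var_p <- rowSums(p_c^2) / (nc - 1)
  var_set <- rowSums(p_set_c^2) / (nc - 1)
  var_rest <- rowSums(p_rest_c^2) / (nc - 1)
  cov2 <- 2 * rowSums(p_set_c * p_rest_c) / (nc - 1)
  zero <- var_p == 0
  if (any(zero)) {
    warn2(sum(zero), " component(s) with zero variance skipped")
  }
  out <- tibble::tibble(
    component = components,
    cc = unname(var_set / var_p),
    implied = unname(cov2 / var_p),
    unexplained = unname(var_rest / var_p),
    negative_implied = unname(cov2 < 0)
  )
  out[!zero, ]
}
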