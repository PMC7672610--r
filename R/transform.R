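#' Staged expression transforms
#'
#' The analysis works on a staged sequence of matrix transforms of the raw
#' UMI counts S:
#' \describe{
#'   \item{scaled fractions (SF)}{each cell's counts divided by its total UMI
#'     count and multiplied by the scaling constant \eqn{\kappa}, the median of
#'     all per-cell totals: \eqn{SF = \kappa \cdot S \cdot T} with
#'     \eqn{T = diag(1/\theta_j)}.}
#'   \item{log fractions (LF)}{\eqn{LF = \log_e(SF + 1)}.}
#'   \item{normalized (N)}{LF restricted to a gene subset and z-scored per
#'     gene across cells (sample sd).}
#' }
#' A `cc_transformed` object records the stage, \eqn{\kappa}, and (after
#' normalization) the per-gene means and sds for later reuse when projecting
#' extrapolated states.
#'
#' @name transforms
NULL

new_transformed <- function(values, stage, kappa,
                            gene_means = NULL, gene_sds = NULL) {
  structure(list(values = values, stage = stage, kappa = kappa,
                 gene_means = gene_means, gene_sds = gene_sds),
            class = "cc_transformed")
}

#' @export
print.cc_transformed <- function(x, ...) {
  cat(sprintf("<cc_transformed stage=%s> %d genes x %d cells (kappa = %.1f)\n",
              x$stage, nrow(x$values), ncol(x$values), x$kappa))
  invisible(x)
}

#' Scaled fraction matrix
#'
#' Divides each cell's counts by the cell's total UMI count and multiplies by
#' \eqn{\kappa}, the median of all per-cell totals, yielding depth-normalized
#' "scaled counts" on a common scale.
#'
#' @param x a [cc_counts] object; every cell must have a positive total.
#' @param kappa scaling constant; defaults to the median of the per-cell
#'   totals of `x`.
#' @return A `cc_transformed` object with `stage = "scaled"`.
#' @export
scaled_fractions <- function(x, kappa = NULL) {
  stopifnot(inherits(x, "cc_counts"))
  theta <- colSums(x$counts)
  if (any(theta == 0)) stop2("cell with zero total UMI count")
  if (is.null(kappa)) kappa <- stats::median(theta)
  sf <- sweep(x$counts, 2, theta, "/") * kappa
  new_transformed(sf, "scaled", kappa)
}

#' Log fraction matrix
#'
#' Elementwise natural log of (scaled fractions + 1).
#'
#' @param x a `cc_transformed` object at stage `"scaled"`.
#' @return A `cc_transformed` object with `stage = "log"`.
#' @export
log_fractions <- function(x) {
  stopifnot(inherits(x, "cc_transformed"))
  if (x$stage != "scaled") stop2("log_fractions expects stage 'scaled'")
  if (any(x$values < 0)) stop2("negative entries in scaled fractions")
  new_transformed(log(x$values + 1), "log", x$kappa)
}

#' Gene-wise normalization
#'
#' Restricts the log-fraction matrix to a gene subset and z-scores each gene
#' row across cells (sample sd). Genes with zero sd are dropped with a
#' warning so downstream PCA weights stay well-defined. The per-gene means
#' and sds are recorded for reuse when projecting extrapolated states.
#'
#' @param x a `cc_transformed` object at stage `"log"`.
#' @param genes character vector of gene ids to keep; default all genes.
#' @return A `cc_transformed` object with `stage = "normalized"` and
#'   `gene_means`/`gene_sds` recorded.
#' @export
normalize_genes <- function(x, genes = rownames(x$values)) {
  stopifnot(inherits(x, "cc_transformed"))
  if (x$stage != "log") stop2("normalize_genes expects stage 'log'")
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing)) stop2("genes not in matrix: ", missing[1])
  v <- x$values[genes, , drop = FALSE]
  z <- zscore_rows(v)
  if (length(z$degenerate)) {
    warn2(length(z$degenerate), " constant gene(s) dropped during normalization")
    keep <- setdiff(seq_len(nrow(v)), z$degenerate)
    v <- z$values[keep, , drop = FALSE]
    means <- z$means[keep]; sds <- z$sds[keep]
  } else {
    v <- z$values; means <- z$means; sds <- z$sds
  }
  names(means) <- rownames(v); names(sds) <- rownames(v)
  new_transformed(v, "normalized", x$kappa, gene_means = means, gene_sds = sds)
}
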