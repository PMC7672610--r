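# Spearman correlation p-values by the t approximation, vectorized over a
# correlation matrix. n is the number of observations per correlation.
spearman_p <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}

# mean of |pairwise Spearman correlations| passing the p filter, over the
# columns of m (observations in rows). Returns c(mean, n_pairs_used).
mean_abs_spearman <- function(m, p_max) {
  n_obs <- nrow(m)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  p <- spearman_p(rho, n_obs)
  ut <- upper.tri(rho)
  ok <- ut & !is.na(rho) & p < p_max
  if (!any(ok)) return(c(NA_real_, 0))
  c(mean(abs(rho[ok])), sum(ok))
}

#' Critical-transition index along the cycle
#'
#' Splits the cells into `n_bins` angular bins of equal cell count and
#' computes, per bin, the ratio of the average absolute pairwise Spearman
#' gene-gene correlation to the average absolute pairwise cell-cell
#' correlation, keeping only pairs whose correlation p-value (t
#' approximation) is below `p_max`. The index rises ahead of a critical
#' state transition: gene-gene coordination increases while cells become
#' more heterogeneous. Bins where no pair passes the filter report `NA`.
#'
#' @param expr genes x cells expression matrix (log-fraction scale
#'   restricted to the variable genes is the intended input; Spearman is
#'   invariant to monotone per-gene transforms).
#' @param angles per-cell angles in `[0, 2*pi)` (aligned pseudotime
#'   angles), same cell order as `expr` columns.
#' @param n_bins number of equal-count angular bins (default 10).
#' @param p_max p-value cutoff for including a pair (default 0.05).
#' @return A tibble (class `cc_transition_profile`) with `bin`,
#'   `angle_start`, `angle_end`, `n_cells`, `ic`, `gene_pairs`,
#'   `cell_pairs`.
#' @export
transition_index <- function(expr, angles, n_bins = 10, p_max = 0.05) {
  stopifnot(is.matrix(expr), ncol(expr) == length(angles), nrow(expr) >= 2)
  n <- length(angles)
  ord <- order(angles)
  bins <- equal_count_bins(n, n_bins)
  if (min(table(bins)) < 3) stop2("each bin needs >= 3 cells")
  out <- lapply(seq_len(n_bins), function(b) {
    cells <- ord[bins == b]
    sub <- expr[, cells, drop = FALSE]
    gg <- mean_abs_spearman(t(sub), p_max)   # gene-gene: genes in columns
    cc <- mean_abs_spearman(sub, p_max)      # cell-cell: cells in columns
    ic <- if (is.na(gg[1]) || is.na(cc[1]) || cc[1] == 0) NA_real_ else gg[1] / cc[1]
    tibble::tibble(bin = b,
                   angle_start = min(angles[cells]),
                   angle_end = max(angles[cells]),
                   n_cells = length(cells),
                   ic = ic,
                   gene_pairs = as.integer(gg[2]),
                   cell_pairs = as.integer(cc[2]))
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("cc_transition_profile", class(res))
  res
}
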