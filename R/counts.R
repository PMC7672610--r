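#' Count-matrix container
#'
#' A `cc_counts` object holds a genes-by-cells digital gene expression (DGE)
#' matrix of non-negative integer UMI counts, with unique gene and cell
#' identifiers and an optional per-cell batch (experiment) label.
#'
#' @param counts integer matrix, genes in rows and cells in columns, with
#'   rownames (gene ids) and colnames (cell ids).
#' @param batch optional character vector of per-cell experiment labels,
#'   length `ncol(counts)`.
#' @return An object of class `cc_counts`: a list with elements `counts`
#'   (integer matrix) and `batch` (character or `NULL`).
#' @examples
#' m <- matrix(c(1L, 0L, 0L, 2L, 5L, 5L), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
#' cc_counts(m)
#' @export
cc_counts <- function(counts, batch = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop2("counts must carry gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    stop2("duplicate gene id: ", dup)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    stop2("duplicate cell id: ", dup)
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop2("counts must be finite non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (!is.null(batch)) {
    if (length(batch) != ncol(counts)) {
      stop2("batch labels must match the number of cells")
    }
    batch <- as.character(batch)
  }
  structure(list(counts = counts, batch = batch), class = "cc_counts")
}

#' @export
print.cc_counts <- function(x, ...) {
  cat(sprintf("<cc_counts> %d genes x %d cells", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$batch)) {
    cat(sprintf(" | %d batches", length(unique(x$batch))))
  }
  cat(sprintf(" | median total UMI %.0f\n", stats::median(colSums(x$counts))))
  invisible(x)
}

#' @export
dim.cc_counts <- function(x) dim(x$counts)

#' Per-cell total UMI counts
#'
#' @param x a [cc_counts] object.
#' @return Named numeric vector of column sums (total UMIs per cell).
#' @export
total_umis <- function(x) {
  stopifnot(inherits(x, "cc_counts"))
  colSums(x$counts)
}

#' Read a digital gene expression matrix
#'
#' Reads UMI count matrices in either of the two common plain-text dialects:
#' the Drop-seq `DigitalExpression` TSV (header row of cell barcodes, first
#' column of gene names) or MatrixMarket coordinate format with companion
#' one-gene-per-line and one-barcode-per-line files.
#'
#' @param path path to the TSV file (`dge_tsv`) or the `.mtx` file
#'   (`mtx_triplet`).
#' @param format `"dge_tsv"` or `"mtx_triplet"`.
#' @param genes_path,barcodes_path companion files for `mtx_triplet`; default
#'   to `genes.tsv` / `barcodes.tsv` next to the `.mtx` file.
#' @return A [cc_counts] object. Entries absent from a sparse triplet file
#'   are zeros.
#' @export
read_counts <- function(path, format = c("dge_tsv", "mtx_triplet"),
                        genes_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (format == "dge_tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             comment.char = "")
    if (nrow(tab) == 0 || ncol(tab) < 2) stop2("no cells in ", path)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop2("non-integer entry in ", path)
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop2("non-integer entry at gene row ", bad[1, 1],
            ", cell column ", bad[1, 2], " in ", path)
    }
    rownames(m) <- genes
    cc_counts(m)
  } else {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    for (p in c(genes_path, barcodes_path)) {
      if (!file.exists(p)) stop2("companion file not found: ", p)
    }
    mm <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    # tolerate cellranger-style two-column genes files; first token is the id
    genes <- vapply(strsplit(genes, "\t"), `[`, character(1), 1L)
    barcodes <- readLines(barcodes_path)
    if (length(genes) != nrow(mm)) stop2("gene list length != matrix rows")
    if (length(barcodes) != ncol(mm)) stop2("barcode list length != matrix cols")
    if (length(barcodes) == 0) stop2("no cells in ", path)
    dimnames(mm) <- list(genes, barcodes)
    cc_counts(mm)
  }
}

#' Write a count matrix
#'
#' Writes a [cc_counts] object in the Drop-seq DGE TSV dialect or as a
#' MatrixMarket triplet with companion gene/barcode files.
#'
#' @param x a [cc_counts] object.
#' @param path output TSV path (`dge_tsv`) or `.mtx` path (`mtx_triplet`).
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("dge_tsv", "mtx_triplet")) {
  stopifnot(inherits(x, "cc_counts"))
  format <- match.arg(format)
  if (format == "dge_tsv") {
    df <- data.frame(GENE = rownames(x$counts), x$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Filter genes and cells to expression thresholds
#'
#' Keeps genes expressed (count > 0) in at least `min_cells` cells and cells
#' expressing at least `min_genes` genes. Because removing genes can push a
#' cell below `min_genes` and vice versa, the gene-pass/cell-pass sweep is
#' repeated until a fixed point, which makes the result deterministic and
#' order-independent. The operation is idempotent.
#'
#' @param x a [cc_counts] object.
#' @param min_cells minimum number of cells a retained gene is detected in.
#' @param min_genes minimum number of detected genes per retained cell.
#' @return Filtered [cc_counts] object (batch labels subset accordingly).
#' @export
filter_matrix <- function(x, min_cells = 5, min_genes = 500) {
  stopifnot(inherits(x, "cc_counts"), min_cells >= 1, min_genes >= 1)
  m <- x$counts
  batch <- x$batch
  repeat {
    keep_g <- rowSums(m > 0) >= min_cells
    m2 <- m[keep_g, , drop = FALSE]
    keep_c <- colSums(m2 > 0) >= min_genes
    m2 <- m2[, keep_c, drop = FALSE]
    if (!is.null(batch)) batch <- batch[keep_c]
    done <- nrow(m2) == nrow(m) && ncol(m2) == ncol(m)
    m <- m2
    if (ncol(m) == 0) stop2("no cells survive filtering")
    if (done) break
  }
  cc_counts(m, batch)
}

#' Subset a count matrix by cells
#'
#' @param x a [cc_counts] object.
#' @param cells character vector of cell ids (or logical/integer index).
#' @return A [cc_counts] object restricted to `cells`.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "cc_counts"))
  if (is.character(cells)) cells <- match(cells, colnames(x$counts))
  if (is.logical(cells)) cells <- which(cells)
  if (anyNA(cells)) stop2("unknown cell id in subset")
  cc_counts(x$counts[, cells, drop = FALSE],
            if (!is.null(x$batch)) x$batch[cells])
}
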