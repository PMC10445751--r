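# Sparse cell x gene container with per-cell metadata.

#' Construct an `ngc_counts` object
#'
#' Light container bundling a sparse gene x cell count matrix with per-cell
#' and per-gene metadata tibbles. All downstream stages accept this object;
#' derived results are returned as plain tibbles.
#'
#' @param counts Gene x cell matrix (coerced to `dgCMatrix`). Dimnames
#'   required.
#' @param cells Tibble of per-cell metadata with a `cell_id` column matching
#'   `colnames(counts)`. Optional columns used downstream: `age`, `platform`,
#'   `tdtom`, `gfp`, `n_genes`, `n_umis`, `n_reads`, `mito_fraction`,
#'   `exonic_fraction`, plus `true_*` truth columns for synthetic data.
#' @param genes Tibble of per-gene metadata with a `gene_id` column matching
#'   `rownames(counts)`; a `role` column records planted gene programs in
#'   synthetic data.
#' @return An `ngc_counts` object.
#' @export
ngc_counts <- function(counts, cells = NULL, genes = NULL) {
  counts <- methods::as(methods::as(as(counts, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    abort("`counts` must carry gene rownames and cell colnames.")
  }
  if (is.null(cells)) cells <- tibble(cell_id = colnames(counts) %||% character())
  if (is.null(genes)) genes <- tibble(gene_id = rownames(counts) %||% character())
  cells <- as_tibble(cells)
  genes <- as_tibble(genes)
  if (!identical(as.character(cells$cell_id),
                 as.character(colnames(counts) %||% character()))) {
    abort("`cells$cell_id` must match colnames(counts) in order.")
  }
  if (!identical(as.character(genes$gene_id),
                 as.character(rownames(counts) %||% character()))) {
    abort("`genes$gene_id` must match rownames(counts) in order.")
  }
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "ngc_counts")
}

#' @export
print.ngc_counts <- function(x, ...) {
  cat(sprintf("<ngc_counts> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  extra <- setdiff(names(x$cells), "cell_id")
  if (length(extra)) cat("cell metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ngc_counts <- function(x) dim(x$counts)

#' Number of cells / genes
#' @param x An `ngc_counts` object.
#' @return Integer count.
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) nrow(x$counts)

#' Subset cells of an `ngc_counts`
#'
#' @param x An `ngc_counts` object.
#' @param keep Character cell ids or logical/integer index.
#' @return Subsetted `ngc_counts`.
#' @export
subset_cells <- function(x, keep) {
  if (is.character(keep)) keep <- match(keep, x$cells$cell_id)
  ngc_counts(x$counts[, keep, drop = FALSE], x$cells[keep, , drop = FALSE],
             x$genes)
}

#' Log-normalized expression of an `ngc_counts`
#'
#' @param x An `ngc_counts` object (or bare matrix, passed through
#'   [log_normalize()]).
#' @param scale Library-size target; 1e6 gives log1p-RPM.
#' @return Dense gene x cell matrix.
#' @export
log_rpm <- function(x, scale = 1e6) {
  m <- if (inherits(x, "ngc_counts")) x$counts else x
  log_normalize(m, scale = scale)
}

#' Write / read counts in MatrixMarket exchange format
#'
#' Emits `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `cell_metadata.tsv`
#' under `dir`, the on-disk convention used throughout the package.
#'
#' @param x An `ngc_counts` object.
#' @param dir Directory (created if needed).
#' @return `dir`, invisibly (for `write_counts_mtx`); an `ngc_counts` for
#'   `read_counts_mtx`.
#' @export
write_counts_mtx <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(x$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(tibble(cell_id = x$cells$cell_id),
                   file.path(dir, "barcodes.tsv"))
  readr::write_tsv(x$cells, file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cell_metadata.tsv"),
                           show_col_types = FALSE)
  rownames(m) <- genes$gene_id
  colnames(m) <- cells$cell_id
  ngc_counts(m, cells, genes)
}
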