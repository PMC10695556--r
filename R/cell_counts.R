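#' Single-cell count container
#'
#' Bundles a sparse gene-by-cell integer count matrix with per-cell
#' annotations (barcode, donor, cell type, doublet flag) and per-gene
#' annotations (identifier, mitochondrial flag). This is the object every
#' downstream module (QC, pseudobulk DE, cell-level DE, benchmark) consumes.
#'
#' @param counts a genes-by-cells matrix (coerced to [Matrix::dgCMatrix-class])
#'   with gene identifiers as rownames and barcodes as colnames.
#' @param cells data.frame with one row per cell: columns `barcode`,
#'   `donor_id`, `cell_type`, `is_doublet` (logical).
#' @param features data.frame with one row per gene: columns `gene_id` and
#'   `is_mito` (logical).
#' @return an object of class `cell_counts`.
#' @export
cell_counts <- function(counts, cells, features = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(features)) {
    features <- data.frame(
      gene_id = rownames(counts) %||% paste0("G", seq_len(nrow(counts))),
      is_mito = grepl("^MT-", rownames(counts) %||% character(0)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(
    nrow(features) == nrow(counts),
    nrow(cells) == ncol(counts),
    all(c("barcode", "donor_id", "cell_type") %in% names(cells))
  )
  if (is.null(cells$is_doublet)) cells$is_doublet <- FALSE
  if (anyDuplicated(cells$barcode)) stop("duplicate barcodes in cell metadata")
  rownames(counts) <- features$gene_id
  colnames(counts) <- cells$barcode
  structure(
    list(counts = counts, cells = cells, features = features),
    class = "cell_counts"
  )
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf(
    "cell_counts: %d genes x %d cells | %d donors, %d cell types, %d doublets\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(x$cells$donor_id)),
    length(unique(x$cells$cell_type)),
    sum(x$cells$is_doublet)
  ))
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

#' Subset cells of a cell_counts object
#'
#' @param x a `cell_counts` object.
#' @param cells logical, integer or barcode index over cells.
#' @param genes logical, integer or identifier index over genes.
#' @return a `cell_counts` object restricted to the selected cells/genes.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "cell_counts"))
  ci <- if (is.null(cells)) seq_len(ncol(x$counts)) else cells
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  if (is.character(ci)) ci <- match(ci, x$cells$barcode)
  if (is.character(gi)) gi <- match(gi, x$features$gene_id)
  cell_counts(
    x$counts[gi, ci, drop = FALSE],
    x$cells[ci, , drop = FALSE],
    x$features[gi, , drop = FALSE]
  )
}

mito_ids <- function(x) x$features$gene_id[x$features$is_mito]
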