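#' QC thresholds for the nucleus-level filter cascade
#'
#' Defaults follow common best-practice snRNA-seq QC: fixed minimums of 200
#' total counts and 200 expressed genes per nucleus, adaptive upper bounds at
#' 4 median absolute deviations (MAD) above the median for library size and
#' expressed-gene count, a 10% mitochondrial-fraction cut-off, and removal of
#' flagged doublets. A gene counts as "expressed" when it has at least
#' `expressed_gene_min_counts` counts in at least `expressed_gene_min_cells`
#' cells, computed once on the full pre-QC matrix.
#'
#' @param min_library_size minimum total counts per cell.
#' @param min_expressed_genes minimum expressed genes per cell.
#' @param mad_multiplier number of MADs for the adaptive upper thresholds.
#' @param mito_max mitochondrial-fraction cut-off in (0, 1].
#' @param mito_inclusive if `TRUE` (default) a cell fails when its
#'   mitochondrial fraction is `>= mito_max`; if `FALSE`, strictly `>`.
#' @param expressed_gene_min_counts,expressed_gene_min_cells definition of an
#'   expressed gene (see above).
#' @param drop_doublets whether flagged doublets fail QC.
#' @param mad_constant scale constant passed to [stats::mad()]; 1 by default
#'   (a plain median absolute deviation, no normal-consistency factor).
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_library_size = 200,
                          min_expressed_genes = 200,
                          mad_multiplier = 4,
                          mito_max = 0.10,
                          mito_inclusive = TRUE,
                          expressed_gene_min_counts = 2,
                          expressed_gene_min_cells = 3,
                          drop_doublets = TRUE,
                          mad_constant = 1) {
  stopifnot(
    min_library_size > 0, min_expressed_genes > 0, mad_multiplier > 0,
    mito_max > 0, mito_max <= 1,
    expressed_gene_min_counts >= 1, expressed_gene_min_cells >= 1
  )
  structure(
    list(
      min_library_size = min_library_size,
      min_expressed_genes = min_expressed_genes,
      mad_multiplier = mad_multiplier,
      mito_max = mito_max, mito_inclusive = isTRUE(mito_inclusive),
      expressed_gene_min_counts = expressed_gene_min_counts,
      expressed_gene_min_cells = expressed_gene_min_cells,
      drop_doublets = isTRUE(drop_doublets),
      mad_constant = mad_constant
    ),
    class = "qc_thresholds"
  )
}

#' Expressed-gene mask
#'
#' A gene is kept when at least `min_cells` cells carry at least `min_counts`
#' counts of it. Computed on the full (pre-QC) matrix.
#'
#' @param x a [cell_counts()] object or genes-by-cells matrix.
#' @param min_counts,min_cells thresholds (both >= 1).
#' @return logical vector over genes.
#' @export
expressed_gene_mask <- function(x, min_counts = 2, min_cells = 3) {
  stopifnot(min_counts >= 1, min_cells >= 1)
  m <- if (inherits(x, "cell_counts")) x$counts else x
  as.vector(Matrix::rowSums(m >= min_counts) >= min_cells)
}

#' Adaptive upper outlier threshold
#'
#' `median(values) + n_mads * mad(values)` with an unscaled MAD
#' (`constant = 1` by default). Values above the threshold are treated as
#' upper-tail outliers by [apply_qc()]. When the MAD is zero the threshold is
#' `+Inf` (no upper outliers) and a warning is raised.
#'
#' @param values numeric vector with at least 2 finite values.
#' @param n_mads number of MADs above the median.
#' @param constant MAD scale constant (see [stats::mad()]).
#' @return single numeric threshold.
#' @export
mad_upper_threshold <- function(values, n_mads = 4, constant = 1) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("need at least 2 finite values")
  m <- stats::median(v)
  s <- stats::mad(v, constant = constant)
  if (s == 0) {
    warning("MAD is zero; returning +Inf (no upper outliers)")
    return(Inf)
  }
  m + n_mads * s
}

#' Per-cell QC metrics
#'
#' Computes, for every cell: total counts (library size over all genes),
#' the number of expressed genes detected in the cell (restricted to the
#' expressed-gene mask when one is supplied), the mitochondrial fraction,
#' and the doublet flag carried in the metadata. Cells with zero total
#' counts get mitochondrial fraction 0 and a `zero_library` flag.
#'
#' @param x a [cell_counts()] object.
#' @param mito_gene_ids identifiers of mitochondrial genes; defaults to the
#'   object's `is_mito` annotation (or an `MT-` prefix match).
#' @param gene_mask optional logical mask over genes restricting which genes
#'   count towards `n_expressed_genes` (see [expressed_gene_mask()]).
#' @return data.frame with one row per cell: `barcode`, `total_counts`,
#'   `n_expressed_genes`, `mito_fraction`, `zero_library`, `is_doublet`.
#' @export
compute_cell_qc <- function(x, mito_gene_ids = NULL, gene_mask = NULL) {
  stopifnot(inherits(x, "cell_counts"))
  if (ncol(x$counts) == 0) stop("empty count matrix")
  m <- x$counts
  if (is.null(mito_gene_ids)) {
    mito_gene_ids <- mito_ids(x)
  } else {
    unknown <- setdiff(mito_gene_ids, x$features$gene_id)
    if (length(unknown)) {
      stop("unknown mitochondrial gene ids: ", paste(unknown, collapse = ", "))
    }
  }
  total <- as.vector(Matrix::colSums(m))
  mito <- if (length(mito_gene_ids)) {
    as.vector(Matrix::colSums(m[x$features$gene_id %in% mito_gene_ids, ,
                                drop = FALSE]))
  } else {
    numeric(ncol(m))
  }
  mm <- if (is.null(gene_mask)) m else m[gene_mask, , drop = FALSE]
  n_expr <- as.vector(Matrix::colSums(mm > 0))
  zero <- total == 0
  data.frame(
    barcode = x$cells$barcode,
    total_counts = total,
    n_expressed_genes = n_expr,
    mito_fraction = ifelse(zero, 0, mito / pmax(total, 1)),
    zero_library = zero,
    is_doublet = x$cells$is_doublet,
    stringsAsFactors = FALSE
  )
}

#' Apply the QC cascade
#'
#' Flags every cell against each criterion independently (fixed minimums,
#' adaptive MAD maximums, mitochondrial cut-off, doublet flag) and keeps the
#' cells that fail none. Because the criteria are evaluated independently, a
#' cell can fail several checks at once: per-criterion failure counts may
#' overlap, and only total-failed plus total-passed sums to the number of
#' input cells.
#'
#' @param metrics output of [compute_cell_qc()].
#' @param thresholds a [qc_thresholds()] object.
#' @return a list of class `qc_result`: `flags` (per-cell logical data.frame,
#'   one column per criterion), `pass` (logical vector), `summary`
#'   (data.frame `criterion`, `cells`, `percentage`), and the MAD thresholds
#'   used.
#' @export
apply_qc <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n <- nrow(metrics)
  if (n == 0) {
    empty <- data.frame(criterion = character(0), cells = integer(0),
                        percentage = numeric(0))
    return(structure(list(flags = data.frame(), pass = logical(0),
                          summary = empty, mad_bounds = c(NA, NA)),
                     class = "qc_result"))
  }
  max_lib <- if (n >= 2) {
    mad_upper_threshold(metrics$total_counts, thresholds$mad_multiplier,
                        thresholds$mad_constant)
  } else Inf
  max_genes <- if (n >= 2) {
    mad_upper_threshold(metrics$n_expressed_genes, thresholds$mad_multiplier,
                        thresholds$mad_constant)
  } else Inf
  mito_fail <- if (thresholds$mito_inclusive) {
    metrics$mito_fraction >= thresholds$mito_max
  } else {
    metrics$mito_fraction > thresholds$mito_max
  }
  flags <- data.frame(
    min_library_size = metrics$total_counts < thresholds$min_library_size,
    max_library_size = metrics$total_counts > max_lib,
    min_expressed_genes = metrics$n_expressed_genes < thresholds$min_expressed_genes,
    max_expressed_genes = metrics$n_expressed_genes > max_genes,
    high_mito = mito_fail,
    doublet = if (thresholds$drop_doublets) metrics$is_doublet else rep(FALSE, n)
  )
  fail <- Reduce(`|`, flags)
  per_crit <- vapply(flags, sum, integer(1))
  summary <- data.frame(
    criterion = c("total_failed", names(flags), "total_passed"),
    cells = c(sum(fail), per_crit, sum(!fail)),
    stringsAsFactors = FALSE
  )
  summary$percentage <- round(100 * summary$cells / n, 2)
  rownames(summary) <- NULL
  structure(
    list(flags = flags, pass = !fail, summary = summary,
         mad_bounds = c(library_size = max_lib, expressed_genes = max_genes),
         n_cells = n),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC cascade over %d cells (criteria overlap; only totals sum to 100%%)\n",
              x$n_cells %||% length(x$pass)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the full QC pipeline on a dataset
#'
#' Convenience wrapper: computes the expressed-gene mask on the pre-QC
#' matrix, per-cell metrics, applies the cascade and returns the filtered
#' object together with the accounting.
#'
#' @param x a [cell_counts()] object.
#' @param thresholds a [qc_thresholds()] object.
#' @param subset_genes if `TRUE`, also drop genes outside the expressed-gene
#'   mask from the returned matrix (default `FALSE`: the mask only defines
#'   the per-cell expressed-gene metric).
#' @return list: `filtered` (a `cell_counts`), `qc` (a `qc_result`),
#'   `metrics`, `gene_mask`.
#' @export
qc_filter <- function(x, thresholds = qc_thresholds(), subset_genes = FALSE) {
  mask <- expressed_gene_mask(x, thresholds$expressed_gene_min_counts,
                              thresholds$expressed_gene_min_cells)
  metrics <- compute_cell_qc(x, gene_mask = mask)
  qc <- apply_qc(metrics, thresholds)
  filt <- subset_cells(x, cells = qc$pass,
                       genes = if (subset_genes) mask else NULL)
  list(filtered = filt, qc = qc, metrics = metrics, gene_mask = mask)
}

#' Write a QC accounting report
#'
#' @param qc a `qc_result`.
#' @param path output TSV path (columns: criterion, cells, percentage).
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "qc_result"))
  utils::write.table(qc$summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
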