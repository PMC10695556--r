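#' Read a 10x-style count bundle
#'
#' Reads `matrix.mtx` (MatrixMarket coordinate format, 1-based indices),
#' `features.tsv`, `barcodes.tsv` and `cell_metadata.tsv` from a directory
#' and assembles a [cell_counts()] object. Dimension mismatches between the
#' matrix header and the TSV lengths, and duplicate barcodes, are errors.
#'
#' @param dir directory containing the four files.
#' @return a [cell_counts()] object.
#' @export
read_count_bundle <- function(dir) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "cell_metadata.tsv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("missing bundle file(s): ", paste(missing, collapse = ", "))
  }
  m <- methods::as(Matrix::readMM(paths[1]), "CsparseMatrix")
  feats <- utils::read.delim(paths[2], header = TRUE, stringsAsFactors = FALSE)
  bcs <- readLines(paths[3])
  meta <- utils::read.delim(paths[4], header = TRUE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m)) {
    stop(sprintf("features.tsv has %d rows but matrix has %d rows",
                 nrow(feats), nrow(m)))
  }
  if (length(bcs) != ncol(m)) {
    stop(sprintf("barcodes.tsv has %d entries but matrix has %d columns",
                 length(bcs), ncol(m)))
  }
  if (anyDuplicated(bcs)) stop("duplicate barcodes in barcodes.tsv")
  if (!identical(sort(meta$barcode), sort(bcs))) {
    stop("cell_metadata.tsv barcodes do not match barcodes.tsv")
  }
  meta <- meta[match(bcs, meta$barcode), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(feats$is_mito)) feats$is_mito <- grepl("^MT-", feats$gene_id)
  meta$is_doublet <- as.logical(meta$is_doublet %||% FALSE)
  cell_counts(m, meta, feats)
}

#' Write a 10x-style count bundle
#'
#' Writes `matrix.mtx` in MatrixMarket coordinate *integer* format (1-based
#' indices, header line), plus `features.tsv`, `barcodes.tsv` and
#' `cell_metadata.tsv`. The bundle round-trips through
#' [read_count_bundle()].
#'
#' @param x a [cell_counts()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_bundle <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(x$counts, "TsparseMatrix")
  if (any(m@x < 0)) stop("negative counts cannot be written")
  con <- file(file.path(dir, "matrix.mtx"), "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x)) {
    writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  }
  utils::write.table(x$features, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(x$cells$barcode, file.path(dir, "barcodes.tsv"))
  utils::write.table(x$cells, file.path(dir, "cell_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a simulated dataset to disk
#'
#' Writes the count bundle plus `donor_design.tsv` and `ground_truth.tsv`.
#'
#' @param dataset an `sc_dataset` from [generate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sc_dataset"))
  write_count_bundle(dataset$counts, dir)
  utils::write.table(dataset$design, file.path(dir, "donor_design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a donor design table
#'
#' @param path TSV with columns `donor_id`, `condition`.
#' @return data.frame.
#' @export
read_donor_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("donor_id", "condition") %in% names(d))) {
    stop("donor design needs columns donor_id, condition")
  }
  d
}

#' Write a DEG table in the reference TSV dialect
#'
#' Columns `Cell, logFC, logCPM, LR, p-Value, adj_pval, HGNC`; the `LR`
#' column is left empty for cell-level results that have no likelihood-ratio
#' statistic.
#'
#' @param table DEG table data.frame (`gene`, `cell_type`, `logFC`,
#'   `p_value`, `adj_pval`, optionally `logCPM`, `LR`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  out <- data.frame(
    Cell = table$cell_type,
    logFC = table$logFC,
    logCPM = table$logCPM %||% rep(NA_real_, nrow(table)),
    LR = table$LR %||% rep(NA_real_, nrow(table)),
    `p-Value` = table$p_value,
    adj_pval = table$adj_pval,
    HGNC = table$gene,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DEG table written by [write_deg_table()]
#'
#' @param path TSV path.
#' @return DEG table data.frame with standard column names.
#' @export
read_deg_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  data.frame(
    gene = raw$HGNC,
    cell_type = raw$Cell,
    logFC = raw$logFC,
    logCPM = raw$logCPM,
    LR = raw$LR,
    p_value = raw[["p-Value"]],
    adj_pval = raw$adj_pval,
    stringsAsFactors = FALSE
  )
}

#' Read and validate a pipeline run configuration
#'
#' A YAML file with optional sections `simulation` (arguments of
#' [sim_params()]), `qc` (arguments of [qc_thresholds()]), `de`
#' (`fdr`, `min_cells`, `normalize`), `benchmark` (`n_perm`, `base_seed`)
#' and `paths`. Referenced input paths must resolve at validation time.
#'
#' @param path YAML file path.
#' @return validated list of class `run_config` with fully-constructed
#'   `sim_params`/`qc_thresholds` objects.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sim <- do.call(sim_params, cfg$simulation %||% list())
  qc <- do.call(qc_thresholds, cfg$qc %||% list())
  de <- cfg$de %||% list()
  de$fdr <- de$fdr %||% 0.05
  de$min_cells <- de$min_cells %||% 10
  de$normalize <- de$normalize %||% TRUE
  if (de$fdr <= 0 || de$fdr >= 1) stop("de$fdr must be in (0, 1)")
  bench <- cfg$benchmark %||% list()
  bench$n_perm <- bench$n_perm %||% 100
  bench$base_seed <- bench$base_seed %||% 1L
  if (bench$n_perm < 1) stop("benchmark$n_perm must be >= 1")
  for (p in cfg$paths$inputs %||% list()) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(
    list(simulation = sim, qc = qc, de = de, benchmark = bench,
         paths = cfg$paths %||% list(),
         log_level = cfg$log_level %||% "info"),
    class = "run_config"
  )
}
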