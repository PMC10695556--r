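#' Summarise a DEG table
#'
#' Restricts a DEG table to rows below an FDR cut-off and reports: the
#' number of unique gene symbols (a gene significant in several cell types
#' counts once), the median absolute log2 fold change, the median adjusted
#' p-value, and per-cell-type DEG row counts with integer-rounded
#' percentages of all DEG rows.
#'
#' @param table a DEG table data.frame with columns `gene`, `cell_type`,
#'   `logFC`, `adj_pval`.
#' @param fdr adjusted p-value cut-off (default 0.05).
#' @return list of class `deg_summary`: `n_deg_rows`, `n_unique_genes`,
#'   `median_abs_logfc`, `median_adj_pval`, `per_cell_type` (data.frame
#'   `cell_type`, `n_deg`, `percentage`).
#' @export
deg_summary <- function(table, fdr = 0.05) {
  need <- c("gene", "cell_type", "logFC", "adj_pval")
  if (!all(need %in% names(table))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  sig <- table[!is.na(table$adj_pval) & table$adj_pval < fdr, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- list(n_deg_rows = 0L, n_unique_genes = 0L,
                median_abs_logfc = 0, median_adj_pval = 0,
                per_cell_type = data.frame(cell_type = character(0),
                                           n_deg = integer(0),
                                           percentage = numeric(0)),
                fdr = fdr)
    return(structure(out, class = "deg_summary"))
  }
  counts <- table(sig$cell_type)
  per_ct <- data.frame(
    cell_type = names(counts),
    n_deg = as.integer(counts),
    percentage = round(100 * as.integer(counts) / nrow(sig)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      n_deg_rows = nrow(sig),
      n_unique_genes = length(unique(sig$gene)),
      median_abs_logfc = stats::median(abs(sig$logFC)),
      median_adj_pval = stats::median(sig$adj_pval),
      per_cell_type = per_ct,
      fdr = fdr
    ),
    class = "deg_summary"
  )
}

#' @export
print.deg_summary <- function(x, ...) {
  cat(sprintf(
    "DEG summary (FDR < %g): %d rows, %d unique genes\n  median |logFC| = %.3f, median adj. p = %.3g\n",
    x$fdr, x$n_deg_rows, x$n_unique_genes,
    x$median_abs_logfc, x$median_adj_pval
  ))
  print(x$per_cell_type, row.names = FALSE)
  invisible(x)
}

#' @export
as.list.deg_summary <- function(x, ...) unclass(x)

#' Correlation between DEG counts and cell counts
#'
#' Sample Pearson correlation between per-cell-type DEG counts and
#' per-cell-type (post-QC) cell counts — the diagnostic that exposes
#' pseudoreplication: treating cells as replicates makes the number of
#' discoveries track the number of cells rather than any biology.
#'
#' @param deg_counts,cell_counts numeric vectors over cell types; when both
#'   are named, they are matched by name and the names must agree.
#' @return Pearson correlation, or `NA` with a warning when either vector is
#'   constant.
#' @export
deg_cellcount_correlation <- function(deg_counts, cell_counts) {
  if (!is.null(names(deg_counts)) && !is.null(names(cell_counts))) {
    if (!setequal(names(deg_counts), names(cell_counts))) {
      stop("deg_counts and cell_counts have mismatched cell-type names")
    }
    cell_counts <- cell_counts[names(deg_counts)]
  } else if (length(deg_counts) != length(cell_counts)) {
    stop("deg_counts and cell_counts must have equal length")
  }
  if (length(deg_counts) < 3) stop("need at least 3 cell types")
  ok <- is.finite(deg_counts) & is.finite(cell_counts)
  if (stats::sd(deg_counts[ok]) == 0 || stats::sd(cell_counts[ok]) == 0) {
    warning("constant vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(deg_counts[ok], cell_counts[ok])
}

#' Fold-change agreement between two DEG tables
#'
#' Inner-joins two DEG tables on (gene, cell type), restricts to rows
#' significant in `tableB` at `fdr_cut`, and reports the Pearson correlation
#' of the paired log2 fold changes.
#'
#' @param tableA,tableB DEG table data.frames (`gene`, `cell_type`, `logFC`,
#'   `adj_pval`).
#' @param fdr_cut significance cut-off applied to `tableB`.
#' @return list: `n_genes` (joined rows), `r` (Pearson correlation, `NA`
#'   with a warning when fewer than 3 rows join or a side is constant).
#' @export
compare_fold_changes <- function(tableA, tableB, fdr_cut = 0.05) {
  b <- tableB[!is.na(tableB$adj_pval) & tableB$adj_pval < fdr_cut, ]
  j <- merge(tableA[, c("gene", "cell_type", "logFC")],
             b[, c("gene", "cell_type", "logFC")],
             by = c("gene", "cell_type"), suffixes = c("_A", "_B"))
  if (nrow(j) < 3) {
    warning("fewer than 3 joined rows; correlation undefined")
    return(list(n_genes = nrow(j), r = NA_real_))
  }
  if (stats::sd(j$logFC_A) == 0 || stats::sd(j$logFC_B) == 0) {
    warning("constant fold changes; correlation undefined")
    return(list(n_genes = nrow(j), r = NA_real_))
  }
  list(n_genes = nrow(j), r = stats::cor(j$logFC_A, j$logFC_B))
}

# md5 digests of the shipped fixture TSVs, frozen at packaging time
.fixture_md5 <- c(
  processed = "1304312ebb55cbaf07198f296a43231d",
  reprocessed = "017e162b8ffe45619dcd62dd6a259122"
)

#' Load a packaged reference DEG table
#'
#' The package ships, as plain-TSV fixtures transcribed from a published
#' pseudobulk reanalysis of the first Alzheimer's-disease snRNA-seq cohort,
#' the two donor-level DEG tables that anchor its worked examples:
#' `"processed"` — pseudobulk DE run on the original authors' processed
#' matrix (26 rows, 25 of them microglial), and `"reprocessed"` — the same
#' procedure on a stringently re-QC'd matrix (16 rows). Files are verified
#' against frozen md5 checksums on load.
#'
#' @param name `"processed"` or `"reprocessed"`.
#' @return a DEG table data.frame: `gene`, `cell_type`, `logFC`, `logCPM`,
#'   `LR`, `p_value`, `adj_pval` (plus `ensembl_id` for `"reprocessed"`).
#' @export
load_deg_fixture <- function(name = c("processed", "reprocessed")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      sprintf("deg_pseudobulk_%s.tsv", name),
                      package = "pseudobulkDE", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[name]))) {
    stop(sprintf("fixture %s failed its checksum (%s)", name, md5))
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  out <- data.frame(
    gene = raw$HGNC,
    cell_type = raw$Cell,
    logFC = raw$logFC,
    logCPM = raw$logCPM,
    LR = raw$LR,
    p_value = raw[["p-Value"]],
    adj_pval = raw$adj_pval,
    stringsAsFactors = FALSE
  )
  if (!is.null(raw$ensembl_id)) out$ensembl_id <- raw$ensembl_id
  out
}

#' Published cell-level summary statistics
#'
#' Printed headline numbers of the reference reanalysis that the package
#' uses as inputs when reproducing its ratio arguments: the cell-level
#' (pseudoreplication) DEG count at FDR 0.05, and the median absolute log2
#' fold change and median FDR of those cell-level DEGs.
#'
#' @return named list: `n_cell_level_degs`, `median_abs_logfc`,
#'   `median_adj_pval`.
#' @export
published_summary_stats <- function() {
  path <- system.file("extdata", "published_summary_stats.json",
                      package = "pseudobulkDE", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
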