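#' Donor-level pseudobulk differential expression
#'
#' The recommended DE procedure: counts are sum-aggregated to one sample per
#' (donor, cell type), lowly-expressed genes are filtered, TMM normalisation
#' factors are computed, and each gene is tested with a negative-binomial
#' GLM likelihood-ratio test on the condition term (see [fit_nb_lrt()]).
#' Donors — the unit of biological replication — carry the degrees of
#' freedom, so within-donor correlation between cells cannot masquerade as
#' evidence.
#'
#' @param x a [cell_counts()] object (typically post-QC).
#' @param design donor design data.frame (`donor_id`, `condition`).
#' @param cell_types cell types to analyse (default: all present).
#' @param min_cells minimum cells per (donor, cell type) sample.
#' @param min_cpm,min_samples gene filter (see [filter_expressed_pb()]).
#' @param normalize compute TMM factors (default `TRUE`).
#' @param dispersion,prior_df dispersion settings (see [fit_nb_lrt()]).
#' @param adjust `"within"` (default) adjusts p-values per cell type,
#'   `"global"` across the combined table.
#' @param ref_condition reference condition for fold changes.
#' @return object of class `pseudobulk_de` with elements `table` (combined
#'   `deg_table` with a `cell_type` column), `pseudobulk` (per-cell-type
#'   matrices), and the call parameters.
#' @seealso [wilcoxon_de()] for the cell-level procedure it is contrasted
#'   with, [run_benchmark()] for the permutation comparison.
#' @export
pseudobulk_de <- function(x, design, cell_types = NULL, min_cells = 10,
                          min_cpm = 1, min_samples = NULL, normalize = TRUE,
                          dispersion = NULL, prior_df = 10,
                          adjust = c("within", "global"),
                          ref_condition = NULL) {
  adjust <- match.arg(adjust)
  pbs <- aggregate_pseudobulk(x, design, min_cells = min_cells,
                              cell_types = cell_types)
  tabs <- lapply(pbs, function(pb) {
    if (ncol(pb$counts) < 4 || length(unique(pb$samples$condition)) < 2 ||
        any(table(pb$samples$condition) < 2)) {
      return(NULL)
    }
    mask <- filter_expressed_pb(pb, min_cpm = min_cpm,
                                min_samples = min_samples)
    pb$counts <- pb$counts[mask, , drop = FALSE]
    if (nrow(pb$counts) == 0) return(NULL)
    if (normalize) pb <- tmm_norm_factors(pb)
    tab <- fit_nb_lrt(pb, dispersion = dispersion, prior_df = prior_df,
                      ref_condition = ref_condition)
    tab$cell_type <- pb$cell_type
    tab
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  tab <- do.call(rbind, lapply(tabs, as.data.frame))
  if (is.null(tab)) tab <- data.frame()
  if (nrow(tab) && adjust == "global") {
    tab$adj_pval <- bh_adjust(tab$p_value)
  }
  rownames(tab) <- NULL
  structure(
    list(table = tab, pseudobulk = pbs, method = "pseudobulk",
         adjust = adjust, min_cells = min_cells),
    class = "pseudobulk_de"
  )
}

#' @export
print.pseudobulk_de <- function(x, fdr = 0.05, ...) {
  cat("Pseudobulk NB-GLM likelihood-ratio differential expression\n")
  if (!nrow(x$table)) {
    cat("  (no testable cell types)\n")
    return(invisible(x))
  }
  sig <- stats::aggregate(adj_pval ~ cell_type, data = x$table,
                          FUN = function(p) sum(p < fdr, na.rm = TRUE))
  names(sig)[2] <- sprintf("DEGs (FDR < %g)", fdr)
  print(sig, row.names = FALSE)
  invisible(x)
}

#' @export
summary.pseudobulk_de <- function(object, fdr = 0.05, ...) {
  deg_summary(object$table, fdr = fdr)
}
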