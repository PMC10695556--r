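# Two-sample rank-sum test vectorised across genes.
#
# For each row of `x` (genes), compares the cells in `grp1` against the
# rest using mid-ranks. Uses the normal approximation with tie-corrected
# variance and a 0.5 continuity correction; switches to exact enumeration of
# all group assignments when both groups have at most `exact_max`
# observations (which is also exact under ties).
rank_sum_matrix <- function(x, grp1, exact_max = 8L) {
  rank_sum_eval(rank_sum_prep(x), grp1, exact_max = exact_max)
}

# Precompute the label-independent parts (mid-ranks and tie corrections);
# the permutation benchmark reuses them across label shuffles.
rank_sum_prep <- function(x) {
  x <- as.matrix(x)
  rk <- t(apply(x, 1L, rank))
  tie_term <- apply(rk, 1L, function(r) {
    t <- tabulate(tabulate(as.integer(round(2 * r))))
    k <- seq_along(t)
    sum(t * (k^3 - k))
  })
  list(rk = rk, tie_term = tie_term, n = ncol(x))
}

rank_sum_eval <- function(prep, grp1, exact_max = 8L) {
  rk <- prep$rk
  n <- prep$n
  n1 <- sum(grp1)
  n2 <- n - n1
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  W <- rowSums(rk[, grp1, drop = FALSE])     # rank sum of group 1
  EW <- n1 * (n + 1) / 2

  if (n1 <= exact_max && n2 <= exact_max) {
    p <- exact_rank_sum_p(rk, which(grp1))
  } else {
    varW <- n1 * n2 / 12 * ((n + 1) - prep$tie_term / (n * (n - 1)))
    z <- (abs(W - EW) - 0.5) / sqrt(varW)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p[varW <= 0] <- 1
    p <- pmin(pmax(p, 0), 1)
  }
  list(statistic = W - n1 * (n1 + 1) / 2, p = p)
}

# Exact two-sided p by enumerating all choose(n, n1) group-1 assignments of
# the observed mid-ranks: p = P(|S - E| >= |obs - E|).
exact_rank_sum_p <- function(rk, idx1) {
  n <- ncol(rk)
  n1 <- length(idx1)
  combos <- utils::combn(n, n1)
  K <- ncol(combos)
  A <- matrix(0, n, K)
  A[cbind(as.vector(combos), rep(seq_len(K), each = n1))] <- 1
  S <- rk %*% A                               # G x K rank sums
  EW <- n1 * (n + 1) / 2
  obs <- rowSums(rk[, idx1, drop = FALSE])
  rowMeans(abs(S - EW) >= abs(obs - EW) - 1e-9)
}

#' Cell-level ("pseudoreplication") Wilcoxon differential expression
#'
#' The procedure under study: every cell is treated as an independent
#' replicate. Within each cell type, each cell is normalised to counts per
#' ten thousand and log1p-transformed (configurable to raw counts), then
#' every gene is tested between case and control cells with a two-sample
#' rank-sum test (mid-ranks; tie-corrected normal approximation with
#' continuity correction, exact enumeration when both groups have <= 8
#' cells). P-values are Benjamini-Hochberg adjusted within each cell type.
#' The log2 fold change is the ratio of group means of the normalised
#' expression with a small pseudo-count.
#'
#' Because cells from one donor are correlated, this test's nominal error
#' control is invalid whenever donor-level variability exists; the package
#' implements it to quantify that inflation, not to recommend it.
#'
#' @param x a [cell_counts()] object (typically post-QC).
#' @param design donor design data.frame (`donor_id`, `condition`).
#' @param cell_types cell types to test (default: all present).
#' @param normalize `"cp10k_log1p"` (default) or `"raw"`.
#' @param exact_max exact-test cutover: exact enumeration when both groups
#'   have at most this many cells.
#' @param ref_condition reference condition (fold changes are case over
#'   reference); defaults to `"control"` when present.
#' @param eps pseudo-count for the fold-change ratio.
#' @return object of class `cellwise_de` with a `table` data.frame:
#'   `gene`, `cell_type`, `logFC`, `p_value`, `adj_pval`, `n_cells_case`,
#'   `n_cells_control`.
#' @export
wilcoxon_de <- function(x, design, cell_types = NULL,
                        normalize = c("cp10k_log1p", "raw"),
                        exact_max = 8L, ref_condition = NULL, eps = 1e-9) {
  normalize <- match.arg(normalize)
  prep <- wilcoxon_prep(x, cell_types = cell_types, normalize = normalize)
  wilcoxon_eval(prep, design, exact_max = exact_max,
                ref_condition = ref_condition, eps = eps)
}

# Label-independent precomputation for the cell-level test: per cell type,
# the normalised matrix, mid-ranks, tie corrections and constant-gene flags.
wilcoxon_prep <- function(x, cell_types = NULL,
                          normalize = c("cp10k_log1p", "raw")) {
  stopifnot(inherits(x, "cell_counts"))
  normalize <- match.arg(normalize)
  cell_types <- cell_types %||% sort(unique(x$cells$cell_type))
  per_ct <- lapply(cell_types, function(ct) {
    j <- which(x$cells$cell_type == ct)
    m <- as.matrix(x$counts[, j, drop = FALSE])
    tot <- pmax(colSums(m), 1)
    norm <- sweep(m, 2, tot, "/") * 1e4
    test_mat <- if (normalize == "cp10k_log1p") log1p(norm) else m
    list(
      cell_type = ct,
      donor_id = x$cells$donor_id[j],
      norm = norm,
      prep = rank_sum_prep(test_mat),
      constant = apply(test_mat, 1L, function(v) all(v == v[1]))
    )
  })
  list(per_ct = per_ct, gene_id = x$features$gene_id, normalize = normalize)
}

wilcoxon_eval <- function(prep, design, exact_max = 8L,
                          ref_condition = NULL, eps = 1e-9) {
  lev <- unique(design$condition)
  if (length(lev) != 2) stop("need exactly two conditions")
  ref <- ref_condition %||% (if ("control" %in% lev) "control" else sort(lev)[1])
  res <- lapply(prep$per_ct, function(pc) {
    cc <- design$condition[match(pc$donor_id, design$donor_id)]
    if (length(unique(cc)) < 2) {
      stop(sprintf("cell type %s has cells from only one condition",
                   pc$cell_type))
    }
    grp1 <- cc != ref
    rs <- rank_sum_eval(pc$prep, grp1, exact_max = exact_max)
    mean_case <- rowMeans(pc$norm[, grp1, drop = FALSE])
    mean_ctrl <- rowMeans(pc$norm[, !grp1, drop = FALSE])
    lfc <- log2((mean_case + eps) / (mean_ctrl + eps))
    p <- rs$p
    p[pc$constant] <- 1
    lfc[pc$constant & abs(mean_case - mean_ctrl) < 1e-12] <- 0
    data.frame(
      gene = prep$gene_id,
      cell_type = pc$cell_type,
      logFC = lfc,
      p_value = p,
      adj_pval = bh_adjust(p),
      n_cells_case = sum(grp1),
      n_cells_control = sum(!grp1),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(table = do.call(rbind, res), method = "pseudoreplication",
         normalize = prep$normalize, ref_condition = ref),
    class = "cellwise_de"
  )
}

#' @export
print.cellwise_de <- function(x, fdr = 0.05, ...) {
  cat("Cell-level (pseudoreplication) Wilcoxon DE\n")
  sig <- stats::aggregate(adj_pval ~ cell_type, data = x$table,
                          FUN = function(p) sum(p < fdr))
  names(sig)[2] <- sprintf("DEGs (FDR < %g)", fdr)
  print(sig, row.names = FALSE)
  invisible(x)
}

#' Two-stage DEG filter over a cell-level and a donor-level table
#'
#' Utility representing the combinatorial rule of requiring a gene to pass a
#' stringent FDR in the cell-level analysis and a looser FDR in a
#' donor-level analysis. Provided for completeness of the comparison; the
#' donor-level partner here is any `deg_table`-shaped result.
#'
#' @param cell_table,donor_table data.frames with `gene`, `cell_type`,
#'   `adj_pval` columns.
#' @param cell_fdr,donor_fdr the two cut-offs (defaults 0.01 and 0.05).
#' @return data.frame of (gene, cell_type) rows passing both.
#' @export
two_stage_deg_filter <- function(cell_table, donor_table,
                                 cell_fdr = 0.01, donor_fdr = 0.05) {
  a <- cell_table[cell_table$adj_pval < cell_fdr, c("gene", "cell_type")]
  b <- donor_table[donor_table$adj_pval < donor_fdr, c("gene", "cell_type")]
  merge(a, b, by = c("gene", "cell_type"))
}
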