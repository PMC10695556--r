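#' Sum-aggregate cells into donor-level pseudobulk samples
#'
#' For each cell type, sums counts over all cells of each donor, producing a
#' genes-by-donors integer matrix in which the donor — not the cell — is the
#' unit of replication. Donor/cell-type combinations contributing fewer than
#' `min_cells` cells are dropped (too few cells make an unstable sample);
#' donors with zero cells of a type are simply absent.
#'
#' @param x a [cell_counts()] object (typically post-QC).
#' @param design donor design data.frame (`donor_id`, `condition`).
#' @param min_cells minimum cells per (donor, cell type) sample; default 10.
#' @param cell_types cell types to aggregate (default: all present).
#' @param verbose message dropped samples.
#' @return named list, one element per cell type, each of class `pseudobulk`:
#'   `counts` (dense genes-by-samples matrix), `samples` (data.frame
#'   `donor_id`, `condition`, `n_cells`, `lib_size`), `norm_factors`
#'   (initially 1).
#' @export
aggregate_pseudobulk <- function(x, design, min_cells = 10,
                                 cell_types = NULL, verbose = FALSE) {
  stopifnot(inherits(x, "cell_counts"))
  if (!all(x$cells$donor_id %in% design$donor_id)) {
    stop("cells reference donors absent from the design")
  }
  cell_types <- cell_types %||% sort(unique(x$cells$cell_type))
  cond <- design$condition[match(x$cells$donor_id, design$donor_id)]
  out <- lapply(cell_types, function(ct) {
    j <- which(x$cells$cell_type == ct)
    donor <- factor(x$cells$donor_id[j], levels = design$donor_id)
    # sparse indicator gives exact integer group sums
    ind <- Matrix::sparseMatrix(
      i = seq_along(j), j = as.integer(donor),
      x = 1, dims = c(length(j), nrow(design))
    )
    pb <- as.matrix(x$counts[, j, drop = FALSE] %*% ind)
    colnames(pb) <- design$donor_id
    ncells <- as.vector(table(donor))
    keep <- ncells >= min_cells
    if (verbose && any(!keep & ncells > 0)) {
      message(sprintf("%s: dropping %d sample(s) with < %d cells",
                      ct, sum(!keep & ncells > 0), min_cells))
    }
    pb <- pb[, keep, drop = FALSE]
    samples <- data.frame(
      donor_id = design$donor_id[keep],
      condition = design$condition[keep],
      n_cells = ncells[keep],
      lib_size = colSums(pb),
      stringsAsFactors = FALSE
    )
    structure(list(counts = pb, samples = samples,
                   norm_factors = rep(1, ncol(pb)), cell_type = ct),
              class = "pseudobulk")
  })
  names(out) <- cell_types
  out
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk [%s]: %d genes x %d samples (%s)\n",
              x$cell_type %||% "?", nrow(x$counts), ncol(x$counts),
              paste(table(x$samples$condition), collapse = " vs ")))
  invisible(x)
}

#' Trimmed mean of M-values normalisation factors
#'
#' Computes per-sample scaling factors relative to a reference sample: genes
#' are trimmed by log-ratio (30% each tail) and by average abundance (5%
#' each tail), the surviving log2 ratios are averaged with inverse
#' asymptotic-variance weights, and the result is exponentiated. Factors are
#' rescaled to geometric mean 1. A sample with zero library size receives
#' factor 1 with a warning.
#'
#' @param x a `pseudobulk` object or genes-by-samples count matrix.
#' @param lib_sizes optional library sizes (default: column sums).
#' @param logratio_trim,abundance_trim two-sided trim fractions.
#' @return numeric vector of normalisation factors (geometric mean 1). When
#'   `x` is a `pseudobulk` object, the object is returned with its
#'   `norm_factors` slot filled.
#' @export
tmm_norm_factors <- function(x, lib_sizes = NULL,
                             logratio_trim = 0.3, abundance_trim = 0.05) {
  obj <- NULL
  if (inherits(x, "pseudobulk")) {
    obj <- x
    x <- x$counts
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 samples")
  N <- lib_sizes %||% colSums(x)
  zero_lib <- N == 0
  if (any(zero_lib)) warning("sample(s) with zero library size get factor 1")
  if (sum(!zero_lib) < 2) stop("need at least 2 samples with positive library size")

  # reference: sample whose 75th count quantile (scaled) is closest to the mean
  f75 <- vapply(which(!zero_lib), function(i) {
    stats::quantile(x[, i], 0.75) / N[i]
  }, numeric(1))
  ref <- which(!zero_lib)[which.min(abs(f75 - mean(f75)))]

  f <- rep(1, ncol(x))
  for (i in seq_len(ncol(x))) {
    if (zero_lib[i]) next
    f[i] <- tmm_pair(x[, i], x[, ref], N[i], N[ref],
                     logratio_trim, abundance_trim)
  }
  f <- f / exp(mean(log(f)))
  if (!is.null(obj)) {
    obj$norm_factors <- f
    return(obj)
  }
  f
}

# TMM factor of `obs` against `ref` (both raw count vectors)
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  o <- obs[keep]; r <- ref[keep]
  M <- log2((o / n_obs) / (r / n_ref))
  # sum-of-logs form: keeps ties bit-identical across samples, which matters
  # because trimming ranks many tied abundances
  A <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  fin <- is.finite(M) & is.finite(A) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (n == 0) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abundance_trim) + 1
  hiS <- n + 1 - loS
  keep2 <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
  if (!any(keep2)) return(1)
  f <- 2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(f)) 1 else f
}

#' Filter pseudobulk genes by expression
#'
#' Keeps genes with counts-per-million above `min_cpm` in at least
#' `min_samples` samples. When `min_samples` is `NULL` it defaults to the
#' smaller condition group size.
#'
#' @param pb a `pseudobulk` object.
#' @param min_cpm CPM threshold (strictly greater than).
#' @param min_samples minimum qualifying samples.
#' @return logical vector over genes.
#' @export
filter_expressed_pb <- function(pb, min_cpm = 1, min_samples = NULL) {
  stopifnot(inherits(pb, "pseudobulk"))
  min_samples <- min_samples %||% min(table(pb$samples$condition))
  N <- pmax(pb$samples$lib_size, 1)
  cpm <- sweep(pb$counts, 2, N, "/") * 1e6
  rowSums(cpm > min_cpm) >= min_samples
}
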