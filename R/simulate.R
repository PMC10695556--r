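#' Simulation parameters for hierarchical single-nucleus counts
#'
#' Constructs and validates the parameter set of the hierarchical count
#' generator. The generator emulates a case/control snRNA-seq cohort: donors
#' are the unit of biological replication, each contributing cells of several
#' cell types with very unequal abundances (excitatory neurons dominate,
#' microglia are rare). Counts for gene g in cell c of type t from donor d
#' are negative binomial with mean
#' `s_c * exp(log mu_gt + u_gd + b_gt * 1[d is case])` and dispersion
#' `phi_g`, where `u_gd ~ N(0, donor_sd^2)` is a gene-by-donor random effect
#' inducing within-donor correlation, `s_c` is a log-normal cell size factor
#' and `b_gt` is the (natural-log) condition effect of a truly DE gene.
#' QC artifacts are layered on top: a fraction of "dying" cells whose counts
#' are redistributed towards mitochondrial genes, and doublet barcodes that
#' are element-wise sums of two cells of the same donor.
#'
#' @param n_case,n_control number of case / control donors (each >= 2).
#' @param cell_type_profile named numeric vector: expected cells per donor
#'   for each cell type (all >= 1). The default spans a 10:1 abundance range
#'   across six cortical cell types.
#' @param n_genes number of genes.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene, per-cell-type baseline mean count `mu_gt`.
#' @param dispersion per-gene NB dispersion `phi_g` (> 0); a scalar, a
#'   length-`n_genes` vector, or `NULL` to draw
#'   `phi_g ~ logNormal(dispersion_meanlog, dispersion_sdlog)`.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters used when
#'   `dispersion` is `NULL`.
#' @param donor_sd standard deviation of the gene-by-donor log-scale random
#'   effect `u_gd`; 0 makes cells from one donor independent.
#' @param de_fraction fraction of genes truly DE, drawn independently per
#'   cell type.
#' @param de_lfc log2 fold-change magnitude of DE genes (sign randomised).
#' @param libsize_sd log-normal sd of per-cell size factors.
#' @param mito_gene_fraction fraction of genes labelled mitochondrial (their
#'   identifiers get the conventional `MT-` prefix).
#' @param dying_cell_fraction fraction of cells whose mitochondrial
#'   proportion is elevated to a Beta draw (dying cells).
#' @param dying_mito_beta length-2 Beta shape parameters of the dying-cell
#'   mitochondrial proportion.
#' @param doublet_rate fraction of emitted barcodes that are element-wise
#'   sums of two cells (flagged in metadata, never silently kept).
#' @param seed single integer; the only entropy source of the generator.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_case = 24L,
                       n_control = 24L,
                       cell_type_profile = c(Exc = 150, Oligo = 90, Astro = 60,
                                             Inh = 45, OPC = 25, Micro = 15),
                       n_genes = 2000L,
                       baseline_meanlog = log(0.1),
                       baseline_sdlog = 1.5,
                       dispersion = NULL,
                       dispersion_meanlog = log(0.5),
                       dispersion_sdlog = 0.5,
                       donor_sd = 0.18,
                       de_fraction = 0.1,
                       de_lfc = 1,
                       libsize_sd = 0.3,
                       mito_gene_fraction = 0.01,
                       dying_cell_fraction = 0.1,
                       dying_mito_beta = c(8, 2),
                       doublet_rate = 0.05,
                       seed = 1L) {
  n_case <- check_count(n_case, "n_case", min = 2L)
  n_control <- check_count(n_control, "n_control", min = 2L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  if (is.null(names(cell_type_profile)) || any(cell_type_profile < 1)) {
    stop("`cell_type_profile` must be a named vector with values >= 1")
  }
  for (nm in c("de_fraction", "mito_gene_fraction", "dying_cell_fraction",
               "doublet_rate")) {
    check_fraction(get(nm), nm)
  }
  if (!is.null(dispersion)) {
    if (any(dispersion <= 0)) stop("`dispersion` must be > 0")
    if (!length(dispersion) %in% c(1L, n_genes)) {
      stop("`dispersion` must have length 1 or n_genes")
    }
  }
  if (donor_sd < 0) stop("`donor_sd` must be >= 0")
  if (libsize_sd < 0) stop("`libsize_sd` must be >= 0")
  if (length(dying_mito_beta) != 2L || any(dying_mito_beta <= 0)) {
    stop("`dying_mito_beta` must be two positive Beta shapes")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      n_case = n_case, n_control = n_control,
      cell_type_profile = cell_type_profile, n_genes = n_genes,
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      dispersion = dispersion, dispersion_meanlog = dispersion_meanlog,
      dispersion_sdlog = dispersion_sdlog,
      donor_sd = donor_sd, de_fraction = de_fraction, de_lfc = de_lfc,
      libsize_sd = libsize_sd, mito_gene_fraction = mito_gene_fraction,
      dying_cell_fraction = dying_cell_fraction,
      dying_mito_beta = dying_mito_beta,
      doublet_rate = doublet_rate, seed = seed
    ),
    class = "sim_params"
  )
}

#' Generate a hierarchical single-nucleus count dataset
#'
#' Draws a full synthetic cohort under the model described in [sim_params()]:
#' per-donor cell numbers are Poisson around the cell-type profile, counts
#' are negative binomial with gene-by-donor random effects, dying cells have
#' their counts redistributed so that the mitochondrial proportion follows
#' the configured Beta law, and a fraction of emitted barcodes are doublets
#' (sums of two same-donor cells). The same seed always reproduces the
#' dataset bit for bit.
#'
#' @param params a [sim_params()] object.
#' @return a list of class `sc_dataset` with elements
#'   \describe{
#'     \item{counts}{a [cell_counts()] object (doublets flagged in metadata).}
#'     \item{design}{donor design data.frame: `donor_id`, `condition`
#'       (`"case"`/`"control"`).}
#'     \item{truth}{ground-truth table: `gene`, `cell_type`, `is_de`,
#'       `true_lfc` (log2; `|true_lfc| = de_lfc` for DE genes, 0 otherwise).}
#'     \item{params}{the generating parameters.}
#'   }
#' @export
generate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, generate_dataset_impl(params))
}

generate_dataset_impl <- function(p) {
  G <- p$n_genes
  n_mito <- round(p$mito_gene_fraction * G)
  gene_id <- sprintf("GENE%05d", seq_len(G))
  if (n_mito > 0) gene_id[seq_len(n_mito)] <- sprintf("MT-%d", seq_len(n_mito))
  is_mito <- seq_len(G) <= n_mito

  donors <- sprintf("donor%02d", seq_len(p$n_case + p$n_control))
  condition <- rep(c("case", "control"), c(p$n_case, p$n_control))
  design <- data.frame(donor_id = donors, condition = condition,
                       stringsAsFactors = FALSE)

  types <- names(p$cell_type_profile)
  phi <- p$dispersion %||% stats::rlnorm(G, p$dispersion_meanlog, p$dispersion_sdlog)
  phi <- rep_len(phi, G)

  # per-cell-type baselines and condition effects
  mu_base <- sapply(types, function(t) {
    stats::rlnorm(G, p$baseline_meanlog, p$baseline_sdlog)
  })
  n_de <- round(p$de_fraction * G)
  if (p$de_lfc != 0 && p$de_fraction > 0 && n_de < 1) {
    warning("de_fraction * n_genes < 1; emitting zero DE genes")
  }
  true_lfc <- matrix(0, G, length(types), dimnames = list(gene_id, types))
  if (p$de_lfc != 0 && n_de >= 1) {
    for (t in seq_along(types)) {
      idx <- sample.int(G, n_de)
      true_lfc[idx, t] <- p$de_lfc * sample(c(-1, 1), n_de, replace = TRUE)
    }
  }
  # gene-by-donor random effects, shared across cell types of a donor
  u <- matrix(stats::rnorm(G * nrow(design), sd = p$donor_sd), G, nrow(design))

  # lay out cells donor-by-donor, type-by-type
  cells <- do.call(rbind, lapply(seq_len(nrow(design)), function(d) {
    n_t <- stats::rpois(length(types), p$cell_type_profile)
    data.frame(
      donor = d,
      cell_type = rep(types, n_t),
      stringsAsFactors = FALSE
    )
  }))
  n_cells <- nrow(cells)
  if (n_cells == 0) stop("cell_type_profile produced an empty dataset")
  sf <- stats::rlnorm(n_cells, 0, p$libsize_sd)

  counts <- matrix(0L, G, n_cells)
  poisson_limit <- all(phi < 1e-8)
  for (d in seq_len(nrow(design))) {
    for (t in seq_along(types)) {
      j <- which(cells$donor == d & cells$cell_type == types[t])
      if (!length(j)) next
      eta <- log(mu_base[, t]) + u[, d] +
        log(2) * true_lfc[, t] * (design$condition[d] == "case")
      m <- exp(eta) %o% sf[j]
      counts[, j] <- if (poisson_limit) {
        stats::rpois(length(m), lambda = m)
      } else {
        stats::rnbinom(length(m), size = 1 / phi, mu = as.vector(m))
      }
    }
  }

  # dying cells: redistribute counts so mito proportion ~ Beta(a, b)
  n_dying <- round(p$dying_cell_fraction * n_cells)
  dying <- if (n_dying > 0) sample.int(n_cells, n_dying) else integer(0)
  if (length(dying) && n_mito == 0) {
    warning("dying_cell_fraction > 0 but no mitochondrial genes; skipping")
    dying <- integer(0)
  }
  for (j in dying) {
    tot <- sum(counts[, j])
    if (tot == 0) next
    frac <- stats::rbeta(1, p$dying_mito_beta[1], p$dying_mito_beta[2])
    m_tot <- stats::rbinom(1, tot, frac)
    t <- match(cells$cell_type[j], types)
    new <- integer(G)
    if (m_tot > 0) {
      new[is_mito] <- stats::rmultinom(1, m_tot, mu_base[is_mito, t])
    }
    if (tot - m_tot > 0) {
      pr <- counts[!is_mito, j]
      if (sum(pr) == 0) pr <- mu_base[!is_mito, t]
      new[!is_mito] <- stats::rmultinom(1, tot - m_tot, pr)
    }
    counts[, j] <- new
  }

  # doublets: merge pairs of same-donor cells into single barcodes
  n_doub <- round(p$doublet_rate * n_cells / (1 + p$doublet_rate))
  first <- if (n_doub > 0) sample.int(n_cells, n_doub) else integer(0)
  used <- rep(FALSE, n_cells)
  used[first] <- TRUE
  partner <- rep(NA_integer_, n_doub)
  for (k in seq_along(first)) {
    cand <- which(cells$donor == cells$donor[first[k]] & !used)
    if (!length(cand)) next
    partner[k] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    used[partner[k]] <- TRUE
  }
  keep_pair <- !is.na(partner)
  first <- first[keep_pair]; partner <- partner[keep_pair]
  if (length(first)) {
    counts[, first] <- counts[, first] + counts[, partner]
  }
  drop <- partner
  keep <- setdiff(seq_len(n_cells), drop)
  is_doublet <- seq_len(n_cells) %in% first

  meta <- data.frame(
    barcode = sprintf("BC%06d", seq_along(keep)),
    donor_id = donors[cells$donor[keep]],
    cell_type = cells$cell_type[keep],
    is_doublet = is_doublet[keep],
    stringsAsFactors = FALSE
  )
  cc <- cell_counts(
    Matrix::Matrix(counts[, keep, drop = FALSE], sparse = TRUE,
                   dimnames = list(gene_id, meta$barcode)),
    meta,
    data.frame(gene_id = gene_id, is_mito = is_mito, stringsAsFactors = FALSE)
  )
  truth <- data.frame(
    gene = rep(gene_id, length(types)),
    cell_type = rep(types, each = G),
    is_de = as.vector(true_lfc != 0),
    true_lfc = as.vector(true_lfc),
    stringsAsFactors = FALSE
  )
  structure(list(counts = cc, design = design, truth = truth, params = p),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf(
    "sc_dataset: %d genes x %d cells, %d case + %d control donors, %d DE gene flags\n",
    nrow(x$counts$counts), ncol(x$counts$counts),
    x$params$n_case, x$params$n_control, sum(x$truth$is_de)
  ))
  invisible(x)
}
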