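test_that("identical seeds give bit-identical datasets", {
  d1 <- tiny_dataset()
  d2 <- tiny_dataset()
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$counts$cells, d2$counts$cells)
  expect_identical(d1$truth, d2$truth)
  d3 <- tiny_dataset(seed = 43L)
  expect_false(identical(d1$counts$counts, d3$counts$counts))
})

test_that("parameter validation rejects malformed settings", {
  expect_error(sim_params(n_case = 1), "n_case")
  expect_error(sim_params(n_case = 3.5), "n_case")
  expect_error(sim_params(de_fraction = 1.5), "de_fraction")
  expect_error(sim_params(dispersion = -1), "dispersion")
  expect_error(sim_params(cell_type_profile = c(A = 0.5)), "cell_type_profile")
  expect_warning(
    generate_dataset(tiny_params(n_genes = 200L, de_fraction = 0.001,
                                 de_lfc = 2)),
    "zero DE genes"
  )
})

test_that("Poisson limit recovers the stated per-gene mean", {
  # sigma_d = 0, phi -> 0, unit size factors, mu = 5: the empirical per-gene
  # mean over ~10,000 cells must sit within Monte-Carlo error of 5
  p <- sim_params(
    n_case = 2, n_control = 2, cell_type_profile = c(A = 2500),
    n_genes = 20, baseline_meanlog = log(5), baseline_sdlog = 0,
    dispersion = 1e-10, donor_sd = 0, de_fraction = 0, libsize_sd = 0,
    mito_gene_fraction = 0, dying_cell_fraction = 0, doublet_rate = 0,
    seed = 7L
  )
  d <- generate_dataset(p)
  n <- ncol(d$counts$counts)
  expect_gt(n, 9000)
  means <- Matrix::rowMeans(d$counts$counts)
  se <- sqrt(5 / n)
  expect_true(all(abs(means - 5) < 3 * se))
})

test_that("flagged DE genes show the configured pseudobulk fold change", {
  p <- sim_params(
    n_case = 8, n_control = 8, cell_type_profile = c(A = 100),
    n_genes = 300, de_fraction = 0.3, de_lfc = 1, donor_sd = 0,
    libsize_sd = 0, mito_gene_fraction = 0, dying_cell_fraction = 0,
    doublet_rate = 0, seed = 11L
  )
  d <- generate_dataset(p)
  cond <- d$design$condition[match(d$counts$cells$donor_id, d$design$donor_id)]
  case_mean <- Matrix::rowMeans(d$counts$counts[, cond == "case"])
  ctrl_mean <- Matrix::rowMeans(d$counts$counts[, cond == "control"])
  tr <- d$truth[d$truth$cell_type == "A", ]
  ratio <- log2(case_mean / ctrl_mean)[tr$is_de] * sign(tr$true_lfc[tr$is_de])
  # Monte-Carlo tolerance: ~90 flagged genes averaged over 1600 cells
  expect_equal(mean(ratio), 1, tolerance = 0.1)
  null_ratio <- log2(case_mean / ctrl_mean)[!tr$is_de]
  expect_lt(abs(mean(null_ratio)), 0.1)
})

test_that("donor random effects induce intraclass correlation that grows with donor_sd", {
  icc_of <- function(sd_d, seed) {
    p <- sim_params(n_case = 3, n_control = 3,
                    cell_type_profile = c(A = 120), n_genes = 60,
                    baseline_meanlog = log(2), baseline_sdlog = 0.3,
                    donor_sd = sd_d, de_fraction = 0, libsize_sd = 0,
                    mito_gene_fraction = 0, dying_cell_fraction = 0,
                    doublet_rate = 0, seed = seed)
    d <- generate_dataset(p)
    donor <- factor(d$counts$cells$donor_id)
    y <- log1p(as.matrix(d$counts$counts))
    n_per <- as.vector(table(donor))
    n0 <- (sum(n_per) - sum(n_per^2) / sum(n_per)) / (length(n_per) - 1)
    iccs <- apply(y, 1, function(v) {
      a <- stats::anova(stats::lm(v ~ donor))
      msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
      (msb - msw) / (msb + (n0 - 1) * msw)
    })
    mean(iccs, na.rm = TRUE)
  }
  icc0 <- icc_of(0, 5L)
  icc_mid <- icc_of(0.3, 5L)
  icc_hi <- icc_of(0.6, 5L)
  expect_lt(abs(icc0), 0.02)
  expect_gt(icc_mid, 0.02)
  expect_gt(icc_hi, icc_mid)
})

test_that("negative-binomial marginals are overdispersed; Poisson limit is not", {
  base <- list(n_case = 2, n_control = 2, cell_type_profile = c(A = 1500),
               n_genes = 40, baseline_meanlog = log(5), baseline_sdlog = 0,
               donor_sd = 0, de_fraction = 0, libsize_sd = 0,
               mito_gene_fraction = 0, dying_cell_fraction = 0,
               doublet_rate = 0, seed = 13L)
  nb <- generate_dataset(do.call(sim_params, c(base, list(dispersion = 0.5))))
  m <- as.matrix(nb$counts$counts)
  vmr_nb <- apply(m, 1, var) / rowMeans(m)
  expect_true(all(vmr_nb > 1.5))   # expected VMR = 1 + phi*mu = 3.5
  po <- generate_dataset(do.call(sim_params, c(base, list(dispersion = 1e-10))))
  mp <- as.matrix(po$counts$counts)
  vmr_po <- apply(mp, 1, var) / rowMeans(mp)
  expect_equal(mean(vmr_po), 1, tolerance = 0.05)
})

test_that("doublet barcodes have systematically larger totals and correct flags", {
  d <- tiny_dataset(doublet_rate = 0.15, dying_cell_fraction = 0,
                    cell_type_profile = c(A = 120), n_genes = 200L)
  tot <- Matrix::colSums(d$counts$counts)
  dbl <- d$counts$cells$is_doublet
  expect_gt(sum(dbl), 5)
  expect_gt(median(tot[dbl]), 1.5 * median(tot[!dbl]))
  # stochastic dominance: doublet totals shifted right across quantiles
  qs <- c(0.25, 0.5, 0.75)
  expect_true(all(quantile(tot[dbl], qs) > quantile(tot[!dbl], qs)))
})

test_that("dying cells carry high mitochondrial fractions but keep their totals", {
  p <- tiny_params(dying_cell_fraction = 0.3, mito_gene_fraction = 0.05,
                   doublet_rate = 0, n_genes = 200L)
  d <- generate_dataset(p)
  met <- compute_cell_qc(d$counts)
  # Beta(8, 2) has mean 0.8: dying cells should be far above any healthy cell
  expect_gt(mean(met$mito_fraction > 0.5), 0.2)
  expect_lt(median(met$mito_fraction), 0.5)
})
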