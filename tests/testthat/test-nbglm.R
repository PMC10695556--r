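test_that("identical condition groups give zero fold change and p = 1", {
  y <- matrix(rpois(50 * 8, 30), 50, 8)
  y <- y[, c(1:4, 1:4)]                 # case columns identical to control
  pb <- make_pb(y, rep(c("control", "case"), each = 4))
  tab <- fit_nb_lrt(pb, dispersion = 0.1)
  expect_true(all(abs(tab$logFC) < 1e-6))
  expect_true(all(tab$LR < 1e-8))
  expect_true(all(tab$p_value > 1 - 1e-6))
})

test_that("Poisson-limit LR matches an independent Poisson GLM oracle", {
  set.seed(10)
  G <- 60; n <- 12
  mu <- exp(rnorm(G, 5, 1))
  off <- log(runif(n, 0.8, 1.2))
  x <- rep(0:1, each = n / 2)
  y <- matrix(rpois(G * n, exp(log(mu) %o% rep(1, n) + rep(off, each = G))), G)
  pb <- make_pb(y, rep(c("control", "case"), each = n / 2),
                lib_size = exp(off))
  tab <- fit_nb_lrt(pb, dispersion = 0)
  oracle <- vapply(seq_len(G), function(g) {
    f1 <- glm(y[g, ] ~ x, family = poisson, offset = off)
    f0 <- glm(y[g, ] ~ 1, family = poisson, offset = off)
    f0$deviance - f1$deviance
  }, numeric(1))
  expect_lt(max(abs(tab$LR - oracle)), 1e-4)
  beta_oracle <- vapply(seq_len(G), function(g) {
    coef(glm(y[g, ] ~ x, family = poisson, offset = off))[2]
  }, numeric(1))
  expect_lt(max(abs(tab$logFC * log(2) - beta_oracle)), 1e-6)
})

test_that("fixed-dispersion LR matches a negative-binomial GLM oracle", {
  set.seed(12)
  G <- 40; n <- 16
  phi <- 0.2
  mu <- exp(rnorm(G, 4, 1))
  x <- rep(0:1, each = n / 2)
  y <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 1 / phi), G)
  pb <- make_pb(y, rep(c("control", "case"), each = n / 2),
                lib_size = rep(1, n))
  tab <- fit_nb_lrt(pb, dispersion = phi)
  fam <- MASS::negative.binomial(theta = 1 / phi)
  oracle <- vapply(seq_len(G), function(g) {
    f1 <- glm(y[g, ] ~ x, family = fam)
    f0 <- glm(y[g, ] ~ 1, family = fam)
    f0$deviance - f1$deviance
  }, numeric(1))
  expect_lt(max(abs(tab$LR - oracle)), 1e-4)
})

test_that("dispersion estimation recovers a known common dispersion", {
  set.seed(14)
  G <- 400; n <- 16
  phi <- 0.4
  mu <- exp(runif(G, 2, 6))
  y <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 1 / phi), G, n)
  disp <- estimate_dispersion(y, rep(0:1, each = n / 2), rep(0, n))
  expect_equal(median(disp$phi_shrunk), phi, tolerance = 0.15)
  # uninformative genes must not collapse to the lower grid boundary
  expect_gt(min(disp$phi_shrunk), 1e-3)
})

test_that("all-zero genes are excluded with a warning", {
  y <- matrix(rpois(20 * 8, 10), 20, 8)
  y[3, ] <- 0
  pb <- make_pb(y, rep(c("control", "case"), each = 4))
  expect_warning(tab <- fit_nb_lrt(pb, dispersion = 0.1), "all-zero")
  expect_equal(nrow(tab), 19)
})

test_that("degenerate designs are rejected", {
  y <- matrix(rpois(10 * 4, 10), 10, 4)
  expect_error(fit_nb_lrt(make_pb(y, rep("case", 4))), "two conditions")
  expect_error(fit_nb_lrt(make_pb(y, c("case", "case", "case", "control"))),
               ">= 2 donors")
})

test_that("more cells per donor does not inflate pseudobulk null discoveries", {
  counts_at <- function(cells_per_donor, seed) {
    p <- sim_params(n_case = 5, n_control = 5,
                    cell_type_profile = c(A = cells_per_donor),
                    n_genes = 500, donor_sd = 0.2, de_fraction = 0,
                    dying_cell_fraction = 0, doublet_rate = 0, seed = seed)
    d <- generate_dataset(p)
    tab <- pseudobulk_de(d$counts, d$design)$table
    sum(tab$adj_pval < 0.05, na.rm = TRUE)
  }
  lo <- counts_at(50, 17L)
  hi <- counts_at(100, 18L)
  expect_lte(lo, 3)
  expect_lte(hi, 3)
})
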