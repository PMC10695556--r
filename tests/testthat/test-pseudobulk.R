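test_that("aggregation sums counts exactly and conserves totals", {
  m <- cbind(c(1, 0), c(2, 1), c(3, 4))   # one donor, one type: sums 6 and 5
  cc <- make_cc(m, donor = rep("dA", 3), type = rep("T1", 3))
  design <- data.frame(donor_id = "dA", condition = "case")
  pb <- aggregate_pseudobulk(cc, design, min_cells = 1)
  expect_equal(unname(pb$T1$counts[, 1]), c(6, 5))

  set.seed(4)
  dense <- matrix(rpois(100 * 60, 1.5), 100, 60)
  donors <- sample(c("d1", "d2", "d3"), 60, replace = TRUE)
  types <- sample(c("A", "B"), 60, replace = TRUE)
  cc2 <- make_cc(dense, donor = donors, type = types)
  design2 <- data.frame(donor_id = c("d1", "d2", "d3"),
                        condition = c("case", "control", "case"))
  pbs <- aggregate_pseudobulk(cc2, design2, min_cells = 1)
  for (ct in c("A", "B")) {
    for (d in design2$donor_id) {
      j <- donors == d & types == ct
      if (!any(j)) next
      oracle <- rowSums(dense[, j, drop = FALSE])
      expect_equal(unname(pbs[[ct]]$counts[, d]), oracle)
    }
    expect_equal(unname(colSums(pbs[[ct]]$counts)),
                 unname(pbs[[ct]]$samples$lib_size))
  }
})

test_that("samples below the min_cells floor are dropped; unknown donors error", {
  m <- matrix(1, 5, 12)
  cc <- make_cc(m, donor = rep(c("d1", "d2"), c(9, 3)), type = rep("A", 12))
  design <- data.frame(donor_id = c("d1", "d2"),
                       condition = c("case", "control"))
  pb <- aggregate_pseudobulk(cc, design, min_cells = 5)
  expect_equal(pb$A$samples$donor_id, "d1")
  cc$cells$donor_id[1] <- "ghost"
  expect_error(aggregate_pseudobulk(cc, design), "absent")
})

test_that("TMM factors behave on identity, pure-depth and random inputs", {
  set.seed(8)
  y <- matrix(rnbinom(500 * 6, mu = 40, size = 5), 500, 6)
  same <- y[, c(1, 1, 1, 1)]
  expect_equal(tmm_norm_factors(same), rep(1, 4))
  # doubling one column is pure depth, no composition change
  scaled <- cbind(y[, 1], y[, 1] * 2L, y[, 1], y[, 1])
  f <- tmm_norm_factors(scaled)
  expect_equal(f, rep(1, 4), tolerance = 1e-6)
  f2 <- tmm_norm_factors(y)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-12)
})

test_that("TMM agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(15)
  for (i in 1:3) {
    y <- matrix(rnbinom(1500 * 8, mu = exp(runif(1500, 1, 5)), size = 3),
                1500, 8)
    f_ref <- edgeR::calcNormFactors(edgeR::DGEList(y))$samples$norm.factors
    expect_equal(tmm_norm_factors(y), f_ref, tolerance = 1e-10)
  }
})

test_that("zero-library samples get factor 1 with a warning", {
  y <- cbind(c(5, 5, 5), c(6, 4, 5), c(0, 0, 0))
  expect_warning(f <- tmm_norm_factors(y), "zero library")
  expect_equal(length(f), 3)
})

test_that("pseudobulk expression filter matches a dense recomputation", {
  set.seed(3)
  y <- matrix(rnbinom(200 * 10, mu = 2, size = 2), 200, 10)
  y[1, ] <- 0                                   # all-zero gene dropped
  y[2, ] <- 50                                  # ubiquitous gene kept
  pb <- make_pb(y, rep(c("case", "control"), each = 5))
  mask <- filter_expressed_pb(pb, min_cpm = 1)
  cpm <- sweep(y, 2, pmax(colSums(y), 1), "/") * 1e6
  oracle <- rowSums(cpm > 1) >= 5
  expect_equal(unname(mask), unname(oracle))
  expect_false(mask[1])
  expect_true(mask[2])
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.7), 0.7)
  set.seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone in ranks
  o <- order(p)
  expect_true(all(diff(adj[o]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
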