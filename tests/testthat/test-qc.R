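test_that("per-cell metrics match hand arithmetic and a dense oracle", {
  m <- matrix(c(10, 90,
                0, 0), nrow = 2, byrow = TRUE)
  cc <- make_cc(cbind(c(10, 90), c(0, 0)), genes = c("MT-1", "G1"))
  met <- compute_cell_qc(cc)
  expect_equal(met$total_counts, c(100, 0))
  expect_equal(met$mito_fraction, c(0.10, 0))
  expect_equal(met$n_expressed_genes, c(2, 0))
  expect_equal(met$zero_library, c(FALSE, TRUE))

  set.seed(1)
  dense <- matrix(rpois(50 * 20, 2), 50, 20)
  genes <- c(sprintf("MT-%d", 1:5), sprintf("G%03d", 1:45))
  cc2 <- make_cc(dense, genes = genes)
  met2 <- compute_cell_qc(cc2)
  expect_equal(met2$total_counts, colSums(dense))
  expect_equal(met2$n_expressed_genes, colSums(dense > 0))
  expect_equal(met2$mito_fraction, colSums(dense[1:5, ]) / colSums(dense))
})

test_that("unknown mitochondrial gene ids are rejected by name", {
  cc <- make_cc(matrix(1:4, 2), genes = c("G1", "G2"))
  expect_error(compute_cell_qc(cc, mito_gene_ids = "NOPE"), "NOPE")
})

test_that("expressed-gene mask implements the 2-counts-in-3-cells rule", {
  m <- rbind(c(2, 2, 2, 0),    # kept: three cells at >= 2
             c(1, 1, 1, 1),    # dropped: no cell reaches 2
             c(5, 0, 0, 0))    # dropped: one qualifying cell
  expect_equal(expressed_gene_mask(m), c(TRUE, FALSE, FALSE))
  expect_equal(expressed_gene_mask(Matrix::Matrix(m, sparse = TRUE)),
               c(TRUE, FALSE, FALSE))
})

test_that("MAD threshold matches hand computation and degenerates safely", {
  expect_equal(mad_upper_threshold(c(1, 2, 3, 4, 100)), 7)
  expect_warning(thr <- mad_upper_threshold(c(5, 5, 5)), "zero")
  expect_identical(thr, Inf)
  expect_error(mad_upper_threshold(3), "at least 2")
  # monotone non-decreasing in n_mads
  v <- c(3, 9, 1, 14, 2, 8)
  thrs <- vapply(1:6, function(k) mad_upper_threshold(v, k), numeric(1))
  expect_true(all(diff(thrs) >= 0))
})

test_that("QC accounting on a hand-built 5-cell fixture matches enumeration", {
  metrics <- data.frame(
    barcode = paste0("c", 1:5),
    total_counts = c(50, 100, 5000, 5200, 5100),   # c1, c2 fail min library
    n_expressed_genes = c(300, 250, 320, 340, 310),
    mito_fraction = c(0.01, 0.25, 0.02, 0.03, 0.0), # c2 also fails mito
    zero_library = FALSE,
    is_doublet = FALSE
  )
  qc <- apply_qc(metrics, qc_thresholds())
  s <- qc$summary
  get <- function(k) s$cells[s$criterion == k]
  expect_equal(get("min_library_size"), 2)
  expect_equal(get("high_mito"), 1)
  expect_equal(get("total_failed"), 2)   # union, not 3
  expect_equal(get("total_passed"), 3)
  expect_equal(get("total_failed") + get("total_passed"), 5)
  expect_equal(qc$pass, c(FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("clean cells all pass and the mito cut-off is monotone", {
  n <- 40
  metrics <- data.frame(
    barcode = paste0("c", 1:n),
    total_counts = 1000 + seq_len(n),
    n_expressed_genes = 500 + seq_len(n) %% 7,
    mito_fraction = seq(0, 0.2, length.out = n),
    zero_library = FALSE,
    is_doublet = FALSE
  )
  strict <- apply_qc(metrics, qc_thresholds(mito_max = 0.05))
  lenient <- apply_qc(metrics, qc_thresholds(mito_max = 0.10))
  s <- function(q) q$summary$cells[q$summary$criterion == "total_passed"]
  expect_gte(s(lenient), s(strict))

  clean <- metrics
  clean$mito_fraction <- 0.01
  clean$total_counts <- 1000
  clean$n_expressed_genes <- 500
  q <- suppressWarnings(apply_qc(clean, qc_thresholds()))
  expect_equal(s(q), n)
})

test_that("accounting identity and union bound hold on random metrics", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(20:80, 1)
    metrics <- data.frame(
      barcode = paste0("c", 1:n),
      total_counts = rpois(n, 400),
      n_expressed_genes = rpois(n, 250),
      mito_fraction = runif(n, 0, 0.2),
      zero_library = FALSE,
      is_doublet = runif(n) < 0.1
    )
    qc <- suppressWarnings(apply_qc(metrics, qc_thresholds()))
    s <- qc$summary
    tot_failed <- s$cells[s$criterion == "total_failed"]
    tot_passed <- s$cells[s$criterion == "total_passed"]
    per_crit <- s$cells[!s$criterion %in% c("total_failed", "total_passed")]
    expect_equal(tot_failed + tot_passed, n)
    expect_lte(tot_failed, sum(per_crit))
  }
})

test_that("empty input yields an empty, zeroed result", {
  qc <- apply_qc(data.frame())
  expect_equal(length(qc$pass), 0)
  expect_equal(nrow(qc$summary), 0)
})

test_that("mito criterion removes nearly all dying cells on default-style data", {
  p <- sim_params(n_case = 4, n_control = 4,
                  cell_type_profile = c(A = 80), n_genes = 400,
                  dying_cell_fraction = 0.1, dying_mito_beta = c(8, 2),
                  mito_gene_fraction = 0.02, doublet_rate = 0, seed = 31L)
  d <- generate_dataset(p)
  q <- qc_filter(d$counts, qc_thresholds(min_library_size = 20,
                                         min_expressed_genes = 10))
  # identify dying cells as those the generator pushed above 50% mito
  met <- q$metrics
  dying <- met$mito_fraction > 0.5
  expect_gt(sum(dying), 20)
  expect_gte(mean(q$qc$flags$high_mito[dying]), 0.95)
})

test_that("the QC pipeline filters cells and writes a readable report", {
  d <- tiny_dataset()
  q <- qc_filter(d$counts, qc_thresholds(min_library_size = 50,
                                         min_expressed_genes = 20))
  expect_s3_class(q$filtered, "cell_counts")
  expect_equal(ncol(q$filtered$counts), sum(q$qc$pass))
  tf <- tempfile(fileext = ".tsv")
  write_qc_report(q$qc, tf)
  rep <- read.delim(tf)
  expect_equal(rep$cells[rep$criterion == "total_passed"], sum(q$qc$pass))
})
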