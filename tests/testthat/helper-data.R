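# Small fixture builders used across test files. Everything is generated in
# code under fixed seeds; no binary fixtures.

tiny_params <- function(...) {
  args <- list(
    n_case = 3L, n_control = 3L,
    cell_type_profile = c(A = 30, B = 12),
    n_genes = 120L, seed = 42L
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_params, args)
}

tiny_dataset <- function(...) generate_dataset(tiny_params(...))

# hand-buildable cell_counts from a dense matrix
make_cc <- function(m, donor = rep("d1", ncol(m)), type = rep("A", ncol(m)),
                    doublet = rep(FALSE, ncol(m)), genes = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_len(nrow(m)))
  rownames(m) <- genes
  cell_counts(
    m,
    data.frame(barcode = sprintf("BC%03d", seq_len(ncol(m))),
               donor_id = donor, cell_type = type, is_doublet = doublet,
               stringsAsFactors = FALSE),
    data.frame(gene_id = genes, is_mito = grepl("^MT-", genes),
               stringsAsFactors = FALSE)
  )
}

`%||%` <- pseudobulkDE:::`%||%`

# a pseudobulk object straight from a count matrix (for engine-level tests)
make_pb <- function(y, condition, lib_size = colSums(y), norm = rep(1, ncol(y)),
                    cell_type = "A") {
  if (is.null(rownames(y))) rownames(y) <- sprintf("g%03d", seq_len(nrow(y)))
  structure(
    list(counts = y,
         samples = data.frame(donor_id = sprintf("d%02d", seq_len(ncol(y))),
                              condition = condition, n_cells = 10L,
                              lib_size = lib_size, stringsAsFactors = FALSE),
         norm_factors = norm, cell_type = cell_type),
    class = "pseudobulk"
  )
}
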