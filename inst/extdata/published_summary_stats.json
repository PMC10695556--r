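{
  "n_cell_level_degs": 14274,
  "median_abs_logfc": 0.16,
  "median_adj_pval": 2.89e-07
}
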