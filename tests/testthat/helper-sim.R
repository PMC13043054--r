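# compact simulation configuration used throughout the unit tests; the
# package defaults are exercised in the acceptance suite
small_sim_config <- function(seed = 1L,
                             n_cells_per_stage = c(immature = 80L,
                                                   early_mature = 140L,
                                                   mature = 80L), ...) {
  sim_config(seed = seed, n_cells_per_stage = n_cells_per_stage,
             n_subfamilies = 6L, genes_per_subfamily = 3L,
             n_background_genes = 200L, mean_depth = 3000, ...)
}

# minimal annotation row factory
ann_row <- function(gene_id, is_or = FALSE, clade = "none", subfamily = NA,
                    chromosome = "chr1", start_bp = 1L, end_bp = 1000L,
                    is_mito = FALSE, has_signal_peptide = FALSE,
                    has_tm_domain = FALSE, marker_class = "none") {
  data.frame(gene_id = gene_id, symbol = gene_id, chromosome = chromosome,
             start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
             is_or = is_or, clade = clade, subfamily = subfamily,
             is_mito = is_mito, has_signal_peptide = has_signal_peptide,
             has_tm_domain = has_tm_domain, marker_class = marker_class,
             stringsAsFactors = FALSE)
}
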