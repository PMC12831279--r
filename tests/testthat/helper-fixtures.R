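# small synthetic worlds shared across test files; everything is generated
# in code at test time

small_truth <- function(seed = 11, n_multi = 12, n_true = 3, n_cdsless = 3,
                        n_seleno = 3, n_rt_pairs = 1, genes_per_chrom = 12) {
  cfg <- sim_config(
    n_multi_exon = n_multi, n_true_intronless = n_true,
    n_cds_intronless = n_cdsless, n_selenoprotein = n_seleno,
    n_readthrough_pairs = n_rt_pairs
  )
  m <- generate_gene_models(cfg, seed = seed)
  emit_genome(m, genes_per_chrom = genes_per_chrom, seed = seed)
}

# reverse-translate a protein into one canonical codon per residue
codons_for <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  vapply(strsplit(protein, "")[[1]],
         function(a) names(gc)[gc == a][1], character(1))
}
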