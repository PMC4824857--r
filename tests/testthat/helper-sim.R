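# small noise-free configuration used by inversion-style tests
noise_free_config <- function(n_genes = 60L, seed = 42L, ...) {
  sim_config(n_genes = n_genes, replicate_cv = 0, transition_cv = 0,
             peptide_bias_log2_sd = 0, dropout_prob = 0, lod_area = 0,
             seed = seed, ...)
}
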