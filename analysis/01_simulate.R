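#!/usr/bin/env Rscript
# Step 1: generate the synthetic census datasets.
#
# Draws a 1000-gene ground truth (log-normal protein abundances spanning
# ~5 orders of magnitude, log-normal translational efficiency with median
# 1035 proteins/transcript), then emits the SRM peak-area experiment
# (2 surrogate peptides/gene, 3 transitions, 4 bioreplicates at 12% CV,
# 3 spike levels, decoy peak groups) and the matched transcriptome with
# gene features.

suppressPackageStartupMessages(library(proteocensus))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_genes = 1000L, seed = 101L)
truth <- simulate_truth(cfg)
srm <- simulate_srm(truth, cfg)
tx <- simulate_transcriptome(truth, cfg)

write_tsv_table(truth, file.path(out_dir, "truth.tsv"))
write_tsv_table(srm$peak_table, file.path(out_dir, "peak_areas.tsv"))
write_transition_list(srm$transitions,
                      file.path(out_dir, "transitions.csv"))
write_tsv_table(srm$peptides, file.path(out_dir, "peptides.tsv"))
write_tsv_table(tx$fpkm, file.path(out_dir, "fpkm.tsv"))
write_tsv_table(tx$features, file.path(out_dir, "features.tsv"))
write_sim_config(cfg, file.path(out_dir, "config.yaml"))
write_run_manifest(file.path(out_dir, "manifest.yaml"), cfg,
                   outputs = list.files(out_dir))

message(sprintf(
  "simulated %d genes: true protein range %.0f-%.2g cpc, total %.3g cpc, median TE %.0f",
  cfg$n_genes, min(truth$protein_cpc), max(truth$protein_cpc),
  attr(truth, "total_protein"), median(truth$te)
))
message(sprintf("peak table: %d transition-level rows (incl. decoys)",
                nrow(srm$peak_table)))
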