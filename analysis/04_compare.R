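#!/usr/bin/env Rscript
# Step 4: cross-dataset comparison.
#
# Rescales the quantified census to ppm (assuming 6e7 protein molecules
# per cell), builds synthetic "independent laboratory" datasets by
# perturbing the ground truth in two method-like blocks, computes the
# pairwise Spearman matrix, clusters the datasets (average linkage on
# 1 - rho) into a Newick dendrogram, and writes an M-versus-A table for
# the census against its closest neighbour.

suppressPackageStartupMessages({
  library(proteocensus)
  library(tibble)
})

out_dir <- "results/compare"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(404)

truth <- read_tsv_table("results/sim/truth.tsv")
prot <- read_tsv_table("results/quant/protein_quant.tsv")
prot <- prot[prot$class %in% c("AA", "AB", "AC") & !is.na(prot$cpc), ]

census <- tibble(protein_id = prot$protein_group,
                 abundance = cpc_to_ppm(prot$cpc))

# two method families emulated as distinct bias/noise structures on truth
mk <- function(bias_slope, noise_sd) {
  lt <- log10(truth$protein_cpc)
  ab <- 10^(bias_slope * (lt - mean(lt)) + mean(lt) +
              rnorm(nrow(truth), 0, noise_sd))
  tibble(protein_id = truth$gene_id, abundance = cpc_to_ppm(ab))
}
tables <- list(
  census_srm = census,
  ms_labelfree_1 = mk(0.95, 0.25),
  ms_labelfree_2 = mk(0.95, 0.25),
  tagging_1 = mk(0.70, 0.45),
  tagging_2 = mk(0.70, 0.45)
)

cm <- correlation_matrix(tables)
write_tsv_table(cbind(dataset = rownames(cm$rho),
                      as.data.frame(cm$rho)),
                file.path(out_dir, "spearman_matrix.tsv"))
cl <- cluster_datasets(cm)
writeLines(cl$newick, file.path(out_dir, "dataset_dendrogram.nwk"))
message("Spearman rho, census vs others: ",
        paste(sprintf("%s %.2f", colnames(cm$rho)[-1],
                      cm$rho["census_srm", -1]), collapse = ", "))
message("dendrogram: ", cl$newick)

# M-versus-A of the census against its most correlated neighbour
best <- names(which.max(cm$rho["census_srm", -1]))
pair <- merge(census, tables[[best]], by = "protein_id")
ma <- ma_transform(pair$abundance.x, pair$abundance.y, pair$protein_id)
write_tsv_table(ma, file.path(out_dir, paste0("ma_census_vs_", best,
                                              ".tsv")))
message(sprintf("M-vs-A against %s: median M %.2f over %d proteins (%d excluded)",
                best, median(ma$M), nrow(ma), attr(ma, "n_excluded")))
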