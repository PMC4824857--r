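#!/usr/bin/env Rscript
# Step 2: in-silico assay design on a synthetic proteome.
#
# Digests a randomly generated 150-protein FASTA, selects two quantotypic
# surrogate peptides per protein (length 7-25, proteome-unique, no
# Met/Cys unless unavoidable, low predicted missed-cleavage risk),
# assembles QconCATs of ~42 peptides ordered to minimise junction risk,
# derives y-ion transitions (top 6 by tier/intensity, then top 3 by
# signal-to-background) and checks the acquisition schedule against the
# 1.25 s cycle / 40 ms dwell capacity of 31 concurrent transitions.

suppressPackageStartupMessages({
  library(proteocensus)
  library(dplyr)
})

out_dir <- "results/design"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(202)

# synthetic proteome FASTA (labelled synthetic: no real organism sequences)
aa_pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
aa_freq <- c(8, 2, 5, 6, 4, 7, 2, 6, 7, 9, 2, 4, 5, 4, 5, 7, 6, 7, 1, 3)
proteins <- tibble(
  protein_id = sprintf("SYNP%03d", 1:150),
  sequence = vapply(1:150, function(i) {
    paste(sample(aa_pool, sample(150:500, 1), replace = TRUE,
                 prob = aa_freq), collapse = "")
  }, character(1))
)
fasta_path <- file.path(out_dir, "synthetic_proteome.fasta")
writeLines(paste0(">", proteins$protein_id, "\n", proteins$sequence),
           fasta_path)

fa <- read_fasta(fasta_path)
digest <- bind_rows(lapply(seq_len(nrow(fa)), function(i) {
  digest_tryptic(fa$sequence[i], fa$protein_id[i])
}))
message(sprintf("digested %d proteins into %d tryptic peptides",
                nrow(fa), nrow(digest)))

selected <- select_quantotypic(digest, digest)
message(sprintf("selected %d quantotypic peptides for %d proteins (%d flagged Met/Cys)",
                nrow(selected), dplyr::n_distinct(selected$protein_id),
                sum(selected$flagged)))
write_tsv_table(selected, file.path(out_dir, "quantotypic_peptides.tsv"))

# QconCATs of ~42 peptides each, junction-risk-minimised ordering
chunks <- split(selected$sequence,
                ceiling(seq_len(nrow(selected)) / 42))
designs <- lapply(chunks, assemble_qconcat)
report <- tibble(
  qconcat = sprintf("QC%02d", seq_along(designs)),
  n_peptides = vapply(designs, `[[`, 0, "n_peptides"),
  length_aa = nchar(vapply(designs, `[[`, "", "sequence")),
  mass_da = vapply(designs, `[[`, 0, "mass"),
  total_junction_risk = vapply(designs, `[[`, 0, "total_junction_risk")
)
write_tsv_table(report, file.path(out_dir, "qconcat_designs.tsv"))
message(sprintf("assembled %d QconCATs, mean %.1f peptides, mean junction risk %.2f",
                nrow(report), mean(report$n_peptides),
                mean(report$total_junction_risk)))

# transitions: y3..y8 candidates with synthetic intensity/background, top 3
rt <- runif(nrow(selected), 10, 70)
trans <- bind_rows(lapply(seq_len(nrow(selected)), function(i) {
  pep <- selected$sequence[i]
  n <- nchar(pep)
  ks <- 3:min(8, n - 1)
  cand <- tibble(
    ion_type = "y", index = ks,
    product_mz = vapply(ks, function(k) compute_mz(pep, 1, paste0("y", k)),
                        0),
    intensity = rlnorm(length(ks), 8, 1),
    s2b = rlnorm(length(ks), 2, 0.5)
  )
  sel <- select_transitions(cand, compute_mz(pep, 2))
  if (!sel$usable) return(NULL)
  tibble(protein = selected$protein_id[i], peptide_sequence = pep,
         precursor_mz = compute_mz(pep, 2), precursor_charge = 2L,
         product_mz = sel$three$product_mz,
         fragment_ion = paste0("y", sel$three$index),
         fragment_charge = 1L, label_type = "light", expected_rt = rt[i])
}))
write_transition_list(trans, file.path(out_dir, "transitions.csv"))

sched <- schedule_srm(trans$expected_rt)
message(sprintf(
  "schedule: %d transitions, max concurrency %d vs capacity %d -> %s",
  nrow(trans), sched$max_concurrency, sched$capacity,
  if (sched$feasible) "feasible" else "infeasible in one injection"
))
if (!sched$feasible) {
  n_inj <- ceiling(sched$max_concurrency / sched$capacity)
  message(sprintf(
    "splitting over %d injections caps concurrency at %d -> feasible",
    n_inj, ceiling(sched$max_concurrency / n_inj)
  ))
}
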