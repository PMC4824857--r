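# proteocensus

Absolute, census-style quantification of a proteome in **copies per
cell** from stable-isotope dilution SRM data, with matched
proteome–transcriptome integration.

Targeted proteomics can put absolute numbers on thousands of proteins:
each target protein is represented by two surrogate tryptic peptides,
heavy-labelled standards for every surrogate are delivered by QconCAT
proteins spiked at known molar amounts, and the light:heavy peak-area
ratio converts directly to molecule counts,

```
cpc = (L/H) · n_spike [mol] · N_A / n_cells ,
```

so a 1 fmol spike at ratio 1 over 2×10⁵ cell equivalents is ≈3011
copies per cell. This package implements the full analysis around that
formula, for analysts building or auditing such a census:

* **Assay design** — in-silico tryptic digestion, quantotypic peptide
  selection (length, uniqueness, Met/Cys and missed-cleavage-risk
  rules), QconCAT assembly with junction-risk-minimised ordering,
  monoisotopic precursor/fragment m/z, two-stage transition selection,
  and scheduled-acquisition feasibility (1.25 s cycle / 40 ms dwell →
  31 concurrent transitions).
* **Peak-group scoring & FDR** — spike-in style decoy transitions,
  a transparent composite score (co-elution correlation, intensity
  dot-product, log S/N), and target-decoy q-values.
* **Quantification** — spike-level selection into the 10:1–1:10 band,
  the 3-of-4 / 1% FDR / S/N>5 QC rule, Type A/B/C outcome taxonomy
  (B = conservative upper limit), robust CVs
  (1.4826·MAD/median), and sibling-peptide reconciliation: concordant
  pairs (|log2 X/Y| < 0.54) are averaged, discordant pairs take the
  higher peptide.
* **Cross-dataset comparison** — ppm rescaling at 6×10⁷ molecules per
  cell, pairwise Spearman matrices, average-linkage dataset clustering
  with Newick export, M-versus-A transforms.
* **Transcriptome integration** — FPKM → mRNA copies (60,000 per
  cell), translational efficiency (proteins per transcript),
  total-proteome extrapolation, Spearman disattenuation, OLS /
  major-axis / ranged-major-axis log-log slopes, and a
  forward-selected multivariate translation model with
  feature×log-mRNA interactions.
* **Synthetic data** — a seeded generator with known ground truth
  (log-normal abundances over ~5 orders, 4 replicates at 12% CV, three
  spike levels, LOD censoring and dropout producing Type B/C outcomes,
  matched transcriptome and gene features) used throughout the tests.

## Worked example

```r
library(proteocensus)

cfg   <- sim_config(n_genes = 200, seed = 7)   # study-like defaults
truth <- simulate_truth(cfg)
sim   <- simulate_srm(truth, cfg)
res   <- srm_quantify(sim$peak_table, cells_on_column = cfg$cells_on_column)

table(res$peptides$type)
#>   A   B   C
#> 363  30   7

table(res$proteins$class)
#>  AA  AB  AC  BB  CC
#> 173  12   5   9   1

head(res$proteins[res$proteins$class == "AA", ], 3)
#>   protein_group class     cpc   rcv rule           log2_ratio
#> 1 G00001        AA    220481.  8.18 higher_peptide      0.735
#> 2 G00003        AA      1086. 11.4  higher_peptide      0.601
#> 3 G00004        AA      1016.  7.94 median_of_pair      0.116
```

363 of 400 simulated peptides yield Type A quantifications; 30 are
heavy-only upper limits (Type B) and 7 undetectable (Type C). At the
protein level, 173 of 200 genes get dual-peptide (AA) values; `rule`
records whether the sibling pair was averaged (discrepancy < 0.54 in
log2) or resolved to the higher peptide. Against the known truth the
recovered values correlate at r = 0.974 (log–log), the median AA
sibling discrepancy is 0.57 in log2, and the median peptide robust CV
is 8.4% — below the generative 12% because the MAD-based rCV is biased
low at four replicates (see the methods vignette).

The worked m/z check: `compute_mz("EGVNDNEEGFFSAR", 2)` → 785.8 Th,
the doubly protonated glu-fibrinopeptide B standard used to quantify
QconCAT stocks.

## Analysis workflow

Numbered drivers under `analysis/` run the full narrative on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # truth + SRM peak table + transcriptome
Rscript analysis/02_design.R        # digestion, Q-peptides, QconCATs, schedule
Rscript analysis/03_quantify.R      # scoring, QC, typing, reconciliation
Rscript analysis/04_compare.R       # ppm, Spearman matrix, dendrogram, M-A
Rscript analysis/05_translation.R   # TE, extrapolation, slopes, model
```

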