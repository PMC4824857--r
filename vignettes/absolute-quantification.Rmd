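---
title: "Methods: census-style absolute proteome quantification by SID-SRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: census-style absolute proteome quantification by SID-SRM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteocensus)
```

# The quantification model

`proteocensus` implements a census-style pipeline for absolute protein
quantification by stable-isotope dilution (SID) selected reaction
monitoring (SRM). Each target protein is represented by two surrogate
("quantotypic") tryptic peptides. Heavy-labelled versions of these
peptides are delivered as QconCATs — artificial concatenations of the
surrogate peptides expressed in stable-isotope-labelled form — spiked at
a known molar amount into a digest of a known number of cell
equivalents. The light:heavy peak-area ratio then converts directly to
copies per cell (cpc):

$$\mathrm{cpc} = \frac{L}{H}\cdot
  \frac{n_{\mathrm{spike}}\,[\mathrm{mol}]\cdot N_A}{n_{\mathrm{cells}}},$$

with $N_A = 6.02214\times10^{23}$. With the default load of
$2\times10^5$ cell equivalents, a 1 fmol spike at ratio 1 corresponds to
about 3011 cpc (`peptide_cpc(1, 1e-15, 2e5)`). The QconCAT stock itself
is quantified the same way against a known spike of light
glu-fibrinopeptide B (EGVNDNEEGFFSAR; `quantify_qconcat_stock()`,
default 21.5 pmol = 10 µl at 2.15 pmol/µl), whose doubly protonated
monoisotopic m/z is 785.8 Th.

## Spike-level selection and quality control

Each sample is acquired at three QconCAT spike levels (low 100–250 amol,
medium 1–2 fmol, high 10–20 fmol) so that the analyte:standard ratio can
be kept between 10:1 and 1:10. `choose_spike_level()` picks, among
levels whose median ratio lies in $[0.1, 10]$, the one with
$|\log_{10}(\text{median ratio})|$ smallest, breaking ties towards the
higher spike (better standard signal); if no level qualifies the closest
one is used and flagged.

A replicate measurement passes QC when its peak-group q-value is at most
0.01 **and** its signal-to-noise exceeds 5; a peptide is quantified only
when at least 3 of the 4 biological replicates pass (`qc_filter()`). The
conjunction is read conservatively: a replicate that clears the FDR gate
but fails S/N still counts against the 3-of-4 rule. The alternative
reading — S/N audited only among FDR-passing replicates — is available
via `sn_all_replicates = FALSE`; the conservative reading is the default
because it is the strictest interpretation consistent with the stated
rule.

## Outcome taxonomy and sibling reconciliation

Peptide outcomes are typed A (light and heavy both acceptable), B (heavy
only: the peptide yields a conservative *upper limit* on the analyte)
and C (neither). The Type B bound is the cpc implied by a hypothetical
light signal at the detection limit, $L^* = 5\times\text{noise}$, given
the observed heavy area; the bound is computed per replicate and
summarised by the median, which also makes it invariant to
per-replicate intensity rescaling. The exact bound formula is this
package's documented choice — published upper limits state the rule
only qualitatively.

At the protein level the two sibling peptides are reconciled
(`reconcile_and_aggregate()`): when $|\log_2(X/Y)| < 0.54$ the protein
value is the median of the pair (for two values, their mean); otherwise
the *higher* peptide is used, reasoning that losses of endogenous
peptide signal (incomplete cleavage, modification) are the more likely
fault. The 0.54 default is the empirical median sibling discrepancy of
the study the pipeline is modelled on; because that value is
dataset-specific, `recompute_threshold = TRUE` re-derives it as the
current dataset's own median AA discrepancy. AB/AC proteins take the
A-peptide value; BB/BC proteins take the tighter (smaller) upper bound;
CC proteins yield nothing. Dispersion is summarised by the robust CV,
$\mathrm{rCV} = 100\times1.4826\times\mathrm{MAD}/\mathrm{median}$,
recomputed over the pooled replicate values of both peptides for
concordant AA pairs.

# Assay design

`digest_tryptic()` applies the canonical trypsin rule (cleave after K/R
except before P). Quantotypic candidates are filtered to length 7–25
(typical SRM practice), proteome-unique sequences, and no Met/Cys
(oxidation and alkylation variability); the Met/Cys rule is relaxed
with a warning flag when a protein would otherwise be unquantifiable.
Candidates are ranked by a rule-based missed-cleavage risk
(`cleavage_risk()`): a required cleavage site followed by proline is
uncleavable (risk 1); acidic residues adjacent to the site and dibasic
contexts add fixed penalties (0.3 and 0.2), additively, clamped to
[0, 1]. The rule table (`cleavage_rules()`) is explicit, versioned data
— a transparent stand-in for trained missed-cleavage predictors, which
cannot be reproduced from their published descriptions. QconCAT
assembly (`assemble_qconcat()`) orders peptides to minimise summed
junction risk — exhaustively for up to 6 peptides, otherwise by
multi-start greedy search that never returns an ordering worse than the
input order.

Transition selection follows the two-stage rule: candidates are tiered
(y ions with product m/z above the precursor first — these cannot arise
from singly charged chemical background), ranked by intensity within
tier, and the top 6 retained; those are re-ranked by signal-to-background
and the top 3 kept for quantification. Ties break by fragment index, so
selection is deterministic. Scheduling feasibility uses the instrument
arithmetic: 12 points across a 15 s peak gives a 1.25 s cycle; at a
40 ms minimum dwell at most $\lfloor 1.25/0.040\rfloor = 31$ transitions
may co-elute within a 3 min retention-time window.

Masses are monoisotopic throughout (proton 1.007276 Da, water
18.010565 Da). The heavy label defaults to +6.02013 Da ([13C6]) on the
C-terminal K/R: of the common label chemistries it is the one closest
to the printed light/heavy pair 785.8/788.8 for glu-fibrinopeptide
(+6.02/2 = +3.01 per charge), and it is configurable
(`label_shift`) because the exact label is not documented. Fragment
b ions are treated as unshifted (they exclude the labelled C-terminal
residue).

# Peak-group scoring and FDR

The mProphet-style discriminant is replaced by a transparent composite
(`score_peak_group()`): Pearson correlation of the light and heavy
per-transition intensity patterns, their normalised dot product, and
log10 mean signal-to-noise, equally weighted by default. All three
sub-scores are invariant to uniform intensity rescaling, so the score
ordering is too. Decoy transitions (`generate_decoys()`) shift each
product m/z by +11 Th (incrementing by 1 Th until at least 0.5 Th from
every real product), keeping precursor and retention window — the
spike-in style of decoy that needs no decoy peptide. FDR is estimated
by plain target-decoy counting:
$\widehat{\mathrm{FDR}}(s) = \#\{d \ge s\} / \max(1, \#\{t \ge s\})$,
monotonised into q-values (`estimate_fdr()`). The counting estimator is
transparent and testable where a semi-supervised discriminant would
not be; on synthetic mixtures with 10% false targets it controls the
1% operating point within 1.5× nominal (see the acceptance tests). A
conservative +1 decoy pseudo-count (q floor 1/#targets) is available
and off by default.

# Proteome–transcriptome integration

FPKM values are converted to mRNA cpc by proportional allocation of a
fixed cellular mRNA budget (default 60,000 copies; the older 15,000
figure scales everything by 1/4). Translational efficiency is the
per-gene ratio protein cpc / mRNA cpc, with the summary median taken
over Type A proteins only (upper limits are bounds, not values). The
total-proteome extrapolation adds median TE × unmeasured mRNA copies to
the measured cpc sum.

Correlations between log protein and log mRNA are corrected for
attenuation by Spearman's classical formula,
$r_c = r/\sqrt{\rho_x\rho_y}$, using between-replicate repeatabilities
as reliabilities. Log-log slopes are fitted three ways: OLS (attenuated
towards 0 by x-noise), the major axis (first principal axis), and the
Ranged Major Axis — both variables ranged to $[0,1]$, the major-axis
slope computed on ranged values and back-transformed by the range
ratio. The model-II slopes are implemented directly from their
closed forms; the major-axis eigen-slope doubles as the independent
oracle in the tests.

The translation model (`fit_translation_model()`) regresses log10
protein on log10 mRNA (always included) plus gene features, each tried
both as a main effect and as an interaction with centred log mRNA
(features centred before multiplication, so main effects keep their
marginal meaning). Forward selection maximises adjusted $r^2$ and
accepts a term only at partial-F $p < 0.01$; this concrete criterion
stands in for the loosely specified "iterative, sequential" selection
of the source analysis and makes the procedure deterministic
(alphabetical tie-breaks, collinear candidates skipped at $|r|>0.99$).
The trace of $r^2$ along the selection is recorded and is non-
decreasing by construction.

Protein turnover classes bin half-lives at 20 and 40 min. Published
descriptions of such bins disagree on whether the shortest-lived bin is
labelled "fast" or "slow"; the figure-legend convention (0–20 min =
fast) is the default and the labels are configurable
(`turnover_labels`).

# The synthetic-data generator

`simulate_truth()`, `simulate_srm()` and `simulate_transcriptome()`
generate datasets with known ground truth whose statistical structure
mirrors the study conditions:

* log10 protein cpc normal with mean 3.5 and SD 0.8 — a median around
  3000 cpc and a ~5-order dynamic range, matching a census spanning
  tens to millions of copies;
* log-normal translational efficiency with median 1035
  proteins/transcript (SD 0.5 in log10), mRNA = protein/TE exactly;
* four biological replicates with 12% multiplicative log-normal CV on
  the light channel; 5% technical CV per transition measurement (a
  typical triple-quadrupole figure; the source study does not state
  one);
* three spike levels drawn from the stated ranges; 200,000 cell
  equivalents on column;
* two surrogate peptides per gene with a log-normal response factor
  (shared by both labels, cancelling in the ratio) and a peptide-
  specific light/heavy recovery bias with log2 SD 0.566, chosen so the
  median AA sibling discrepancy is ~0.54
  ($0.6745\times\sqrt{2}\times0.566$). The bias distribution itself is
  a modelling convenience — no published distribution exists for
  peptide recovery bias;
* a hard limit of detection on light transition areas plus a 2% whole-
  group dropout, producing genuine Type B and C outcomes; noise-only
  decoy peak groups for FDR estimation.

An alternative generative mode (`feature_effects`) builds log protein
from log mRNA, feature main effects and feature×log-mRNA interactions
with noise scaled to a target generative $r^2$, for parameter-recovery
testing of the translation model; TE is then derived, so the
TE = protein/mRNA identity holds in both modes. All randomness flows
from the single config seed (truth, SRM and transcriptome use seed,
seed+1, seed+2), so identical configs give byte-identical outputs.

Simulated FPKM is proportional to true mRNA with log-normal noise.
Rescaling FPKM back to copies reproduces the truth only when the
allocation total equals the simulated genes' true mRNA total — a
simulated panel is a subset of a transcriptome, so its true total is
not the cellular 60,000.

What the generator does **not** emulate: chromatographic time series
(peak shapes, RT drift), isotope envelopes, interferences that vary by
transition, shared-peptide protein inference, or the long right tail of
real replicate failures. Passing tests therefore demonstrate the
correctness and calibration of the pipeline's rules, not robustness to
every failure mode of real chromatography.

# Numerical choices and known limitations

* **Degenerate inputs.** Constant peak-group patterns score zero
  co-elution; all-zero light groups score below any real signal; the
  robust CV requires ≥2 values and a positive median; slope fitting
  requires ≥3 positive pairs and non-constant logs.
* **Small-sample rCV bias.** The MAD-based rCV is consistent only
  asymptotically: with 4 replicates its median is ≈8% when the true CV
  is 12% (with 3, ≈6.5%). Pipeline rCV summaries at replicate counts
  this small are systematically below the generative CV; this is a
  property of the estimator the field uses, and it should be kept in
  mind when comparing reported rCV medians against nominal noise
  levels. The calibration checks in the test suite sit at the edge of
  their band for exactly this reason.
* **Reconciliation bias.** The "higher of two peptides" rule for
  discordant siblings and the arithmetic mean for concordant ones both
  bias protein estimates upward when peptide biases are symmetric on
  the log scale (observed as a ~0.2 median log2 excess on default
  synthetic data). This is faithful to the published protocol rather
  than a defect of the implementation.
* **Problem sizes.** The bundled analyses and tests use 500–1200 genes,
  50–100 FDR/model-recovery replications and $10^4$-point slope
  simulations — sizes at which the Monte-Carlo error of every checked
  quantity is well inside its test tolerance.
* **Scope.** Chromatogram peak-picking, RT alignment and prediction,
  spectral-library lookup, and computation of the gene features (tAI,
  PARS, PEST, poly-A, RIP enrichment) are out of scope; features
  arrive as columns and any numeric feature is accepted.
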