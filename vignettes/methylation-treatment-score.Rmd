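---
title: "Methylation treatment scores from dual-cohort EWAS: models and design"
author: "methylMTS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation treatment scores from dual-cohort EWAS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylMTS)
```

## The problem

Interferon-beta (IFN\(\beta\)) was among the first disease-modifying
therapies for multiple sclerosis, and its use leaves a strong, reproducible
imprint on whole-blood DNA methylation at interferon-response genes.
methylMTS packages the statistical machinery needed to study such
treatment imprints on Illumina EPIC-style beta values: a dual-cohort
differential-methylation scan, a weighted **methylation treatment score**
(MTS) built from replicated index CpGs, discrimination and
time-since-treatment analyses, reference-based immune-cell deconvolution
with a cell-specific interaction scan, a quartile-based genotype
association scan, hypergeometric overrepresentation analysis, and a
covariate sensitivity analysis. Because the patient cohorts behind this
design are not publicly available, the package ships a synthetic data
generator that reproduces the study conditions, so every stage is testable
end to end.

## Models

### Per-CpG association scan

The scan uses the case-control orientation: treatment status is the
outcome and each CpG's beta value is a predictor next to the covariates,

\[
\mathrm{glm}\bigl(\text{Treated}_{0-1} \sim \beta_{\text{CpG}_i}
  + \text{Age} + \text{Sex} + \text{CellFractions}\bigr),
\]

with six cell fractions (NK, monocytes, B cells, CD8+ T, CD4+ T,
neutrophils) and, for the combined two-cohort model, a cohort indicator.
The effect size \(\Delta\beta\) is deliberately the *raw* difference of
group mean beta values (treated minus untreated); the regression
contributes only the p-value.

**Which test for the CpG term.** At the effect sizes this design is built
to detect (\(|\Delta\beta|\) of 0.05-0.27 against residual noise of a few
percent), the CpG nearly or completely separates the two outcome classes.
Under (quasi-)separation the Wald statistic collapses: the estimated
coefficient and its standard error both diverge and the Wald p-value tends
to 1 (the Hauck-Donner effect), so the strongest true signals would be the
ones most likely to be *missed*. The package therefore tests the CpG term
with the likelihood-ratio test against the covariate-only model, which is
fitted once per scan. When the per-CpG ML fit itself is unreliable — it
ends at the boundary of the parameter space or does not converge, in which
case its deviance is arbitrary — the record is flagged
(`"separation"`/`"nonconverged"`) and the p-value reported is the Rao
score test evaluated under the covariate-only null model, which is defined
and powerful regardless of separation. A CpG constant across samples is
flagged `"degenerate"` and gets no p-value. Covariates that are constant
in a cohort (for instance sex in an all-female discovery cohort) are
dropped from the design rather than passed to the fitter.

Genome-wide significance uses the fixed EPIC-scale threshold
\(9.8\times10^{-8}\), with no further multiple-testing adjustment, and
probes on the sex chromosomes are retained.

### Replication and index CpGs

A probe *replicates* when it meets the significance threshold in both
cohorts with the same sign of \(\Delta\beta\). Both thresholds default to
the strict \(9.8\times10^{-8}\); a lenient replication preset of
\(10^{-4}\) is available (`threshold_repl`), since published index tables
of this design include two probes whose replication p-values sit between
the two. Within each gene, replicated probes sharing a sign are reduced to
a single **index CpG**: the probe with the smallest discovery p-value,
ties broken by larger \(|\Delta\beta|\), then lexicographic probe id (the
tie-break is this package's choice; no published rule exists). Genes with
mixed-sign probes are skipped with a warning.

### The methylation treatment score

\[
\mathrm{MTS}_s = \sum_i \beta_{s,\text{CpG}_i}\,\Delta\beta_{\text{CpG}_i},
\]

an exact weighted sum over the index CpGs with the discovery
\(\Delta\beta\) as weight — no normalisation, no intercept. Weights default
to the full-precision \(\Delta\beta\) computed by the pipeline;
`ifnb_index_weights()` provides the published rounded weights for worked
examples (the published group MTS means are not exactly recoverable from
rounded weights, so precision is configurable). Discrimination is
summarised by the rank-based AUC (midrank tie handling, identical to
all-pairs counting) over both cohorts pooled, and group separation by a
two-sided Wilcoxon rank-sum test. The time model is ordinary least squares
of the score on \(\log_{10}(\text{days since first treatment})\), with an
optional restriction to early samples (default window 100 days); the
88.2-day therapeutic-lag line drawn by `plot_time_model()` is a cited
annotation constant, not a computed quantity.

### Deconvolution and the cell-specific scan

Cell proportions are estimated by constrained least squares against a
reference panel: non-negative least squares with the sum-to-one constraint
imposed as a strongly weighted pseudo-observation, followed by
renormalisation onto the simplex. This is a deliberate substitution for
reference-based deconvolution packages with robust-regression and
sample-filtering layers; proportions here are only covariates and inputs,
and the constrained least-squares estimator recovers noiseless mixtures of
a well-conditioned panel to machine precision.

The cell-specific scan fits, per DMP and cell type,

\[
\mathrm{lm}\bigl(\beta_{\text{CpG}_i}\times 100 \sim \text{CellProp}
 + \text{CellProp}\times\text{Treated}_{0-1} + \text{Sex} + \text{Age}
 + \text{Cohort}\bigr),
\]

and reads the treatment effect attributable to the cell type from the
interaction coefficient. Two filtering rules apply: interaction p below
\(9.8\times10^{-8}\) and absolute interaction coefficient of at least 2.
A coefficient threshold of 2 is impossible on the \([0,1]\) beta scale —
no cell-level difference can exceed 1 — so the response is modelled on the
percent scale, making the rule a 2-percentage-point cell-level effect;
both the scale and the threshold are configurable. The published filtering
sentence is ambiguous about direction; the default *keeps* records passing
both rules (consistent with reporting counts of cell-specific DMPs), and
`filter_cell_records(direction = "drop_significant")` selects the other
reading.

**A structural caveat.** The interaction model contains no treatment
main-effect term. A genuinely cell-specific effect of size \(\delta\) in a
cell with mean proportion \(\bar p\) shifts the *mean* bulk beta of
treated samples by \(\bar p\,\delta\), and with no main effect available
that shift is absorbed by *every* cell type's interaction term with
coefficient roughly \(\bar p\,\delta / \bar p_{\text{cell}}\) — large
precisely for low-abundance cells. In simulations with a pure Treg effect,
unaffected low-abundance cell types (dendritic cells especially) also pass
both filters in a substantial fraction of runs, while the truly affected
cell type fits best (smallest interaction p) essentially always. Users
should read multi-cell-type hits of this scan as "the effect is carried by
low-abundance cells, best explained by the top-ranked one", not as
independent discoveries per cell type.

### Genotype scan, ORA, sensitivity

The MTS-quartile genotype scan splits treated samples into top and bottom
score quartiles by the nearest-rank rule (each group
\(\lceil n/4 \rceil\); the published split of 64 treated samples gives 16
per group) and, per SNP, tests the 2x3 genotype count table — the
published analysis tests "difference in genotype", not alleles — with the
Freeman-Halton exact conditional test, implemented by full enumeration
over tables with fixed margins (feasible at these group sizes; results
agree exactly with `fisher.test`). Thresholds: genome-wide
\(7.69\times10^{-8}\), suggestive \(10^{-5}\). Monomorphic SNPs get p = 1.

Overrepresentation analysis is the one-sided hypergeometric upper tail of
a query gene list against GMT gene sets over a fixed background (the EPIC
array background has 26,650 genes), with Benjamini-Hochberg adjustment
across sets (the adjustment method is this package's choice). Sensitivity
analysis uses Pearson correlation for continuous covariates, a Wilcoxon
rank-sum test for binary categorical ones, and — a documented extension,
since the published design names only a two-group test — a Kruskal-Wallis
rank test for categoricals with more than two levels (MS subtype).

## The synthetic data generator

`generate_cohorts()` emulates the study conditions: a discovery cohort of
31 treated vs 83 untreated samples (all female) and a replication cohort
of 33 vs 202 (~75% female), with one probe per published gene planted at
its discovery effect size on top of the published untreated mean:

```{r planted, eval = FALSE}
cfg <- simulation_config(seed = 1)   # the study conditions
ds  <- generate_cohorts(cfg)
head(ds$truth$planted_bulk)
```

Model, per probe and sample: background probes draw a baseline
\(\beta_0 \sim U(0.05, 0.95)\) shared across cohorts and cell types; a
configurable number of *signature probes* (default 200) instead draw
independent per-cell-type levels — without them the reference panel would
be exactly rank-1 and deconvolution impossible. Bulk beta is the
Dirichlet-mixture of cell profiles plus, for treated samples, the planted
bulk \(\Delta\beta\) and any cell-specific effect scaled by that sample's
cell proportion, plus additive Gaussian noise clipped to
\([0.001, 0.999]\). Probes of a planted cluster share a latent noise
factor giving the configured within-cluster correlation. All randomness
descends from one master seed through fixed sub-streams
(`substream_seed()`), so changing, say, the SNP count cannot perturb the
beta matrix.

Parameter defaults and what they mean:

| parameter | default | meaning |
|---|---|---|
| `noise_sd` | 0.03 | additive beta-scale noise; chosen for power at planted effects \(\ge 0.04\), not fidelity to (unreported) per-CpG variances |
| `dirichlet_concentration` | 40 x whole-blood means | neutrophils 0.55, CD4 0.15, CD8 0.08, B 0.06, NK 0.05, monocytes 0.08, DC 0.01, Treg 0.02 |
| `n_signature_probes` | 200 | probes with cell-type-specific levels conditioning the panel |
| `maf_range` | (0.05, 0.49) | uniform MAF range for Hardy-Weinberg genotypes, independent of all phenotypes |
| `female_prop_disc`, `female_prop_repl` | 1.0, 0.75 | cohort sex composition |
| `age_shift_treated` | 0 | opt-in confounding knob; labels are otherwise independent of age and sex |

Noise is additive Gaussian on the beta scale with clipping, not
logit-normal: simpler, and adequate at the effect sizes of interest. The
generator does **not** simulate raw intensities, probe-type chemistry,
detection p-values, or batch structure, and the pipeline consumes
already-normalised beta values — so passing tests demonstrate the
statistical machinery under clean, exchangeable noise, not robustness to
array artefacts, batch effects, or the heavier-tailed, heteroscedastic
variation of real blood methylomes.

## Numerical choices and calibration

* **Small-sample calibration.** With ~31 outcome events and 8-10
  predictors in the discovery model, asymptotic p-values are mildly
  anti-conservative: in null simulations the ECDF of p-values exceeds the
  nominal level by about 0.005-0.013 through the mid-range (the extreme
  tail is clean; genome-wide false positives were never observed in 100
  null scans). A Kolmogorov-Smirnov uniformity check at \(\alpha = 0.01\)
  on 2,000 null CpGs consequently rejects in roughly 5% of seeds for the
  combined scan (more for the smaller discovery-only scan). An
  F-referenced LRT and the Rao score test were evaluated and do not
  repair this; it is a limitation of maximum-likelihood asymptotics at
  these cohort sizes, shared with standard EWAS practice.
* **Power design for the cell-specific scenario.** Detecting a cell-level
  effect of 0.25 in a cell at 2% mean abundance means resolving a ~0.5%
  bulk shift: \(\mathrm{SE} \approx \sigma / (\mathrm{sd}(p_{\text{Treg}})
  \sqrt{n_{\text{treated}}})\) requires residual noise
  \(\sigma \approx 0.005\) (array technical-noise scale) for genome-wide
  significance; at the bulk default \(\sigma = 0.03\) the power is nil.
  The cell-specific power scenario therefore documents and uses
  \(\sigma = 0.005\), while the bulk default stays 0.03.
* **Degenerate inputs.** Empty groups, constant covariates, constant
  scores at the quartile split, rank-deficient panels, monomorphic and
  all-missing SNPs, out-of-range beta values and unknown genotype codes
  are all rejected or flagged with named coordinates; nothing is imputed
  silently.
* **Problem sizes in the shipped tests.** Unit tests use cohorts of tens
  of samples and tens of probes; the end-to-end recovery checks run the
  full study sizes (31/83 and 33/202) over 5,000 background probes, null
  calibration uses 2,000 probes and 100 seeds, and the genotype null uses
  5,000 SNPs at 16 vs 16 over 100 seeds — sizes at which the whole suite
  completes in a few minutes on one core.

## Known limitations

The package scans CpGs marginally (no region-level smoothing), trusts the
supplied normalisation, and provides no batch correction, probe filtering,
imputation, kinship adjustment, or GO annotation retrieval — gene sets are
supplied by the user as GMT. The cell-specific scan inherits the
interaction-model leakage described above, and compositional cell
proportions make the per-cell-type comparison tests mutually dependent
(noted at run time).
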