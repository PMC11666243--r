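---
title: "Methods: sorted-bin screen statistics and lipid-class association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sorted-bin screen statistics and lipid-class association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscreen)
```

## The experimental design this package models

A pooled CRISPRi screen reads out a continuous cellular phenotype — here,
the intensity of an amyloid-binding dye that stains endogenous protein
aggregates — by FACS-sorting the stained library into a phenotype-high
and a phenotype-low bin (top and bottom quartiles) and sequencing the
guide cassettes of each bin. Guides whose knockdown raises the phenotype
are over-represented in the high bin; guides that lower it accumulate in
the low bin. The library contains a few guides per gene plus several
hundred to several thousand non-targeting (NT) guides that match no
genomic site and act as designed negative controls.

Two features of this design drive the statistical choices below:

* **The sorter gate is a covariate-adjusted gate.** Staining intensity
  correlates with cell size, so sorting on raw intensity would sort
  partly on size. The simulator reproduces this: observed log intensity
  is `z + beta * size` with `size ~ N(0, 1)`, and the gate ranks cells on
  the residual of an ordinary least-squares regression of intensity on
  size. The functional form of the instrument's correction is not
  observable from sequencing data; a linear residual is the simplest
  model consistent with "corrected for the size-intensity correlation"
  and the package treats it as a modeling assumption, not a fact about
  the instrument. With residual gating the mean size difference between
  bins is ~0 (a property the test suite asserts); with raw-intensity
  gating it is large.
* **NT guides provide a designed null.** Gene-level significance is
  assessed against resampled NT guides rather than against permuted gene
  labels, because NT guides are exposed to every step of the experiment
  (infection, selection, staining, sorting, PCR, sequencing) without a
  biological effect.

## Screen statistics

`normalize_counts()` applies median-of-ratios size factors per sample
(computed over guides detected in every sample), the standard depth
correction for sequencing count matrices. `guide_lfc()` computes
`log2(high + 0.5) - log2(low + 0.5)` per replicate and averages
replicates with equal weight; the 0.5 pseudocount keeps guides absent
from one bin finite and is symmetric at zero counts.

`gene_stats()` aggregates guides to genes by the **median** guide LFC —
robust to a single failed guide in a typical 5-guide design — and builds
the null for a gene with *k* guides as the distribution of medians of
*k* NT-guide LFCs resampled with replacement (10,000 draws by default).
Two-sided p-values use the permutation floor `(b + 1) / (n_perm + 1)`,
so no p-value is exactly zero, and FDR is Benjamini-Hochberg over all
tested genes. Genes sharing a guide count share the identical null
distribution, which is therefore computed once per distinct count.

This permutation scheme is a documented alternative to the gene test of
the established RRA-based screen pipeline; it is not expected to be
numerically identical to it, and the reader for that pipeline's
gene-summary layout (`read_mageck_gene_summary()`) exists so externally
produced tables can be filtered with the same hit rules.

## Hit calling and the prerank score

Two hit rules are provided, reflecting the two conventions a screen
report may use:

* `count_fdr_hits()` — the plain directional `FDR < alpha` filter.
* `volcano_hit_call()` — the volcano-contour rule: a gene is a hit when
  `|log2FC| * -log10(FDR) >= -log10(alpha)`, the hyperbola that passes
  through (1, alpha) on a volcano plot. The boundary counts as a hit,
  and the rule is monotone: lowering FDR or raising `|log2FC|` never
  un-calls a hit.

`prerank_score()` condenses effect size and confidence into one signed
quantity per gene:

score = (|LFC| / sigma_LFC + nlFDR / sigma_nlFDR) * D,
nlFDR = log10(1 / FDR),

where both sigmas are sample standard deviations (n − 1 denominator)
over the full gene table, giving the two terms similar weight, and D is
±1 so the score's sign matches the fold change (D = +1 at LFC = 0, a
documented tie-break; the score is then 0 unless nlFDR > 0). FDR is
floored before the log — at `1/(n_perm + 1)` when produced by this
package's permutation test, or at a tiny constant such as 1e-12 when
ingesting external tables that report FDR = 0 — which keeps the score
finite without reordering genes.

## Preranked GSEA

`gsea_prerank()` implements the classic weighted Kolmogorov running-sum
enrichment score with exponent p = 1 on `|score|`: descending ranking
(ties broken by gene identifier so results are deterministic), hit
increments proportional to normalized `|score|`, miss decrements of
`1/(N - N_hit)`, ES equal to the maximum signed deviation. The null
permutes gene labels (equivalently, draws random sets of the same size)
1,000 times by default; NES divides ES by the mean |null ES| of the same
sign, and nominal p and FDR q follow the standard preranked procedure
computed separately for positive and negative enrichment. The
permutation count, weighting exponent, and set-size bounds (5–500 after
intersection with the scored genes) are conventional preranked defaults,
chosen because the upstream method names the algorithm without fixing
its parameters. The implementation is verified in the tests both against
an exhaustive O(N) running-sum oracle and against an independent
reference implementation of the same statistic.

## Lipid-species regression and class enrichment

`lipid_r2()` fits ordinary least squares (with intercept) of a species'
log abundance — perturbation-level values, averaged over replicates
before regression — on the perturbation phenotype and reports the
coefficient of determination, which for simple regression equals the
squared Pearson correlation; it is symmetric in its arguments and
invariant to affine transforms, both asserted as properties.
`fit_all_lipids()` maps this over a species table, optionally restricted
to a named "core" perturbation subset, since association strength is
most interpretable across perturbations that act directly on lipid
metabolism.

`class_ks()` compares each lipid class's R² values to the R² values of
**all** lipids with a two-sided two-sample Kolmogorov–Smirnov test. The
reference deliberately includes the class's own members (the
class-versus-everything reading); `exclusive_reference = TRUE` gives the
class-versus-rest variant. Because the class overlaps the inclusive
reference, between-sample ties always exist and the textbook exact
two-sample distribution does not apply. When the class is small
(min(n1, N) ≤ 10), the R² values are tie-free and the enumeration is
tractable (≤ 1e5 subsets), the exact permutation p-value is computed by
enumerating every assignment of class labels; otherwise the asymptotic
two-sample p-value is used, which is also the tie-break when R² values
repeat. The inclusive-reference test is conservative under the null
(overlap shrinks D); the suite checks that the fraction of null classes
at p < 0.05 stays at or below twice the nominal rate, and no
multiple-testing correction is applied across classes, matching how such
class-level p-values are conventionally reported.

## Flow-cytometry quantification

Three small, exact formulas, each applied to **median** event
intensities (medians are robust to the heavy right tails of cytometry
distributions; the pH-reporter protocol specifies medians and the same
summary is applied uniformly):

* `proteostat_normalize()` — spike-in double normalization
  `(sample_treated / sample_spikein) / (control_treated /
  control_spikein)`; scale-invariant within each sample pair.
* `phlare_ratio()` — `(sfGFP - bg_sfGFP) / (mCherry - bg_mCherry)` with
  channel-wise background medians from cognate non-reporter controls.
  Background ≥ signal is an error, never clamped, because a clamped
  ratio would silently misreport pH. No inversion to absolute pH is
  attempted: the calibration series is reported as ratios, and
  `simulate_ph_series()` generates it from a Henderson–Hasselbalch
  sigmoid (apparent pKa 5.9 for sfGFP), which makes the expected ratio
  strictly increasing over the pH 4–7.5 buffer series.
* `gal3_puncta_score()` — puncta per average-cell-equivalent:
  `puncta / (total_cell_area / mean_cell_area)` per field, averaged over
  fields within a time point, with the time-course maximum reported.
  Pooling sub-fields before averaging leaves the score unchanged
  (additivity), a property the tests assert. Puncta counts are inputs;
  spot detection belongs to the imaging platform, not this package.

## What the simulators do and do not emulate

`simulate_screen()` reproduces the statistical structure the analysis
assumes: per-gene latent effects (a configurable fraction of non-null
genes at a configurable magnitude with random sign), cell-level noise,
the size covariate, exact-quantile gating, and multinomial (optionally
Dirichlet-multinomial) sequencing of each bin. Defaults — 1,000 genes ×
5 guides, 500 NT guides, 10% non-null at 2 cell-noise SD, 150 cells per
guide, two replicates, quartile bins, 1e6 reads per bin — form a
desk-scale screen with the geometry of a genome-wide experiment (5
guides per gene, an NT fraction of a few percent, ~180 reads per guide
per bin). Not modeled: infection multiplicity, selection bottlenecks,
PCR amplification bias, guide-efficacy variation, dead-cell exclusion
(the viability stain has no computational description), and chromatin-
or position-dependent CRISPRi efficiency. Passing recovery tests on
these simulations therefore demonstrates the statistics are correct and
calibrated under the stated generative model, not that real screens meet
that model.

`simulate_lipidome()` generates class-structured linear coupling between
log abundance and the phenotype with Gaussian noise. The default panel
(SM, CE strongly coupled; Cer, LacCer, HexCer nearly uncoupled; 12
perturbations) mirrors the qualitative structure of the study system —
sphingomyelins and cholesterol esters tracking the aggregation
phenotype. Real lipidomics adds censoring at the detection limit,
correlated species within a class beyond the shared coupling, and
non-Gaussian residuals, none of which are modeled.

`simulate_flow_events()` and `simulate_ph_series()` produce log-normal
event intensities per labelled population; no spectral spillover,
autofluorescence structure, or gating debris is modeled.

## Numerical choices and problem sizes

* Permutation p-values are floored at `1/(n_perm + 1)`; BH is applied
  over all tested genes.
* Median-of-ratios factors take the median of linear-space ratios; the
  log-space variant used by a popular RNA-seq package differs only in
  how an even number of ratios is averaged, and the two agree to ~0.1%
  on the tested fixtures.
* GSEA ranking ties are broken by gene identifier; the running-sum
  extremum is evaluated in closed form at hit boundaries, which is
  algebraically identical to the full O(N) walk.
* The test suite and the reproduction script use 20 screens of 1,000
  genes for operating characteristics (realized FDR ≤ 0.10 and power ≥
  0.8 at q < 0.05), 100 lipidome simulations for class recovery, and 20
  random instances for the ES oracle equivalence; these sizes give
  stable Monte-Carlo estimates while keeping a full run in minutes on
  one CPU.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_screen(screen_sim_params(), seed = 1)
stats <- gene_stats(guide_lfc(normalize_counts(sim$counts)),
                    n_perm = 10000, seed = 2)
stats <- volcano_hit_call(stats, alpha = 0.05)
table(stats$hit)

scores <- prerank_score(stats, fdr_floor = 1 / 10001)
regulon <- sim$truth$gene[sim$truth$true_effect > 0]
gsea_prerank(scores, list(regulon = regulon), n_perm = 1000, seed = 3)

lip <- simulate_lipidome(lipid_sim_params(), seed = 4)
fits <- fit_all_lipids(lip$lipids, lip$phenotype)
class_ks(fits)
```

## Known limitations

* The NT-resampling null assumes NT guide LFC dispersion matches that of
  null targeting guides; strong guide-efficacy heterogeneity in real
  data would violate this and is not simulated.
* The gene test is a median/permutation scheme, not the RRA gene test of
  the established pipeline; rankings will correlate but not coincide.
* The inclusive-reference K-S test is conservative; its p-values are
  comparable within an analysis, not calibrated error rates.
* `run_pipeline()` orchestrates simulation-backed analyses; applying the
  statistics to real count or lipid tables uses the reader functions
  directly.
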