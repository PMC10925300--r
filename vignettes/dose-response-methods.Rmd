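---
title: "Methods: dose-response analysis of CRISPRi/a titration screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response analysis of CRISPRi/a titration screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scdose)
```

This vignette documents the models, estimators, default parameters and
design choices behind `scdose`, in the order the pipeline applies them.

## The experimental design being analysed

Two pooled K562-style effector lines — CRISPR interference (dCas9 fused to
KRAB-MeCP2) and CRISPR activation (dCas9-VPR) — are transduced at low MOI
with one guide library (~96 sgRNAs: TSS-targeting, TSS-tiling at ~100 bp
steps within ±1 kb, distal CRE-targeting, mismatch-attenuated, plus 5
non-targeting controls) directed at a handful of *cis* genes. Cells are
read out with targeted multimodal sequencing: a ~90-gene cDNA panel, sgRNA
capture, and hashtag oligos. Each guide induces some fold change of its cis
gene; across guides this traces out a dosage series, and every panel
(*trans*) gene's pseudo-bulk fold change can be studied as a function of
cis dosage.

## Cell calling

**Line demultiplexing** (`demux_cell_lines`). Hash counts are
centred-log-ratio transformed within each cell; the top hashtag must beat
the runner-up by a CLR margin of 1.0 (default). Independently, the dominant
effector transcript (the KRAB-dCas9 vs VPR cDNA, captured on the panel)
must agree with the hash call; disagreement or absence of either signal
yields `ambiguous`. Requiring agreement between two independent modalities
trades recall (~89% of simulated cells are line-called at 5% hash error)
for a line-assignment accuracy above 99%, which matters because fold
changes are always computed within line.

**Guide assignment** (`assign_guides_gmm`). For each guide a two-component
Gaussian mixture is fitted to `log10(count + 1)` over cells with at least
one UMI of that guide, separating ambient background from true delivery.
The EM is deliberately plain and deterministic: initialisation by a median
split, at most 100 iterations, log-likelihood tolerance 1e-6. A cell is
positive when its high-component posterior exceeds 0.5 and its raw count is
at least 3 (defaults); guides with fewer than 20 nonzero cells, or whose
components collapse to within 0.1 on the log10 scale, fall back to the
plain count threshold with a warning. Cells positive for exactly one guide
are assigned; cells positive for two or more are treated as multiplets and
dropped. The mixture is per guide across cells (not per cell across
guides): per-guide bimodality is the dominant published convention for
guide calling and is directly testable against simulation truth.

## Pseudo-bulk fold changes

For a guide group \(g\) and gene \(j\), with matched-line pooled-NTC
reference \(r\), the estimator is

\[
\widehat{\mathrm{lfc}}_j \;=\; \log_2\frac{S^g_j + 0.5}{S^r_j + 0.5}
\;-\; \mathrm{median}_k \log_2\frac{S^g_k + 0.5}{S^r_k + 0.5},
\]

where \(S_j\) are summed UMIs over the group's cells and the median runs
over the analysed panel. The median term simultaneously removes the depth
imbalance between group and reference and the *compositional* shift:
targeted panels are small, so when many genes respond strongly the panel
total itself moves, and plain count fractions would book that movement as
an apparent fold change of every unchanged gene (we measured ~0.2 log2
units of such spurious shift under strong perturbations of the default
simulation). The median-of-ratios correction assumes that the genes with a
median log-ratio are unchanged — true whenever responders are a minority or
are balanced between directions, which holds for this panel design (and for
the default simulation, where up- and down-responders are symmetric). The
plain fraction estimator remains available (`composition_correct = FALSE`),
and the single-pair operation `pseudobulk_log2fc` keeps the documented
fraction form. The pseudocount of 0.5 UMI-equivalents keeps zero-count
groups finite; its behaviour is tested at the null.

Standard errors are nonparametric bootstrap over cells of both the group
and the reference (200 replicates, seeded). Significance is a two-sided
Wilcoxon rank-sum test per (guide, gene) on per-cell normalised expression,
using the normal approximation with tie correction and *without* the
continuity correction: the cell groups here are large (tens to thousands)
and on heavily tied count data the continuity correction makes null
p-values visibly conservative — with it, pooled null p-values fail a KS
uniformity check; without it they are calibrated (KS p ≈ 0.4 in our null
simulations). Per-cell normalisation for these tests defaults to the
median-ratio size factor (`normalize_cells(method = "median_ratio")`), for
the same compositional reason as above; classic median-depth scaling is the
`"depth"` method.

Benjamini-Hochberg correction is applied in two reporting families: the
cis tests (each guide against its own target; judged at 10% FDR) and the
trans tests (all other pairs; 5% FDR). The family structure is a
configuration choice, not a law: for the *unresponsive* call below we use a
different family (see there).

## Dose-response models

For each (cis gene, trans gene) pair, the per-guide data are
\(x\) = the guide's estimated log2FC on the cis gene and \(y\) = its log2FC
on the trans gene, over all guides targeting that cis gene plus the NTC
guides as anchors near zero dosage (~25–35 points in the default design).

Three mean models are fitted:

* **Linear** — ordinary least squares.
* **Four-parameter sigmoid** —
  \(f(x) = c + (d-c)/(1+e^{-b(x-a)})\), with \(a\) the inflection dosage,
  \(b\) the steepness (the analytic slope at the inflection is
  \(b(d-c)/4\), reported as `slope_at_inflection` alongside raw \(b\)),
  and \(c \le d\) the asymptotes. Orientation is carried by the sign of
  \(b\); \((a,b,c,d)\) and \((a,-b,d,c)\) describe the same curve, so fits
  are canonicalised to \(c \le d\). Fitting is damped (Levenberg-Marquardt)
  least squares via `minpack.lm::nlsLM` with box bounds
  (\(|a| \le\) twice the x-range beyond the data, \(|b| \le 50\), \(c,d\)
  within the y-range ±50%) and multi-start: one heuristic start (asymptotes
  from the y extremes, \(a\) at the steepest local change, \(b\) from
  range/IQR) plus 9 seeded random starts; the best-RSS converged solution
  wins, and the reported RSS is never allowed above the constant-model RSS
  (which the sigmoid nests).
* **Loess** — local quadratic regression, tricube weights, span 0.75,
  evaluated with clamping to the observed x-range (never extrapolated);
  used for non-monotonic responses, which no sigmoid can represent.

**Model comparison.** AIC in the least-squares Gaussian convention,
\(\mathrm{AIC} = n\log(\mathrm{RSS}/n) + 2k\) with \(k\) counting mean
parameters plus the error variance (linear 3, sigmoid 5), so
\(\Delta\mathrm{AIC} = \mathrm{AIC}_\text{linear} -
\mathrm{AIC}_\text{sigmoid}\) is positive when the sigmoid captures the
dose response better. Alternative AIC conventions shift both terms equally
and leave ΔAIC unchanged. Overfitting is guarded by 10-fold
cross-validation partitioning *guides* (the independent units of the
regression, not cells), reporting the Pearson correlation between pooled
held-out predictions and observations.

**Classification** (`fit_dose_response`), evaluated in this order:

1. *unresponsive* — no guide test on this gene reaches 5% FDR **and** the
   data carry no dose-effect evidence. Two deliberate choices here:
   * Significance is judged by BH within the pair's own guide tests, not
     within the global trans family. With thousands of genuine positives
     in the experiment, global BH pulls null q-values below 0.05, and in
     simulations about half of truly flat pairs acquired a false
     "significant" test through that route alone.
   * "No dose-effect evidence" means the AIC-selected model's span over the
     observed dosage window (`effective_range`: \(|slope| \times\) x-range
     when ΔAIC ≤ threshold, \(d - c\) otherwise) is below `range_min`
     (default 0.1 log2), **or** the OLS slope is statistically
     indistinguishable from zero (p > 0.05). The unconstrained sigmoid's
     asymptote difference has a long upper tail on pure noise (90th
     percentile ≈ 0.22 at noise SD 0.05), so using it alone as the range
     guard mislabels noise as response.
   The raw dynamic range \(d - c\) is still reported for every fit.
2. *nonmonotonic* — the loess leave-one-out error beats the sigmoid's by
   more than 5% **and** the loess curve has an internal extremum with
   amplitude above twice the sigmoid residual SD. The LOO comparison is
   only run when the cheap preconditions (derivative sign change with
   sufficient amplitude) fire.
3. *nonlinear* — ΔAIC > `daic_threshold` (default 2; enrichment analyses
   also use the more permissive 0, and both presets are exposed).
4. *linear* otherwise.

**One-copy restriction** (`restrict_copy_range`) refits using only dosages
within a hypothetical single copy loss to single copy gain,
\([-1, \log_2 1.5]\), closed at both ends.

**Grid prediction** (`predict_grid`) evaluates each pair's selected model
on a shared dosage grid, by default 100 points on \([-1.83, 0.51]\) — the
empirically observed common range of the titration — with an
`extrapolated` mask where the grid leaves that cis gene's own observed
dosage range.

## Downstream analyses

* `cluster_responses`: trans genes described by predicted curves
  concatenated across cis genes; Euclidean distance, Ward (`ward.D2`)
  linkage, cut at k = 6 by default. Curves are clustered on the raw log2FC
  scale so that dynamic range contributes to cluster identity (a z-scaled
  variant is available).
* `correlate_parameters` / `compare_groups`: Pearson correlations of fit
  parameters (a, b, c, d, dynamic range) with quantitative gene metrics
  (pairwise-complete, BH within each cis gene), and two-sided rank-sum
  tests over binary annotations.
* `enrich_nonlinear`: 2×2 Fisher exact tests of {ΔAIC > cut} × {gene in
  set}, BH across sets per cis gene; the odds ratio is computed directly
  from the table with a Haldane 0.5 correction on degenerate margins
  (flagged). The same machinery with `row_variable = "unresponsive"` gives
  the unresponsive-by-gene-set (e.g. housekeeping) variant.
* `celltype_correlation`: Pearson correlation of each perturbation's trans
  log2FC vector with cell-type expression profiles z-scored per gene across
  cell types, BH at 10% across the whole matrix — an interpretable
  "phenotype" axis for each dosage perturbation.
* `pca_foldchanges`: diagnostic PCA of the perturbation × trans-gene
  fold-change matrix; under a dominant dosage signal the leading components
  order perturbations along dosage.

## The synthetic-data generator

`simulate_experiment` draws a full three-modality dataset from a
`sim_config`. What it emulates:

* ~96 guides (5 NTC) across 4 cis genes in two effector lines, with
  per-guide cis effects spanning roughly −1.8 to +0.5 log2 — generated by a
  Gaussian efficacy-vs-TSS-offset profile peaked at +238 bp for CRISPRi and
  −99 bp for CRISPRa, so the cis-feature analyses have a known planted
  optimum;
* trans responses as flat / linear / sigmoid / non-monotonic functions of
  cis dosage, all anchored to 0 at dosage 0; the default panel plants three
  archetypes ("activated", "repressed", "buffered") over 80 trans genes,
  with four activated genes additionally non-monotonic on the second cis
  gene, and a fourth cis gene with an entirely flat network as a negative
  control;
* negative-binomial UMI counts (variance \(\mu + \mu^2/10\) by default)
  with an extra-zero dropout layer, logistic in log mean:
  \(P(\text{drop}) = \mathrm{logit}^{-1}(-s\,\log\mu)\) with midpoint at
  \(\mu = 1\) and \(s = 1\) by default (\(s = 0\) disables);
* ambient guide background (Poisson, 0.2 UMIs/guide/cell), delivered-guide
  capture at mean 30 UMIs, hashtag cross-contamination at 5%, and effector
  transcripts present only in the matched line;
* an optional binary on/off mode in which CRISPRi knock-down cells are
  either fully silenced (with probability \(1 - 2^{\mathrm{lfc}}\), so the
  pseudo-bulk mean matches the nominal effect) or untouched — the
  adversarial generative model that the on/off-split robustness check
  (`onoff_split_check`) is designed to detect; and an optional mode
  propagating cell-level dosage noise into trans responses.

What it does **not** emulate: read-level structure (UMI collapsing,
sequencing errors), cell cycle and lineage heterogeneity, doublet
transcriptomes beyond a configurable second-guide rate, batch/lane effects
(lanes exist only as optional metadata), and any feedback of trans genes
onto cis genes. Passing tests on this generator therefore demonstrate
estimator and classifier correctness under a realistic noise model — not
robustness to every artefact of real droplet data.

Determinism: a config's seed fully determines the dataset, and all seeded
package functions (simulation, bootstrap, mixture fitting, random starts,
CV folds) restore the caller's RNG stream, so identical configs are
bit-identical regardless of calling context.

## Numerical choices and degenerate inputs

* Constant-y sigmoid fits collapse to \(c = d = \bar y\) with RSS equal to
  the constant model; RSS = 0 maps to AIC −∞ (flagged).
* Wilcoxon on two constant groups returns p = 1; zero-variance metrics and
  empty annotation groups are reported missing with a reason rather than
  silently dropped.
* Guide groups below 10 cells produce records with missing estimates and a
  reason code; dose-response pairs with fewer than 6 points (or fewer after
  one-copy restriction) are skipped with a reason.
* Fisher odds ratios on degenerate margins use Haldane's 0.5 and are
  flagged; BED overlap follows the 0-based half-open convention
  (`start <= pos < end`).
* Test problem sizes: unit tests use compact screens (one cis gene, ~12–15
  trans genes, 15–400 cells/guide); the operating-characteristic and
  end-to-end checks use 30-guide regression designs with noise SD 0.05 and
  the default 96-guide / 84-gene / 150-cells-per-guide fixture — sizes at
  which every stated property is measurable in minutes on one CPU.

## Known limitations

* The per-guide dosage \(x\) is an estimate; its error is ignored by the
  regression (no errors-in-variables treatment). With pseudo-bulk SEs of
  ~0.03–0.05 against dosage spans of ~2 log2 units this attenuation is
  small, but it will bias steepness estimates for cis genes with narrow
  spans.
* The median-of-ratios correction fails if a large majority of the panel
  responds in one direction; panel designs should retain anchors
  (housekeeping genes, balanced responders).
* The non-monotonicity rule is conservative by construction (LOO
  comparison plus amplitude guard); shallow non-monotonic responses are
  typically classified as nonlinear instead.
* CRISPRi and CRISPRa arms of the same cis gene are pooled into one dosage
  axis; genuine mechanism-specific trans responses (same dosage, different
  effector) would be averaged over.
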