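# scdose

Dose-response analysis for CRISPRi/CRISPRa dosage-titration Perturb-seq
screens with targeted multimodal single-cell readout.

## The problem

Classical perturbation screens knock a gene out or overexpress it massively,
giving a two-point view of gene function. Guide tiling around a gene's TSS
with pooled CRISPR interference (dCas9-KRAB-MeCP2) and activation (dCas9-VPR)
lines instead produces a *graded* series of dosages of the same gene — a
synthetic allelic series. Reading the perturbed cells out with targeted
single-cell sequencing (cDNA panel + sgRNA capture + hashtag oligos) then
lets one ask, for every downstream (*trans*) gene, what function maps
upstream (*cis*) regulator dosage to the trans response — and in particular
whether that function is linear, sigmoid, or non-monotonic.

`scdose` implements the full analysis chain for such screens:

1. **Cell calling** — hashtag demultiplexing (CLR transform + margin rule,
   required to agree with the dominant effector transcript) and single-sgRNA
   assignment by a per-guide 2-component Gaussian mixture on
   log10(counts + 1).
2. **Pseudo-bulk fold changes** — for every (guide, gene), the log2 ratio of
   pooled counts against the matched non-targeting-control (NTC) cells of
   the same line, median-of-ratios corrected for panel composition, with
   bootstrap standard errors, Wilcoxon rank-sum p-values on per-cell
   normalised expression, and Benjamini-Hochberg q-values (cis family at
   10% FDR, trans family at 5%).
3. **Dose-response fitting** — per (cis gene, trans gene), ordinary least
   squares vs the four-parameter sigmoid

   `f(x) = c + (d - c) / (1 + exp(-b (x - a)))`

   fitted by damped (Levenberg-Marquardt) least squares with multi-start;
   model comparison by `ΔAIC = AIC_linear - AIC_sigmoid` (positive favours
   the sigmoid); 10-fold cross-validation over guides; loess for
   non-monotonic shapes; classification into
   unresponsive / linear / nonlinear / nonmonotonic; prediction on a common
   dosage grid (`[-1.83, 0.51]` log2FC by default).
4. **Downstream analysis** — Ward clustering of predicted response curves,
   correlation of fit parameters with gene metrics, Wilcoxon comparisons
   over binary annotations, Fisher-exact enrichment of nonlinear responses
   in gene sets, cell-type correlation "phenotypes", and PCA diagnostics.
5. **Synthetic data** — a seeded generator
   (`default_sim_config()` / `simulate_experiment()`) emulating the screen
   design (96 guides incl. 5 NTCs, 4 cis genes, 80 trans genes, two pooled
   effector lines, negative-binomial counts with dropout, ambient guide
   background, hash cross-contamination) with full ground truth, so every
   stage is testable without external data.

## Worked example

```r
library(scdose)

cfg <- pipeline_config(output_dir = "scdose_results", seed = 1)
res <- run_pipeline(cfg)   # simulates the default screen, then analyses it
```

The pipeline logs each stage:

```
assign: 15150 cells; 13448 line-called; 12064 single-guide assigned
dosage: 8686 (guide, gene) fold changes; 73 cis-significant at 0.1 FDR
response: 320 pairs fitted; classes: linear 74, nonlinear 67, nonmonotonic 2, unresponsive 177
downstream: 80 trans genes clustered into 6 clusters (0 excluded)
```

15,150 simulated cells pass through demultiplexing and GMM guide assignment
(~80% receive a unique guide, as in real screens at low MOI); 73 of the
guide-on-target tests are significant at 10% FDR, and all 73 have the fold
change sign expected from their effector line
(`direction_concordance(res$fc_table, res$dataset$guide_library)` returns
concordance 1 over n = 73). The 320 (cis gene x trans gene) dose-response
fits split into the four response classes; comparing with the generator's
truth tables:

```r
m <- merge(res$dosefits, res$dataset$truth$response_class,
           by.x = c("cis_gene", "trans_gene"), by.y = c("cis_gene", "gene_id"))
mean(m$response_class == m$class)   # 0.87 class recovery at seed 1
```

Inspecting one fitted pair:

```r
subset(res$dosefits, cis_gene == "CISG1" & trans_gene == "TRANS10",
       select = c(a, b, c, d, delta_aic, cv_r, response_class))
#         a    b     c    d delta_aic  cv_r response_class
#    -0.538 3.07 -1.58 0.33      30.2 0.984      nonlinear
```

i.e. this trans gene follows a sigmoid with inflection at cis log2FC -0.54,
asymptotes -1.58 and 0.33 (a dynamic range of ~1.9 log2 units), and the
sigmoid beats the line by 30.2 AIC units with held-out correlation 0.98.

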