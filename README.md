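# mirmodnet

Discovery of miRNA-mediated (ceRNA) network modules that mark cancer
progression, from matched miRNA / mRNA / lncRNA count profiles.

Tumor progression is shaped by competitive-endogenous-RNA regulation:
lncRNAs and mRNAs sharing miRNA response elements compete for the same
miRNAs, so a miRNA family that is lost during progression releases a whole
block of coding and non-coding targets at once. `mirmodnet` turns that idea
into a reproducible pipeline for two-arm cohorts (early-stage vs late-stage
tumors, e.g. ESGC vs LSGC in gastric cancer):

1. **Differential screen** per RNA class (median-of-ratios normalization;
   NB Wald or Wilcoxon; BH within class, adjusted p < 0.05).
2. **Rule-based network**: miRNA–mRNA edges need Spearman SCC < −0.3 *and*
   a prediction score > 50; miRNA–lncRNA edges need SCC < −0.3, or SCC < 0
   plus database support; a ceRNA closure keeps only miRNAs bridging both
   partner classes.
3. **RNs prioritization**: every node is scored by

   ```
   RNs = K * Rs / L
   ```

   with `K` the degree, `L` the node's total shortest-path length within
   its component (closeness is reported as `C = (N−1)/L`), and `Rs` the
   SVM-RFE rank score of its expression (`Rs = n − rank + 1`; rank 1 is
   eliminated last). Hubs that are close to everything *and*
   discriminative rise to the top.
4. **Family-anchored module**: top-ranked miRNAs (tagged by family, e.g.
   miR-200 vs miR-183) and lncRNAs, plus every mRNA wired to *both*
   families; validation recomputes edge correlations ("green" edges:
   SCC < −0.5, p < 0.05) and Wilcoxon group contrasts.
5. **Cox risk score** on the module miRNAs (risk = Σ βᵢ·xᵢ on a stored
   expression scale; median-cutoff stratification; Kaplan–Meier + log-rank)
   and chi-square tables against clinical categories.
6. **Exhaustive subset SVM classifier**: all non-empty subsets of the
   module panel, trained on one cohort, scored on another; Mann–Whitney
   AUC with a stored ROC whose trapezoidal area matches exactly.

A negative-binomial Gaussian-copula simulator (`generate_cohort()`,
`generate_evidence()`) plants differential genes, miRNA→target
anti-correlations, family co-expression, proportional-hazards survival and
clinical associations — with full ground truth — so the entire pipeline is
testable offline. See `vignettes/mirmodnet-methods.Rmd` for the models and
all numerical choices.

## Worked example

```r
library(mirmodnet)

res <- run_pipeline(pipeline_config(seed = 1L))
res
#> <pipeline_result> status: ok
#>   DE genes: 89 of 1220
#> <gcpmir_network> 3 lncrna, 7 mirna, 11 mrna nodes; 49 miRNA-mRNA and 15 miRNA-lncRNA edges
#> <progression_module> 6 miRNAs (famA + famB), 0 lncRNAs, 5 mRNAs; 29 edges
#>   log-rank p (train/test/whole): 2.443e-16 / 2.057e-07 / 6.84e-23
#> <subset_search> 2047 subsets; best AUC = 0.942 with {mir-B1, m-M2, m-M3}
```

Reading this: of 1220 simulated genes, 89 pass the differential screen; the
edge filters leave a 21-node network; the module rule recovers the planted
five both-family mRNAs plus six family miRNAs; the risk score separates
high- from low-risk patients (log-rank p ≪ 0.05 on training, held-out and
whole cohorts, as planted through the hazard coefficients); and the best of
the 2047 gene subsets classifies early vs late stage with AUC 0.94 on the
held-out samples.

Fitted objects follow broom conventions:

```r
tidy(res$risk_model)
#> # A tibble: 6 × 7
#>   gene_id   beta    se    hr hr_low hr_high p_value
#>   <chr>    <dbl> <dbl> <dbl>  <dbl>   <dbl>   <dbl>
#> 1 mir-A2   0.685 0.240 1.98   1.24     3.18 0.00431
#> 2 mir-A1  -0.185 0.198 0.831  0.564    1.23 0.352
#> ...
autoplot(res$stratification$whole)   # Kaplan-Meier curves
autoplot(res$classifier)             # best-subset ROC
```

Every stage is callable alone (`de_screen()`, `spearman_edges()`,
`build_network()`, `compute_topology()`, `svm_rfe_rank()`, `rns_scores()`,
`extract_module()`, `fit_cox()`, `risk_stratify()`,
`search_combinations()`), and `run_pipeline(..., outdir =)` writes a TSV /
GraphML / JSON bundle with an md5 manifest that reproduces byte for byte
under the same seed. A thin CLI lives at `inst/scripts/run_pipeline.R`
(`simulate` and `run` subcommands).

The package also ships the worked-example prioritization table of a
155-node gastric-cancer progression network (`reference_rns_example()`):
`invert_rns_table()` recovers integer `(L, Rs)` pairs from the printed
closeness and RNs values, which pins down the `(N−1)/L` closeness
convention and the integer-rank reading of `Rs`.

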