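---
title: "Methods: miRNA-mediated network module discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mediated network module discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mirmodnet` implements a full discovery pipeline for miRNA-mediated (ceRNA)
network modules that mark cancer progression, together with a synthetic
cohort generator so that every stage is testable without protected patient
data. This vignette is the package's account of the underlying models, the
tunable parameters, the numerical choices, and what the tests do and do not
establish.

## The analysis model

The pipeline takes three count matrices (miRNA, mRNA, lncRNA; genes x
samples) over the same tumor samples, split into an early-stage (ESGC) and a
late-stage (LSGC) group, plus target-prediction evidence tables, and runs:

1. **Differential screen.** Counts are normalized by median-of-ratios size
   factors. Each gene is tested for a group difference; p-values are
   Benjamini-Hochberg adjusted *within each RNA class* (the three classes
   have very different sizes and base-rate signal, and pooling would let the
   large mRNA class dominate the adjustment). Genes with adjusted p < 0.05
   form the node universe.

2. **Network construction (four rules, all strict inequalities).** Spearman
   correlations are computed between every differential miRNA and every
   differential partner over the pooled tumor samples; pairs with p >= 0.05
   are dropped. A miRNA-mRNA edge survives iff SCC < -0.3 *and* its
   prediction score exceeds 50 (miRDB-style 0-100 scale). A miRNA-lncRNA
   edge survives iff SCC < -0.3, or SCC < 0 with support from at least one
   lncRNA-interaction database. Finally the ceRNA closure retains only
   miRNAs incident to at least one mRNA *and* one lncRNA edge: a ceRNA
   relation needs a shared miRNA bridging the coding and non-coding side.
   The closure is a `cerna_closure = FALSE` switch away for inspection.
   Correlations are pooled across both stage groups because the edge sign
   and the differential direction must be interpretable jointly; the choice
   is configurable by passing any sample subset to the correlation step.

3. **RNs prioritization.** Nodes are ranked by
   \(RNs = K \cdot R_s / L\), where \(K\) is the degree, \(L\) the node's
   total shortest-path length to the other nodes of its component, and
   \(R_s\) the SVM-RFE score: a linear-kernel SVM (C = 1) is trained on
   log2(x+1), per-gene standardized expression, the feature with the
   smallest squared weight is removed, and the process repeats;
   \(R_s = n - \mathrm{rank} + 1\), so the last-surviving (most
   discriminative) gene gets \(R_s = n\). RNs therefore rewards hubs with
   short paths to the rest of the network *and* discriminative expression.
   Closeness is reported as \(C = (N_c - 1)/L\). This convention is locked
   by the worked-example table shipped with the package
   (`reference_rns_example()`): under it, every printed closeness and RNs
   value inverts to integer \((L, R_s)\) pairs bounded by the network size,
   which the reciprocal-sum convention does not achieve
   (`invert_rns_table()` is the oracle).

4. **Module extraction.** Among the top-k RNs genes, the miRNAs (tagged by
   family) and lncRNAs are kept, and every network mRNA adjacent to at
   least one member of *each* miRNA family joins the module. "Interacts
   with both families" is read as >= 1 edge per family — the weakest reading
   consistent with the rule — and the threshold is exposed
   (`min_edges_per_family`). When the top-k selection covers fewer than two
   families, the selection extends down the RNs ranking to the
   highest-ranked member of each missing family; the rule is rank-driven
   and uses no ground-truth information. Module validation recomputes every
   edge's Spearman correlation on an independent expression set and flags
   "green" edges (SCC < -0.5 and p < 0.05, both strict), plus two-sided
   Wilcoxon rank-sum group comparisons per gene.

5. **Survival model.** The module miRNAs enter a multivariable Cox model
   (Efron ties) on log2(x+1), per-gene z-scored expression; the center and
   scale learned on the training cohort are stored in the model so test
   cohorts are scored on exactly the same scale (the expression scale is
   otherwise a free choice, and an unrecorded one would make the risk
   score irreproducible). The risk score is the linear predictor; the
   cutoff defaults to the *median* training score (a mean cutoff and
   numeric cutoffs are exposed) and patients with score > cutoff are
   high-risk. Kaplan-Meier curves and the two-group log-rank chi-square
   test quantify separation. Association with clinical categories uses a
   median High/Low expression split and Pearson's chi-square — Yates
   continuity correction for 2x2 tables (this is what reproduces the
   reference worked example `[[36,53],[101,67]] -> p = 0.004`), uncorrected
   otherwise; expected cells below 1 trigger a warning recommending an
   exact test.

6. **Progression classifier.** Every non-empty subset of the module panel
   (capped at 14 genes, i.e. at most 16383 subsets) is fitted with a
   linear-kernel SVM (C = 1) on the training cohort, features standardized
   on the training data only, and scored on the held-out cohort by decision
   values. AUC uses the Mann-Whitney identity with ties counting 1/2; the
   ROC polyline is stored and its trapezoidal area equals the Mann-Whitney
   value exactly (both are implemented and compared in the tests). Ranking
   ties break toward smaller subsets, then lexicographic gene lists.

## The synthetic cohort generator

`generate_cohort()` draws negative-binomial counts
(\(\mathrm{var} = \mu + \alpha \mu^2\), one global dispersion
\(\alpha = 0.4\) by default, kept global so the generator stays auditable)
around log-normal per-gene baselines, with per-sample depth factors
(log-normal, sd 0.25) that the normalization stage must remove.

Dependence is injected through a **Gaussian copula**: each gene has a latent
standard normal; counts are `qnbinom(pnorm(z), mu, size)`. Because every
downstream filter is rank-based, quantile mapping preserves the planted
Spearman levels, which direct mean-coupling under NB noise would distort.
Module miRNAs load on a module-wide factor plus a family factor
(`module_cor = 0.35`, `family_cor = 0.35` by default: within-family latent
correlation 0.7, cross-family 0.35 — the two families are positively
co-expressed, as module miRNAs in real tumors are). Each planted target's
latent is \(-\rho \cdot \bar z_{\text{regulators}}\) plus independent noise,
with the Spearman-to-Pearson conversion \(\rho_P = 2\sin(\pi\rho_S/6)\), so
a single-regulator target hits `rho_plant` exactly and multi-regulator
targets have per-pair expectations recorded in the ground truth.

Planted stage effects multiply the NB mean by \(2^{\mathrm{lfc}}\) in the
late group (default: miRNAs -1, targets +1, mirroring down-regulated
miRNA families with up-regulated targets); 5% of background genes get
alternating +/-1 effects so the differential screen has realistic decoys.
Survival is Weibull (shape 1.2, scale 1800 days) with log-hazard equal to
0.35 per standard deviation of each module miRNA's log2 expression, plus
uniform administrative censoring on 1-8 years. Clinical categories are
thresholded latent scores: a category with `strength` s correlates its
latent with the module factor, making chi-square associations plantable;
the default spec plants age-group and grade links and leaves gender null.
Evidence tables emulate prediction databases: planted pairs appear with
probability `evidence_sensitivity` (mRNA scores uniform(51,100)), non-pairs
with probability `1 - evidence_specificity` (scores uniform(0,100)).

The default cohort is 129 early + 128 late samples — the size regime the
method targets — with 120 miRNAs, 1000 mRNAs and 100 lncRNAs: large enough
that normalization, multiplicity adjustment and the correlation screen
behave realistically, small enough that the full pipeline runs in well
under a minute. The generator emulates the *statistical* structure the
analysis assumes (NB marginals, rank dependence, proportional hazards,
category associations); it does not emulate read-level noise, batch
effects, gene-length or GC biases, isoform structure, or correlated decoy
blocks. Passing tests therefore demonstrate that the pipeline recovers the
structures it is designed for at realistic sample sizes — not that it is
robust to every artifact of real sequencing data.

## Numerical choices and degenerate inputs

- **Differential engine.** The default is a negative-binomial Wald test
  with a method-of-moments dispersion pooled within groups, on normalized
  counts, with a +0.5 stabilizer inside fold changes so all-zero genes stay
  finite. It is a deliberately simple, documented default — the screen is a
  candidate filter, and the stage is pluggable (`method = "wilcoxon"` swaps
  in the rank-sum test; constant genes then report p = 1, not an error).
- **Spearman p-values** use the t approximation with average-rank ties;
  |rho| = 1 maps to p = 0. Constant expression vectors are skipped with a
  warning rather than producing NA edges.
- **Normalization** requires at least one gene with positive counts in all
  samples; otherwise it stops and points to `pseudo_reference = TRUE`
  (geometric mean over positive counts).
- **SVM-RFE** is deterministic given the data; constant genes are
  eliminated first; chunked elimination (`step > 1`) assigns within-chunk
  ranks by weight order and is exposed as configuration. Rs ties are
  permitted.
- **Ranking tie-breaks** are deterministic everywhere: RNs ties go to the
  higher degree, then lexicographic id; subset-AUC ties to the smaller
  subset, then lexicographic gene list.
- **Empty networks** (no edge survives the filters) are a status
  (`"empty_network"`), not an exception; the pipeline halts downstream
  stages and keeps partial outputs.
- **Cox fits** drop zero-variance genes with a warning, error when nothing
  fittable remains or the partial likelihood fails to converge, and refuse
  to score cohorts with missing genes (no imputation).
- Betweenness is normalized per component by \((N_c-1)(N_c-2)/2\); it is
  reported for completeness but does not enter RNs, so the convention
  cannot corrupt the prioritization.

## Simulation sizes used by the test suite

Property-style tests run on deliberately scaled-down regimes chosen once:
recovery checks use 40-150 genes per class and ~220 samples over 50 seeds;
Cox coefficient recovery uses n = 1000 over 20 seeds; null calibrations use
1000 replicates; the planted six-gene classifier signal uses a log2 effect
of 0.6 per gene in 10-gene panels (n = 260) — a *combination* signal, since
individually near-perfect markers would make the best subset a two-gene tie
and the multi-gene recovery property vacuous. The seeded split derives its
seed from the pipeline master seed, so whole bundles reproduce byte for
byte (see the manifest written by `run_pipeline(..., outdir = )`).

## Known limitations

- The NB Wald default has no dispersion shrinkage, independent filtering or
  outlier handling; for real cohorts a dedicated differential-expression
  package is the better engine behind the same interface.
- The generator's single global dispersion and factor-structured dependence
  are idealizations; per-gene dispersion is configurable but not default.
- Family assignment of miRNAs is nomenclature knowledge supplied by the
  caller (`family_map`); the pipeline does not infer families from sequence.
- The exhaustive subset search is bounded at 20 genes by design; beyond
  that, proper feature selection is out of scope.
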