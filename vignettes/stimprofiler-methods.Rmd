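---
title: "stimprofiler: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stimprofiler: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimprofiler)
```

# The analysis problem

Lymphocyte populations sorted from peripheral blood (CD4⁺ Th, CD8⁺ CTL,
CD16⁺CD7⁺ NK, CD19⁺ B cells) are profiled by bulk RNA-seq twice: immediately
after sorting ("steady-state") and after 18 h of culture with either
plate-bound anti-CD3 (aCD3, T-cell stimulation) or PBS (control). Donors are
healthy controls (HD) or patients with primary Sjögren's syndrome (pSS) or
systemic lupus erythematosus (SLE), each patient carrying a clinical
disease-activity index (ESSDAI for pSS, SLEDAI for SLE).

The central difficulty is that disease signal at steady-state is weak
relative to donor-to-donor heterogeneity; the stimulation protocol, with its
within-donor PBS control, unmasks it. The pipeline therefore maintains two
analysis layers:

* **Relative expression** (stimulated samples):
  $r_{gd} = \log_2\frac{\mathrm{FPKM}^{aCD3}_{gd} + c}{\mathrm{FPKM}^{PBS}_{gd} + c}$
  per gene $g$ and donor/cell-type pair $d$, which cancels donor effects
  exactly. The pseudocount $c$ defaults to 0.1 FPKM; it bounds the ratio
  when the control is zero. The log2 transform treats up- and
  down-regulation symmetrically (the ratio scale itself is not dictated by
  the protocol, which only says "normalized by").
* **Centralized expression** (steady-state samples, no within-donor
  control): $z_{gs} = (x_{gs} - \mathrm{median}_g(x_{gs}))/\mathrm{SD}_g(x_{gs})$
  per sample $s$, a skew-robust location/scale correction. The SD is the
  sample SD ($n-1$ denominator); the worked boundary example
  $\{1,2,3\}\mapsto\{-1,0,1\}$ fixes that convention. Centralization is a
  per-sample transform, so it can be computed once across all culture
  conditions and subset afterwards.

Downstream statistics are deliberately rank-based or exact — Wilcoxon
rank-sum for differential expression and cytokine activity, hypergeometric
over-representation, Kolmogorov–Smirnov regulatory scores, Fisher exact
occurrence tests, a permutation null for co-expression — matching the
skewed, heavy-tailed distributions the FPKM-derived layers carry.

# Tunable parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `pseudocount` (`relative_expression`) | 0.1 | FPKM; guards zero controls |
| `lo_pct`, `hi_pct` (`filter_genes`) | 45, 99.5 | percentile band of per-gene count totals |
| DEG significance | q ≤ 0.10 | BH FDR; "highly significant" column at q ≤ 0.01 |
| `n_top` (`rank_by_fdr`) | 50 | genes per direction handed to ORA |
| ORA set-size rule (`ora`) | 3–300 | in-universe pathway size; outside → p = 1 exactly |
| KS catalog filter (`filter_sets`) | 3–500 | in-universe set size for regulatory scores |
| `high_cutoff` (`classify_activity`) | 8 (inclusive) | first index value classed High |
| `n_perm` (`gba_permutation_test`) | 10,000 | permutation draws per interferon gene |
| `top_fraction` (`driver_genes`) | 0.10 | fraction of set genes kept as drivers |
| `max_size` (`select_clusters`) | 500 | exclusive ceiling; 499 retained, 500 dropped |
| `ligand_top_fraction` (`detect_interactions`) | 0.10 | of the sender's up-regulated genes |
| `receptor_min_fpkm` (`detect_interactions`) | 1 | FPKM; "expressed" threshold for receptors |
| `k`, `n_init` (`kmeans_genes`) | config, 50 | clusters; k-means++ restarts |

Conventions worth spelling out:

* **Percentile filter.** Percentiles are linear interpolation of the
  empirical CDF (R `quantile` type 4) with inclusive bounds: for totals
  1..100 the 45–99.5 band retains totals 45..99 (55 genes). Type-7
  interpolation would drop the boundary gene. The filter is applied
  globally, not per batch.
* **Activity classes.** Low is 1–3, Moderate 4–7, High ≥ 8; a score of 0 is
  classed Low and flagged (the clinical banding starts at 1). The
  Moderate/High boundary has two circulating conventions (4–7/≥8 and
  4–8/>8); the first is implemented and `high_cutoff` exposes the boundary.
* **ORA size rule.** The "input gene set" of the p = 1 rule is the pathway
  set after reduction to the expressed universe, not the query — the query
  is fixed at 50 by construction, so the rule is only meaningful for
  pathway sets. Only over-representation (upper tail) is computed.
* **Wilcoxon.** Exact null when both groups have ≤ 25 samples and the gene
  has no cross-group ties; otherwise normal approximation with continuity
  and tie correction. Fully tied genes get p = 1 (no evidence). n < 3 per
  group is refused.
* **KS regulatory score.** $D$ is signed: positive when the set's CDF lies
  below the background's at the maximizing threshold (set stochastically
  larger). Both $D$ and $|D|$ are exported. The one-sided p-value uses the
  asymptotic bound $\exp(-2D^2 mn/(m+n))$, which is anti-conservative for
  very small sets; the catalog filter (≥ 3, in practice ≥ 10s of genes)
  keeps it serviceable, and the statistic itself — not the p — carries the
  trajectory analyses.
* **Per-stratum summarization.** Regulatory scores are computed on per-gene
  mean centralized expression across a stratum's samples (group × cell type
  × activity class); a "regulatory level per condition" reading.

# Guilt-by-association co-expression

For each interferon-response gene $g$ and condition $c$ (cell type × donor
group × culture condition), every other gene $x$ gets the scale-normalized
Euclidean distance
$d_c(g,x) = \lVert z_g - z_x \rVert_2 / \sqrt{n_c}$
over the condition's samples. The null contrasts a candidate's distance in
one condition against the pooled distances of all genes across all
conditions for the same interferon gene: $p = (1 + \#\{\text{draws} \le d\})
/ (1 + n_{perm})$ with $n_{perm}$ draws with replacement, BH-adjusted within
(condition, interferon gene), significant at q ≤ 0.10.

Two normalizations make the pooled comparison valid, and both were forced by
measurement rather than taste:

1. $\sqrt{n_c}$ puts strata of different sizes on one scale.
2. Each condition's distances are additionally divided by their
   per-condition median (`scale_normalize = TRUE`). Stimulated samples
   carry inflated per-sample SDs (the stimulation program lifts the FPKM
   high tail), which compresses every centralized distance in aCD3 strata;
   without the median step those strata flood the pooled low tail and the
   test loses both calibration and power (measured sensitivity for planted
   co-expression: 0). Raw distances are still exported.

Conditions are built by `gba_conditions()` as cell type × group × culture
condition — balanced strata of ~16–25 samples. Activity-class resolution is
deliberately not offered here: 4-sample strata contribute a heavy low tail
of noise distances to the pool. Activity trajectories belong to the
regulatory score, not the permutation test.

By construction this test detects **condition-specific** closeness: a gene
pair that is equally close in every condition sits in its own null and is
undetectable. That is a property of the method, not a defect of the
implementation, and it dictates how the simulator plants co-expression (one
scoped stratum, below).

Distances are computed per interferon gene (the protocol speaks of distance
"to a particular IFN response gene"); `centroid = TRUE` offers the
set-centroid alternative.

# Gene modules

Genes are clustered by k-means on their mean expression per stratum (cell
type × donor group), the column blocks of the module heatmaps. Feature rows
are standardized (mean 0, SD 1 per gene) before clustering: modules are
defined by profile *shape*, and without row scaling the gene's absolute
expression level (spanning orders of magnitude) dominates the Euclidean
metric and k-means recovers expression strata instead of co-regulation
(measured ARI ≈ 0 against planted modules). Seeding is k-means++ with the
best of `n_init = 50` restarts by total within-cluster SS; results are
deterministic given the seed, and cluster labels are reported only through
gene membership. k itself is a configuration choice (the heatmaps suggest
~8–10); a silhouette sweep is easy to run over `kmeans_genes()` results.

# Cell-cell communication

A donor contributes only if all four sorted populations passed QC. Senders
are T cells (Th, CTL); every population can receive. An interaction
(ligand L → receptor R) is detected in a donor iff L ranks within the top
10 % of the *up-regulated* (positive relative-expression) genes of the
sender's stimulated sample — reconciling "top 10 % of the genes" with
"up-regulated genes after TCR stimulation" — and R exceeds
`receptor_min_fpkm` (default 1 FPKM) in the receiver's stimulated sample.
The rank cutoff is `floor(0.10 · n_up)`: rank 10 of 100 is in, rank 11 out.
Detection is monotone in the top fraction. Group differences per pair use
the two-sided Fisher exact test on donor-level detection; the
disease-vs-healthy comparison pools pSS and SLE as stated by the protocol,
and per-disease contrasts are available the same way. Hosted
cytokine-activity models are out of scope; `compare_activity()` consumes
any cytokine × sample Z-score matrix, and `signature_activity()` ships a
plain mean-Z projection clearly labelled as a synthetic-testing stand-in.

# The synthetic world

`simulate_dataset()` generates one sample per donor × cell type × condition
(24 HD / 23 pSS / 25 SLE donors by default), then removes a seed-driven
`qc_dropout` fraction of whole samples (default 5 %), emulating QC
attrition without modelling its biology. Expression is log-normal on the
FPKM scale:

$\log \mathrm{FPKM}_{gs} = \mu_g + \delta_{d(s)} + \text{planted effects}
+ \varepsilon_{gs}, \qquad \varepsilon_{gs} \sim N(0, \sigma^2)$

with donor offsets $\delta_d \sim N(0, 0.25^2)$ and noise
$\sigma = 0.3$ (`dispersion`). Background baselines are
$\mu_g \sim N(\log 5, 1.2^2)$; planted-signal genes draw
$\mu_g = \log 3 + |N(0, 0.8^2)|$, i.e. robustly expressed — every analysis
operates on the expressed-gene subset, and truth planted on near-zero-FPKM
genes is unmeasurable by any method (at FPKM ~1 counting noise destroys a
planted correlation of 0.9). Planted structure, all blocks disjoint:

* a stimulation program (150 genes, ±2 log2) in every aCD3 sample;
* per-disease differential genes (100 per contrast, ±1.5 log2) added on top
  of the stimulation response in the disease group's aCD3 samples — the
  two-step contrast design;
* an interferon set (50 genes) shifted in steady-state patient samples by
  `activity_effect` per the donor's class (default Low 0.5, Moderate 1.0,
  High 2.0 log2 — the monotone trajectory; a bell-shaped vector plants the
  Moderate-peaked variant);
* co-expressed genes (20) sharing the first interferon gene's noise at
  correlation 0.9 *within one scoped stratum* (default steady-state SLE Th),
  because the permutation test can only see condition-specific closeness;
* three modules (80/60/40 genes) with orthogonal one-hot cell-type profiles
  at ±`module_sep`·σ (default 3 SDs) — deterministic profiles, since random
  ones can collide and make recovery a matter of luck;
* marker sets (30 genes per population, +2 log2 in their own cell type);
* ligand–receptor events switched on per donor (defaults: 0.9 disease /
  0.3 HD), the ligand jumping +4 log2 in the sender's aCD3 sample of active
  donors, receptors constitutively high.

Counts are Poisson draws of FPKM × length_kb × depth/10⁶ with per-gene
lengths (log-normal around 1.5 kb) and per-sample depths (log-normal around
5 × 10⁶). The latent FPKM matrix is first normalized per sample so that
$\sum_g \mathrm{FPKM}_{gs} \cdot \mathrm{len}_{kb,g} = 10^6$ — the identity
that makes FPKM exactly invertible from counts and gives it its real
compositional behavior (the stimulation program's mass deflates every other
gene's FPKM, which is why null genes show a small negative shift on the
relative layer). FPKM magnitudes of ~100–300 for a typical gene are correct
for a reduced 2,000-gene universe, FPKM being per-million of the measured
transcriptome. Patient activity scores are uniform integers 0–14 so all
three classes are populated; HD donors carry none. The pre-QC sample count
of the real study is unknown (only the post-QC figure is reported), so the
attrition fraction is a free parameter.

**What the simulator does not emulate** — and hence what a green test does
not establish: batch effects, library-size artefacts beyond Poisson
sampling, gene–gene correlation outside the planted blocks, realistic gene
identifiers or annotation, cell-type composition shifts, read-level
properties. Recovery results certify the statistics against their stated
nulls and planted effects, not robustness to unmodelled structure.

# Numerical choices and degenerate inputs

* BH adjustment is computed within each result family (per contrast, per
  (condition, interferon gene), per pair table, per cytokine table) and is
  invariant to input row order; ties in FDR ranking break by raw p, then
  |mean difference| descending, then gene id, so outputs are reproducible
  under row permutation.
* `fpkm()` refuses zero-depth samples and missing/non-positive gene
  lengths; `centralize()` refuses constant samples; `deg_test()` refuses
  groups under 3 samples; `gba_permutation_test()` refuses n_perm < 100;
  oversized k is an error in `kmeans_genes()`.
* PCA outlier flags use leave-one-out stratum mean/SD: with the plain SD a
  single gross outlier inflates the denominator enough to hide itself in
  strata under ~17 samples (the maximum attainable z-score is
  $(n-1)/\sqrt{n}$). Strata under 3 samples are never flagged, and
  `k_sd = Inf` flags nothing.
* The permutation p-value carries the +1 finite-sample correction, so its
  floor is $1/(n_{perm}+1)$ and null calibration is slightly conservative.
* Seeds determine everything: the simulator consumes `config$seed`;
  permutation draws and k-means restarts take explicit `seed` arguments.

# Known limitations

* The KS one-sided p is asymptotic; for sets near the minimum size its
  calibration is rough (the D statistic is exact).
* The signature QC replaces a published QC package with a one-sided
  rank-sum enrichment of the same spirit; concordance with that package on
  real data is untested here.
* `ora()` computes over-representation only; depletion is out of scope.
* The communication analysis handles single ligand/receptor gene pairs; no
  multi-subunit complexes.
* FPKM inherits its compositional artefacts by design; no TMM-style
  correction is applied, matching the protocol being reproduced.
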