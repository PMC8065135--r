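---
title: "Methods: integrative methylome-transcriptome analysis of paired muscle-cell cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative methylome-transcriptome analysis of paired muscle-cell cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The study design epimyo models

`epimyo` implements the statistical core of an integrative epigenomic study of
human muscle stem cells: primary myoblasts isolated from two donor groups —
normal glucose tolerance (NGT) and type 2 diabetes (T2D), around 14 subjects
per group, cases selected to match controls on sex, age and BMI — are assayed
twice, once as proliferating myoblasts and once after differentiation into
myotubes. Each subject therefore contributes a *paired* two-state design on
two platforms: a log2-normalized expression array (genes x samples) and a
450K-style methylation array whose beta values are fractions in $[0,1]$
(printed tables use percent).

The analysis has three strands:

1. **Between-group differential expression.** Per gene and per state, OLS of
   expression on `group + age + BMI + sex` (sex coded female = 0, male = 1);
   the group coefficient is in log2 units (fold change $2^{\hat\beta}$), its
   t statistic has $n - \mathrm{rank}$ residual df, and Benjamini-Hochberg
   q-values are computed across all tested genes ($q < 0.05$ throughout).
   Genes significant in both states are partitioned by direction concordance.
2. **Methylation-expression integration.** CpGs annotated to the
   differentially expressed genes are screened for correlation between beta
   and expression across the subjects of one state (both groups pooled). The
   screen is deliberately *nominal* ($p < 0.05$, column `p_nominal`, no
   multiplicity correction) because it is a filter, not an inference; the
   genomic context of the negatively correlated CpGs is then compared with
   all screened CpGs by goodness-of-fit chi-squared over gene-region
   (TSS200/TSS1500/5'UTR/1stExon/Body/3'UTR) and island-context
   (island/shore/shelf/open sea) classes. Candidate genes must be
   significantly *down* in **both** states and carry at least one nominally
   significant negative CpG correlation; literature triage of candidates is
   human judgment and is not automated.
3. **Within-group differentiation dynamics.** Per CpG and per group, a
   subject-paired Wilcoxon signed-rank test of myotube vs myoblast betas,
   with BH correction *within* the group across all probes. The groups'
   significant sets are intersected by direction, and **opposite-direction
   sites** — significant in both groups with strictly opposite signed
   differences — are reported in a printed-table shape (percent means ± SD
   to one decimal, signed myotube-minus-myoblast difference, p, q).

Enrichment layers: preranked GSEA on the t-ranked gene list, keyword-query
frequency enrichment over GO-style term annotations, and promoter motif
enrichment by PWM scanning 1 kb upstream windows.

# Statistical primitives and numerical choices

All primitives live in `stats_core` and are checked against independent
oracles in the test suite (brute-force enumeration, closed forms, textbook
hand calculations):

* **BH step-up** (`bh_fdr`): $q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$ clipped
  at 1, input order preserved. Checked exactly against a loop-based
  tail-cummin oracle on 1,000 random vectors.
* **Wilcoxon signed-rank** (`wilcoxon_signed_rank`): zero differences are
  dropped (Wilcoxon's original treatment), ties get midranks. The exact
  two-sided p comes from a dynamic-programming convolution of the
  signed-rank-sum distribution run on doubled ranks (so midranks stay
  integral); `auto` mode uses it for $n \le 25$ untied cases — i.e. always,
  at this cohort size — and otherwise a normal approximation with
  tie-corrected variance and 0.5 continuity correction. The untied exact
  distribution depends only on $n$ and is cached, which keeps the 10,000-probe
  per-group scan around a second. Exact p equals full $2^n$ enumeration for
  all $n \le 10$ in the tests.
* **Chi-squared** (`chi2_test`): no Yates correction (counts here are in the
  hundreds); an expected cell below 1 is a recorded warning, not an error.
* **Correlation** (`correlation_test`): the method is a package-level choice
  because the original screen does not state one; the default is Spearman
  (robust to array-intensity outliers; also exactly $-1$ for any monotone
  decreasing coupling), Pearson selectable, and every output names the
  method. p-values use $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df.
* **PCA** (`pca_top_components`): features centered across samples, SVD in
  sample space; explained-variance fractions sum to 1.
* **Two-sided p everywhere**, with the single exception of the motif z test
  (one-sided by construction: enrichment means higher best scores).

**Preranked GSEA** (`gsea_preranked`): hit steps $|t|^w$ normalized by the
set total (default $w = 1$, classic weighted; $w = 0$ gives the
Kolmogorov-Smirnov form), miss steps $1/(N - N_h)$, ES = maximum deviation of
the running sum, computed in $O(|S|)$ from the sorted hit positions. Because
phenotype permutation is unavailable in preranked mode, the null is gene-set
randomization: `n_perm` random same-size draws (seeded; nulls are shared
across sets of equal size). NES divides ES by the mean same-sign null |ES|,
the nominal p is the same-sign null tail fraction, and FDR follows the
pooled-NES procedure per sign. Set sizes are restricted to 1–500 members
after intersection with the ranked universe.

**Motif enrichment** (`motif_enrichment`): counts plus a
background-proportional pseudocount (0.8) give log2-odds columns; each
promoter's score is the best window over all offsets *and both strands* (the
reverse strand via the reverse-complemented matrix). The headline statistic
is the z of the foreground mean best score against the background
distribution, $z = (\bar s_{fg} - \bar s_{bg})/(\mathrm{sd}_{bg}/\sqrt{n_{fg}})$,
one-sided. Presence fractions at relative score $\ge 0.8$ (the conventional
PWM cutoff; relative score rescales log-odds to $[0,1]$ between the motif's
attainable minimum and maximum) are reported descriptively — they are
threshold-dependent and are *not* claimed to reproduce any particular
published fraction.

**"Highest occurrence" probe collapse** is ambiguous in array pipelines; the
default `highest_mean` keeps the probe with the highest mean intensity, and
`most_detected` (fewest missing values, mean as tie-break) implements the
other reading.

# The synthetic cohort: what it emulates, and what a green test establishes

`simulate_cohort()` generates the full data structure with planted ground
truth. Its defaults *are* the stated world; they were fixed once and the
acceptance thresholds were never adjusted to fit them.

| parameter | default | rationale |
|---|---|---|
| `n_per_group` | 14 | cohort size of the emulated design |
| `n_genes`, `n_probes` | 2,000 / 10,000 | 450K methylome and array transcriptome scaled down ~45x |
| `frac_de_genes`, `de_effect_log2`, `expr_sd` | 0.05, 1.0, 0.5 | a 2-fold effect at array-typical residual noise |
| `frac_de_both_states` | 0.5 | half the DE genes keep their effect after differentiation |
| `coupling_frac`, `coupling_strength` | 0.6, 0.8 | fraction of DE genes with a negatively coupled TSS-proximal CpG, and the expected correlation magnitude |
| `dynamics_frac_ngt`, `dynamics_ratio_t2d` | 0.05, 2.0 | controls remodel 5% of probes during differentiation; cases twice as many |
| `n_opposite_sites` | 39 | opposite-direction sites planted with detectable (8–15 pp) shifts, mixed directions in equal halves |
| `motif_frac_fg` / `motif_frac_bg` | 0.9 / 0.05 | planted promoter-motif presence in down-truth vs other genes |
| age, BMI | N(56, 7) yr, N(25.7, 3.1) kg/m² | pooled covariate distributions; sex balanced 7/7 |

Generator design points worth knowing:

* **Matched covariates.** Cases in the emulated study were *selected* to
  match controls on sex, age and BMI. Age and BMI are therefore drawn
  pair-matched (a shared base per subject pair plus a 30% within-pair
  jitter): marginals keep the configured mean/SD while chance group
  imbalance stays far below independent sampling. With independent draws,
  2-sigma age imbalances inflate the adjusted standard errors enough to cost
  about one planted candidate per cohort.
* **Logit-normal betas.** Baselines are drawn on the logit scale around two
  modes (hypo ≈ 0.1, hyper ≈ 0.9) and inverse-logit transformed, which keeps
  betas in $[0,1]$ by construction, yields the bimodal methylome real arrays
  show, and makes coupling injection additive on the logit scale.
* **Couplings** are planted TSS-biased (TSS200/TSS1500-heavy) so the
  genomic-context enrichment has a true signal; a coupled probe's beta is a
  monotone decreasing function of its gene's realized expression plus noise
  calibrated so the expected correlation magnitude equals
  `coupling_strength` (at strength 1 and zero noise the sample Spearman
  correlation is exactly −1).
* **Both-state allocation.** `frac_de_both_states` governs the fraction of
  DE genes *overall* whose effect persists into myotubes, split evenly over
  directions by default. The optional `n_candidate_genes` pins the
  down-and-both stratum to exactly that many genes (all coupled — the
  candidate truth) and moves the remainder of the both-state quota to
  up-regulated genes, so the myotube signal density, and hence the BH
  cutoff, stays as configured. Without this, the candidate-recovery check
  would conflate detector quality with an arbitrarily harsher multiplicity
  burden.
* **The planted gene set** draws its 70% DE membership from one direction
  (up); a set mixing up- and down-regulated genes has hits at both ends of
  the ranking and its running-sum ES self-cancels — a property of GSEA, not
  a detector defect.
* **Dynamics** probes get mid-range baselines (0.25–0.65) and paired
  myotube = myoblast + shift structure; non-dynamic probes get independent
  state draws, so their paired differences are symmetric about zero under
  the null.

What the generator does **not** emulate: probe chemistry (type I/II designs,
detection p-values), batch structure, genetic variation between subjects,
correlated probe blocks within CpG islands, or realistic annotation ontology.
A green simulation test therefore establishes that the *detectors* behave as
specified on data with the assumed statistical structure — it does not
certify performance on real arrays, whose noise is less well-behaved.

Published counts from real cohorts of this design — e.g. hundreds of DE
genes in myoblasts, dozens in myotubes, a few hundred genes with nominal
methylation-expression correlations, the genome-wide dynamic-site totals, or
clamp-correlation values — depend on the deposited arrays and are **not**
desk-reproducible here; the test suite substitutes property-based criteria
(oracle equivalence, null calibration, parameter recovery on the synthetic
cohort) at the tolerances stated in their tests.

# Degenerate inputs and tie-breaks

* All-zero paired differences: p = 1 with a warning (probe kept).
* Zero-variance vectors in the correlation screen: record skipped, tallied.
* Constant genes in DE: skipped with a warning, never NaN.
* Gene ranking ties: broken alphabetically by symbol, so ranking is total
  and deterministic.
* Rank-deficient designs: error naming the collinear columns, never a
  silent drop.
* Betas are validated to $[0,1] \pm 10^{-9}$ at the I/O boundary and stored
  as fractions; percent appears only in report writers (rounded to one
  decimal, matching printed tables — the signed difference is computed
  before rounding, so the printed difference can differ from the difference
  of printed means by up to 0.1).

# Reproducibility

Every stochastic stage (simulation, GSEA permutations, pipeline) flows from
one integer seed recorded in every output header and in
`run_manifest.json`. `run_full_pipeline()` on the default configuration is a
deterministic function of the seed and finishes in well under a minute on a
single CPU; the 15-minute budget in the acceptance suite is a hard ceiling,
not a typical runtime.

```{r example}
library(epimyo)
manifest <- run_full_pipeline(simulation_config(seed = 1),
                              out_dir = "epimyo_out")
print(manifest)
```
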