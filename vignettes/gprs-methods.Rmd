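---
title: "Genetic-distance clumping for polygenic risk scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic-distance clumping for polygenic risk scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clumping-and-thresholding (C+T) polygenic risk scores prune GWAS summary
statistics to an approximately independent SNP set (clumping), keep the SNPs
passing a p-value threshold, and score individuals by the additive sum
$S_i = \sum_j \beta_j G_{ij}$ of risk-allele dosages weighted by the GWAS
effect sizes. The clumping step conventionally uses a *physical* window: a
candidate SNP absorbs its neighbours within some fixed distance (250 kb is
the common default) whose squared dosage correlation with it exceeds a
threshold.

For strongly HLA-driven diseases — the endocrine autoimmune disorders are
the motivating case — this convention fails structurally. The HLA region
spans roughly 8 Mb of exceptionally strong, long-range linkage
disequilibrium: SNPs megabases apart can be tightly correlated. A 250 kb
window cannot absorb them, so physical-window clumping retains stacks of
mutually redundant "index" SNPs across the region. Their marginal effects
all tag the same underlying signals, so the resulting score over-weights
the region and accumulates correlated estimation noise.

`gprs` implements the alternative this package is organized around:
clumping windows measured in **genetic distance** (centimorgans). Because
recombination is suppressed across HLA, the whole ~8 Mb region spans only a
few cM; a 3 cM window therefore covers it entirely, and absorption is
decided by LD alone rather than by an arbitrary physical horizon. Outside
such regions, where 1 cM roughly equals 1 Mb, behaviour is close to
conventional clumping. The package also provides the physical-window
comparator, HLA-exclusion mode, AUC-driven threshold selection,
pathway-restricted scores, and the ordinal score–metabolite association
analysis, so the full analysis can be run and compared end to end.

## The pipeline, stage by stage

### Genetic maps

`load_genetic_map()` reads chr/bp/cM knot tables (HapMap-style rate columns
are detected and ignored) and `interpolate_cm()` converts physical
positions by piecewise-linear interpolation between knots. Positions
outside the mapped range take the nearest knot's cM (clamped, constant
extrapolation). The map sources themselves do not dictate an interpolation
or end rule; we chose linearity for transparency and clamping because
linear extrapolation can produce negative or runaway cM at telomeres.
Within a chromosome the loader enforces strictly increasing positions and
non-decreasing cM, rejecting violating rows with a report rather than
silently reordering genetic distance.

### Summary-statistic QC and harmonization

`qc_sumstats()` applies, in order: structural validity (single ACGT
alleles, $p \in (0,1]$, positive standard errors and sample sizes),
strand-ambiguous pair removal (A/T, C/G), duplicate-id removal (all
copies), a reference-panel MAF floor (default 0.01), an association
chi-squared ceiling $(\beta/\mathrm{se})^2 \le 80$, and a sample-size
outlier rule (mean ± 3 sd). The chi-squared and sample-size cutoffs are
standard practice defaults — the literature this follows does not fix
numeric values — and both are configurable. `harmonize()` joins on SNP id
(warning when chr/bp disagree between sources), keeps the weight when the
effect allele matches the panel's counted allele, negates it when the
allele pair is swapped, and drops anything else. Complement matches that
would require assuming a strand flip are *not* rescued: after ambiguous
pairs are removed this situation is rare and unresolvable without strand
information, so the conservative choice is to treat it as a mismatch.

### Genotype QC

`filter_variants()` applies the per-variant filters (call rate ≥ 0.98,
missing rate ≤ 0.10, MAF ≥ 0.01, Hardy–Weinberg exact p ≥ 0.001). Call
rate and missing rate are kept as two separate rules even though the first
implies the second at these defaults, mirroring how such filter lists are
conventionally specified. The HWE exact test (`hwe_exact_test()`) computes
the two-sided conditional-on-allele-counts p-value from the closed-form
log-multinomial expression, and is evaluated in controls only when
phenotypes are available, since true risk loci can deviate from HWE in
cases. Relatedness is estimated by the robust pairwise moment estimator
$\hat\varphi = (N_{het,het} - 2N_{opp.hom}) / (N_{het(i)} + N_{het(j)})$
and `prune_related()` greedily removes the sample with the most pairs
above 0.125 until none remain. Missing dosages are imputed per variant by
the modal genotype (mean dosage as an option). `compute_pcs()` derives the
top principal components from the column-standardized dosage matrix after
thinning to at most one variant per 0.5 cM to soften local-LD dominance;
component signs are fixed by making the largest-magnitude loading positive
so results are reproducible.

### Clumping

`clump()` is the greedy algorithm: candidates sorted by ascending p (ties:
position, then id); the best unassigned SNP becomes an index SNP and
absorbs every unassigned same-chromosome SNP with $|\Delta\,\mathrm{cM}|
\le 3$ (genetic mode) or $|\Delta\,\mathrm{bp}| \le 250$ kb (physical
mode) **and** $r^2 \ge 0.1$. Both conditions are required — a SNP beyond
the window is never absorbed regardless of LD — and windows are half-widths
around the index SNP, the standard clumping semantics. Chromosome
boundaries are always respected. The $r^2$ default of 0.1 is the common
C+T choice and is exposed in `clump_config()`; values above 1 are accepted
as an explicit "no absorption" setting. LD is computed on the fly against
the reference panel within each window, so no global LD matrix is formed.
HLA exclusion mode drops the configured region
(default chr6:25–34 Mb, covering the ~8 Mb extended region) before
clumping. Deterministic tie-breaking makes results identical across runs
and platforms.

### Threshold selection and scoring

`select_threshold()` walks the grid $\{10^{-8}, 5\times10^{-8}, 10^{-5},
5\times10^{-5}, 0.001, 0.01, 0.05, 0.1, 0.2, 0.5\}$. For each threshold it
builds the model from index SNPs with $p \le t$, scores the cohort, adjusts
the score, and evaluates AUC on the held-out 20% of a phenotype-stratified
8:2 split. Thresholds admitting no SNPs are skipped rather than failing,
which keeps the grid usable on small panels where nothing reaches
genome-wide significance. The chosen threshold maximizes test AUC with
ties broken toward the more stringent threshold (parsimony). Note the
reported AUC is the quantity the threshold was selected on; with a single
split this is the design being emulated, and its optimism at the null is
visible in the package's own null-simulation checks.

Adjustment is residualization: the raw score is regressed on the top PCs
plus a sex indicator and replaced by the residual, which keeps the AUC a
pure function of the genetic score rather than of a covariate-assisted
classifier. A logistic evaluator (score + covariates as predictors, fit on
the training split) is available as an alternative where a
covariate-inclusive classifier is wanted; both are recorded in the output
provenance. Scoring reconciles allele orientation exactly as harmonization
does — a swapped panel orientation negates the weight. The per-SNP
constant that a dosage-complement rewrite would add is deliberately
dropped: it shifts every sample equally, and omitting it makes scores
exactly invariant to allele-swapped, sign-flipped model copies.

### Pathway scores and association

`pathway_subset()` restricts a model to SNPs inside BED intervals (0-based
half-open; a 1-based position bp is inside $[start, end)$ iff
$start < bp \le end$). The association stage bins adjusted scores within
each sex at the 10th/40th/60th/90th percentile ranks into five ordered
categories (bottom 10%, low 30%, middle 20%, high 30%, top 10%) — the
binning is rank-based, hence exactly (10/30/20/30/10)% for n divisible by
10 with distinct scores, and invariant to monotone transformations.
`kendall_tau_b()` then tests each (metabolite, sex) pair. Tau-b rather
than tau-a is forced by the design: the five-level score guarantees massive
ties, which tau-b's denominator corrects for. The p-value uses the normal
approximation with the tie-corrected null variance (the same statistic
`cor.test` uses in the presence of ties, which the test suite confirms to
machine precision), and the 95% CI is built from the corresponding
asymptotic standard error. That SE is a null-variance approximation;
for the moderate correlations this analysis targets it is serviceable, but
the CI should not be over-interpreted at large $|\tau_b|$. Benjamini–
Hochberg q-values are appended per sex as an annotation, never as a filter.
Metabolite missingness is completed beforehand by `knn_impute()`: each
missing cell takes the mean of its metabolite over the k = 10 nearest
samples, with Euclidean distances on standardized columns averaged over the
jointly observed ones (so samples with different missingness patterns are
comparable). k = 10 is a conventional choice; the method, not the k, is
what the analysis specifies.

Finally `proportion_explained()` summarizes how much of the full-score
correlation structure a pathway score reproduces: the no-intercept
least-squares slope of pathway $\tau_b$ on full $\tau_b$ across aligned
(metabolite, sex) pairs, with a percentile bootstrap CI over pairs. This
single-slope-per-disease reading is one consistent interpretation of a
per-disease "proportion of correlation explained" with a CI spanning
metabolites; it is flagged as such, and slopes above 1 are possible and
preserved.

## The synthetic study generator

Nothing in the package requires restricted cohort data: `simulate_study()`
generates every input the pipeline consumes, and its defaults define the
conditions under which the package validates itself.

* **Maps.** 3 chromosomes at 1 cM/Mb, with an 8 Mb block on chromosome 6
  (25–33 Mb) at 0.125 cM/Mb, so the block spans 1 cM — wide open to a 3 cM
  window, far beyond a 250 kb one.
* **Genotypes.** A latent Gaussian copula per chromosome with correlation
  $\exp(-|\Delta\,\mathrm{cM}|/0.3)$; two latent draws per sample are
  thresholded at each SNP's MAF (drawn uniformly on [0.05, 0.5]), giving
  Hardy–Weinberg genotypes whose LD decays with *genetic* distance. Inside
  the block this stretches strong LD across megabases ($r^2 \ge 0.1$ out to
  ~2.5 Mb) while leaving several mutually weakly-correlated sub-signals —
  deliberately so: HLA-inclusive fitted models are observed to retain a
  substantial fraction of their SNPs inside HLA, which a single-clique
  block could not reproduce. A background correlation floor of 0.3
  (below the absorption threshold on the genotype scale) adds the
  region-wide elevated LD. The floored matrix is eigenvalue-clipped back to
  a valid correlation matrix before the Cholesky factorization.
* **Phenotype.** Liability threshold: 30 causal SNPs, 60% inside the block
  (autoimmune GWAS concentrate association there), standard-normal effects
  on standardized dosages, scaled to $h^2 = 0.5$ on the liability scale —
  strong but defensible for highly heritable autoimmune disease — with
  prevalence 0.15 as in a case-enriched case-control cohort. Discovery and
  target cohorts (2,000 each by default) are independent draws, so
  discovery-to-target overfitting is excluded by construction.
* **Summary statistics.** Vectorized per-SNP linear association on the 0/1
  phenotype (a per-SNP logistic GLM is available); for threshold-and-rank
  purposes the two orderings agree. About 30% of records are emitted with
  flipped allele orientation and negated beta, so every downstream run
  exercises harmonization; this is provably weight-neutral.
* **Metabolites.** Each metabolite is $d_{sex}\,\gamma\,\tilde S_i +
  \varepsilon$, with $\tilde S$ the standardized true genetic score, unit
  noise, per-sex directions $d \in \{-1, 0, +1\}$ and effect sizes around
  0.2–0.3 — one trait with opposite signs by sex (the HDL-like pattern),
  several shared-direction traits, one null trait — plus 5%
  missing-completely-at-random cells to exercise KNN completion.

What the generator does **not** emulate: real human LD maps and allele
frequency spectra, ancestry structure and admixture, sex chromosomes,
imputation error, genotyping batch effects, or case-control sampling bias.
Passing the package's simulation checks therefore demonstrates the
*algorithmic* claims — that genetic-distance windows handle long-range-LD
architecture better than physical ones, and that every statistical
component computes what it says — not that any particular real-data AUC
would be reproduced.

## Numerical and degenerate-input conventions

* LD $r^2$ of a zero-variance variant is 0 by definition; such variants
  never absorb or get absorbed on LD grounds.
* Constant covariate columns are dropped before score adjustment (an
  intercept-only regression then returns centered scores); remaining rank
  deficiency is an error.
* All-identical scores within a sex make percentile bins undefined and
  raise an error rather than producing an arbitrary assignment.
* Monomorphic SNPs in the simulated GWAS are emitted with beta 0, p 1.
* Every random step (splits, simulations, bootstrap) flows through one
  seed argument; fixed seeds give bit-identical results, which the
  reproducibility tests assert at the level of file digests.

## Problem sizes used in validation

The flagship simulation contrast runs the default configuration (2,000
discovery + 2,000 target samples, 3 × 500 SNPs) over five seeds and asks
that genetic-mode 3 cM clumping match or beat the physical 250 kb
comparator on held-out AUC in at least four, plus a null run ($h^2 = 0$)
where every method must stay near AUC 0.5. Exact oracles (clumping,
Kendall, AUC, Hardy–Weinberg) run at their natural combinatorial sizes
(200-SNP panels, n ≤ 300 pair enumeration, all genotype tables with total
≤ 200). These sizes were chosen to make the full validation suite a
minutes-scale exercise on a laptop while keeping every stochastic
assertion comfortably powered.

## Known limitations

* The package implements one-split threshold selection faithfully; it does
  not provide cross-validation, and the reported test AUC is the selection
  criterion itself (see above).
* Shrinkage-based weighting schemes (continuous-shrinkage priors, penalized
  regression on the full SNP set) are out of scope; the comparison table
  accepts externally computed scores instead.
* Kinship pruning uses dense matrix algebra, comfortable to a few thousand
  samples; biobank-scale cohorts would need a blocked implementation.
* The tau-b confidence interval uses the null-variance SE (see above).
* X-chromosome handling, genotype calling, phasing and reference-panel
  imputation are out of scope; dosage imputation is deliberately simple
  and per-variant.
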