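# gprs — genetic-distance clumping and thresholding for polygenic risk scores

`gprs` builds clumping-and-thresholding (C+T) polygenic risk scores whose
LD clumping window is measured in **genetic distance (centimorgans)**
instead of physical distance (kilobases). The additive score is the usual

&nbsp;&nbsp;&nbsp;&nbsp;*S*<sub>i</sub> = Σ<sub>j</sub> β<sub>j</sub> · G<sub>ij</sub>,

with GWAS effect sizes β<sub>j</sub> as weights over an approximately
independent SNP set selected by greedy clumping: candidates ordered by
ascending p-value, each index SNP absorbing same-chromosome neighbours
with |ΔcM| ≤ 3 **and** r² ≥ 0.1. The point of the cM window is long-range
LD regions such as HLA: ~8 Mb of physical span but only a few cM of
genetic distance, so a 3 cM window covers the whole region where a 250 kb
window leaves stacks of mutually redundant index SNPs that over-weight the
region and add correlated noise. That matters for any strongly HLA-driven
phenotype — autoimmune endocrine disease is the motivating case — and the
package is aimed at statistical geneticists who want the genetic-distance
variant, the conventional physical-window comparator, and the downstream
score-to-biomarker association analysis in one reproducible toolchain.

The package covers the full analysis path:

* **genetic maps** — bp → cM piecewise-linear interpolation with clamped ends;
* **summary-statistic QC/harmonization** — ambiguous/duplicate/MAF/outlier
  filters, allele orientation reconciliation with sign flips;
* **genotype QC** — call-rate/missingness/MAF filters, Hardy–Weinberg exact
  test, robust kinship pruning, dosage imputation, genetic PCs
  (PLINK bed/bim/fam I/O included);
* **clumping** — genetic or physical windows, optional HLA exclusion,
  per-gene SNP enrichment;
* **PRS** — model building on the `1e-8 … 0.5` threshold grid, AUC-driven
  selection on a stratified 8:2 split, PC+sex residualization, pathway
  subsetting from BED intervals;
* **association** — KNN metabolite completion, per-sex 10/30/20/30/10
  percentile binning, tie-corrected Kendall τ<sub>b</sub> with CIs,
  Kolmogorov–Smirnov sex comparison, and the pathway-vs-full
  "proportion of correlation explained" slope;
* **synthetic studies** — a generator with an HLA-like
  recombination-suppressed block so the whole pipeline is testable without
  restricted cohort data.

## Worked example

Everything below is simulated, so it runs anywhere in ~30 seconds:

```r
library(gprs)

study <- simulate_study(sim_config(), seed = 1)   # 2,000 + 2,000 samples, 1,500 SNPs
cmp <- compare_methods(study, gprs_config(), seed = 1)
print(cmp, digits = 3)
#>      method chosen_threshold n_snps auc_test hla_fraction
#> 1      gprs            1e-03      8    0.751        0.500
#> 2 gprs_nhla            1e-03      4    0.640        0.000
#> 3        ct            1e-08     12    0.744        0.917
```

The three rows are genetic-distance clumping (`gprs`), the same with the
HLA-like region excluded (`gprs_nhla`), and the traditional 250 kb
physical-window comparator (`ct`), all on one shared train/test split.
Here the genetic window wins on held-out AUC (0.751), excluding the
long-range-LD block costs the most (0.640), and the physical window fills
92% of its model with mutually redundant block SNPs where the genetic
window keeps a balanced 50%.

```r
run <- run_gprs(study, gprs_config(), seed = 1)
print(run)
#> <gprs_run> 819 index SNPs, chosen p <= 0.001, test AUC 0.751, HLA fraction 0.50

subset(run$associations, metabolite == "hdl_c")
#>  metabolite    sex score_kind   tau_b        p  ci_low ci_high   n        q
#>       hdl_c female       full -0.1427 1.36e-09 -0.1889 -0.0966 989 4.08e-09
#>       hdl_c   male       full  0.1307 2.61e-08  0.0847  0.1767 995 7.84e-08
#>       hdl_c female    pathway -0.0951 5.42e-05 -0.1412 -0.0489 989 1.08e-04
#>       hdl_c   male    pathway  0.0887 1.59e-04  0.0427  0.1347 995 3.17e-04

run$proportion_explained
#> pathway explains 74.8% of the full-score correlations (95% CI 0.682-0.807)
```

The HDL-like metabolite was simulated with opposite per-sex couplings, and
the per-sex Kendall τ<sub>b</sub> recovers exactly that: positive in
males, negative in females, both strongly significant. Restricting the
score to the in-block "inflammation" pathway genes preserves the
correlation pattern at reduced magnitude, summarized by the no-intercept
slope of pathway τ<sub>b</sub> on full τ<sub>b</sub>.

A thin command-line wrapper is installed with the package
(`system.file("cli/gprs.R", package = "gprs")`) with `simulate`, `run` and
`compare` subcommands over study directories.

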