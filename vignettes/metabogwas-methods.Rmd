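---
title: "Untargeted NMR metabolome GWAS with metabogwas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted NMR metabolome GWAS with metabogwas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabogwas)
```

## The problem

Untargeted metabolomics by 1D ^1^H-NMR measures a urine (or plasma)
sample as a spectrum: intensity as a function of chemical shift (ppm).
Rather than quantifying named metabolites first, the untargeted GWAS
approach treats the spectrum itself as a panel of molecular phenotypes:
the spectrum is cut into fixed-width chemical-shift bins, and the mean
intensity in each bin — a *metabolome feature* — is tested for
association against genome-wide SNP dosages. Associated features are
then traced back to the metabolite that generates them. `metabogwas`
implements this whole chain: feature construction, the per-feature
association scan with its multiple-testing machinery, pruning and
two-cohort replication, *metabomatching* (compound identification from
the association signal itself), allelic-heterogeneity testing, and
Mendelian-randomization follow-up, together with a synthetic-cohort
simulator that makes every stage testable without access to cohort
data.

## Feature construction

`bin_spec(bin_width, ppm_min, ppm_max)` fixes the grid. Bins are
half-open intervals $[x, x + w)$ labelled by their centre rounded to 4
decimals; at the standard width of 0.005 ppm an 11-ppm spectrum yields
2,200 features. `bin_spectrum()` averages the raw points falling in
each bin (empty bins are missing), `average_replicates()` averages
replicate spectra of an individual on the log scale (non-positive
intensities cannot be logged and are flagged missing), and
`filter_matrix()` removes features with more than 5% missing values
*and then* samples with more than 5% missing values on the surviving
features — the order changes the result and is fixed.

`normalize_profiles()` offers three per-sample normalizations. The
default, a per-individual Z-score across features (population, i.e.
$1/n$, variance), removes overall dilution differences between urine
samples; it behaves much like normalization by total metabolite
content, which is also provided, along with division by a named
reference bin (creatinine surrogate). The Z-score is idempotent and
leaves every profile with mean 0 and variance 1.

Two cohorts binned on different grids (say 0.005 vs 0.0032 ppm) are
matched with `align_features()`: each discovery feature pairs with the
nearest replication bin centre within a tolerance defaulting to the
coarser bin width.

Design choices made where the convention was open: half-open intervals
with centre labels; natural logarithms throughout; features-then-
samples filtering taken literally; an optional water-suppression
exclusion window (off by default, since no range is standard); and a
`scale_features` flag in the association scan (on by default) that
standardizes each feature before regression so effect sizes are in
feature-SD units per allele.

## The association scan and its thresholds

`associate()` fits, per SNP and feature, ordinary least squares of the
feature on allelic dosage plus selected covariates and an intercept;
two-sided P-values come from the $t$ distribution with $n - k$ degrees
of freedom. The scan is vectorized over SNPs per feature
(Frisch–Waugh residualization followed by cross-products), which makes
cohort-scale scans (thousands of SNPs x features) a matter of seconds.
Monomorphic SNPs yield $\beta = 0, P = 1$ and a flag. Alongside the
raw statistics the records carry a signed
$z = \mathrm{sign}(\beta)\,\Phi^{-1}(1 - P/2)$, computed on the log
scale so genome-wide significances survive floating-point underflow;
this makes statistics comparable across cohorts of different size,
which metabomatching relies on.

Covariates are chosen per feature by `select_covariates()`: forward
stepwise inclusion of the candidate factor with the smallest
conditional P-value while it stays below $0.05/(\text{number of
candidates})$, with categorical factors expanded to indicators and
ties broken by name so the selection is deterministic.

Because neighbouring bins are strongly correlated, Bonferroni over all
features would be far too harsh. `effective_tests()` estimates the
effective number of feature tests as the smallest number of leading
eigenvalues of the feature correlation matrix summing to 99.5% of the
total (the simpleM convention). `gwas_thresholds()` then returns the
three decision thresholds of the two-stage design: suggestive
significance at the genome-wide constant $5\times10^{-8}$ in the
discovery cohort, a combined threshold
$0.05/(M_\mathrm{eff}\times n_\mathrm{SNPs,eff})$, and a replication
threshold $0.05/\#\text{hits}$. The effective SNP count is an explicit
input, not a constant, since it depends on the genotyping panel.

## Pruning, replication, meta-analysis, loci

A strong mQTL produces a block of suggestive SNP-feature pairs: many
SNPs in LD with the causal variant, each associated with many
correlated bins. `clump_pairs()` reduces these to independent
associations by extending PLINK-style clumping to pairs: hits are
sorted by P; the best remaining hit becomes a representative and
absorbs every remaining hit whose SNP is in LD with it
($r^2 > 0.3$) *and* whose feature is correlated with it
($r^2 > 0.4$). Both conditions are required; absorption is greedy with
respect to the representative, not transitively closed.

`assess_replication()` declares a discovery hit replicated iff the
replication effect direction is concordant, the replication P-value is
below $0.05/\#\text{hits}$, and the inverse-variance-combined P-value
is below the combined threshold. `ivw_meta()` is the fixed-effect
inverse-variance meta-analysis ($w_i = 1/\mathrm{se}_i^2$), with
allele harmonization by REF/ALT label matching and flagging of
strand-ambiguous A/T and C/G SNPs; no heterogeneity gate is applied —
cohorts with genuinely different allele frequencies can show different
effect sizes, which attenuates but does not invalidate the combined
signal. A useful side effect of meta-analysis across cohorts with
different LD structure is *signal narrowing*: only SNPs linked to the
causal variant in both cohorts keep a strong combined P, so the meta
lead tends to fall inside the shorter of the two LD blocks (this is a
tested property of the pipeline).

`group_loci()` groups replicated associations on one chromosome into
loci by single linkage with a 1 Mb window. Single linkage (rather than
lead-centred ±500 kb) was adopted because reported locus spans
slightly exceeding 1 Mb indicate chained grouping; each locus reports
its lead SNP (smallest combined P, ties to the smaller position) and
its feature set.

## Metabomatching

The identification step is the package's core. The *pseudo-spectrum*
of a SNP (`pseudo_spectrum()`) is its association profile across all
features: signed $z$ and $-\log_{10} P$ per bin. When a SNP shifts the
concentration of one metabolite, every NMR peak of that metabolite
responds, so the pseudo-spectrum visually resembles the metabolite's
reference spectrum.

`score_metabolite()` quantifies that resemblance: the metabolite's
reference peaks are mapped to feature bins (`map_peaks()`: nearest bin
centre within 0.02 ppm, ties to the lower bin, peaks sharing a bin
collapse), the matched bins are pruned to an independent subset
(`prune_correlated()`: greedily keep the largest $|z|$, drop bins with
$r^2 > 0.4$ to a kept one), and the score is

$$ S = \sum_{i=1}^{k} z_i^2, $$

over the $k$ surviving bins. Under the null of no association, and
with independent bins, $S \sim \chi^2_k$, giving a match P-value;
`rank_library()` scores a whole reference library and ranks by P (ties
by descending score, then id), also reporting percentile ranks for
top-1% style evaluation. `score_pair()` pools two compounds' peak sets
(two-compound mode, with an anchor-times-library enumeration) for SNPs
that drive two co-regulated metabolites. Reference relative
intensities are carried but unweighted — peak *positions*, not
heights, carry the identification signal in this formulation, because
association strength need not be proportional to peak height once
bins saturate or overlap.

Numerical notes: the peak-to-bin tolerance (0.02 ppm) allows for
chemical-shift variation between the library's reference conditions
and cohort urine; the pruning threshold reuses the clumping value 0.4;
$-\log_{10}P$ values are computed from $z$ on the log scale, so
features at $P \sim 10^{-400}$ remain finite and ordered.

**Calibration and its limits.** The $\chi^2_k$ null holds when the
pruned bins are independent. Pruning removes strong correlation
($r^2 > 0.4$) but not the latent-factor structure of a real (or
realistically simulated) spectrum: every bin loads on the underlying
metabolite concentrations through peak tails, so in any one cohort a
chance correlation between a SNP and a few concentrations shifts $z$
across the whole spectrum, and the per-library p-values come out
overdispersed for that SNP even with no true effect. We observed
within-realization variances of $z$ up to 1.9 on forward-rendered null
cohorts. The package's calibration test therefore checks the regime
the formula actually promises — independent features — where the
match P-values are uniform to KS precision; on crowded spectra the
P-values should be read as a ranking device (their intended use), not
as exact tail probabilities.

## Allelic heterogeneity

For a confirmed locus, `stepwise_select()` searches the surrounding
1 Mb of SNPs for the best multivariate model of the feature by forward
selection under AIC (the feature having been residualized on
covariates; the lead SNP — the best marginal association, which is
also forward selection's first pick whenever any SNP helps — is always
included so a region model is never empty; candidates with $r^2>0.99$
to the selected span are skipped). The model reports $R^2$, the best
single-SNP $R^2$, and their difference $R^2_\mathrm{diff}$ — the
additional variance explained beyond the lead.

`permutation_model_p()` calibrates $R^2_\mathrm{diff}$ by rerunning
the entire stepwise selection on permutations of the residualized
feature and reporting the add-one estimate
$(\#\{R^{2,\mathrm{perm}}_\mathrm{diff} \ge R^{2,\mathrm{obs}}_\mathrm{diff}\} + 1)/(n_\mathrm{perm}+1)$,
which can never be zero; at the conventional 2,500 permutations the
smallest reportable value is $1/2501 \approx 4\times10^{-4}$.

A subtlety worth knowing: permuting the phenotype destroys the *lead*
signal too, so in the permuted runs the largest chance association is
consumed by the lead slot, while in the observed run the secondary
gains are maximized over all non-lead SNPs. The test is therefore
exactly calibrated under a global null (verified empirically) but
mildly anti-conservative when a single strong causal SNP is present —
about 2–3 times the nominal 5% rate at single-SNP $R^2$ around
0.1–0.2 in our simulations. Model P-values near the threshold should
be read accordingly; the package keeps the published permute-everything
design rather than silently switching to a conditional permutation.

`replicate_locus()` reruns selection and permutation in a replication
cohort over the same window — the *locus*, not the exact SNPs, is
replicated, because LD structure differs between cohorts — and
declares success when the replication model keeps at least two SNPs
with model P below 0.05.

## Mendelian randomization

For a metabolite-disease follow-up with a single genetic instrument:
`first_stage()` reports the instrument's F statistic (weak-instrument
diagnostic), `tsls()` the one-sample two-stage least-squares estimate
(second-stage SEs recomputed with the observed exposure, the standard
correction), `wald_ratio()` the two-sample ratio estimate
$\hat\beta_{GY}/\hat\beta_{GX}$ with first-order delta-method SE, and
`durbin_hausman()` the regression-based endogeneity test (first-stage
residual added to the outcome model and t-tested). The two one-sample
estimators agree exactly for a single instrument. Of the qualitative
instrument-validity audits, the one implementable check is kept:
`mr_analysis()` reports (without gating) association tests of the
instrument against any measured candidate confounders.

`mr_power()` gives the asymptotic power of the IV Wald test from the
non-centrality $\lambda = n\, r^2_{GX} \beta^2\, \mathrm{var}(x) /
\mathrm{var}(y)$, and `mr_required_n()` inverts it by bisection. The
scales of $\beta$, $\mathrm{var}(x)$ and $\mathrm{var}(y)$ are the
caller's declaration; the package does not guess units.

## The synthetic-cohort simulator

`sim_config()` + `simulate_cohort()` generate everything the pipeline
consumes, with known ground truth:

* **Genotypes** (`simulate_genotypes()`): haplotype-copying. Each
  population has a pool of 24 founder haplotypes; an individual
  haplotype walks along the SNPs keeping its founder with probability
  `ld_rho` and jumping to a random founder otherwise; dosage is the
  sum of two haplotypes (Hardy-Weinberg by construction). Founder
  alleles are built from per-founder AR(1) latent Gaussians
  (parameter `ld_rho`) thresholded by rank, so founder haplotypes
  carry serially correlated alleles — this is what produces realistic
  within-block $r^2$ (median adjacent $r^2 \approx 0.27$ at
  `ld_rho = 0.9`, checked against a brute-force oracle) while exact
  per-SNP minor-allele counts keep empirical MAFs inside `maf_range`.
  Two-population mode gives each half-cohort its own founders and
  copying paths (distinct LD-block boundaries), which is what the
  meta-analysis narrowing experiments need.
* **Concentrations** (`simulate_metabolome()`): log-concentration =
  per-metabolite intercept + additive SNP effects (the `effect_table`)
  + optional covariate effects + Gaussian noise. A SNP with effect
  $\beta$ at MAF $p$ explains $2p(1-p)\beta^2$ of the variance;
  `effect_size_for_r2()` inverts this.
* **Spectra** (`make_library()`, `render_spectra()`): each metabolite
  gets 2-6 peaks uniform in the ppm range with relative heights;
  intensity at $x$ is $\sum_m e^{c_m} \sum_p h_p L(x - (\mu_p +
  \delta_i))$ with $L$ a unit-height Lorentzian of FWHM `peak_width`
  (0.01 ppm default — a typical urine linewidth on a 600 MHz
  instrument after shimming), $\delta_i$ a per-sample global shift
  jitter (SD 0.002 ppm, emulating pH/reference drift; it stresses the
  peak-to-bin tolerance exactly as real drift does), plus a small
  positive baseline with noise. Implementation: one
  metabolite-signature matrix product followed by a rigid per-row grid
  shift — identical to per-peak evaluation, an order of magnitude
  faster. Missing values are injected after binning at `missing_rate`.

What the simulator deliberately does not model: J-coupling multiplet
structure, water-suppression artifacts, baseline distortions, peak-
shape deviations, and within-sample differential peak shifts. Passing
tests on these cohorts therefore demonstrate the statistical machinery
(binning, scan calibration, clumping, scoring, replication logic), not
robustness to spectral artifacts, which real studies handle upstream.

One emergent property of the forward model matters for interpretation:
on the log scale, every bin where a metabolite's signal exceeds the
baseline carries that metabolite's *full* genetic effect — Lorentzian
tails included. In sparse spectra this smears associations across many
bins and makes the two peaks of one metabolite correlate at
$r \approx 1$ (so pruning collapses them to $k = 1$). Crowded spectra
— all 100 library metabolites rendered, as in real urine — bury the
tails under other signals and restore the multi-peak advantage; the
recovery experiments are therefore run on crowded cohorts.

## Problem sizes used by the tests

The bundled experiments run at desk scale, chosen to make the
statistical properties measurable in minutes on one core: compound
recovery uses 25 cohorts of 500 individuals with one SNP explaining
10% of a 3-peak metabolite's variance against 99 decoys (rank 1
expected in over 90% of seeds); pipeline calibration uses ten null
cohorts of 200 individuals x 2,000 SNPs x 300 features;
heterogeneity recovery uses 50 regions of 800 individuals with two
causal SNPs at $r^2 = 0.1$ and 5% variance each (500 permutations);
MR coverage uses 2,500 replicates at $n = 5000$. The corresponding
cohort-scale quantities (hundreds of thousands of SNPs, 2,200
features) differ only in compute, not in code paths.
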