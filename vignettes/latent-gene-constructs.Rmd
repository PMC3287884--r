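---
title: "Latent gene constructs for rare and common variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent gene constructs for rare and common variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesem)
```

# The problem

Single-SNP regression treats every variant in a gene as a separate
hypothesis. Rare variants are then individually underpowered, and the
joint effect of a gene's common and rare variation has no single summary.
This package implements a two-stage alternative. Stage 1 is a conventional
screen: additive linear regression per SNP with covariate and
principal-component adjustment, rare variants (MAF < 0.05) collapsed into
per-gene carrier indicators, and a Bonferroni rule that flags potentially
interesting genes (PIGs). Stage 2 replaces the per-SNP view with a latent
variable per gene: the observed SNP codes are treated as indicators of one
construct representing the gene's overall variation, and all constructs
act on the trait simultaneously inside a structural equation model (SEM).

# The model

With indicator vector $y$, latent vector $\eta$, covariates $x$:

$$y = \Lambda \eta + \varepsilon, \qquad
  \eta = \alpha + \mathrm{B} \eta + \Gamma x + \zeta$$

Writing $A = (I-\mathrm{B})^{-1}$, $\Phi = \mathrm{Cov}(x)$,
$\Theta = \mathrm{Cov}(\varepsilon)$, $\Psi = \mathrm{Cov}(\zeta)$, the
implied covariance of the modeled observed vector $(y, x)$ is

$$\Sigma_{yy} = \Lambda A (\Gamma \Phi \Gamma' + \Psi) A' \Lambda' + \Theta,
  \quad \Sigma_{yx} = \Lambda A \Gamma \Phi, \quad \Sigma_{xx} = \Phi .$$

Estimation minimizes the normal-theory discrepancy
$F_{ML} = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$ over the
free parameters; $T = (n-1) F_{ML}$ is the test statistic (the $n$
multiplier can be toggled). Covariates are modeled jointly (saturated,
free $\Phi$ block) rather than conditioned on, so the usual fit statistics
apply to the full covariance matrix. The mean structure is not modeled:
all reported quantities are covariance-level, and $\alpha$ is therefore
not estimated by default.

Assumptions worth stating plainly: indicators enter as continuous
variables even though genotype codes take three values and rare-variant
columns are mostly zero. That is exactly why the robust corrections below
are on by default; limited-information ordinal estimation is out of scope.
Missingness is handled by listwise deletion only — the intended inputs are
complete genotype/phenotype tables.

## Robust corrections

With raw data available, the package computes the empirical fourth-moment
matrix $\hat\Gamma$ of the half-vectorized covariance, sandwich standard
errors $(\Delta'V\Delta)^{-1} \Delta'V\hat\Gamma V\Delta (\Delta'V\Delta)^{-1}/(n-1)$
with $V$ the normal-theory weight matrix and $\Delta = \partial\,\mathrm{vech}\,
\Sigma / \partial\theta$, and a mean-scaled statistic $T/c$ with
$c = \mathrm{tr}(U\hat\Gamma)/df$,
$U = V - V\Delta(\Delta'V\Delta)^{-1}\Delta'V$. Under multivariate
normality $c \to 1$ (a property the test suite asserts at $n = 10{,}000$).
Fit indices are computed from both the unscaled and the scaled statistic
and labeled accordingly, since either convention is defensible.

## Fit indices and cutoffs

CFI $= 1 - \max(T-df,0)/\max(T_b-df_b, T-df, 0)$ against the independence
baseline (closed form: $\Sigma_b = \mathrm{diag}(S)$); RMSEA
$= \sqrt{\max(T-df,0)/(df\,(n-1))}$, undefined at $df=0$; SRMR is the root
mean square of correlation-metric residuals over the unique moments
including the diagonal. `classify_fit()` applies the conventional labels:
CFI at least 0.95 good / 0.90 acceptable, RMSEA at most 0.06 good / 0.10
acceptable, SRMR at most 0.08 good / below 0.10 acceptable.

## Identification and the model grammar

Models are plain text: `latent G = snp1 + snp2 + ...`, `path A -> B`,
`covary A B`, `fix <label> = <value>`. The first listed indicator is the
marker (loading fixed to 1); `std_latent` instead fixes exogenous latent
variances to 1. An observed path target becomes a single-indicator latent
with zero measurement error, which is how the trait enters. Exogenous
latents are uncorrelated unless `covary` says otherwise — correlations are
declared, not implied. `assemble_model()` adds two guard rails learned
from practice: a one-indicator construct gets its indicator residual fixed
to 0 (the construct coincides with the SNP), and a two-indicator construct
gets tau-equivalent loadings (both fixed to 1), because a free loading
split between two indicators is identified only through the construct's
outside correlations and otherwise rides a likelihood ridge.

## Numerics

The optimizer is quasi-Newton (`nlminb`, then L-BFGS-B/`nlminb` polish
rounds, then Newton steps using twice the expected information) on a
preconditioned parameter space: free variances on the log scale (positive
and unit-free), every other parameter divided by the standard-deviation
products of its connected variables. Without that preconditioning a
covariate measured in large units (age in years against a unit-variance
trait) stalls the gradient norm orders of magnitude above the tolerance.
Convergence requires a preconditioned gradient norm below `1e-6`
(`control$gr_tol`); non-convergence is flagged and warned about, never
silently returned. Log-variances are bounded below at `1e-10` times the
largest observed variance, so a Heywood direction stops at a tiny positive
value and is flagged inadmissible rather than sliding to $-\infty$.
Gradients are analytic,
$dF = \mathrm{tr}[(\Sigma^{-1} - \Sigma^{-1} S \Sigma^{-1})\, d\Sigma]$,
with the per-matrix derivative blocks assembled in closed form; the test
suite checks them against finite differences indirectly through the
brute-force refits. Start values are marker-scaled sample moments. Naive
standard errors come from the inverse expected information over $(n-1)$.
Standardized estimates rescale by implied standard deviations; their
standard errors use a numeric delta-method Jacobian.

# The synthetic study generator

The generator emulates the shape of the motivating exon-sequencing data
set without reproducing it: 697 individuals in 7 populations, 9 causal
genes carrying 39 causal SNPs among configurable decoy genes, a normal
trait built additively from minor-allele counts plus Age/Sex/Smoking
effects and unit residual noise, and replicate sets in which genotypes and
covariates are fixed while the trait is redrawn.

Population differentiation follows the Balding–Nichols model
(per-population frequency $\sim$ Beta with mean $p$ and variance
$F p(1-p)$; default $F = 0.1$, a continental-scale value). Two structural
choices matter and are deliberate:

* **Within-gene LD.** Alleles at a gene's SNPs are drawn through a
  Gaussian haplotype copula with equicorrelation (default 0.9). The
  binary thresholding attenuates this severely — 0.9 at the latent level
  yields realized genotype $r^2$ around 0.2–0.45 for common pairs and
  frequency-bounded smaller values for rare/common pairs, which is what
  dense variants inside one gene look like. Values much below that leave
  essentially independent SNPs, for which a "gene construct" is
  undefined — an early version of the generator did exactly this, and
  every construct degenerated.
* **Block drift.** The Balding–Nichols quantile is drawn once per gene per
  population and mapped through each SNP's exact marginal Beta
  distribution. Drift acts on haplotypes, so a gene's population frequency
  deviations are strongly correlated; drawing them independently per SNP
  (the obvious implementation) destroys pooled LD across populations.

Per-SNP marginals remain exactly Binomial(2, frequency) under
Hardy–Weinberg equilibrium in both cases. Private variants are planted as
a single heterozygous carrier. Effect sizes default to a trait
$R^2 \approx 0.4$ with the strongest gene (FLT1) near 10% of trait
variance and the rest at 2–6%.

What the generator does *not* emulate: haplotype phase and recombination
maps (LD is exchangeable within a gene, not block-boundary structured),
sequencing error and missingness, family structure, and any resemblance of
decoy-gene LD to specific real genes. Passing tests therefore say the
methods behave correctly on data with this covariance anatomy — not that
real exon data would give the same power or false-positive rates.

# Stage-1 conventions

MAF is the folded allele-count fraction, and the rare/common boundary is
strictly `MAF < 0.05`. Collapsing is the indicator coding: 1 if an
individual carries at least one minor allele across the gene's rare SNPs
(a per-gene count variant is available behind `method = "count"`). The
Bonferroni denominator is the number of columns actually tested in the
configuration at hand — collapsing changes the denominator, which is why
a collapsed and an uncollapsed scan have different thresholds. PCs are
scores of the centered (not variance-scaled) genotype matrix with the sign
convention that each component's largest-magnitude loading is positive.
P-values are two-sided from the $t$ distribution with residual degrees of
freedom. Degenerate fits (zero residual variance, monomorphic columns) are
flagged with `NA` rather than dropped silently; rank-deficient designs
error and name the collinear columns.

# Construct building

`select_snps()` freezes the judgment-based "most informative SNPs" step
into a deterministic greedy rule: rank the gene's SNPs by stage-1 p-value
(ties by SNP id), then keep a SNP when its maximum LD $r^2$ with the SNPs
already kept lies in `[r2_min, r2_threshold]` (defaults 0.1 and 0.8),
stopping at `max_indicators` (default 6). The upper bound prunes
near-duplicates that add no information; the lower bound is the coherence
floor standing in for scree/reliability screening — an indicator
uncorrelated with the others does not measure the same construct and
leaves the factor empirically underidentified. A MAF floor
(`maf_min = 0.01`) keeps near-monomorphic columns out of the measurement
model; their evidence enters through stage-1 collapsing instead.
`cronbach_alpha()`, `eigen_screen()` and `ld_r2()` expose the screening
diagnostics directly.

# The replicate bias protocol

`evaluate_replicates()` takes a reference fit's standardized solution as
population values, refits the identical model to every replicate, and
reports mean relative bias per parameter, per class ($\Lambda$,
$\varepsilon$, $\zeta$, paths) and overall. Definitional choices, each of
which was genuinely open:

* **Bias, not dispersion.** The headline MRB of a parameter is the
  magnitude of the *mean* signed relative deviation across replicates —
  the relative bias of the estimator. The per-replicate *absolute*
  deviation, which adds sampling dispersion on top of bias and cannot fall
  below roughly $0.8 \times$ the relative sampling SD however well the
  estimator behaves, is reported alongside as `mad_est`/`mad_se`. For a
  residual variance estimated with a relative SD of several percent at
  $n = 697$, only the bias reading can approach the sub-percent values a
  stable measurement model should show.
* **Standardized metric.** Comparisons are on the standardized solution
  (and its robust standard errors by default), making the MRB
  scale-invariant.
* **Zero population values** are excluded and listed — a relative bias
  against zero is undefined, and near-zero paths are reported but
  dominate no average.
* **Warm starts.** Replicate refits start at the reference solution.
  Replicates perturb the reference data only slightly; cold starts can hop
  between local basins of a weakly identified likelihood, and the protocol
  is meant to measure sampling stability of one tracked solution, not
  optimizer dispersion. More than 20% non-convergence is a hard error.

`bias_study()` packages the default protocol: simulate one reference study
(the generator's default dimensions), build constructs for the nine causal
genes (up to 5 indicators each, ordered so the highest-MAF SNP is the
marker), fit the joint model, then redraw the trait per replicate as its
reference-estimated conditional mean given the genotype indicators plus
fresh normal noise — the same mechanism that produced the workshop's own
replicates, with the conditional estimated from the reference replicate.
Because the redraw matches the reference sample moments in expectation,
the reference solution is the exact population value of the refitting
estimator, and the reported MRB isolates estimator behavior. The default
evaluation model contains the nine constructs and the trait only: the
generator's covariate effects are standardized near zero, where relative
bias is uninformative (the same instability the protocol itself exposes
for weak paths), and the population-structure misfit is identical across
replicates. Both can be switched back on (`covariates`, `n_pcs`).

The test suite asserts that the overall MRB of standardized parameters
and of standard errors stays within 5% over 100 replicates — and holds
the dispersion-inclusive variant to the same bound.

# Problem sizes

The test suite runs the full 100-replicate bias study on the default
9-gene study (about 25 indicators, roughly 60 free parameters, $n = 697$),
200 recovery simulations of a 2-gene model at $n = 5000$, 2000 null
regressions for the type-I error check, a 60-replicate null study for the
family-wise error bound, and brute-force refits of four fixture models of
up to 6 variables against an independent Nelder–Mead/BFGS minimizer of
hand-coded implied covariances. The whole suite completes in a few minutes
on one CPU.

# Known limitations

* Single-group, covariance-only analysis: no mean structure, no
  multi-group constraints, no equality constraints across parameters
  (tau-equivalence is expressed by fixing, not constraining).
* Genotype indicators as continuous variables: robust corrections fix the
  standard errors and the test statistic scale, not the fundamental
  coarseness of a 3-valued indicator; ultra-rare variants are excluded
  from measurement models by design.
* The greedy SNP selection is a reproducible stand-in for expert
  judgment; it will not reproduce any particular published construct.
* The brute-force oracle in the tests is an independent *implementation*,
  not an independent *derivation* — it shares the normal-theory ML
  objective, which is the quantity being tested.
* RMSEA confidence intervals, FIML missing-data handling, and categorical
  (WLSMV-style) estimation are out of scope.
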