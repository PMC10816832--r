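---
title: "Methods: mixed-model GWAS in inter-heterotic-group hybrid populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model GWAS in inter-heterotic-group hybrid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridGWAS)
```

## The problem

Maize breeding programs maintain two complementary heterotic groups of
inbred lines and create commercial varieties by crossing them: the F1
hybrids express heterosis that neither inbred pool shows.  Mapping the loci
behind hybrid performance therefore has to be done *in the hybrids
themselves*, where additive, dominance and epistatic gene action are all
visible, rather than in inbred panels where every locus is homozygous.
This package implements a GWAS pipeline for exactly that design: a panel of
genotyped inbred parents from groups A and B, a (typically partial
factorial) cross design, and adjusted phenotypes of the resulting F1
hybrids.

Because the parents are inbred, hybrid genotypes never need to be assayed:
at every biallelic SNP the F1 genotype is fully determined by the two
parental homozygotes (`deduce_hybrids()`).  A residually heterozygous
parental call has no defined F1 genotype and is treated as missing (a
strict mode raises an error instead); missing hybrid calls are repaired by
imputing the *parents* (LD-kNN, `knn_impute()`) and re-deducing, never by
imputing hybrids directly, so the pedigree constraint is preserved.

## The model

The phenotype vector $y$ (environment-adjusted hybrid means) is modelled
with the mixed linear model

$$ y = X\beta + M\alpha + g + e, \qquad e \sim N(0, I\sigma_e^2), $$

where $X\beta$ is just the intercept, $M$ is the design column of the SNP
(or SNP pair) under test with fixed effect $\alpha$, and $g$ is the
polygenic background.  Two background models are provided:

* **KinA** — $g = g_a$, $g_a \sim N(0, K_a\sigma_a^2)$;
* **KinADE** — $g = g_a + g_d + g_{aa} + g_{ad} + g_{da} + g_{dd}$ with one
  genomic kinship per term.

Per marker, the additive design column $Z$ codes the two homozygotes as
$-1$ and $+1$ and the heterozygote as $0$; the dominance column $W$ codes
the heterozygote as $1$.  Epistatic design columns are direct
(element-wise) products of the relevant $Z$/$W$ columns of the two loci
(types `aa`, `ad`, `da`, `dd`).  $K_a \propto ZZ^\top$ and
$K_d \propto WW^\top$ are scaled to mean diagonal 1 so that all variance
components live on the phenotype scale; the four epistatic kinships are
Hadamard products of the normalized main kinships, re-scaled the same way.
This Hadamard construction is the standard genome-scale shortcut for
epistatic covariance: it is mathematically equivalent to building all
$m^2$ interaction columns, stays positive semi-definite, and is the only
tractable route for tens of thousands of markers.  Note that $K_{ad}$ and
$K_{da}$ built from one marker set are *equal*; both slots are kept so the
model's seven components remain nameable, and REML splits their joint
variance evenly between them.

By default $Z$ and $W$ are the raw codes above, matching the literal
coding statement of the modelled analysis; `build_kinships(center = TRUE)`
switches to column-centered codings.  This choice matters for
identifiability (see *Known limitations*).

## Fitting and testing

Variance components are estimated once under the null (no tested marker)
by REML — a few stabilized multiplicative EM steps followed by
average-information updates with step-halving and a non-negativity floor
of $10^{-8}\,\mathrm{var}(y)$ (`fit_null_reml()`).  Convergence is declared
when the restricted log-likelihood changes by less than $10^{-6}$;
non-convergence is reported on the fit object and warned about, never
silently ignored.  Degenerate kinships (for example every
dominance-containing matrix on an all-inbred panel, where $W \equiv 0$)
are flagged and dropped from the model, and an additive kinship that
equals the identity triggers an unidentifiability warning because
$\sigma_a^2$ and $\sigma_e^2$ then play the same role.

Scans are P3D/EMMAX-style: $\hat V = \sum_k \hat\sigma_k^2 K_k +
\hat\sigma_e^2 I$ is held fixed while every marker (or marker pair) is
tested by generalized least squares after whitening with the Cholesky
factor of $\hat V$.  The test statistic is the finite-sample *t* form: the
background covariance is treated as known up to a per-marker residual
scale re-estimated from the GLS residuals, giving $t$-tests with $n - p$
degrees of freedom.  Two properties recommend this over the asymptotic
1-df Wald chi-square: when $\hat V \propto I$ the marker test collapses
*exactly* to ordinary least-squares regression (the package's oracle
tests exploit this), and the per-test type-I error is calibrated at the
modest sample sizes (a few hundred hybrids) these populations have.

Markers with all three genotype classes are fitted with $Z$ and $W$
jointly; the reported mode is `Add`, `Dom` or `Add/Dom` according to which
terms pass the threshold.  Markers where one homozygote class is absent
from the hybrid population — common when a locus is monomorphic within one
group's testers — get a single confounded column and the `Add/Dom` label
with reason `one_homozygote_missing`, since additive and dominance action
cannot be separated there.  Monomorphic markers are skipped and logged.

The epistasis scan fits, for each unordered candidate pair and requested
type, the estimable main-effect columns of both loci plus the typed
interaction column, and tests the interaction term only.  Constant or
collinear interaction columns (e.g. `dd` when one locus has no
heterozygotes) are skipped as inestimable and logged.  The candidate set
defaults to an LD-pruned list of the top main-scan markers
(`candidate_n` in the run configuration) because an exhaustive scan over
all pairs of a dense panel is rarely informative at these sample sizes; an
exhaustive scan over any explicit candidate list is available by passing
that list.

## Multiple testing

Thresholds use the effective number of independent markers $M_e$: the
smallest number of principal components of the marker correlation
structure capturing 99.5% of the variance (`effective_marker_number()`).
Main-effect tests use $-\log_{10}(\alpha / M_e)$ and pairwise tests
$-\log_{10}(\alpha / (M_e(M_e-1)/2))$; with $M_e = 883$ and
$\alpha = 0.10$ these give the working thresholds 3.95 and 6.59 (7.59 at
$\alpha = 0.01$ for interaction-rich traits).  Correction is Bonferroni on
$M_e$ only; no FDR option is offered by default.

Significant markers are LD-clumped: within 150 kb and pairwise
$r^2 > 0.2$ only the most significant marker survives (ties broken by
smaller position), and retained QTNs must explain at least 1% of the
phenotypic variance.  PVE is computed as
$100\cdot\mathrm{var}(M\hat\alpha)/\mathrm{var}(y)$ with the observed
genotype distribution — for epistatic entries the interaction term only.
The alternative estimator (variance-component ratio) was not used because
the fitted-term form applies identically to main and epistatic effects
and needs no extra model fit; this is a declared choice, the quantity is
not uniquely pinned down by its verbal definition.

## Model comparison

`crossvalidate_models()` compares KinA and KinADE by repeated five-fold
cross-validation: per repeat and fold the background is re-fitted on the
training samples and held-out phenotypes are predicted by the mixed-model
BLUP ($\hat y_{test} = \hat\mu + C \hat V_{train}^{-1}(y_{train} -
\hat\mu)$ with $C$ the genetic cross-covariance).  Predictive PVE is 100
times the squared correlation of prediction and observation over the
held-out samples.  Under simulated dominance-plus-epistatic variance the
KinADE model is consistently the better predictor, which is the package's
criterion for preferring it as the default background.

## The synthetic-data generator

`simulate_founders()` emulates the structure of a breeder panel, not its
history: per-marker ALT-allele frequencies for the two groups are drawn
from Beta distributions whose means are separated proportionally to
`divergence` (default 0.3), with a lower Beta concentration for group B
(10 vs 30) so that the B pool is the more diverse one, as in real
complementary heterotic pools.  Founders are fully homozygous.  LD is
produced by sharing a per-block latent uniform across markers within
`ld_block_span` (default 150 kb, the LD decay scale of such panels) with
probability `ld_rho` (default 0.9), which correlates markers without
changing marginal frequencies; `ld_rho = 0` yields independent markers for
calibration studies.  Defaults of 30 group-A and 89 group-B founders and a
partial factorial design mirror a typical breeder population; phenotype
heritabilities default to 0.6, the middle of the 0.44–0.82 range such
agronomic traits show.

`simulate_phenotypes()` adds QTN effects in exactly the codings the scan
fits (additive on $Z$, dominance on $W$, epistasis on direct products), a
polygenic term drawn with covariance proportional to the hybrids' $K_a$
(its share of genetic variance set by `polygenic_share`, default 0.3), and
Gaussian residual noise scaled so the realized genetic variance fraction
matches the target heritability.  The generator does **not** emulate
coalescent recombination structure, genotype-by-environment interaction
(phenotypes are "adjusted" single values by construction), selection, or
allele-frequency clines beyond the two-group split — so passing tests
demonstrate correctness of the estimators under the model's own
assumptions, not robustness to every feature of real field data.

## Numerical choices

* REML: variance floor $10^{-8}\mathrm{var}(y)$, likelihood tolerance
  $10^{-6}$, at most 100 AI iterations, 20 step-halvings; the AI matrix is
  ridge-regularized by $10^{-8}$ of its diagonal scale before solving.
* Whitening uses the Cholesky factor of $\hat V$; rank-deficient marker
  designs fall back to the confounded single-column fit; aliased epistatic
  columns are detected through QR pivoting.
* Kinship simulation draws add a $10^{-8}$ (test code) / $10^{-6}$
  (phenotype generator) diagonal jitter before Cholesky.
* Clumping ties are broken by smaller position; `qc_filter()` keeps a
  marker whose missing rate is exactly at the threshold and drops a marker
  whose MAF is strictly below it.
* KNN imputation uses $k = 5$ neighbours over the 30 flanking markers
  (distance = mean absolute genotype difference, weight $1/(d + 0.1)$);
  the named method's original settings are not published, so these
  defaults are the package's own and make no compatibility claim.
* Sites fully missing in all samples are filled with homozygous REF and
  logged; markers with no finite neighbour distance fall back to the major
  genotype.

## Breeding analytics

Favorable genotypes are the genotype class with the best predicted
phenotype in the trait's breeding direction; the shipped direction table
marks GM, EH and TBN as lower-is-better and the remaining standard traits
as higher-is-better, and is fully overridable.  The accumulation
regression is ordinary least squares of phenotype on the per-hybrid count
of favorable genotypes.  TOP/BOT tail comparisons use a Wilcoxon rank-sum
test — the underlying multiple-comparison display in this literature does
not name its test, so a nonparametric default was chosen deliberately.

A one-genotype-missing-site (OGMS) is a marker whose hybrid population can
only show one homozygote plus the heterozygote.  `count_ogms()` evaluates
OGMS from the *achievable* classes of the parental tester genotypes by
default (so partial factorial designs with unrealized pairs are handled
uniformly), with a realized-design mode for comparison.
`compare_mating_strategies()` resamples doubled/tripled tester sets under
a constant hybrid budget; the default budget of 442 hybrids (a typical
breeder population) exceeds the multiplied tester grids, so every grid
pair is realized — with budgets *below* the grid size the thinning of
realized pairs can lose genotype classes and reverse the benefit, which is
worth knowing before shrinking the budget.  Tester pairing within a
strategy is uniform at random; no pairing rule is claimed beyond that.

## Known limitations

* With the default raw codings the six kinships are strongly collinear
  ($K_a$ and $K_{aa}$ correlate at $\approx 0.99$ on simulated panels), so
  individual epistatic variance components are not separately
  identifiable — only certain sums are.  Centered codings
  (`center = TRUE`) decorrelate the main terms and recover $\sigma_a^2$
  and $\sigma_d^2$ cleanly, but the near-diagonal epistatic kinships still
  trade off against the residual.  Fixed-effect scans are unaffected.
* Under a pure-noise phenotype (no polygenic background at all) the
  mixed-model scan is mildly conservative, because spuriously positive
  background components deflate structured markers; calibration holds
  under the model-matched null (background present, marker effects zero),
  which is the design used in the package's calibration tests.
* P3D holds the background fixed across tests; an effect large enough to
  perturb the variance components is slightly shrunk.  No
  leave-one-chromosome-out mode is currently provided.
* No genotype likelihoods, multi-allelic sites, phasing, structural
  variants, G×E modelling, or genomic prediction of untested hybrids.

## Problem sizes used by the test-suite

The packaged tests and the acceptance script run entirely on synthetic
data at sizes chosen to make the statistical checks sharp yet quick:
effect-recovery uses 50 replicates of 400 hybrids × 2,000 markers;
calibration pools three phenotype draws over 2,000 independent markers ×
300 hybrids; the model-comparison cross-validation uses 400 hybrids with
10–20 repeated five-fold partitions; structural and oracle checks use
panels of 30–150 samples.  These sizes are the package's own choices and
are stated here so results can be reproduced exactly.
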