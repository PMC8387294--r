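---
title: "From SRM peak areas to Mendelian-randomization estimates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From SRM peak areas to Mendelian-randomization estimates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhrmr)
library(dplyr)
```

`fhrmr` implements an analysis chain for the complement factor H protein
family — FH, its splice variant FHL-1, and the five factor-H-related
proteins FHR-1 through FHR-5, all encoded at the *CFH*/*CFHR* locus — in
the context of age-related macular degeneration (AMD):

1. **Quantitation** of circulating protein concentrations from
   stable-isotope-dilution selected reaction monitoring (SRM) transition
   peak areas;
2. **Case-control association** of those concentrations with disease;
3. **pQTL genome scans** of the concentrations on genotype dosages in
   controls;
4. **Mendelian randomization** (MR) from the resulting summary statistics.

A synthetic cohort generator reproduces the statistical structure every
stage assumes, so the full chain is testable without individual-level
cohort data.

## Single-point isotope-dilution quantitation

Each protein is represented by one proteotypic Glu-C peptide, synthesized
with a heavy isotope label (K+8.0142, R+10.00827, F/Y+10.02728 Da) and
spiked into each plasma digest at a known level. Three SRM transitions are
monitored per peptide in both light (endogenous) and heavy (standard)
channels. Per batch and peptide, the transition with the largest mean
heavy area is the *quantifier*; the endogenous concentration is

$$ c = \frac{A_\text{light}}{A_\text{heavy}} \times c_\text{spike}, $$

and the two remaining *qualifier* transitions confirm specificity: their
light/heavy ratios must sit within a relative tolerance (default 30%; no
published value exists, and 20–40% behaves identically on clean data) of
the quantifier's ratio.

The spike concentration itself is pure bookkeeping. The concentrated
standard (stocks 47.6, 0.95, 7.14, 19, 4.76, 4.76 and 4.76 ng/uL for FH,
FHL-1 and FHR-1 through FHR-5) is diluted 40-fold (5 uL + 195 uL) and 2 uL
are spiked into a digest of 5 uL plasma, giving a mass concentration in
plasma equivalents that the peptide's monoisotopic mass converts to nM:

```{r spikes}
spike_concentration(fh_peptides(), spike_scheme()) |>
  select(protein, mass_da, spike_nM)
```

These reproduce the nominal levels of 500, 5, 32.75, 86.75, 21.68, 41.5
and 27.5 nM within 2% (the FHR-2 figure is the least exact; the remainder
agree to three significant figures). Cysteines carry carbamidomethyl
(+57.02146 Da) as the fixed modification, matching the iodoacetamide
alkylation in the digestion protocol; the mass is configurable. Because
quantitation is a light/heavy *ratio* within one injection, the injected
plasma equivalent cancels; it is carried as metadata only (the nominal
0.8 uL figure is inconsistent with the stated volumes, which give 0.4 uL
for a 4 uL injection of a 50 uL reconstitution of 5 uL plasma — another
reason not to let it enter the arithmetic). Concentrations below the
assay LLOQ (25, 0.25, 2, 1, 1, 4 and 3 nM respectively) are retained and
flagged, never imputed; a value exactly at the LLOQ counts as
quantifiable. No between-batch normalization is applied; batch quality is
summarised as the %CV of replicate QC samples.

## Association model

Concentrations are first transformed toward normality: square root for
FH, FHR-2, FHR-3 and FHR-4; natural log for FHL-1 and FHR-5; identity for
FHR-1. (Natural rather than base-10 log: the per-SD odds ratio downstream
is invariant to the base, so the choice is cosmetic but documented.) The
case-control contrast is a per-protein ordinary least-squares regression
of the transformed concentration on case status, adjusted for sex, age and
two genetic principal components, with a two-sided Wald test. The odds
ratio per standard deviation is a covariate-adjusted logistic regression
on log concentration standardised by the SD of the pooled analysis sample
(cases and controls together; the convention is not stated anywhere
authoritative, and the pooled SD is the estimable choice in a case-control
sample). Missing concentrations are complete-case per protein. Confidence
intervals are Wald intervals at 1.96 SE throughout. Pairwise protein
correlations are pairwise-complete Pearson coefficients, computed in
controls.

## pQTL scans, LD and clumping

Variants are filtered to MAF ≥ 1% and, if imputed, imputation R² ≥ 0.3
(both boundaries inclusive). Each scan is one OLS fit per variant of the
transformed concentration on the 0–2 effect-allele dosage with the same
covariates, vectorised by residualising trait and dosages on the covariates
(Frisch–Waugh), with degrees of freedom identical to the full per-variant
model — the tests agree with `lm()` to 1e-10 in the suite. The effect
allele is the minor allele. Genome-wide significance is fixed at
5 × 10⁻⁸.

Pairwise LD is computed two ways, for two purposes. `ld_stats()` estimates
haplotype frequencies from unphased genotypes by EM over the
double-heterozygote ambiguity (started from linkage equilibrium, up to 50
iterations or a 1e-10 change) and reports D, D′ and r²; this is the
precise pairwise measure. `ld_matrix()` is the squared Pearson correlation
of dosages — the standard composite estimate — and serves as the clumping
reference, where thousands of pairs are needed cheaply. Clumping is
greedy: take the smallest-p variant below the threshold, discard
everything with r² at or above the cut-off (0.001 by default; 0.01 is
supported and, on the bundled instruments, selects the same variants),
repeat. Ties on p break by genomic position then variant id, so results
are reproducible; variant pairs missing from the LD source are treated as
independent and logged.

## Mendelian randomization

For one instrument the causal estimate is the Wald ratio
$\hat\theta = \hat\beta_Y / \hat\beta_X$ with the first-order delta SE
$\text{se} = \text{se}_Y / |\hat\beta_X|$; the second-order term is
deliberately omitted (it matches the convention of the standard software
this mirrors, and with the instrument strengths involved — F statistics of
30 and up — the correction is below the rounding of every reported
figure). For several instruments the fixed-effect inverse-variance
weighted estimate pools the ratios with weights $w_j = \text{se}_j^{-2}$;
a single instrument reduces exactly to its Wald ratio. Heterogeneity is
Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ on $k-1$ df with
$I^2 = \max(0, (Q - \text{df})/Q) \times 100$.

Instrument strength is reported as the variance explained, recovered from
the published p-value and sample size by inverting the F test:
$F = F^{-1}_{1,n-2}(1-p)$, $R^2 = F/(F+n-2)$, computed on the log-p scale
so that values like 10⁻³⁰⁰ never overflow.

Exposure and outcome statistics are harmonized on the effect allele:
swapped allele pairs flip the outcome sign, irreconcilable pairs are
dropped with a warning, and palindromic (A/T, C/G) variants with MAF above
0.42 are dropped because their strand cannot be resolved. In the
one-sample design the exposure associations come from the *controls only*
of the cohort whose full case-control logistic scan supplies the outcome
associations (the usual justification: under low prevalence the control
exposure distribution approximates the population's); the two-sample
design takes outcome statistics from an external file. The reported OR is
per unit of the *transformed* concentration — recomputing the bundled
FHR-3 example confirms that is the scale on which the published estimates
live.

The package bundles the published seven-instrument FHR-3 table (plus the
single cis instruments of FHR-1, FHR-2, FHR-4 and FHR-5) as a worked
example:

```{r fhr3}
mr_from_instruments("FHR-3", design = "one-sample")
mr_from_instruments("FHR-3", design = "two-sample")
```

The one-sample pool is null (OR 0.99, 95% CI 0.93–1.06) with Q below its
degrees of freedom, hence I² = 0%. Note the two-sample I² recomputed from
the rounded published betas is ~63%, not the published 57%; rounding of
the inputs fully explains the gap, and only the point estimate should be
compared against the publication.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions end to end:

* **Genotypes** — haplotypes from a latent-Gaussian threshold model:
  within a block, latent values share an equicorrelation ρ (default 0.8,
  6 variants per block) and an allele is carried where the latent value
  falls below the MAF quantile; two haplotypes sum to a dosage. This was
  chosen over coalescent simulation because the only requirements here are
  tunable r²/D′ for clumping and EM tests, with no external simulator.
* **Proteins** — on each protein's transformed scale, intercept + cis
  effect × dosage + Gaussian noise, with the noise SD solved so the cis
  variant explains a requested R²; defaults follow the published
  instrument strengths (0.53, 0.44, 0.35, 0.25, 0.15 for FHR-1 through
  FHR-5) and no pQTL for FH or FHL-1, so FHL-1 exercises the
  "no instrument" path. Intercepts and residual SDs emulate the control
  group's marginal means; back-transformed negatives are truncated at 0
  and counted.
* **Disease** — Bernoulli with logit equal to an intercept plus per-protein
  effects, either per SD of log concentration (the observational scale;
  defaults use the published per-SD ORs, 1.01–1.81) or per transformed
  unit (the MR estimand scale). Standardisation moments are frozen from
  the first pre-selection batch so case-control sampling cannot redefine
  the per-SD unit. Batches of individuals are drawn until the requested
  352 cases and 252 controls exist.
* **Covariates** — sex ~ Bernoulli(0.42), age ~ N(74.5, 8²), PCs ~ N(0,1),
  with null effects by default, matching the cohort demographics.
* **SRM peaks** — heavy areas lognormal around fixed per-transition
  intensities; light = heavy × conc/spike × multiplicative lognormal noise
  with CV 10% by default (the reproducibility tables report 10–21% per
  protein); an optional corruption rate triples one qualifier's light area
  to exercise the concordance check.

Everything is a pure function of (config, seed). What the generator does
*not* emulate: genuine recombination maps, population stratification or
pleiotropy, chromatographic artefacts (retention-time drift, interference)
or between-batch intensity drift. Passing recovery tests therefore show
the *statistics* are implemented correctly at realistic signal strengths,
not that the pipeline is robust to every failure mode of real LC-MS or
genotyping data.

## Numerical choices and degenerate inputs

* A missing heavy standard (area 0) flags the sample rather than
  quantifying to zero; log of a non-positive concentration is `NA` with a
  warning; %CV of a zero-mean or single replicate is `NA` with a warning.
* Rank-deficient design matrices abort naming the collinear columns;
  logistic non-convergence (e.g. perfect separation) aborts rather than
  returning a silent estimate.
* Monomorphic variants are skipped in scans and undefined in LD, with
  messages.
* Quantifier ties (identical mean heavy areas) resolve to the first
  transition id, deterministically.
* The EM for haplotype frequencies starts at independence; with no double
  heterozygotes it converges in one step to the phase-exact answer.

## Problem sizes in the test suite

The simulation-based checks run at the cohort's own scale — 252 controls
for scan-based recovery, 604 individuals for end-to-end runs — with 200
replicates for recovery/coverage claims, 2,000 draws for type-I error
checks, and toy fixtures elsewhere; the complete suite, including the
end-to-end recovery block, completes in a few minutes on one CPU. These
sizes were chosen so Monte-Carlo standard errors are small enough to
detect implementation bias at the magnitudes the pipeline reports, while
staying comfortably interactive.

## Known limitations

* Calibration is single-point isotope dilution; no standard-curve fitting
  beyond that, no raw-file parsing, no peak picking.
* No mixed models, kinship adjustment or genomic-control inflation
  correction in the scans; covariate adjustment only.
* MR is univariable Wald/IVW under a fixed-effect model; MR-Egger,
  weighted-median, multivariable MR, colocalization and stepwise
  conditional instrument selection are out of scope.
* Real-cohort numbers that depend on individual-level data (the published
  association table, GWAS top signals) are not reproducible from summary
  inputs; the package instead demonstrates parameter recovery on synthetic
  cohorts generated at those published magnitudes.
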