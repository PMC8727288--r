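---
title: "Methods: the CLL polygenic risk score pipeline"
author: "cllprs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CLL polygenic risk score pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical machinery in `cllprs`: the score and
its association models, the quality-control and ancestry components, what
the synthetic cohort generator does and does not emulate, and the numerical
and design choices made where the field's conventions leave room.

## The score

The CLL polygenic risk score is the plain weighted sum over a fixed panel of
susceptibility SNPs,
\[
\mathrm{PRS}_i \;=\; \sum_{j=1}^{41} w_j\, g_{ij},
\]
with $g_{ij} \in \{0,1,2\}$ the risk-allele dosage and $w_j$ the published
per-allele log odds ratio. Although such scores are often described as
"weighted averages", the published score scale — a control median near 7.5
and quintile boundaries between 4.3 and 11.3 over 41 SNPs whose individual
log-ORs are all well below 1 — is only consistent with the *sum*: dividing
by the weight total or the SNP count would put the score near 1 or 0.2.
`computePRS()` therefore computes the sum; a `normalize` argument divides by
the panel size for users who want a per-SNP average, but it is off by
default and nothing downstream depends on it. The unweighted score is the
raw risk-allele count.

Missing genotypes are mean-imputed by default as twice the reference control
allele frequency, which keeps every individual scorable and is unbiased
under missingness unrelated to genotype; `complete_only` instead refuses to
score individuals with any missing panel SNP and flags them. The two
policies coincide exactly on complete data (a tested invariant).

## Stratification

Quintile boundaries come from a reference control population — either the
shipped external cutoffs (interior boundaries 6.80, 7.32, 7.77, 8.28 derived
from 7983 consortium controls, `eaReferenceCutoffs()`) or internal controls
(`referenceCutoffs()`). Quantiles use the inverse-empirical-CDF convention
(type-1, no interpolation): the $p$-quantile is the smallest observed value
whose CDF reaches $p$. Bins are left-closed and right-open with open-ended
extremes, so a score equal to a boundary belongs to the upper bin and every
finite score is assignable. This convention is deterministic, reproduces
half-open printed intervals exactly, and makes self-binning of the reference
sample uniform to within one observation per bin (tested). The 99th
percentile flag uses the same convention and is inclusive at the threshold.

## Association models

All binary contrasts are logistic regressions adjusted for age (years) and
sex, fitted by iteratively reweighted least squares with Wald covariance
from the observed information; confidence intervals use $z = 1.959964$
throughout, matching standard 95% reporting. Complete or quasi-complete
separation is detected (fitted probabilities pinned at 0/1 together with
diverging coefficients) and flagged rather than silently penalized — Firth
correction is deliberately out of scope for transparency. Age enters in
years; per-decade odds ratios are obtained by rescaling the coefficient
(`oddsRatioWald(..., scale = 10)`), not by refitting.

The quintile model uses indicator terms for the four non-reference bins with
the middle quintile as reference, so its odds ratio is 1 by construction.
The top-percentile contrast compares flagged individuals with the
middle-quintile group, restricted to those two groups.

Per-SNP models are log-additive (dosage as a single linear term), flagged at
the nominal p < 0.05 with *no* multiple-testing correction, appropriate for
an a-priori panel of established susceptibility loci.

The c-statistic is the Mann–Whitney concordance probability with half
credit for ties, computed from midranks (identical to the $O(n^2)$ pairwise
count, a tested equivalence); its confidence interval uses the
Hanley–McNeil standard error, truncated to [0, 1]. The Hanley–McNeil form
was chosen as the era-appropriate default for this reporting style; DeLong
variance estimation is a natural extension but not required by any output.

### Heterogeneity (trend) across outcome categories

Whether the PRS effect grows from LC-MBL to HC-MBL to CLL is tested by a
likelihood-ratio comparison of two polytomous logits sharing the control
reference: the unconstrained model gives each case category its own PRS
slope; the constrained model forces a single shared slope. Covariate (age,
sex) effects remain category-specific in *both* models, so the test
isolates slope heterogeneity; constraining covariates too would mix
covariate misfit into the trend statistic. The statistic is
$2(\ell_{\text{free}} - \ell_{\text{shared}})$ on (number of case
categories − 1) degrees of freedom. Both models are maximized directly
(BFGS on the exact log-likelihood with analytic gradient, started at zero,
relative tolerance $10^{-12}$); the unconstrained fit is cross-checked
against an independent multinomial implementation in the tests, and with a
single case category both models collapse to the binary logistic fit
(tested to $10^{-6}$).

## Quality control

`qcFilter()` applies, in a fixed order: (1) sample call rate < 0.90
removed, together with precomputed sex-discordance and relatedness flags;
(2) monomorphic variants removed; (3) variant call rate < 0.95 removed;
(4) Hardy–Weinberg exact-test p < $10^{-5}$ removed, computed on retained
samples. Samples are filtered first so that sample-level missingness cannot
distort variant call rates or HWE statistics; all thresholds are strict
inequalities. HWE is tested in controls only when phenotype is available
(configurable to all samples), since true case-control association can
itself distort genotype proportions in cases.

The HWE test is the exact conditional test — the sum of probabilities of
all heterozygote counts no more probable than the observed one, conditional
on the allele counts — built by the standard two-sided recurrence. The
exact test is the field standard for QC because it is well defined at small
expected counts where the 1-df chi-square is anticonservative; the
chi-square variant is provided as an option. The two agree asymptotically
but converge slowly: the tests verify agreement to 0.01 only at very large
sample sizes and rough agreement at cohort-scale sizes.

Allele harmonization matches a file's REF/ALT pair to the panel's
(risk, other) pair in order ("direct" = REF carries the risk allele),
allowing reverse-complement (strand-flip) matches. Palindromic A/T and C/G
pairs cannot be oriented by allele identity; the default policy excludes
them with a report entry — the conservative choice when the file's strand
convention is unknown — and `trust_file` accepts the file's orientation for
pipelines with a known strand convention. The default synthetic panel
avoids palindromic pairs so the demonstration pipeline is not thinned by
this policy.

## Ancestry

Ancestry proportions are estimated by *supervised* admixture: with
reference allele frequencies $f_{kj}$ held fixed, the individual's mixture
$q$ maximizes the binomial likelihood
$\sum_j [g_j \log p_j + (2-g_j)\log(1-p_j)]$, $p_j = \sum_k q_k f_{kj}$,
over the simplex via EM. For fixed frequencies this likelihood is concave
in $q$, so the uniform-simplex start affects only the iteration count and
the result is deterministic. Frequencies are clamped to
$[10^{-6}, 1-10^{-6}]$ to avoid infinite log terms; missing dosages are
skipped (missing-at-random). The log-likelihood is non-decreasing at every
EM step (tested), and estimates are invariant to variant order and to
uninformative sites. Near-pure individuals converge slowly as $q$
approaches the simplex boundary, so the cohort-level wrapper allows more
iterations (5000) than the single-individual default (1000). The default
reference has $K = 3$ populations (EUR, AFR, EAS), a config choice; the
classification rules are African proportion ≥ 50% → AA (inclusive), else
European proportion > 80% → EA (exclusive), else OTHER, with the AA rule
checked first.

The supervised formulation replaces unsupervised joint estimation of
frequencies and mixtures: with an external reference panel fixed, it is the
well-posed desk-scale analog, fully testable against a grid-search oracle.

## The synthetic cohort generator

The generator exists so that every downstream stage has inputs with known
truth. It emulates:

* **Panel**: 41 independent SNPs; per-allele ORs uniform in [1.10, 1.40]
  and European risk-allele frequencies uniform in [0.25, 0.60], chosen once
  so the control score is approximately normal with mean ≈ 7.5 and SD ≈ 1 —
  the scale implied by the published control median and quintile
  boundaries; African-ancestry frequencies are shifted ≈ 0.07 lower,
  matching the reported median European–African frequency difference of
  7.2%.
* **Genotypes**: Hardy–Weinberg draws, dosage ~ Binomial(2, $f$), independent
  across SNPs and individuals.
* **Outcomes**: a multinomial logit against control with category-specific
  intercepts and per-unit PRS slopes; default slopes log(1.75), log(2.14),
  log(2.53) for LC-MBL, HC-MBL, CLL — the published graded effects — plus
  an age effect of log(1.83)/10 per year and a male effect of log(1.73).
  Intercepts are calibrated once, at population-mean PRS/age/sex, to
  prevalences of 5% (LC-MBL), 2% (HC-MBL), 5% (CLL); these are artifact
  choices (true prevalences are unidentifiable from a case-control design)
  that only set the oversampling cost.
* **Sampling design**: case-control with exact group sizes (default: the
  study's 2631/396/164/696), achieved by drawing a candidate pool and
  subsampling assigned categories, growing the pool geometrically up to a
  100× cap — matching the study's design, where all contrasts are
  case-control.
* **Covariates**: age from a truncated normal (mean 64, SD 10, range
  30–100 years); sex Bernoulli with a 45% male source population, so that
  the injected effects reproduce the observed case-control covariate
  imbalances rather than hard-coding them.
* **Artifacts**: per-variant and per-sample missingness, exact duplicates
  with a controllable discordance rate, forced-monomorphic variants, and
  Hardy–Weinberg violations parameterized by an inbreeding-like coefficient
  $F$ with $P(\text{het}) = 2f(1-f)(1-F)$ — a single sign-controllable knob
  for heterozygote deficit or excess.

It deliberately does **not** emulate linkage disequilibrium, haplotypes,
genotyping intensities, or relatedness beyond exact duplicates. Two
consequences matter for interpreting green tests. First, passing tests show
the *analysis machinery* is correct under the assumed generative model, not
that real genotype data meet those assumptions. Second, with no LD the
weighted PRS is the true linear predictor, so the per-unit continuous OR is
invariant to allele frequencies; the cross-ancestry attenuation that lower
allele frequencies genuinely produce — and that the package's property
tests assert — appears in the score *variance*, hence in quintile-contrast
odds ratios and in the c-statistic. Real-data attenuation of the per-unit
OR additionally involves population differences in LD tagging, which is out
of scope here. Relatedly, the acceptance simulation of the
African-American arm injects no age or sex effects, since the published AA
demographics show cases and controls matched on both.

Reproducibility: one global integer seed; each operation derives a
deterministic substream from it, so whole-pipeline outputs are bit-identical
across runs at fixed config (tested at the byte level).

## Numerical choices and degenerate inputs

* Logistic IRLS: convergence tolerance $10^{-10}$, 100-iteration cap;
  aliased (collinear) columns yield NA coefficients with NA variance rows
  rather than errors.
* Multinomial BFGS: relative tolerance $10^{-12}$, zero start, analytic
  gradient, covariance from the numeric Hessian at the optimum; the LRT is
  floored at 0 against roundoff.
* HWE recurrence starts near the conditional mode and normalizes at the
  end, stable for the sample sizes QC sees; ties in the probability
  ordering are included using a $1 + 10^{-12}$ relative guard.
* 2×2 tables: odds ratio by cross-product with Woolf CI; zero cells make
  the OR non-estimable unless the Haldane–Anscombe 0.5 correction is
  explicitly requested — estimates are never silently modified. Fisher's
  exact p is always available.
* Kruskal–Wallis with all-identical values returns H = 0, p = 1 rather
  than erroring.
* Degenerate association inputs (constant outcome, empty quantile bins,
  monomorphic variants, single-level exposures) produce flagged NA rows,
  not errors, so batch reports survive pathological cells.
* Exposure screening is complete-case *per exposure*; denominators are
  reported because they differ under missingness.

## Problem sizes

The test suite runs cohorts of a few hundred to a few thousand individuals
with replicate counts chosen to keep the full suite under a few minutes:
oracle equivalences are exact so small sizes suffice; calibration checks
(Wald coverage in 93–97% over 500 replicates, heterogeneity null rejection
near 5% over 400 seeds) use the smallest sizes at which the asymptotics are
trustworthy. The acceptance script uses the study's actual group sizes with
5–10 replicates per arm, which bounds Monte-Carlo error on recovered log-ORs
at roughly ±3%.

## Known limitations

* No LD-aware scoring, shrinkage re-weighting, or genome-wide scoring
  beyond a provided panel.
* No genetic inference of sex or kinship: sex-discordance and relatedness
  removals are accepted as precomputed flags.
* No exact logistic regression or Firth correction; separation is flagged,
  not repaired.
* The heterogeneity test's default leaves covariate effects
  category-specific; a fully-constrained variant can be fitted through
  `fitMultinomial()`'s `sharedCols` but is not the reporting default.
* Imputation to reference panels, genotype calling, and flow-cytometry
  phenotyping are entirely out of scope; phenotype categories are inputs.
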