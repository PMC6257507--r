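---
title: "Two-sample Mendelian randomization for iron status and stroke: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization for iron status and stroke: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The causal question and the instrumental-variable model

Observational associations between systemic iron status and stroke risk are
contradictory, in part because iron biomarkers respond to inflammation and
diet. Mendelian randomization (MR) sidesteps this confounding by using
genetic variants as instruments: a variant that changes iron status, is
allocated at conception independently of lifestyle, and affects stroke only
through iron status, identifies the causal effect.

`ironmr` implements the two-sample summary-statistic form of this design.
For variant $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its association
with an iron biomarker in SD units from one GWAS, and $\hat\beta_{Yj}$
(SE $\sigma_{Yj}$) its log-odds association with stroke from an independent
case-control GWAS. Each variant gives a Wald ratio

$$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj},$$

and the main estimate pools these by fixed-effect inverse-variance
weighting (IVW):

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j}, \qquad
  w_j = 1/\mathrm{se}(\hat\theta_j)^2, \qquad
  \mathrm{se}(\hat\theta) = 1\Big/\sqrt{\sum_j w_j}.$$

With first-order delta SEs this is algebraically the weighted
least-squares slope of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
origin — an identity the test suite checks against an explicit
normal-equations solve. Estimates are reported as odds ratios of stroke
per SD-unit increase of the biomarker, $\mathrm{OR} = e^{\hat\theta}$.

The fixed-effect model assumes all instruments estimate one common effect;
heterogeneity beyond sampling noise (for example from pleiotropy) violates
it, which is why the sensitivity estimators below exist.

## Instrument selection from four biomarkers

Systemic iron status has no single assay; serum iron, (log) ferritin and
transferrin saturation rise with it while transferrin falls. An instrument
for *systemic* iron status should therefore move all four biomarkers in
that concordant pattern. `select_instruments()` implements two rules over
the four biomarker GWAS tables:

* **strict** — genome-wide significance ($p < 5\times10^{-8}$) in *all
  four* biomarkers with the concordant direction pattern. On the bundled
  fixture this yields the classic trio rs1800562, rs1799945 (both *HFE*)
  and rs855791 (*TMPRSS6*).
* **relaxed** — genome-wide significance in *at least one* biomarker and
  direction concordance (at any $p$) in the rest, adding rs9990333
  (*TFRC*), rs7385804 (*TFR2*) and rs411988 (*TEX14*) for six instruments.
  The larger set trades instrument validity for the degrees of freedom the
  sensitivity estimators need.

All selected instruments are re-oriented so the effect allele is the
iron-*increasing* allele; under that allele transferrin's exposure beta is
negative, so a protective transferrin odds ratio (< 1) is the same
biological signal as a harmful serum-iron odds ratio (> 1).

Instrument strength is summarized by the first-stage statistic
$F = (R^2/k) \,/\, [(1-R^2)/(n-k-1)]$ via `f_statistic()`; values far
above 10 make weak-instrument bias negligible.

## Harmonization and proxies

The two GWAS may report the same variant on different strands or with
effect/other alleles interchanged. `harmonize()` aligns each pair to the
exposure's effect allele: a pure label swap negates the outcome beta;
non-palindromic strand complements are resolved silently. Palindromic
variants (A/T, C/G) are genuinely ambiguous, and the source consortia's
strand conventions are not recoverable, so the package makes an explicit
policy choice:

* default `"frequency"` policy: keep the pair only when both effect-allele
  frequencies are available and both fall outside the ambiguous band on
  the same side of 0.5 (both < 0.42 or both > 0.58), in which case the
  labelled orientation is trusted; otherwise drop the variant with a
  warning;
* `"drop"` policy: never use palindromic variants.

The 0.42 band edge is the conventional two-sample MR choice: inside it,
minor/major status cannot distinguish strands reliably. A variant with a
missing frequency is dropped, never guessed.

A variant absent from an outcome dataset may be replaced by a proxy in
linkage disequilibrium with it. `find_proxy()` requires $r^2$ *strictly*
greater than 0.3 (the threshold is a strict inequality by design), takes
the highest-$r^2$ qualifying candidate, and breaks exact ties by the
lexicographically smallest rsID so results never depend on input order.
LD values are consumed from a user-supplied table; the package does not
estimate LD from genotype panels.

## Sensitivity estimators

**MR-Egger** (`egger_regression()`) regresses $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ with weights $1/\sigma_{Yj}^2$ and an *unconstrained*
intercept, after re-orienting every instrument to $\hat\beta_{Xj} > 0$.
Under the InSIDE assumption the slope is a pleiotropy-adjusted causal
estimate and the intercept estimates average directional pleiotropy; the
intercept's test is the directional-pleiotropy test. Numerical choices:

* SEs use a multiplicative random-effects scale $\sigma = \max(1,
  \hat\sigma)$, where $\hat\sigma$ is the weighted residual standard
  error: over-dispersion inflates the SEs, under-dispersion is never
  allowed to shrink them. The unscaled coefficient covariance
  $(X^\top W X)^{-1}$ is computed directly so an exact (zero-residual) fit
  still yields finite SEs.
* With only 3–6 instruments the normal approximation is poor, so p-values
  and CIs use the $t$ distribution with $k-2$ degrees of freedom.
* Fewer than 3 instruments is an error: two points fit a line exactly and
  admit no test.

**Weighted median** (`weighted_median()`) pools the per-variant ratios by
the weighted median with inverse-variance weights, which is consistent
whenever valid instruments carry more than half the total weight — up to
just under half the instruments may be arbitrarily invalid. The estimator
sorts the ratios, assigns standardized mid-cumulative weights
$s_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$, and interpolates linearly
to $s = 0.5$, clamping at the extreme ratios; at equal weights this is the
ordinary interpolated median. Its SE is the standard deviation of the
estimate over parametric-bootstrap replicates (default 10,000, minimum
1,000) that re-draw each beta pair from its normal sampling distribution;
the seed is mandatory so the SE is reproducible. Simple inverse-variance
weights are used rather than a penalized variant, matching the plainest
form of the estimator.

**Delta order.** The Wald-ratio SE can be taken to first order
($\sigma_{Yj}/|\hat\beta_{Xj}|$) or second order (adding
$\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$). The methodological
literature supports both and the original analysis's order is not
recoverable, so the package defaults to the more conservative second
order and exposes `order = "first"` everywhere; the per-ratio SEs inside
the weighted median follow the same order for consistency. The suite
verifies the second-order SE against a $10^6$-draw Monte-Carlo SD of the
ratio distribution.

A `|bx|/sex < 1` denominator triggers a weak-instrument warning but the
variant is still used — dropping post hoc would change the estimand.
Significance is uncorrected $p < 0.05$ throughout: the four biomarkers
probe the same exposure and the subtype analyses only validate the main
one, so no multiplicity adjustment is applied anywhere.

## The synthetic-data generator

`simulate_summary_stats()` generates summary statistics directly at the
summary level: for each variant it draws a minor-allele frequency, a true
exposure effect $b_{Xj} \sim N(\mu_b, \sigma_b^2)$, a direct (pleiotropic)
outcome effect $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ on a
configurable subset of variants, sets the true outcome effect
$\theta b_{Xj} + \alpha_j$, and adds sampling noise with the
standardized-genotype SEs $1/\sqrt{2p(1-p)N}$ (exposure) and
$1/\sqrt{2p(1-p)\,N_1N_0/(N_1+N_0)}$ (case-control outcome). Allele pairs
are random, optionally palindromic, and outcome labels are randomly
swapped so harmonization is always exercised end to end.

Defaults are fixed at the study's scale and are not tuning knobs: exposure
GWAS $N$ = 48,972; outcome GWAS 67,162 cases / 454,450 controls; six
instruments; $\mu_b = 0.2$, $\sigma_b = 0.05$ SD per allele (per-variant
first-stage $F$ in the hundreds, matching the strong-instrument regime of
the real trio, whose $F$ ranged roughly 47–2100); MAF uniform on
(0.05, 0.5). `scenario()` packages the validation settings: `null`
($\theta = 0$), `causal` ($\theta = 0.1$, chosen as the magnitude of the
reported any-stroke effect), `balanced_pleiotropy`
($\mu_\alpha = 0,\ \sigma_\alpha = 0.02$), `directional_pleiotropy`
($\mu_\alpha = 0.02,\ \sigma_\alpha = 0.01$ — about a fifth of the causal
signal, enough to bias IVW visibly without drowning it), and
`half_invalid` ($\mu_\alpha = 0.05$ on exactly
$\lceil n/2 \rceil - 1$ variants, so the weighted-median validity
condition still holds). `simulate_study()` extends this to the full
pipeline input: four biomarker tables sharing latent effects with signs
(+, +, +, −) and any number of independent outcome tables.

What the generator deliberately does **not** emulate: LD between
instruments, sample overlap between the two GWAS, population
stratification, allele-frequency differences between studies, winner's
curse in instrument discovery, and nonlinear exposure–outcome
relationships. Passing simulation tests therefore demonstrates estimator
correctness under the stated model, not robustness to those features of
real data.

## Validation design and problem sizes

The suite validates three layers, at sizes chosen to give tight
Monte-Carlo error at desk scale: exact oracles (normal-equations solves,
a 4-million-point grid percentile search, a $10^6$-draw Monte-Carlo ratio
SD) for the estimator algebra; 1,000-replicate recovery and type-I-error
studies (mean IVW within 2 Monte-Carlo SEs of $\theta$, 95% CI coverage
in 93–97%, rejection rate in 3–7%); and 500-replicate bias-ordering
studies under directional pleiotropy (|IVW bias| > |Egger slope bias|,
positive mean intercept) and under a minority of invalid instruments
(|weighted-median bias| < |IVW bias|). `scripts/acceptance.R` recomputes
all of these from scratch at the same sizes.

Reproducing the published odds ratios themselves requires the public
consortium summary downloads (the per-variant stroke betas are not
redistributable here); the corresponding check runs whenever those files
are placed under `tests/testthat/real_data/` and otherwise reports their
absence. The bundled `gis_synthetic_*.tsv` fixture is a synthetic
stand-in whose significance/direction *pattern* — not its numbers —
matches the published instrument selection.

## Known limitations

* Fixed-effect IVW only; no random-effects variant or Cochran's Q beyond
  what the Egger $\sigma$ absorbs.
* No MR-PRESSO, mode-based, or multivariable estimators. Multivariable
  adjustment (e.g. for blood pressure) is deliberately out of scope: with
  3–6 instruments and covariate-adjusted published GWAS it would be
  unreliable.
* Proxy lookup assumes the supplied candidate shares the target's allele
  coding; allele mapping through LD-phase information is not implemented,
  and incompatible proxies are dropped with a log entry.
* MR estimates lifetime effects of genetically determined iron status;
  they do not extrapolate to acute or extreme exposure changes.
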