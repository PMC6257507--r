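# ironmr

Two-sample Mendelian randomization (MR) of systemic iron status on stroke
risk, packaged as a reusable, tested pipeline for anyone analysing GWAS
summary statistics with genetic instruments: instrument selection across
the four iron biomarkers, allele harmonization, Wald-ratio/IVW estimation,
instrument-strength F statistics, and MR-Egger / weighted-median
sensitivity analyses — plus a summary-level simulator with known causal
truth so every estimator is validated end to end without any downloads.

## The model

For variant *j*, with exposure association β̂<sub>Xj</sub> (SD units of an
iron biomarker, SE σ<sub>Xj</sub>) and outcome association β̂<sub>Yj</sub>
(log-odds of stroke, SE σ<sub>Yj</sub>) from two independent GWAS:

* per-variant Wald ratio: θ̂<sub>j</sub> = β̂<sub>Yj</sub> / β̂<sub>Xj</sub>,
  with a delta-method SE (first-order σ<sub>Yj</sub>/|β̂<sub>Xj</sub>|, or
  the default second order adding the exposure-noise term);
* fixed-effect IVW pool: θ̂ = Σw<sub>j</sub>θ̂<sub>j</sub> / Σw<sub>j</sub>,
  w<sub>j</sub> = 1/se(θ̂<sub>j</sub>)², se(θ̂) = 1/√Σw<sub>j</sub>,
  reported as OR = e<sup>θ̂</sup> per SD-unit increase of the biomarker;
* instrument strength: F = (R²/k) / [(1−R²)/(n−k−1)];
* MR-Egger: weighted regression of β̂<sub>Yj</sub> on β̂<sub>Xj</sub> with a
  free intercept (average directional pleiotropy), multiplicative
  random-effects scale σ = max(1, σ̂), t-based inference on k−2 df;
* weighted median of the ratios at inverse-variance weights, with a
  parametric-bootstrap SE — consistent while valid instruments hold >50%
  of the weight.

Instruments are selected for *systemic* iron status by concordance:
genome-wide significance (p < 5×10⁻⁸) in all four biomarkers — serum
iron, log-ferritin and transferrin saturation up, transferrin down —
(strict mode, 3 variants) or in at least one biomarker with concordant
directions in the rest (relaxed mode, 6 variants), all oriented to the
iron-increasing allele. Variants missing from an outcome dataset can be
replaced by an LD proxy with r² strictly > 0.3.

See `vignettes/iron-stroke-mr.Rmd` for the full methods account.

## Worked example

Select instruments from the bundled synthetic biomarker fixture (a
stand-in table whose significance/direction pattern reproduces the real
selection), then run a fully synthetic study with known causal effect
θ = 0.1:

```r
library(ironmr)

tabs <- lapply(names(gis_synthetic_paths()), function(bm)
  read_gwas_summary(gis_synthetic_paths()[[bm]], trait = bm))
names(tabs) <- names(gis_synthetic_paths())
select_instruments(tabs, mode = "strict")[
  , c("snp", "effect_allele", "beta_iron", "beta_transferrin")]
#>         snp effect_allele beta_iron beta_transferrin
#> 1 rs1799945             G     0.189           -0.114
#> 2 rs1800562             A     0.328           -0.479
#> 3  rs855791             G     0.181           -0.046

study <- simulate_study(simulation_config(theta = 0.1, seed = 2026),
                        outcomes = "any_stroke")
res <- run_study(run_config(study$exposures, study$outcomes,
                            mode = "both", seed = 2026, n_boot = 2000))
subset(res$results, method == "ivw" & mode == "strict",
       c(exposure, n_snps, odds_ratio, or_ci_low, or_ci_high, pvalue))
#>      exposure n_snps odds_ratio or_ci_low or_ci_high   pvalue
#> 1        iron      5      1.072     1.034      1.110 0.000127
#> 2    ferritin      5      1.072     1.034      1.112 0.000152
#> 3  saturation      5      1.070     1.033      1.107 0.000132
#> 4 transferrin      5      0.932     0.899      0.966 0.000120
```

Each row is the pooled causal odds ratio of stroke per SD-unit increase
of one biomarker: the three iron-raising biomarkers show OR ≈ e^0.07 ≈
1.07 (the simulation's true θ = 0.1 attenuated only by sampling noise;
each CI covers e^0.1) and transferrin, which falls as iron status rises,
mirrors it below 1. Only 5 of the 6 simulated variants pass the strict
four-biomarker filter in this draw — one true effect lands below
genome-wide significance in one biomarker, exactly as happens with real
consortium data. The relaxed 6-variant set powers the sensitivity
estimators:

```r
subset(res$results, exposure == "iron" & mode == "relaxed",
       c(method, n_snps, beta, se, pvalue))
#>            method n_snps    beta     se   pvalue
#> 5             ivw      6  0.0711 0.0180 7.75e-05
#> 6     egger_slope      6 -0.0200 0.0709 7.92e-01
#> 7 egger_intercept      6  0.0157 0.0118 2.54e-01
#> 8 weighted_median      6  0.0651 0.0214 2.30e-03
```

The Egger intercept's p = 0.25 gives no evidence of directional
pleiotropy (correct — none was simulated), and the weighted median agrees
with IVW; the Egger slope's wide SE shows the usual power cost with six
instruments. `f_statistic(0.02, 1, 48972)` returns `999.4`, far above the
weak-instrument rule of thumb of 10.

A thin CLI wraps the same functions
(`inst/cli/ironmr run|simulate|estimate`), and `run_study()` writes a
results TSV, a per-variant forest-plot TSV, a JSON manifest and a
decision log when given an `output_dir`.

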