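# ratedecomp

Why did the age-standardized burden of a disease change between two points
in time — because populations' risk-factor exposures changed, or because the
association between those exposures and the outcome changed? `ratedecomp`
answers this for panels of age-standardized incidence, mortality, or DALY
rates (the kind of per-100,000 extracts the Global Burden of Disease results
tool produces), using a non-linear multivariate decomposition of the
Blinder–Oaxaca family for the log-link Poisson model.

It is aimed at epidemiologists and biostatisticians doing descriptive
burden-of-disease analysis across countries and decades, and at anyone who
needs a tested, scriptable implementation of the endowment/coefficient split
with per-covariate attribution outside of Stata.

## The method

Each period's rates are modelled as `Y = F(Xβ)` with `F = exp`: a
quasi-Poisson (log-link) regression of the rate on risk-factor exposures
(summary exposure values, 0–100) and a development index (0–1), fitted
separately to the comparison year (1990) and the reference year (2019). The
difference in mean rates then splits exactly into two counterfactual parts:

    E = mean F(X₂₀₁₉ β₂₀₁₉) − mean F(X₁₉₉₀ β₂₀₁₉)   (endowments: covariate change)
    C = mean F(X₁₉₉₀ β₂₀₁₉) − mean F(X₁₉₉₀ β₁₉₉₀)   (coefficients: association change)

Because the Poisson score equations force each fitted mean to equal its
observed mean, `E + C` telescopes to the observed difference of mean rates.
Each component is attributed to individual covariates by the normalized
weight linearization

    W_ΔXₖ = β₂₀₁₉,ₖ (X̄₂₀₁₉,ₖ − X̄₁₉₉₀,ₖ) / Σⱼ β₂₀₁₉,ⱼ (X̄₂₀₁₉,ⱼ − X̄₁₉₉₀,ⱼ)
    W_Δβₖ = X̄₂₀₁₉,ₖ (β₂₀₁₉,ₖ − β₁₉₉₀,ₖ) / Σⱼ X̄₂₀₁₉,ⱼ (β₂₀₁₉,ⱼ − β₁₉₉₀,ⱼ)

which sums to one in each direction and does not depend on the order in
which covariates enter the model. Uncertainty comes from an
influence-function delta method (default) or a within-period location
bootstrap. See `vignette` source `vignettes/decomposition-methods.Rmd` for
the full account.

## Worked example

The built-in generator emulates a GBD-like two-period panel (200 locations,
SEV-scale risk factors, an SDI-like index moving 0.48 → 0.64, rates rising
from about 2.9 to 4.4 per 100,000):

```r
library(ratedecomp)

panel <- generate_panel(gbd_like_spec(), seed = 42)
res <- decompose(panel, reference_year = 2019, comparison_year = 1990)
res
#> Non-linear multivariate decomposition of mean rate difference
#>   Reference 2019 (mean 4.41) vs comparison 1990 (mean 2.96)
#>   Endowments      1.36  [1.03, 1.69]  p=<0.001   94.09%
#>   Coefficients    0.09  [-0.15, 0.33]  p=0.49    5.91%
#>   Difference      1.45  [1.11, 1.79]  p=<0.001
#>   Inference: delta
```

The mean rate rose by 1.45 per 100,000; 94% of that rise is explained by
where the covariate distributions moved (endowments), and the remaining 6%
by changes in the covariate–rate associations — here not statistically
distinguishable from zero. The per-covariate attribution:

```r
decomposition_detail(res)[, c("term", "weight_E", "E_k", "C_k", "pct_Ek", "p_Ek")]
#>          term weight_E     E_k     C_k pct_Ek     p_Ek
#> 1 (Intercept)   0.0000  0.0000 -0.2742   0.00 1.00e+00
#> 2 alcohol_use   0.0904  0.1233 -0.0223   8.51 1.43e-02
#> 3    high_bmi   0.4091  0.5578  0.0788  38.49 3.10e-10
#> 4         sdi   0.5331  0.7270  0.1896  50.16 2.86e-12
#> 5     smoking  -0.0326 -0.0444  0.1138  -3.07 3.20e-01
```

Rising BMI-like exposure alone accounts for 38% of the rate increase
(`E_k = 0.56` of the 1.45 total), the development-index shift for 50%.
Adjusted effects come from the per-period fits as rate ratios per unit of
exposure:

```r
rate_ratios(res$fits$reference)
#>     covariate rate_ratio ci_low ci_high   p_value
#> 1 alcohol_use      1.017  1.012   1.023 4.630e-09
#> 2    high_bmi      1.018  1.013   1.023 4.610e-14
#> 3         sdi      3.325  2.586   4.275 7.259e-21
#> 4     smoking      1.013  1.008   1.018 1.980e-08
```

Real GBD extracts go through `read_gbd_csv()` + `build_panel()`, or the
whole pipeline via a YAML config:

```r
cfg <- run_config(
  mode = "real", out_dir = "out",
  measures = list(ASIR = "asir.csv", ASMR = "asmr.csv", ASDR = "asdr.csv"),
  covariates = list(high_bmi = "bmi_sev.csv", alcohol_use = "alc_sev.csv",
                    sdi = "sdi.csv"),
  covariate_ranges = list(high_bmi = c(0, 100), alcohol_use = c(0, 100),
                          sdi = c(0, 1)),
  sdi_covariate = "sdi", inference = "delta", seed = 1
)
run_pipeline(cfg)
```

which writes `decomposition_overall.csv` (the familiar
Endowments/Coefficients/Mean-difference table per measure, for the
risk-factors-only and the +SDI model), `decomposition_detail.csv`,
per-measure delta-change and covariate-summary tables, adjusted-effects
tables, and a run log. A thin CLI wrapper lives at
`inst/scripts/decomp.R` (`run`, `simulate`, `decompose` subcommands).

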