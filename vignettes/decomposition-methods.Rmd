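---
title: "Decomposing changes in disease-burden rates: model, inference, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing changes in disease-burden rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratedecomp)
```

## The question and the model

Between two time points, the mean age-standardized rate of a disease across
locations changes. Two mechanisms can drive that change: the distribution of
risk-factor exposures across locations can move (people become heavier,
richer, smoke less), or the association between exposures and the rate can
move (the same exposure profile now maps to a different rate). `ratedecomp`
separates the two.

Each period's rates are modelled with a log-link Poisson-family mean,

$$ E[Y \mid x] = \exp(x\beta), $$

fitted separately per period. The outcome is a non-negative rate per
100,000, not a count, so the fit is quasi-Poisson: the score equations are
those of the Poisson likelihood, valid for any non-negative outcome, and a
Pearson-based dispersion scales the coefficient covariance. The choice of
dispersion mode (`"pearson"`, the default, or `"fixed"` at 1) affects
standard errors only, never point estimates; both are available because the
convention differs between software implementations of this analysis.

No exposure offset is used: the rate itself is the outcome, equivalent to an
offset of $\log R = 0$, i.e. $R \equiv 1$. The offset argument remains in
the fitting engine for generality but the pipeline fixes it to zero.

Rates are analyzed on the scale on which they are published (per 100,000),
and means across locations are unweighted — each location counts once,
which is the convention of cross-country burden comparisons, not a
population-weighted global rate. Coefficients are therefore interpretable as
log rate ratios per unit of exposure (per SEV point, per SDI unit).

## The decomposition

Write $\bar F(X\beta)$ for the average of $\exp(x_i\beta)$ over the
locations of a given period. With the later period (2019) as the
*reference* group and the earlier (1990) as the *comparison* group, the
difference in mean rates splits as

$$
\bar Y_{2019} - \bar Y_{1990}
 = \underbrace{\bar F(X_{2019}\beta_{2019}) - \bar F(X_{1990}\beta_{2019})}_{E
   \text{ (endowments, explained)}}
 + \underbrace{\bar F(X_{1990}\beta_{2019}) - \bar F(X_{1990}\beta_{1990})}_{C
   \text{ (coefficients, unexplained)}}.
$$

$E$ asks: holding 2019's associations fixed, how much of the difference is
due to the covariate distribution moving from its 1990 to its 2019 state?
$C$ asks: holding the 1990 covariate distribution fixed, how much is due to
the associations changing? The identity is exact, not approximate: the
Poisson score equations force $\bar F(X\hat\beta) = \bar Y$ within each
period (mean matching), so the two interior counterfactual terms telescope.
The package asserts this additivity to $10^{-8}$ relative on every fit.

Counterfactual means are always averages of row-level predictions, never a
prediction at the mean covariate vector: with a convex $F$ the two differ,
and only the former telescopes exactly.

The asymmetry of the split (reference-year coefficients in $E$,
comparison-year covariates in $C$) is inherent to two-way decompositions.
`run_pipeline()` offers a `reverse` diagnostic that exchanges the group
roles so the sensitivity of conclusions to the convention can be quantified;
the default follows the 2019-reference convention.

### Per-covariate attribution

Each component is linearized over covariates with normalized weights

$$
W_{\Delta X_k} = \frac{\beta_{2019,k}(\bar X_{2019,k} - \bar X_{1990,k})}
  {\sum_j \beta_{2019,j}(\bar X_{2019,j} - \bar X_{1990,j})},\qquad
W_{\Delta\beta_k} = \frac{\bar X_{2019,k}(\beta_{2019,k} - \beta_{1990,k})}
  {\sum_j \bar X_{2019,j}(\beta_{2019,j} - \beta_{1990,j})},
$$

with $E_k = W_{\Delta X_k} E$ and $C_k = W_{\Delta\beta_k} C$. Both weight
sets sum to one by construction, so $\sum_k E_k = E$ and $\sum_k C_k = C$
hold to floating-point accuracy, and — unlike sequential-substitution
detailed decompositions — the attribution is invariant to the order in which
covariates enter the model. The intercept has mean value 1 in both periods:
it contributes nothing to the endowment weights (its covariate difference is
zero) and enters the coefficient weights like any other term; its $C_k$ line
is reported rather than hidden, since a shift in the baseline rate is a real
part of the unexplained component.

Two numerical guards apply. If a weight denominator is smaller than
$10^{-12}$ relative to its term magnitudes the decomposition direction is
degenerate (e.g. two identical periods) and `detailed_weights()` refuses
rather than divide; `decompose()` then reports the overall split with the
detail marked `NA`. If $|E + C|$ is indistinguishable from zero, the
percentage shares are undefined and flagged (`degenerate_percentages`)
instead of divided. Percentages are never clipped: when $E$ and $C$ have
opposite signs, shares above 100% and below 0% are legitimate and reported
as computed.

## Inference

The sampling unit is the location. Two methods are provided.

**Influence-function delta method (default).** Every reported quantity is a
smooth function of the two coefficient vectors and the two empirical
distributions. Each location contributes (a) its influence on its period's
coefficient estimate, $n\,(X^TWX)^{-1}x_i(y_i - \hat\mu_i)$ — the empirical
(sandwich) form, so overdispersion is automatically absorbed — mapped
through the coefficient-gradient of the decomposition, and (b) its direct
influence on the empirical counterfactual means and covariate means at
fixed coefficients. Variances are sums of squared per-location influences,
independent across periods. Gradients are evaluated by central differences
(`pracma::jacobian`) of the exact decomposition map, which is cheap,
deterministic, and avoids transcribing long analytic derivatives. This
estimator targets the same variance as resampling locations, and on the
default synthetic conditions agrees with a 2,000-replicate bootstrap within
a few percent.

A pure fixed-covariate propagation (only the model-based coefficient
covariances, covariates treated as constants) is available as
`design_variation = FALSE`. It answers a narrower question — uncertainty in
the coefficients only — and materially understates the variability of $E$
whenever the covariate-distribution sampling matters, which is why it is not
the default.

**Location bootstrap.** Locations are resampled with replacement
independently within each period, the entire decomposition (both fits,
all components) is recomputed per replicate, and percentile 95% intervals
plus bootstrap-SE normal p-values are reported. Replicates with a
non-convergent fit or a degenerate weight direction are dropped and counted;
more than 10% dropped aborts. The bootstrap is the reference standard here
but note one caveat: per-covariate $C_k$ values are ratios whose denominator
$\sum_j \bar X_j \Delta\beta_j$ can pass near zero in replicates when the
true coefficient drift is weak, making their bootstrap SD heavy-tailed and
much larger than the linearized SE; the overall $E$, $C$ and total SEs are
unaffected. The delta method is the default for this reason as well as for
speed and determinism.

CIs use the conventional Wald multiplier 1.96; rate ratios from
`rate_ratios()` are $\exp(\hat\beta_k \pm 1.96\,se_k)$ with two-sided normal
p-values.

## Fitting engine

The IRLS engine initializes all slopes at zero and the intercept at
$\log(\bar y + 10^{-8})$, iterates weighted least squares with weights
$\mu$, and stops when the relative deviance change falls below $10^{-10}$
(at most 100 iterations; non-convergence is a warning on the fit and a hard
error inside `decompose()`). The linear predictor is capped at 700 to avoid
overflow of $\exp$ during early iterations. Rank-deficient designs are
rejected up front with the collinear columns named. Outcome zeros are
allowed (their deviance terms vanish). The engine is validated against an
independent reference GLM implementation to $10^{-6}$ relative on random
fixtures, and against closed forms (intercept-only, single binary
covariate) to $10^{-8}$.

## Data ingest conventions

GBD results-tool CSVs vary across portal versions, so column names are
matched case-insensitively through an alias table (`location` /
`location_name`, `val` / `value`, ...). Rows default to both-sex,
age-standardized entries when those columns exist, matching an analysis of
age-standardized both-population rates; the filters are configurable because
extract queries differ. Values that fail numeric parsing are dropped with a
counted warning; a missing mandatory column is a hard error naming the
column.

Panel assembly is strictly complete-case across both years: a location
missing the outcome or any covariate in either year is excluded from both,
because the decomposition must compare the same covariate set across
periods; exclusions are logged. Covariate values outside their declared
range (SEV outside [0, 100], SDI outside [0, 1]) are rejected, never
clamped — a range violation signals an upstream extract problem that silent
correction would hide. Panels round-trip through CSV bit-exactly (numerics
are serialized at 17 significant digits and parsed by correctly-rounded
`strtod`).

## The synthetic generator and what it does (not) emulate

`gbd_like_spec()` defines the default validation conditions: 200 locations;
three SEV-scale exposures (truncated normal on [0, 100]) whose
between-period standardized mean differences span roughly 0.1–1.0, the
largest being the BMI-like exposure; an SDI-like index on [0, 1] moving
0.48 → 0.64; coefficients of realistic size (rate ratios near 1.02 per SEV
point) with a small between-period drift; multiplicative log-normal noise
with $\sigma = 0.3$, a typical residual between-country heterogeneity after
conditioning on exposures. The implied mean rates are about 2.9 rising to
4.4 per 100,000, with most of the rise attributable to the covariate shift
— the signal regime of a global kidney-cancer-like analysis.

Deliberate simplifications: covariates are drawn independently (no
cross-exposure correlation), independently across periods (no
location-level autocorrelation), and noise is i.i.d. Passing tests
therefore demonstrate correctness of the estimator and its inference under
the stated model, not robustness to correlated exposures, spatial
structure, or shared GBD estimation error across locations — caveats that
apply equally to the real analysis.

`ground_truth()` computes oracle $E$ and $C$ by Monte-Carlo integration of
the four counterfactual mean terms over the spec's covariate distributions
using the *true* coefficient vectors (no fitting; $\ge 10^5$ draws). One
subtlety: with multiplicative log-normal noise the conditional mean is
$E[Y\mid x] = \exp(x\beta)\,e^{\sigma^2/2}$, and the quasi-Poisson fit
consistently estimates that conditional mean (the intercept absorbs
$\sigma^2/2$). The oracle therefore includes the factor $e^{\sigma^2/2}$;
without it, the "truth" would be systematically below what any consistent
estimator of the mean-rate decomposition converges to. In Poisson-count
mode the analogous factor is the 100,000 rate scale.

`recovery_spec()` provides the two single-source-of-change diagnostics:
means-shift-only (equal coefficient vectors; the endowment share must
approach 100%) and coefficients-shift-only (equal covariate distributions;
the coefficient share must approach 100%). The coefficient shift in the
latter is sized so the total difference is well away from zero
(intercept +0.35, small slope increases): the percentage share is a ratio,
and with a weak shift its denominator is dominated by sampling noise, which
would test numerical conditioning rather than estimator correctness. With
these sizes the recovered shares sit within about 1–3 points of 100 at
n = 10,000.

## Validation problem sizes

The shipped test-suite exercises: additivity and weight normalization on 50
random 5-covariate panels of 200 locations; a literal-transcription oracle
of the counterfactual means and weight formulas at $10^{-10}$; closed-form
and reference-GLM checks of the engine; recovery on the two
single-source specs at n = 10,000 (±3 points of 100%); estimator-vs-truth
agreement over 20 seeds of the default spec against a $2\times 10^5$-draw
Monte-Carlo oracle (within 3 combined standard errors); delta-vs-bootstrap
SE agreement (2,000 replicates, within 25%); and an end-to-end run of the
pipeline on a GBD-layout synthetic extract checking the overall-table
structure and cross-file additivity. These sizes keep the full suite under
a minute of compute apart from the bootstrap comparison, while leaving the
Monte-Carlo error well below the tolerances they assert.

## Known limitations

- Two-way decomposition only: no third interaction term for simultaneous
  endowment-and-coefficient change; the split's asymmetry is quantified via
  the reverse diagnostic, not removed.
- No age-period-cohort adjustment; the unit is the location-period.
- Ecological analysis: location-level associations need not hold within
  locations.
- The per-covariate bootstrap SEs of $C_k$ are unstable when coefficient
  drift is weak (see Inference); prefer the delta method for detail-level
  uncertainty.
- The generator's independence assumptions understate the collinearity of
  real exposure panels; rank-deficiency is detected, but near-collinearity
  in real extracts will widen detail-level uncertainty in ways the default
  synthetic conditions do not probe.
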