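---
title: "Methods: trait allocation, response curves and tipping-point detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait allocation, response curves and tipping-point detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotip)
```

`ecotip` implements a trait-based analysis chain for running-water
macroinvertebrate surveys: fuzzy-coded trait allocation, functional
diversity indices, single-predictor response models, and segmented
(broken-line) tipping-point detection. This vignette documents the
models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic test bed does and does not establish.

## Trait allocation

Fuzzy coding records a taxon's affinity for each trait of a grouping
feature as an integer score 0–5. Within a grouping feature the scores
are normalized to allocation coefficients, $c_t = a_t / \sum_t a_t$, so
a taxon with feeding scores 1 (deposit feeder) and 3 (scraper) receives
coefficients 0.25 and 0.75. A count of 8 then allocates
$\mathrm{round}(8 \times 0.25) = 2$ individuals to deposit feeder and 6
to scraper; allocated abundances are summed over the taxa present at a
site.

Three conventions need fixing that the procedure's verbal description
leaves open:

* **Rounding.** "Nearest whole number" does not settle halves. We round
  half *away from zero* (`round_half_away()`), not half-to-even:
  it keeps symmetric splits count-conserving (a count of 1 with
  coefficients 0.5/0.5 yields 1+1, not 0+0 or biased 1+0 depending on
  parity) and matches the worked example. The rule is a single
  swappable function, and allocation conserves each taxon's count to
  within $T/2$ where $T$ is the number of traits with a positive
  coefficient. Rounding happens per taxon *before* summing across taxa,
  following the narrative order of the allocation procedure.
* **All-zero coded scores vs. uncoded taxa.** A taxon *coded* for a
  feature with all scores zero expresses no affinity and contributes
  nothing there (all-zero coefficients). A taxon with *no fuzzy
  information* for a feature instead receives the equal-coding
  fallback: $1/T$ over the $T$ traits it is recorded to possess (0.5
  each for two traits). The two cases are kept distinct in the
  `trait_affinity` container (`coded` flag).
* **Unknown taxa.** Taxa absent from the affinity table abort the
  matrix build by default; `unknown_taxa = "skip"` drops them with a
  warning instead. Full coverage by expert assignment is the expected
  use.

Traits that are zero at more than `max_zero_fraction` of sites (default
0.9) can be flagged for exclusion from count models —
near-all-zero counts cannot be expected to follow a negative-binomial
response — and an explicit exclude-list reproduces any fixed exclusion
set. Flags never remove data; diversity indices use all traits by
default while response models use the retained set (both configurable).

## Functional diversity

Per site, with $p_i$ the proportion of trait $i$:
$H = -\sum p_i \ln p_i$, $D_1 = 1 - \sum p_i^2$,
$D_2 = 1/\sum p_i^2$, richness $S$ (traits with positive abundance) and
Pielou's evenness $J = H / \ln S$. Natural logarithms are used for both
$H$ and $J$ so that $J = 1$ exactly at perfect evenness; $0 \ln 0 = 0$
applies. $J$ is undefined at $S \le 1$ and is reported as missing,
never as 0 or 1; all-zero sites are retained with all metrics missing
and a `defined = FALSE` flag. Shannon, Simpson and inverse Simpson are
computed by `vegan::diversity()`; richness counts positive *allocated
abundance* (the computable reading of "number of traits"). These
metrics depend only on abundance proportions, so they are invariant to
rescaling a site's row and to trait-column permutation — properties the
test suite checks on randomly generated rows.

## Response curves

Trait counts are modelled as negative binomial with log link
($\log \mu$ linear or quadratic in the predictor; variance
$\mu + \mu^2/k$), diversity metrics as Gaussian. All models are
single-predictor; predictors are mean-centered before fitting, which
weakens the collinearity between linear and quadratic terms without
changing the fitted curve on the original scale (the package's tests
verify prediction invariance to centering at $10^{-8}$).

Backward elimination selects the polynomial form: fit the quadratic
model, test the quadratic term at $\alpha = 0.05$; if dropped, test the
linear term the same way; failing both leaves the intercept-only model.
Two choices are deliberate:

* **Likelihood-ratio tests** ($\chi^2_1$) back the 5% decisions for
  both families, preferred over Wald tests for stability at $n \approx
  80$. This is a potential divergence from any analysis that used Wald
  z-tests; simulated spurious-quadratic retention under a linear truth
  is 4.8% at $n = 80$, inside Monte-Carlo tolerance of the nominal 5%.
* **Hierarchy.** A retained quadratic always keeps its linear term.

Estimation is by maximum likelihood via `MASS::glm.nb()` and
`stats::lm()`; the dispersion estimate is flagged when it hits the
$[10^{-3}, 10^6]$ plausibility bounds (a very large $k$ simply means
equidispersion: the fit then matches Poisson coefficients to $10^{-3}$,
another tested property). Non-convergence is flagged, never silently
accepted. Prediction applies the stored centering constant and the
inverse link; grid points outside the observed predictor range warn.
Deviance residuals against fitted values (`residual_diagnostics()`)
support the usual homogeneity check without an automatic verdict.

## Segmented regression and tipping points

The broken-line model on the linear-predictor scale is

$$y = \alpha + \beta_1 x \quad (x < \psi), \qquad
  y = (\alpha - \beta_2\psi) + (\beta_1 + \beta_2)x \quad (x > \psi),$$

continuous at $\psi$ with difference-in-slopes $\beta_2$. For counts
the same form describes $\log \mu$ of a negative-binomial model, with
the dispersion re-estimated at every iteration (a fixed-dispersion
variant would condition on the null fit; re-estimation is the default
because $\psi$ and $k$ are not orthogonal at survey sizes).

**Estimation.** At a working $\psi$ the model is fitted with the hinge
term $(x-\psi)_+$ and the indicator correction term $-\mathbf{1}(x >
\psi)$; the ratio of the correction and hinge coefficients proposes the
$\psi$ update (the classical linearization of broken-line fitting).
The raw update can oscillate or escape the data range, so each proposal
passes a backtracking line search on the *profile log-likelihood*:
the step is halved until it improves the profile, making every accepted
step an ascent and the iteration converge to a local profile optimum.
Because the profile is kinked at the data points, the converged iterate
can still sit one basin short of the nearest optimum; a deterministic
polish probes the midpoints of the four data gaps on either side and
re-iterates from any improvement (at most three rounds). With this
scheme the fitter reproduced an exhaustive 1000-point profile-grid
search within one grid step on every random instance tried in the test
suite, for both families. Convergence is declared when the accepted
step falls below $10^{-6} \cdot \mathrm{range}(x)$ (at most 50
iterations); the standard error of $\psi$ comes from the delta method
on the correction/hinge coefficient ratio.

**Existence testing.** $\beta_2$ vanishes under the no-breakpoint null,
so its test statistic is maximized over $K = 10$ interior candidate
$\psi$ values (equally spaced quantiles of $x$; configurable) and
referred to the Davies upper bound
$p \le 2\{\Phi(-M) + V e^{-M^2/2}/\sqrt{8\pi}\}$, where $M$ is the
maximal $|$statistic$|$ and $V$ the total variation of the signed
statistics across candidates. The pointwise statistic is the hinge
coefficient's Wald statistic in a Gaussian fit (Davies test) and the
GLM score statistic for adding the hinge to the null negative-binomial
fit, dispersion held at the null estimate (score test). Simulated
type-I error at $n = 80$, $K = 10$ is 4.7% (Davies) and 4.2% (score),
re-verified by the test suite at 1000 replicates each.

**Selection rule.** The segmented fit is run from a grid of starting
values (interior deciles of $x$ within its 5th–95th percentile band),
and among converged fits the estimate *closest to the existence test's
best candidate* is reported; ties break by higher log-likelihood, then
smaller $\psi$ (deterministic). The estimate is reported whatever the
test verdict — `significant` records the 5% decision separately — and a
segment containing fewer than `min_segment = 5` observations attaches a
warning without suppressing the estimate, since survey analyses do
report breakpoints supported by as few as three right-side points,
with caveats. One breakpoint only: the two-equation model is
single-break by construction, and multi-break estimation is out of
scope.

## Synthetic test bed

The generator emulates the survey design the methods target: 88 sites
(8 with an incomplete environmental record, so 80 analysable after
listwise deletion), velocity $\sim$ truncated Normal(0.3, 0.29) on
[0, 1.5] m/s, and right-skewed turbidity and elevation — truncated
LogNormal(log 2, 1.2) on [0.02, 34.7] NTU and truncated
LogNormal(log 86, 1.15) on [2, 1075] m a.s.l. — matching the reported
ranges and the median-well-below-mean shape of such basins. Predictors
are sampled independently. The 30-family pool spans the full trait
catalogue; feeding-style traits carry the generative ground truth
(dispersion $k = 2$, typical of overdispersed benthic counts), with
the scraper's log mean broken-linear in turbidity
($\alpha = 2.0$, $\beta_1 = 0.35$, $\beta_2 = -0.45$, $\psi = 5$ NTU —
a rise to a breakpoint at low turbidity followed by decline, the
pattern of interest at survey scale).

Counts are generated at *trait* level — where the models operate and
ground truth must live — and disaggregated to taxa: a seeded share
(25%) of each trait count is routed through mixed-affinity taxa using
the same rounding rule the allocation stage applies, and each trait's
pure carrier absorbs the exact remainder. Re-running the allocation
stage therefore recovers the generated trait counts exactly, which is
what lets full-pipeline recovery tests attribute any failure to the
statistical stages rather than to allocation noise. The generator
requires a pure-carrier taxon per generative trait and raises an error
otherwise.

What the synthetic bed does *not* emulate: spatial autocorrelation and
stream-network topology, seasonal dynamics, correlated predictors
(available as an explicit knob only through custom scenarios), and
taxonomic misidentification. Passing recovery tests show the estimators
work under the stated model at the stated scale; they do not certify
field data free of those complications.

## Problem sizes and reproducibility

Test-suite simulation sizes are chosen to keep Monte-Carlo error small
at desk scale: 1000 replicates for the test-calibration and
backward-elimination suites, 500 for breakpoint-interval coverage, 200
for full-pipeline recovery (coefficients within 3 SE in ≥95% of fits;
mean $\hat\psi$ within 2 Monte-Carlo SE of 5 NTU; detection in ≥80% of
replicates), and 20 random instances per family for the
profile-grid oracle. All generators are pure functions of (scenario,
seed); every simulation fixes its seed, and `run_pipeline()` writes a
manifest with per-stage checksums so identical configuration reproduces
identical outputs. Scenarios serialize losslessly to JSON
(`write_scenario()` / `read_scenario()`); the bundled configuration
ships in `inst/extdata/survey_scenario.json`.

## Known limitations

* Single-predictor models only; interactions and multi-predictor fits
  are out of scope by design.
* No zero-inflated or hurdle count models; heavily zero-inflated traits
  should be excluded by the sparsity filter rather than modelled.
* The Davies bound is an upper bound; the existence tests are mildly
  conservative, which the calibration suite quantifies.
* Breakpoint standard errors rely on the delta method and become
  optimistic when a segment holds very few points — exactly the case
  the minimum-segment warning marks.
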