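# ecotip

Trait-based biomonitoring response curves and ecological tipping points
for stream macroinvertebrate surveys.

## What it does

Biomonitoring programmes in tropical lowland rivers count benthic
macroinvertebrates at family level along gradients of flow velocity
(m/s), turbidity (NTU) and elevation (m a.s.l.). `ecotip` turns those
counts into *functional* signals and asks where along a gradient a
community's functioning changes abruptly:

1. **Trait allocation.** Each taxon carries fuzzy-coded affinity scores
   (0 = no affinity … 5 = high affinity) for the traits of five grouping
   features (feeding style, respiration, locomotion, reproduction,
   maximal size). Scores normalize to coefficients `c_t = a_t / Σ a_t`;
   a taxon's count is split as `round(count · c_t)` and summed over the
   taxa at each site, giving a site × trait abundance matrix. Taxa
   without fuzzy information get the equal-coding fallback (`1/T` over
   the `T` traits they possess).
2. **Functional diversity.** Per site, with `p_i` the proportion of
   trait *i*: Shannon–Weaver `H = −Σ p_i ln p_i`, Simpson
   `D1 = 1 − Σ p_i²`, inverse Simpson `D2 = 1/Σ p_i²`, trait richness
   `S`, Pielou's evenness `J = H / ln S`.
3. **Response curves.** Trait abundances are modelled by
   negative-binomial regression (log link, variance `µ + µ²/k`),
   diversity metrics by Gaussian linear regression, each against one
   mean-centered predictor, with backward elimination
   (quadratic term tested first, then linear, both at the 5% level by
   likelihood-ratio test).
4. **Tipping points.** Segmented (broken-line) regression estimates the
   breakpoint ψ of `y = α + β₁x` (x < ψ) /
   `y = (α − β₂ψ) + (β₁ + β₂)x` (x > ψ). Breakpoint existence is
   tested — Davies test for Gaussian responses, score test for
   negative-binomial counts, both maximized over candidate ψ with a
   Davies-bound adjusted p-value — and among multi-start segmented fits
   the estimate closest to the test's best candidate is reported.

A synthetic-survey generator (`survey_scenario()`, `simulate_survey()`)
produces an 88-site community with known coefficients, dispersion and a
known 5-NTU turbidity breakpoint, so every stage can be validated
against ground truth without field data.

## Worked example

```r
library(ecotip)

scenario <- survey_scenario()                 # bundled survey-scale scenario
survey   <- simulate_survey(scenario, seed = 42)

cc  <- filter_complete_cases(survey$env, survey$taxa)   # 88 -> 80 sites
mat <- build_trait_abundance_matrix(cc$taxa, survey$affinity,
                                    sites = cc$env$site_id)
mat
#> Trait-abundance matrix: 80 sites x 33 traits (0 excluded)

head(trait_diversity(mat), 3)
#>   site_id        H        D1       D2  S         J defined
#> 1    S001 3.297446 0.9577785 23.68462 32 0.9514419    TRUE
#> 2    S002 3.126539 0.9443986 17.98517 31 0.9104690    TRUE
#> 3    S003 2.953043 0.9294213 14.16858 28 0.8862130    TRUE

turb <- cc$env$turbidity[match(rownames(mat), cc$env$site_id)]
trait_response(as.integer(mat[, "scraper"]), turb, family = "negbin",
               response = "scraper", predictor = "turbidity")
#> Negative-binomial response curve: scraper ~ turbidity (quadratic)
#> Coefficients (centered predictor scale):
#> intercept    linear quadratic
#>    3.0730    0.2869   -0.0252
#> Dispersion k: 1.450
#> logLik: -302.58   n: 80

tipping_point(as.integer(mat[, "scraper"]), turb, family = "negbin",
              response = "scraper", predictor = "turbidity")
#> Tipping point: scraper ~ turbidity (negative-binomial)
#>   score test: statistic 4.036, p = 0.0005266 (significant at 5%)
#>   psi = 4.836 (SE 0.97); slopes 0.3835 -> -0.0591
```

The scraper's abundance rises with turbidity up to an estimated tipping
point of 4.8 NTU and flattens/declines beyond it — close to the 5 NTU
written into the generating scenario — and the score test rejects the
no-breakpoint null decisively. `run_pipeline()` chains all stages from
CSV inputs and writes per-stage CSVs plus a checksum manifest.

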