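# stageshift

Analysis of how the diagnostic pathway of colorectal cancer (CRC) —
iron-deficiency anaemia (IDA), bowel-cancer screening (BCSP), or
symptomatic presentation — relates to tumour side and stage, and of the
missed opportunity for earlier diagnosis hidden in prior blood-count
testing. It is aimed at epidemiologists and biostatisticians working on
cancer stage-shift questions with routinely collected secondary-care
data.

The package provides, as composable tibble-in/tibble-out functions:

* **Cohort management** — CSV reading/writing with schema validation,
  derivation rules (TNM I–II → early, III–IV → late; any lesion proximal
  to the splenic flexure → right-sided), explicit exclusion accounting,
  and blood-count-history classification against a look-back window.
* **Descriptive case-mix tables** and figures per pathway and per
  blood-count class, including the cumulative prevalence of prior blood
  counts by look-back horizon.
* **Binary logistic regression from first principles** (IRLS with Wald
  odds-ratio intervals), with the four standard model specifications:
  side ~ pathway + sex, side ~ Hb, side ~ age, stage ~ pathway.
* **A Bayesian Weibull proportional-hazards model for current-status
  data** on the age at late-stage onset in the IDA subgroup. Each case is
  observed once, at diagnosis age `C`: a late-stage diagnosis places the
  onset in `[0, C]`, an early-stage diagnosis in `[C, C + 10]` (the
  10-year bound encodes the assumption that untreated early-stage disease
  progresses within a decade). With survival
  `S(t | x) = exp(−(t/σ)^k · e^{βx})`, where `x = 1` marks a blood count
  in the two prior years and the shape is constrained to `k > 1`
  (non-decreasing hazard), the posterior of `(k, σ, β)` is sampled by
  adaptive random-walk Metropolis (4 chains × 1000 kept draws), with
  split R-hat and effective-sample-size diagnostics.
* **Sample-size computation** for chi-square association tests via the
  noncentral chi-square distribution (Cohen's w).
* **A calibrated synthetic-cohort generator**, so the full pipeline runs
  and is validated without access to patient data.

## Worked example

```r
library(stageshift)
library(dplyr)

cohort <- generate_cohort(calibrated_config(), seed = 2024)
pathway_summary(cohort) |>
  select(pathway, n, percent, early_percent, right_percent)
#>   pathway         n percent early_percent right_percent
#> 1 IDA           171    15            57.3          83.6
#> 2 BCSP          187    16.4          58.8          27.3
#> 3 SYMPTOMATIC   780    68.5          39.2          32.2
```

171 of 1138 simulated cases (15.0%) present through the IDA pathway, and
83.6% of them are right-sided against ~32% of symptomatic cases — the
case-mix the generator is calibrated to. Fitting the multivariable side
model:

```r
fits <- fit_pathway_models(cohort)
wald_or_table(fits$A)
#>   term      or conf.low conf.high or_ci               p.value p_display
#> 1 IDA    11.3      7.27     17.5  11.26 (7.27-17.46) 2.34e-27 < 0.0001
#> 2 BCSP    0.84     0.58      1.2  0.84 (0.58-1.20)   3.32e- 1 0.33
#> 3 female  2.11     1.62      2.75 2.11 (1.62-2.75)   2.71e- 8 < 0.0001
```

The odds of right-sided disease are about eleven times higher on the IDA
pathway than the symptomatic one (the generating truth is 10.61), about
double in women, and indistinguishable for screening.

For the current-status survival question, simulate a world in which a
prior blood count multiplies the late-stage onset hazard by 0.66
(median onset 75 years for tested, 70 for untested):

```r
d <- generate_current_status(calibrated_truth(), n = 171,
                             p_tested = 118 / 171, seed = 1)
fit <- fit_current_status(d, seed = 1)
tidy(fit) |> filter(quantity %in%
  c("hr_untested_vs_tested", "median_onset_tested",
    "median_onset_untested"))
#>   quantity               mean    sd median cri.low cri.high
#> 1 hr_untested_vs_tested  2.00 0.418   1.97    1.31     2.90
#> 2 median_onset_tested   74.1  1.28   74.2    71.5     76.4
#> 3 median_onset_untested 68.1  1.64   68.0    65.1     71.3
```

The fitted onset medians sit close to the generating 75/70; the hazard-ratio
posterior overshoots the generating 1.53 because the 10-year progression
assumption is informative relative to this unbounded generating world —
see the methods vignette (`vignettes/stageshift-methods.Rmd`) for the
full analysis of that bias. `autoplot(fit)` draws the posterior survival
bands for both groups, and `run_pipeline()` executes
simulate → descriptive → logistic → survival end to end into an output
directory.

Design-stage sample sizes for a chi-square association test:

```r
chisq_sample_size(w = 0.1, alpha = 0.05, power = 0.80, df = 2)  # 964
chisq_sample_size(w = 0.1, alpha = 0.05, power = 0.90, df = 2)  # 1266
```

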