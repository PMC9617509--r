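# vitreopkpd

Quantitative comparison of intravitreal anti-VEGF biologics in the rabbit
eye. The package implements, as one tested pipeline, the model chain that
links a drug's molecular properties to its in vivo ability to suppress
VEGF-induced retinal vascular leakage:

1. **Solution-phase affinity** — the kinetic exclusion assay (KinExA)
   measures the free inhibitor fraction of an equilibrated drug/VEGF
   mixture. The one-site homogeneous model gives the free site fraction as
   the positive root of the mass-balance quadratic,
   `f = ((I − L − K_D) + sqrt((I − L − K_D)² + 4 K_D I)) / (2I)`, and a
   single K_D is fitted globally across titration curves run at several
   constant inhibitor concentrations (N-curve analysis), with a
   profile-likelihood 95% CI.
2. **Cell potency** — four-parameter logistic IC50 fits of normalized
   calcium-mobilization inhibition curves, with Tukey-adjusted pairwise
   log-IC50 comparisons.
3. **Ocular PK** — a minimal physiology-based model in which biologics are
   eliminated by the anterior route (diffusion through the vitreous,
   washout with aqueous humor turnover). With hydrodynamic radius
   `r_h ∝ MW^(1/3)`, the vitreal half-life is `ln 2` over the slowest
   eigenvalue of the two-compartment system and, in the anterior-dominated
   limit, proportional to `r_h`. Observed profiles are summarized by
   noncompartmental analysis (linear-up/log-down AUC, best adjusted-R²
   terminal window for λz, `CL = dose/AUC`, `Vss = CL·MRT`).
4. **VEGF challenge PD** — mass-action kinetics of drug, VEGF-A165 and
   their complex after an intravitreal VEGF bolus; the free-VEGF AUC over
   the 47-h observation window, as a percent of the vehicle AUC, is the
   exposure metric.
5. **Leakage response** — a two-parameter logistic
   `p(x) = 1 / (1 + exp(−(x − x50)/s))` mapping percent free VEGF `x` to
   the probability of moderate-to-severe leakage (angiography score ≥ 2),
   fitted by Bernoulli maximum likelihood, with exact back-calculation of
   the exposure at any probability.

A synthetic-study generator reproduces the assay designs (duplicate KinExA
curves at the study's constant concentrations and titration spans,
destructive-sampling vitreous PK with assay-specific LLOQ censoring,
leakage cohorts of 7 animals per agent per challenge day with a 47 ± 3 h
observation window), so the whole chain runs with no external data. It is
aimed at preclinical modellers designing or re-analyzing ocular
anti-VEGF studies.

## Worked example

```r
library(vitreopkpd)
report <- run_pipeline(seed = 1, out_dir = "study_out")
print(report)
#> <pipeline_report>
#>   aflibercept K_D = 1.7e-13 M
#>   brolucizumab K_D = 1.257e-12 M
#>   ranibizumab K_D = 2.149e-11 M
#>   aflibercept t1/2 = 5.95 d (NCA)
#>   brolucizumab t1/2 = 3.18 d (NCA)
#>   ranibizumab t1/2 = 3.28 d (NCA)
#>   leakage x50 = 68.2%, accuracy 0.901
#>   design window: days 1-70
#>   protection order: aflibercept > brolucizumab > ranibizumab
```

Reading the output: the global KinExA fits recover sub-picomolar affinity
for aflibercept and rank the agents aflibercept < brolucizumab <
ranibizumab in K_D (tightest binder first); NCA of the simulated vitreous
profiles recovers each agent's terminal half-life (the 115 kDa trap
persists ~5.9 days, the smaller fragments ~3.2); the fitted leakage
logistic puts the 50%-probability point at 68.2% free VEGF (generating
truth 70%) and classifies 90% of observations correctly; and the predicted
loss-of-protection order over the challenge schedule is aflibercept (last
to fail) > brolucizumab > ranibizumab. `study_out/` contains the
machine-readable summary (`summary.json`), the per-day exposure table
(`pd_timecourse.csv`), the probability/exposure back-calculation
(`backcalc.csv`) and a markdown report.

Individual stages are plain functions, e.g.

```r
m <- leakage_logistic_from_points(46, 0.2, 94, 0.8)
backcalc_free_vegf(m, 0.5)
#> [1] 70
pk <- calibrate_anterior_model(eye_geometry(), anchor_mw = 48,
                               anchor_half_life = 3.8)
predict_vitreal_half_life(26, pk)
#> [1] 3.097616
```

A study configuration (agents, eye geometry, challenge design) can be read
from YAML — `load_study_config()`; the shipped default is at
`inst/extdata/default_study.yaml`. Tabular inputs are delimited text:
binding curves as `curve_id, constant_conc_molar, titrant_conc_molar,
signal`; inhibition curves as `replicate_id, conc_nM, response`; vitreous
concentrations as `animal_id, agent, day, conc_ug_per_ml, flag`; leakage
scores as `animal_id, agent, challenge_day, score, percent_free`.
`inst/scripts/run-study.R` is a thin command-line wrapper around
`run_pipeline()`.

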