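---
title: "Methods: from binding affinity to retinal leakage probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from binding affinity to retinal leakage probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitreopkpd)
```

This vignette documents the models behind `vitreopkpd`, the assumptions
they make, the defaults they ship with, and the choices taken where the
design was genuinely open. The package compares intravitreal anti-VEGF
biologics — a receptor-trap fusion (aflibercept, 115 kDa), an scFv
(brolucizumab, 26 kDa) and a Fab (ranibizumab, 48 kDa) — in the rabbit
VEGF-challenge model of retinal vascular hyperpermeability.

## Solution-equilibrium affinity (KinExA)

A kinetic exclusion assay equilibrates the drug with titrated VEGF-A165
and measures the *free* drug by a bead-capture step too brief to perturb
the equilibrium. We model concentrations as binding-site concentrations
(KinExA theory is site-based); the conversion from molecules to sites via
each agent's stoichiometry lives in the study-configuration layer. For
total inhibitor sites $I$, ligand sites $L$ and dissociation constant
$K_D$, the free site fraction solves the 1:1 mass balance,

$$ f = \frac{(I - L - K_D) + \sqrt{(I - L - K_D)^2 + 4 K_D I}}{2I}. $$

When $I - L - K_D \ll 0$ this root cancels catastrophically, so the code
switches to the algebraically identical form $2K_D/(s - b)$ with
$b = I - L - K_D$, $s = \sqrt{b^2 + 4 K_D I}$.

The signal model per curve is `background + amplitude × f`, optionally
scaled by a linear drift over injection order (centered, multiplicative).
The vendor's drift-correction form is unpublished; ours is a declared
reconstruction and is **off by default**. One $K_D$ is fitted globally
across all curves (N-curve analysis). Because amplitude and background
enter linearly, they are profiled out in closed form at every trial
$K_D$, reducing the fit to one dimension in $\log_{10} K_D$; a fixed
15-point multi-start grid over $10^{-16}$–$10^{-9}$ M plus local
refinement makes the optimum deterministic, with ties broken toward the
smaller $K_D$. The 95% CI is a profile-likelihood interval bounded by the
F-threshold $SSR_{min}(1 + q_F(0.95, 1, df)/df)$, scanned over ±3 decades
(121 points) with interpolated crossings; a profile that never crosses on
one side yields an open bound, never a fabricated one.

The ranibizumab assay design is stated as a 50–400 pM constant-partner
range; we use two constant levels (50, 400 pM). Titration series are
3-fold dilutions from the stated top concentration, with the dilution
count chosen to best match the stated lower end of each range.

## Cell potency (4PL)

Responses are assumed pre-normalized peak calcium-mobilization summaries
(1 = uninhibited, 0 = fully inhibited); raw fluorescence kinetics are out
of scope. The fit is the standard four-parameter logistic in
$\log$-concentration with deterministic initialization (IC50 starts at
the concentration nearest the half-range response) and the Hill slope
bounded to $[0.3, 5]$. Pairwise potency comparisons use the studentized
range: replicate log-IC50s are combined by inverse-variance weighting and
$q = \sqrt{2}\,|d|/se_d$, so with two groups the adjusted p-value equals
the two-sided t-test p.

## Ocular pharmacokinetics

The minimal physiology-based model assumes biologics leave the vitreous
predominantly by the **anterior route**: diffusion through the vitreous
into the anterior chamber, then washout with aqueous humor turnover.
Posterior elimination, melanin binding and Fc recycling are deliberately
absent. The vitreous→aqueous transfer rate scales as $1/r_h$ with
$r_h = MW^{1/3}$ (compact-globule scaling, prefactor irrelevant after
calibration), and the aqueous washout rate is outflow/volume. The
predicted half-life is $\ln 2$ over the slowest eigenvalue of the 2×2
linear system; with rabbit defaults (outflow 3 µL/min, anterior chamber
0.3 mL) washout is ~14/day, far faster than transfer (~0.2/day), so the
anterior-dominated proportionality $t_{1/2} \propto r_h$ holds. The
single geometry factor is calibrated against one reference agent's
half-life; absolute Stokes–Einstein diffusivities are not used because
the required geometry parameters are not reliably known — the
calibrated-ratio form needs none of them. Eye-geometry defaults
(vitreous 1.5 mL, within the 1.15–1.7 mL rabbit range) are
implementer-chosen and overridable in the YAML configuration.

NCA follows standard practice: terminal slope $\lambda_z$ by log-linear
regression over the adjusted-$R^2$-maximizing suffix of ≥3 post-peak
points (Cmax excluded, ties to the longer window); linear-up/log-down
trapezoids; $C_0$ back-extrapolated log-linearly from the first two
points and included as the $t=0$ anchor; tail $C_{last}/\lambda_z$;
$CL = dose/AUC_\infty$ and $V_{ss} = CL \cdot AUMC/AUC$. Concentrations
below the assay LLOQ (aflibercept 6.25, ranibizumab 3.0, brolucizumab
20.0 ng/mL) are excluded, never imputed; the last quantifiable point
defines $t_{last}$. Destructive-sampling replicates are pooled by the
per-day geometric mean before analysis (concentrations are treated as
log-normal); per-animal NCA remains available via `pool = FALSE`.

## VEGF challenge pharmacodynamics

After a 500 ng VEGF-A165 bolus (50 µL) the vitreous holds ~8.7 nM of VEGF
dimer. The drug–VEGF–complex system follows mass-action kinetics with
species-specific first-order elimination. No kinetic rates are reported
for these agents in the eye, so $k_{on}$ defaults to the
diffusion-limited class value $10^6\ \mathrm{M^{-1}s^{-1}}$ and
$k_{off} = k_{on} K_D$ with $K_D$ taken at body temperature
(`kd_temp_factor`, default 1 — a documented hook, since no correction
factor is published). VEGF and complex half-lives come from their
molecular weights through the same size-scaling model (complex MW = VEGF
dimer + stoichiometric drug load). Endogenous rabbit VEGF is ignored: the
challenge is exogenous human VEGF and two of the three agents lack rabbit
cross-reactivity.

The default integration mode is **quasi-equilibrium**: only the species
totals are integrated, partitioned algebraically at each step through the
mass-balance quadratic. The full stiff ODE (deSolve `lsoda`, rtol 1e-8)
is retained as the verification oracle; at diffusion-limited $k_{on}$ the
two agree within 1% in free-VEGF AUC wherever free VEGF is appreciable.
In deep drug excess the full ODE retains the ~20 s post-bolus binding
transient that the quasi-equilibrium form lacks by construction; both
exposures are then ≈0% and the discrepancy is irrelevant to any decision
the model informs. The output time grid is quadratically condensed near
$t = 0$ so the trapezoid quadrature resolves that transient.

The exposure metric is the free-VEGF AUC from injection to the leakage
observation (exactly 47 h in the analysis layer; the ±3 h protocol jitter
exists only in the synthetic-data generator), normalized to a vehicle run
of the same simulation (100%).

`find_design_window()` interprets "discriminating window" as: a
contiguous run of challenge days on which the agents' predicted leakage
probabilities are pairwise separated by more than `margin`, and which
contains every agent's 0.5-probability crossing. `margin = 0` (default)
gives the widest such window; identical agents yield an empty one.

## Leakage exposure–response

Scores dichotomize at ≥2 (moderate-to-severe); the ordinal scale is
assumed 0–4 but only the cut matters. The default exclusion rule drops
vehicle observations at study week 10, where the control response was
unreliable; every dropped record is logged with the rule that fired. The
logistic is parameterized as $p(x) = 1/(1+e^{-(x - x_{50})/s})$ so that
exposure back-calculation $x(p) = x_{50} + s\,\mathrm{logit}(p)$ is a
one-liner; the intercept/coefficient form is a trivial conversion.
Fitting is Bernoulli maximum likelihood (binomial GLM); repeated
observations of an animal are treated as independent trials, as the
exposure–response analysis it mirrors did. Complete separation is
detected geometrically (non-overlapping class supports in one dimension)
and flagged. Reported accuracy is in-sample at the 0.5 cutoff and labelled
as such; whether to cross-validate is left to the user since the design
has only ~24 agent×day cells. The "elbow" exposure at which leakage risk
starts rising steeply is reported as $x(p = 0.1)$ by convention and is
interpretive, not a fitted parameter.

## Synthetic studies: what they do and do not show

The generator reproduces the *design* of the in vivo study: duplicate
KinExA curves at each agent's constant concentrations and titration
spans with 2% multiplicative signal noise; destructive vitreous sampling
at days 5/26/33/40/54/56 with 7 animals per day, 15% lognormal
inter-animal CV and assay-specific LLOQ censoring; leakage cohorts of 7
animals per agent per challenge day (days 5/26/33/40/54/68), each animal
challenged at most twice via (first, final) cohort pairing, observed at
47 ± 3 h with Bernoulli outcomes drawn from a generating logistic truth
($x_{50} = 70$, $s = 24/\ln 4 \approx 17.31$); ordinal scores are
synthesized as 0/1/3 since only the ≥2 cut is informative. The default
study totals 84 challenge animals plus satellite-like PK animals,
consistent with the scale of the real design.

What passing tests show: the estimators recover their generating truths
at the study's own designs and noise levels, and the pipeline's rank
orderings are stable. What they do not show: real KinExA drift behavior,
real inter-animal correlation structure (outcomes are generated
independently given exposure), real score distributions, or any
biological misspecification of the anterior-elimination and
quasi-equilibrium assumptions. End-to-end $x_{50}$ recovery deserves a
caveat: under the real cohort design most exposures saturate at 0% or
100% free VEGF, so a single simulated study estimates $x_{50}$ with a
standard error near 5 percentage points; the estimator is unbiased, but
individual seeds scatter accordingly.

## Problem sizes and numerics

Test and reproduction runs use 50-seed ensembles for affinity and potency
recovery, 100 for NCA recovery, and single seeded studies end-to-end;
the full suite runs in well under a minute on one core. Key numeric
choices: ODE rtol $10^{-8}$ with state-scaled atol; profile-CI grid 121
points over ±3 decades; multi-start grid fixed (never random) so fits
are reproducible; stable quadratic roots everywhere a subtraction can
cancel; all internal units are days, mL, nM and µg, converted only at
I/O boundaries.

## Known limitations

- The anterior-route model ignores posterior elimination; for molecules
  with substantial retinal clearance the size-scaling prediction will
  overestimate half-life.
- The complex is assumed fully formed at its stoichiometric maximum for
  sizing purposes; mixed partial complexes are not modelled.
- The leakage point estimates ignore within-animal clustering; an
  animal-level cluster-robust (sandwich) variance is available via
  `fit_leakage_logistic(cluster_robust = TRUE)` but is off by default, to
  match the independent-trials analysis the model reconstructs.
- Affinities are assay-temperature values unless a temperature factor is
  supplied; no published correction exists for these agents.
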