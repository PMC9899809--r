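# ucmforce

Uncontrolled-manifold (UCM) analysis of four-finger isometric force
recordings, for motor-control researchers studying how finger-force
variability is organized around a total-force task — e.g. comparing
force-stabilizing synergies across children with cerebral palsy, children
with traumatic brain injury, and typically developing controls.

## What it computes

During a force-ramp trial the task variable is the total force
F<sub>TOT</sub> = Σ f<sub>i</sub> of the four fingers (index, middle, ring,
little). The task Jacobian is J = [1 1 1 1]; fluctuations inside its null
space do not perturb the total force. After zero-phase Butterworth filtering
(4th order, 4 Hz, applied forward and backward) and per-finger linear
detrending, the fluctuation df(t) is projected onto the orthonormal
null-space basis e₁ = (−1/2, 5/6, −1/6, −1/6), e₂ = (−1/2, −1/6, 5/6, −1/6),
e₃ = (−1/2, −1/6, −1/6, 5/6):

    f∥(t) = Σᵢ (eᵢᵀ df(t)) eᵢ        f⊥ = df − f∥

    v_good = Σₜ |f∥(t)|² / (3N)      v_bad = Σₜ |f⊥(t)|² / N

    Δv = (v_good − v_bad) / ((3 v_good + v_bad) / 4)     ∈ [−4, 4/3]

Positive Δv means relatively more task-irrelevant ("good") than
task-relevant ("bad") variance — a force-stabilizing synergy. The package
also computes the standard performance measures (MVC, straight-line
deviation of the total force, finger-sharing percentages), a two-step
AIC/BIC mixed-model selection protocol over age × group × paretic
structures (lme4/lmerTest, ML fits), and ships a synthetic-data generator
whose trials and cohorts have known ground-truth variance structure and
age/group effects, so the entire pipeline is validated by parameter
recovery.

## Worked example

```r
library(ucmforce)

# one synthetic ramp trial: good fluctuation sd 0.25 N per null-space
# dimension, common-mode (bad) total-force sd 0.8 N
tr  <- simulate_ramp_trial(trial_spec(sigma_good = 0.25, sigma_bad = 0.8,
                                      seed = 42))
fit <- ucm(tr)       # filter -> detrend -> project -> decompose
fit
#> Single-trial UCM analysis
#> v_good = 0.06236 N^2  v_bad = 0.1597 N^2  delta_v = -1.123  (N = 1020)
#>   straight-line deviation: 0.6735 N, peak total: 21.69 N
#>   sharing (%): index 30.1, middle 29.8, ring 25.1, little 15.0

delta_v_from_sigmas(0.25, 0.8)   # analytic value of the generating process
#> [1] -1.122302
```

The recovered Δv (−1.123) matches the analytic synergy index of the
generating parameters (−1.122): v_good ≈ σ²_good = 0.0625 N² and
v_bad ≈ (σ_bad/2)² = 0.16 N². A full cohort, analysed end to end:

```r
coh <- simulate_cohort(cohort_spec(n_per_group = 8, trials_per_subject = 6,
                                   seed = 3))
res <- analyze_trials(coh$trials)          # one row per trial
sel <- select_synergy_model(summarize_subjects(res))
sel
#> Model selection for outcome 'delta_v' (n = 48)
#>   step 1 (AIC): fixed-only 14.9 vs + (1|subject) -5.0 -> random subject intercept kept
#>   step 2 (BIC):
#>     age*group            10.0  <- selected
#>     age+group            21.3
#>     age                  22.3
#>   skipped (factor constant): age*group*paretic
#>   significant effects (alpha = 0.05):
#>     age_years: +  t(24) = 2.35, p = 0.0275
#>     groupTBI: +  t(24) = 2.75, p = 0.0111
#>     age_years:groupTBI: -  t(24) = -3.94, p = 0.000606
```

The selection recovers exactly the generating structure: a subject random
intercept, an age × group fixed structure, a positive age trend in Δv for
controls, and a negative, significant TBI × age interaction (the TBI-like
group was generated with the opposite age slope).

A file-based pipeline (`run_simulate()`, `run_analyze()`, `run_stats()` on
a YAML/JSON config, with a thin CLI wrapper in
`inst/scripts/ucm_pipeline.R`) covers the same stages for batch use;
`recovery_experiment()` runs replicated end-to-end recovery studies.

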