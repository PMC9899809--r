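---
title: "Uncontrolled-manifold analysis of multi-finger force: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncontrolled-manifold analysis of multi-finger force: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucmforce)
```

## The model

In a four-finger isometric pressing task the controlled variable is the total
force, $F_{TOT} = \sum_{i=1}^4 f_i$. The uncontrolled-manifold (UCM)
hypothesis asks how trial-to-trial (here: moment-to-moment) fluctuations of
the individual finger forces are organized relative to this task variable.
The Jacobian of the task is $J = [1\,1\,1\,1]$: a change $df$ in the finger
forces changes the total force by $dF_{TOT} = J\,df$. Fluctuations inside the
null space of $J$ leave the total force unchanged; `ucmforce` uses the
conventional orthonormal basis of that null space,

$$e_1 = \left(-\tfrac12, \tfrac56, -\tfrac16, -\tfrac16\right),\quad
  e_2 = \left(-\tfrac12, -\tfrac16, \tfrac56, -\tfrac16\right),\quad
  e_3 = \left(-\tfrac12, -\tfrac16, -\tfrac16, \tfrac56\right),$$

returned by `null_space_basis()`. For a single ramp trial the pipeline is:

1. **Filter** every channel with a fourth-order, two-way (zero-phase)
   Butterworth low-pass at 4 Hz (`lowpass_filter()`).
2. **Detrend** each finger channel by removing its own least-squares line
   over time (`detrend_linear()`), giving the fluctuation matrix $df(t)$.
3. **Project**: $f_\parallel(t) = \sum_i (e_i^\top df(t))\,e_i$ is the
   task-irrelevant part (each row sums to zero) and
   $f_\perp = df - f_\parallel$ the task-relevant remainder (each row has
   four equal entries) (`project_ucm()`).
4. **Decompose**: with $N$ samples,
   $v_{good} = \sum_t |f_\parallel(t)|^2 / (3N)$ (normalized per null-space
   dimension) and $v_{bad} = \sum_t |f_\perp(t)|^2 / N$, both in N².
5. **Synergy index**:
   $\Delta v = (v_{good} - v_{bad}) \,/\, \big((3 v_{good} + v_{bad})/4\big)$,
   bounded in $[-4, 4/3]$; positive values indicate force-stabilizing
   covariation.

`ucm()` composes these stages and additionally computes the per-trial
performance measures: the maximal voluntary contraction (MVC,
`compute_mvc()`: the maximum per-sample four-finger sum over the — normally
three — maximal-effort repetitions), the straight-line deviation
(`straight_line_deviation()`: mean distance of the total-force trace from
its own best-fit line), and finger sharing (`finger_sharing()`: mean
percentage of the total force contributed by each finger).

This is *single-trial* UCM analysis: variance is computed across time
samples within one detrended trial, not across trials at matched time
points. The sums divide by $N$ exactly (no $N-1$ correction), matching the
defining formulas. Variances are kept in Newtons rather than normalized to
%MVC, because low MVC values (young children) turn small absolute force
changes into outlying relative ones; $\Delta v$ is already normalized.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `cutoff_hz` | 4 | Hz | Standard low-pass for slow isometric force tracking; the two passes square the magnitude response. |
| `order` | 4 | – | Single-pass Butterworth order. |
| `trim_s` | 0 | s | Trials are analysed in full; a trim option exists because filtered edges are the least reliable samples. |
| `sharing_floor_n` | 0.5 | N | Samples with total force below this are excluded from sharing percentages to avoid 0/0 near ramp onset. |
| `method` (straight-line deviation) | `mean_abs` | – | "Mean distance" from the line read as the mean absolute vertical OLS residual; RMS is available as an option. |

Two readings deserve a note. First, the straight-line deviation uses
*vertical* residuals (force on time), not perpendicular distances, because
the line is fitted by regressing force on time. Second, MVC is computed on
filtered signals by default (all force data are filtered before analysis);
`filter = FALSE` gives the raw alternative since the choice is not forced by
the definition — on smooth plateau trials the two differ by well under 1%.
$\Delta v$ enters the statistics untransformed; a Fisher-style
variance-stabilizing map (`delta_v_fisher()`) is provided but off by
default.

## Numerical choices

The zero-phase filter is built from `signal::butter` coefficients, but the
forward–backward pass is implemented in the package: each pass starts from
steady-state direct-form-I initial conditions at the first sample's value,
and the signal is extended by odd (point) reflection at both ends before
filtering. With a 4 Hz cutoff at 170 Hz the poles sit close to the unit
circle and naive zero-initialized filtering leaves order-1e-3 edge errors on
a 6-s trial; the combination used here keeps a constant exact, a ramp
correct to ~1e-7 N in the interior, and matches the analytic two-pass
magnitude response at 20 Hz to better than 0.1%.

Degenerate inputs are signalled, not patched: $\Delta v$ is undefined (and
reported as missing) when $v_{good} = v_{bad} = 0$; trials shorter than the
filter's padding requirement, non-uniform time vectors, NaN forces, and
cutoffs at or above Nyquist are errors.

## The synthetic-data generator

`simulate_ramp_trial()` emulates a 6-s force-ramp tracking trial at 170 Hz:
expected per-finger force is a sharing fraction times a linear ramp, and the
superimposed fluctuation $df = g + b$ is built from two independent
band-limited Gaussian processes:

* $g(t)$ — a 4-channel low-pass process projected onto the null space of
  $J$, each retained dimension rescaled to standard deviation
  `sigma_good`; its rows sum to zero, so it contributes only good variance
  ($v_{good} = \sigma_{good}^2$).
* $b(t)$ — a common-mode process, identical on all four fingers, whose
  total-force standard deviation is `sigma_bad`; it contributes only bad
  variance ($v_{bad} = \sigma_{bad}^2/4$).

Design choices, made once:

* **Noise spectrum.** Nothing forces a particular fluctuation color; the
  generator low-pass-filters white noise at a 1.5 Hz corner (second order,
  zero phase, burn-in trimmed rather than reflection-padded — reflecting a
  white signal injects a DC pedestal of $\approx 2x_1$ at the edges). The
  corner sits below the 4 Hz analysis cutoff so the injected structure
  survives preprocessing; because good and bad components share one
  spectrum, any residual filter attenuation cancels in $\Delta v$.
* **Exact scaling.** Each retained noise dimension is detrended and
  RMS-normalized before scaling, so the realized per-trial variances equal
  their targets exactly and the analytic $\Delta v$ of the generating
  parameters is recovered to machine precision when the analysis filter is
  off — the basis of the noiseless-limit tests.
* **Nonnegativity.** Forces are floored at 0 N (pressing sensors cannot
  pull). Heavy clipping biases the variance split, so default ramps keep
  clipping rare; the per-trial count is exposed as attribute `n_clipped`.
* **Ramp range.** The force range of the on-screen ramp is not dictated by
  the task description, so it is an explicit parameter; cohort simulation
  uses 25%–75% of the subject's MVC over 6 s, with
  MVC = `mvc_base_n` + `mvc_age_slope_n`·age (defaults 10 N + 2.5 N/yr,
  plausible for school-age children).

`simulate_cohort()` draws subjects with ages uniform on [4, 12] years (the
cohort's age spread; no finer distribution is claimed) in up to three groups
— `control`, `CP` (cerebral-palsy-like) and `TBI` (traumatic-brain-
injury-like) — and gives each subject a target synergy index linear in age
with group-specific intercepts and slopes. Defaults mirror the qualitative
pattern of interest: positive age slopes for the control and CP-like groups
and a negative slope for the TBI-like group. The subject-level target is
perturbed per trial (`trial_jitter_sd`, default 0.15) so that within-subject
variance is realistic and the mixed-model stage has a well-defined residual;
`sigmas_from_delta_v()` inverts the $\Delta v$ formula at fixed total
fluctuation power (`fluct_power_n2`, default 0.3 N²) to obtain the per-trial
noise scales. Each subject performs 20 trials by default, 10 per tracking
task, matching the two-task protocol; subjects are single-hand and
non-paretic, so paretic-involving model structures are dropped (and
reported) automatically.

What the generator does **not** emulate: finger enslaving (mechanical and
neural coupling that makes single-finger forces co-vary beyond the task),
fatigue or learning across trials, heteroscedastic noise over the ramp, and
real sensor artifacts. Passing recovery tests therefore shows the pipeline
is correct and well-calibrated for band-limited Gaussian fluctuations with
a known good/bad split — not that every feature of children's force data is
captured.

## The statistics stage

`select_synergy_model()` reproduces a two-step information-criterion
protocol on the subject-level table (per-trial outcomes averaged within
subject, hand and task; the subject/task mean is the aggregation level
because group-level plots carry one point per subject):

1. The "beyond optimal" fixed structure (all interactions of age, group and
   paretic hand that the data support) is fitted with and without a subject
   random intercept; AIC decides.
2. Among the fixed structures `age*group*paretic`, `age*group`, `age+group`,
   `age`, BIC decides.

All fits use maximum likelihood (information criteria compared across
different fixed structures require ML, not REML). Age is continuous. The
random structure is limited to a subject intercept — no random slopes, and
no hand term beyond the fixed paretic flag. Effects are reported as
sign + t + p at α = 0.05 with no multiple-testing correction;
Satterthwaite degrees of freedom are used for mixed fits. Singular or
failed fits are recorded in the selection report, never silently dropped.

`recovery_experiment()` closes the loop: simulate a cohort, analyse every
trial, aggregate, select, and score the recovered age slopes of $\Delta v$
against the generating ones.

## Problem sizes used in validation

The shipped validation suite uses 1,000 random fluctuation matrices for the
conservation/oracle checks; 20 replicates of a 45-subject, 10-trial cohort
for slope recovery and model selection; a 6-point good/bad-ratio grid with
10 trials per point for monotonicity; and 20 replicates of a 30-subject null
cohort for the type-I check (threshold: 10% of replicates plus a one-sided
binomial margin at the nominal 5% rate, i.e. at most 3 of 20). The
acceptance script reruns the same experiments at 10 recovery replicates.

## Known limitations

* The decomposition works in raw finger-force space; no enslaving-matrix
  (finger-mode) transformation is applied, and no across-trial UCM variant
  is provided.
* Real cohorts with two recorded hands per patient are supported through the
  subject random intercept plus the fixed paretic flag, but hand-specific
  random effects are not modelled.
* Degrees-of-freedom conventions differ across mixed-model software;
  reported t and p values are Satterthwaite-based and need not match other
  implementations to the last digit.
* With fluctuations whose spectrum extends beyond the 4 Hz analysis cutoff,
  absolute $v_{good}$ and $v_{bad}$ are attenuated by filtering (equally, to
  first order), so comparisons should stay within one filtering convention.
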