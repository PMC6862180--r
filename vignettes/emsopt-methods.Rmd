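---
title: "Methods: simulating and optimizing ED crowding with emsopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and optimizing ED crowding with emsopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emsopt` is a simulation-optimization pipeline for emergency department
crowding (EDC). This vignette explains the model behind each stage, the
parameters that matter, the numerical conventions, and what the test
evidence does and does not show about real EDs.

## 1. The patient-flow simulator

`run_simulation()` executes an event-driven model of an internal-medicine
ED. One replication proceeds as follows.

**Arrivals.** Patients arrive as a Poisson process at rate λ patients/day
(noise factor: 350 on regular days, 425 on holidays). Interarrival gaps
are produced by inverse-transform sampling of the exponential
distribution, `x = −ln(1 − θ)/λ` with `θ ~ U(0,1)`
(`interarrival_from_uniform()`), so simulated daily counts are
Poisson-distributed by construction. Triage levels 1–5 (TTAS, 1 most
urgent) are i.i.d. draws from a configurable mix.

**Stations.** Each patient passes registration (parallel desks), the
physician exam (M ∈ {1,2} physicians — the signal factor), a subset of
three checkup rooms (urine, CT, X-ray), and disposition
(discharge, or admission with boarding). Triage 1–3 patients always
preempt the triage-4/5 order at the physician queue (strict priority by
triage number, non-preemptive service); factor D orders the 4/5 queue.

**Control factors.**

* **A (persuasion, continuous in [1,3]).** Arriving triage-4/5 patients
  are persuaded to outpatient care when the *previous day's* EDWIN^C
  reached `1.5 + (A − 1)·0.5`. The three integer levels anchor the
  published interval lower bounds 1.5/2.0/2.5; intermediate values
  interpolate linearly, because the downstream optimizer treats A as a
  continuous variable and a membership-interval reading would not be
  continuous in A. Persuasion succeeds with probability `p_divert`
  (default 1; the study does not quantify it); persuaded patients leave
  the system and do not re-enter (their later care happens outside the
  model's scope).
* **B (checkup routing).** Level 1 enforces urine→CT→X-ray; level 2 sends
  the patient to the first free room still needed (scan order
  urine, CT, X-ray) and revisits skipped rooms later; level 3 visits the
  needed rooms in a uniformly random order.
* **C (bed release).** Every hour, if the fraction of ED patients waiting
  for a sickbed strictly exceeds 15/20/25 %, up to 5/10/15
  internal-medicine beds are released and the longest-boarding patients
  are transferred out.
* **D (triage-4/5 sequencing).** Shortest expected exam first /
  registration order / all triage 4 before triage 5. "Expected exam
  duration" is the patient's (pre-drawn) physician service time, i.e.
  shortest-job-first with perfect information.

**Metrics.** EDWIN^C is sampled hourly from the census snapshot:
`Σ nᵢ(6 − i) / (Nₐ(Bₜ − B_A))`. The "previous day's EDWIN^C" driving
factor A is, by default, the mean of the day's 24 hourly values (`max`
and `last` are selectable); the sampling frequency behind the daily value
is not specified in the source design, so hourly-then-mean is the
documented default. Per-patient system time is the sum of all recorded
waits and services, which equals departure minus arrival because all
transitions are immediate. Warm-up days (default 1) are excluded from
both response summaries. Arrivals stop at the horizon and the system then
drains, so every patient ends as exactly one of diverted / discharged /
admitted.

**Degenerate census.** When boarding fills every registered bed
(`Bₜ − B_A ≤ 0`) the index denominator degenerates; the hourly value then
carries the last valid value forward rather than aborting the
replication. In heavily overloaded scenarios this can plateau the index —
visible in the worked example in the README — and is reported as-is.

**Determinism.** All randomness (arrivals, triage, service times, checkup
needs, persuasion/admission draws, random room orders) is drawn in R
under `set.seed(config$seed)` and passed to the C++ event core, which is
a deterministic function of its inputs. Identical configurations produce
bit-identical results; event ties are broken by insertion order.

### Fixture parameters

The study hospital's patient-level data is not published, so the
generator's distributional inputs are package defaults, chosen once to be
plausible for an internal-medicine ED and documented here (all
configurable through `scenario_config()` or YAML):

| parameter | default | unit |
|---|---|---|
| service times (lognormal, mean ± sd) | registration 5±2, physician 15±8, urine 10±5, CT 20±10, X-ray 10±4 | min |
| triage mix (levels 1–5) | 0.02, 0.08, 0.45, 0.35, 0.10 | prob. |
| beds Bₜ / registration desks / rooms | 30 / 2 / 1 each | count |
| checkup need (urine, CT, X-ray) | 0.50, 0.35, 0.45 | prob. |
| admission probability (triage 1–5) | 0.90, 0.70, 0.40, 0.15, 0.05 | prob. |
| horizon / warm-up | 3 / 1 (desk), 7 / 1 (paper) | days |

With these defaults the ED is far beyond its service capacity at both
arrival rates (two physicians at ~15-min exams can serve well under 350
patients/day), so simulated responses sit deep in the crowded regime.
That is the regime the method is about; none of the method-level
properties depend on stability. The queueing fidelity of the engine is
checked separately in a *stable* single-class configuration against the
closed-form M/M/c (Erlang-C) waiting time.

### What the generator does and does not emulate

It emulates the stochastic structure the design needs: Poisson demand at
two rates, a five-level acuity mix, multi-station flow with shared
checkup rooms, boarding, and the four policy levers. It does **not**
emulate: outpatient competition for exam rooms (rooms serve only ED
patients, so the "ED priority" aspect of factor B levels 1–2 vs 3 is
partially moot), time-varying arrival intensity within a day, patient
re-entry after persuasion, staff fatigue, or calibration to any real
hospital. Passing tests therefore demonstrate that the *method* — design,
SN analysis, surrogate, optimizer, sensitivity arithmetic — behaves
correctly on a system with the right stochastic skeleton, not that the
recovered optimum would transfer to a particular ED.

## 2. Dynamic Taguchi stage

`build_plan()` crosses the standard L9(3⁴) inner array with the signal
and noise levels: 36 cells, each simulated `replications` times with
seeds derived by a counter scheme (`seed + 1000·cell + rep`), so cells
can be re-run in isolation.

Per L9 row and response, the zero-intercept ideal function `y = βM` is
fitted by least squares through the origin (`β = ΣMy/ΣM²`) to the four
(signal × noise) cell means; pooling the noise levels into one fit lets
noise-induced variation contribute to the MSE, which is the robustness
reading of a dynamic design (per-noise fitting is available via
`pool_noise = FALSE`). Numerical conventions, each chosen once:

* **MSE denominator** is `n − 1` (the source says only "mean square
  error"); `n` is available as an option.
* **SN form.** The printed `SN = 10 log₁₀(β/MSE)` is dimensionally odd
  (the conventional dynamic SN uses β²) but is the default;
  `variant = "conventional"` switches. Because fitted slopes can be
  negative, |β| enters the numerator and the sign is reported
  alongside rather than raising an error.
* **Level selection** maximizes the per-factor mean SN (three rows per
  level by L9 balance); ties break toward the lower level index and are
  reported. The predicted optimum SN is the standard additive estimate:
  overall mean plus the chosen levels' deviations.
* The two responses are SN-analyzed separately, each yielding its own
  level setting — which is exactly why the subsequent desirability/TP
  stage exists to arbitrate.

## 3. Desirabilities and the surrogate

Cell-mean responses are normalized to [0,1] by linear ramps:
EDWIN^C enters **larger-the-better** (d1) and system time
**smaller-the-better** (d2). The LTB orientation for a crowding index is
clinically counter-intuitive but follows the printed equations of the
source design; `edwinc_orientation = "stb"` flips it for users who want
the intuitive direction (the default is used everywhere in this
package's reported results). Specification limits are not published, so
bounds default to the observed cell-mean extrema
(`bounds_from_responses()`, optional symmetric margin), which guarantees
at least one 0 and one 1 per response; explicit bounds can be supplied.
The ramps are linear (exponent 1) as printed; an exponent parameter
exists.

The surrogate is a single-hidden-layer perceptron, 6 inputs (M, Z, A–D,
affinely scaled to [0,1]; discrete factors enter as scaled numeric
levels, not one-hot, preserving the 6-input structure) and 2 sigmoid
outputs (so predictions are natively in [0,1]). Training is full-batch
backpropagation on the joint MSE of both outputs with momentum 0.65 and
10,000 iterations; the "auto-adjusting learning rate in [0.01, 0.5]" is
implemented as a bold-driver rule (×1.05 after an improving iteration,
×0.5 after a worsening one, clamped) — any clamped adaptive rule
satisfies the stated behaviour, and bold driver is the simplest
deterministic one. Weights initialize U(−0.5, 0.5) under the stage seed.
The train/test protocol is unstated in the source; an 80/20 seeded
split with round-half-up on the train count (29/7 of 36) is the fixed
rule. `architecture_search()` scans hidden widths 2..8 and selects the
minimal test RMSE, ties toward the smaller network.

## 4. GA and sensitivity

The GA maximizes `TP = d1·d2²`. Chromosomes hold continuous A and
discrete B, C, D. The source states only the rates (1000 generations,
population 80, crossover 0.5, mutation 0.08), so the operators are this
package's choices for mixed encodings: binary tournament selection,
arithmetic blend crossover on A with uniform gene swap on B/C/D,
mutation as a clamped Gaussian on A (σ = 0.1) and uniform re-draw on the
discrete genes, elitism of one (hence a non-decreasing best-so-far
trace). Since the optimizer varies only A–D while the surrogate also
takes (M, Z), fitness averages predictions over the four study
combinations by default; `worst` (conservative) and `nominal`
aggregations exist.

`ofat_sweep()` evaluates TP through the *same* fitness (internal
consistency), sweeping A over the 0.2-step grid 1.0..3.0 — matching the
published sensitivity-table layout, which suggests a 0.2 grid even
though the optimizer keeps A continuous — and B/C/D over {1,2,3}.
Adjusted TP% is rounded half-away-from-zero to two decimals, the
convention that reproduces the published tables' style. The sweep queries
the surrogate rather than re-simulating; that reading follows the
source's workflow, where the sensitivity stage operates on the trained
model.

## 5. Problem sizes and budgets

The `desk` profile (20 replications per cell, 3-day horizon, 1 warm-up
day) is the package's working scale: the full five-stage workflow runs
in well under a minute on one CPU, which makes the deterministic
end-to-end test cheap. The `paper` profile (1000 replications, 7-day
horizon) reproduces the source scale and is provided for completeness.
Property tests that need tight Monte-Carlo error (arrival moments,
M/M/c waits, planted-effect recovery) choose their own sizes — e.g.
1000 simulated days for arrival statistics, 400 days for the queueing
oracle, 1000-replicate synthetic cells for level-selection recovery.

## 6. Known limitations

* The published study's numeric results (its ideal-function fit, SN
  optima, network RMSEs, and TP = 0.593 optimum) derive from unpublished
  hospital data and are not reproduction targets; the pipeline reproduces
  the *procedures* and verifies them against independent oracles.
* Under the fixture defaults the simulated ED is heavily overloaded;
  mean system time then grows with the horizon, and the EDWIN^C series
  can saturate at the carry-forward value once boarding fills all beds.
  Factor C's thresholds are rarely exceeded in deep overload (boarders
  are a small fraction of a very large census), which mutes that lever.
* Exam rooms serve only ED patients, so factor B's "priority over
  outpatients" distinction reduces to its routing component.
* The printed LTB orientation of d1 rewards *higher* crowding; users
  studying their own ED should consider `edwinc_orientation = "stb"`.
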