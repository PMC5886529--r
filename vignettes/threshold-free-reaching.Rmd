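---
title: "Threshold-free modelling of numerosity comparison reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-free modelling of numerosity comparison reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numreach)
```

## The model

`numreach` simulates and analyses two-alternative number comparison tasks in
which the response is a continuous reach: the participant sees two dot
arrays for 200 ms and moves a finger from a start button (~29 cm from the
screen) to the lateral target with more dots. The package's core is a
*threshold-free* account of how the decision unfolds inside the movement.
Three stages run concurrently on a millisecond clock:

1. **Evidence.** Every $R$ ms the approximate number system emits a sample
   of the numerical difference,
   $s_i \sim \mathcal{N}\!\left(|n_L - n_R|,\; \omega\sqrt{n_L^2 + n_R^2}\right)$,
   where $\omega$ is the Weber fraction (second argument is the SD — the
   standard numerosity scaling). Negative samples favour the wrong side.
   Because the stimulus disappears after 200 ms, samples are drawn from
   memory; a decaying exponential moving average
   $\mathrm{EMA}_i = D\,s_i + (1-D)\,\mathrm{EMA}_{i-1}$ (initialized at
   $s_1$) models memory: $D = 1$ is memory-free sampling, $D \to 0$ locks
   onto the first sample (primacy).
2. **Inference.** With a flat prior and a normal likelihood of variance $W$,
   the posterior over the difference after $n$ filtered samples is
   $\mathcal{N}(\bar e, W/n)$ ($W$ is a *variance*; this makes $W/n$ the
   textbook conjugate result). The probability that the correct side is
   larger is $\Phi(\bar e \sqrt{n/W})$, and *certainty* is the rescaled
   binary entropy $(H(0.5) - H(p))/H(0.5) \in [0, 1]$.
3. **Control.** A finite-horizon minimum-jerk feedback law
   $\dddot{x} = -\tfrac{60}{\delta^3}(x - x_f) - \tfrac{36}{\delta^2}\dot x
   - \tfrac{9}{\delta}\ddot x$ (remaining time $\delta = t_f - t$) drives a
   2-D effector (lateral + depth) toward the currently most probable
   target. Every Euler update of the whole kinematic state is multiplied by
   the certainty. There is no decision threshold: movement "starts" with
   the first evidence sample, slowly at first because certainty is low.

Reaction time is read off the trajectory as the time to accumulate 0.28 mm
of Euclidean displacement, plus a fixed non-decision time (200–500 ms). A
change of mind is a mid-flight excursion at least 1 cm into the half-plane
opposite the endpoint side.

Two extensions and one competitor are included:

* **Accumulation gate** (`threshold > 0`): motor updates are blocked until
  the magnitude of the running sum of EMA samples reaches the threshold;
  inference uses pre- and post-gate samples, and the trial clock is shared
  with the threshold-free model, so a vanishing threshold is exactly
  continuous with it (before the first sample nothing moves either way).
  Raising the gate leaves less of the movement horizon but more evidence
  in hand: the visible reach — the lift-off window — becomes a direct
  dash, and its across-ratio modulation range shrinks monotonically
  (`sweep_threshold()`).
* **Satisficing weight** (`satisficing = TRUE`): the update weight becomes
  $\text{certainty}^{\,d}$ with $d$ the normalized remaining depth (1 at
  the button, 0 at the screen; $0^0 \equiv 1$). Near the screen the
  certainty brake is released, so equal-count (ratio 1) trials still settle
  onto a target instead of stalling midway. Two distance measures are
  exposed: the literal depth distance of the effector, and the remaining
  movement-time fraction. The literal reading can bootstrap-stall in a
  fully certainty-weighted 2-D rig (low certainty keeps the depth axis
  from progressing, so the exponent never decays); the time proxy — which
  is exactly what the depth distance becomes if the depth axis runs
  unweighted — guarantees the brake releases by flight end and fully
  reproduces the settle-onto-a-target behaviour on ratio-1 trials.
* **Traditional collapsing-bound accumulator** (`simulate_ddm_trial()`):
  per-ms samples $\mathcal{N}(\text{drift}, \sigma^2)$ with drift mapped
  from the ratio via $1 - \mathrm{erfc}\!\left(|r-1| / (\sqrt 2\,
  \text{dft} \sqrt{r^2+1})\right)$, accumulated against the collapsing
  bound $\text{thr}/(1+t)^k$. After crossing, the controller moves to the
  crossing side, weighted by the certainty of the two-hypothesis posterior
  $p(\text{Corr}\mid s) = \text{logistic}(2\,\text{dft}\,\Sigma s/\sigma^2)$,
  which keeps updating in flight. Optional second threshold / deadline
  mechanisms for in-flight target flips are provided.

## Parameters, units, defaults

| parameter | meaning | unit | default | bounds |
|---|---|---|---|---|
| `R_ms` | evidence sampling interval | ms | 30 | [1, 100] |
| `D` | EMA memory decay | — | 0.06 | [0, 1] |
| `W` | likelihood noise (variance) | diff² | 10 | > 0 |
| `omega` | Weber fraction | — | 0.17 | > 0 |
| `ndt_ms` | non-decision time | ms | 300 | [200, 500] |
| `threshold` | accumulation gate | diff units | 0 (off) | ≥ 0 |
| `x_f_cm` | lateral target | cm | 10 | ≠ 0 |
| `start_depth_cm` | button-to-screen depth | cm | 29 | > 0 |
| `dt` | integration step | s | 0.001 | ≤ delta floor |

`R_ms = 30`, `D = 0.06` and `omega = 0.17` are the task's reference values
(the Weber fraction estimated from accuracy; the strong primacy the
short stimulus induces). `W` is not separately published for this task; we
fixed `W = 10` after a design sweep — all values in 2–50 preserve the
qualitative orderings, and 10 places the mean-horizontal-position gradient
(≈ 4.7 → 3.0 cm for ±10 cm targets) and the RT spread (≈ 360 → 450 ms) in
the empirically familiar range. All positional results are scale-invariant
in `x_f_cm` because the controller is linear in its target.

Movement times are sampled per trial from a per-ratio lognormal
(moment-matched mean/SD; defaults 0.6 ± 0.1 s, the scale of a brief
reach). Dot pairs realizing a ratio are drawn uniformly from the exact
integer pairs within 25 dots (`pair_mode = "sampled"`); the per-sample
error rate depends on the counts only through their ratio, so accuracy is
unaffected by this choice, while evidence magnitude (hence certainty
growth) scales with the pair — `pair_mode = "fixed"` pins the smallest
pair if that matters.

### A change-of-mind-rich regime

The reference parameterization produces very few changes of mind (< 1%),
as expected when fitted positions and accuracy dominate. To study
change-of-mind phenomenology we use a deliberately noisier regime:
`omega = 0.39` (the Weber fraction implied when reach dynamics are allowed
to inform the estimate), `D = 1` (memory-free sampling, so the belief can
still move late in the trial), `W = 2` (certainty saturates quickly, so
early wrong commitments penetrate deep enough to count), and flights of
0.8 ± 0.15 s. There, change-of-mind rates rise steeply with ratio
(≈ 0 / 6% / 22% at ratios 0.5 / 0.75 / 0.9), the large majority are
corrective (incorrect→correct), and double changes of mind occur at
≈ 0.1–0.3% — well below single ones.

## Numerical choices

* Explicit Euler at `dt` = 1 ms; the remaining time δ is clamped at `dt`
  to avoid the finite-horizon singularity as $t \to t_f$. Against the
  closed-form minimum-jerk polynomial
  $x_f(10\tau^3 - 15\tau^4 + 6\tau^5)$ the integrated trajectory is
  accurate to well under 1% of the amplitude for $t_f$ between 0.4 and 1 s.
* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before entropy
  evaluation; certainty saturates at 1 long before the clip matters.
* At exactly $p = 0.5$ the heading tie goes to the positive-frame side;
  certainty is 0 there, so the motor update vanishes and nothing depends
  on the rule.
* Equal-count trials have no correct side; internally the frame defaults
  to left-positive, and all reported statistics are invariant to that
  choice (verified by mirror tests).
* The collapse clock of the bounded accumulator uses seconds by default:
  with collapse rates near 3.5 a per-ms clock flattens the bound within a
  few ms, which is incompatible with any non-degenerate RT structure. Both
  units are exposed (`t_unit`).
* Per-trial RNG streams are derived from (master seed, trial index), so
  datasets are bit-reproducible and independent of execution order.
* Degenerate inputs: when no evidence sample arrives within `max_wait_s`
  the trial ends at rest, flagged no-evidence/non-responsive; immobile
  trajectories have undefined RT (flagged, not imputed).

## Trajectory analysis conventions

Recorded or simulated trials are time-normalized to 101 points by linear
interpolation. Two windows are available for simulated trials: the full
trial span from stimulus onset (the default for model summaries — the slow
pre-lift-off phase carries the certainty signature that identifies the
sampling parameters) and the lift-off window from the 0.28 mm displacement
onset to arrival, which is the span a motion-capture recording covers and
the window in which "reach becomes direct under a rising gate" is the
meaningful statement; recorded datasets begin at lift-off, so for them the
two coincide. A trial is *correct* when at least 50% of its points —
including the endpoint — lie on the correct side of the screen midline.
Left trials are sign-flipped so the correct target is positive, and
per-ratio mean trajectories, their scalar mean horizontal position (HP),
accuracy, mean RT and change-of-mind rates are tabulated
(`flip_and_average()`). Pull-back trials are excluded before analysis: we
flag a trial when the (lightly smoothed) distance to the screen rises at
least 0.5 cm above its running minimum. We deliberately use a
retreat-amplitude rule rather than an instantaneous velocity-sign rule:
at 200 Hz with millimetre-scale positional jitter the velocity sign is
noise-dominated and a naive rule flags most clean trials. HP is computed
over the full 101-point window (a sub-window is configurable).

## The synthetic-data generator

`generate_dataset()` emulates the *structure* of the study's data — 22
subjects, 420 trials each, five ratios {0.1, 0.25, 0.5, 0.75, 0.9}
(optionally ratio 1), per-ratio movement-time distributions, accuracy
drawn from the Weber psychometric model with a known `omega_true`,
minimum-jerk paths toward the chosen target, and injected change-of-mind
excursions (≥ 1 cm opposite-side dips), pull-backs (≈ 2 cm depth retreats
dented into the progress profile) and positional jitter — with every
latent recorded in the metadata. It is a generator-side construct,
deliberately independent of the decision model, so the analysis and
fitting stages can be validated against exact ground truth. What it does
*not* emulate: genuinely human kinematic variability (submovements,
velocity asymmetries), RT distributions beyond the displacement-onset
construction, attention drift across blocks. Tests passing on synthetic
data therefore validate the *pipeline*, not claims about human data.

## Fitting

`fit_threshold_free()` minimizes the sum of two mean-squared errors —
per-ratio mean horizontal positions and per-ratio accuracy, 480 simulated
trials per ratio per evaluation — over the box R ∈ [1, 100] ms,
D ∈ [0, 1], W ∈ [0.1, 100] (optionally ω and the gate threshold). The
objective uses common random numbers (one master seed for every
evaluation), making it deterministic given (parameters, seed); the best
point is re-evaluated afterwards with 10 fresh seeds to report loss mean ±
SD under new noise. The optimizer is a seeded Latin-hypercube exploration
(log-scaled for the variance parameter W, which spans three decades)
followed by a Nelder–Mead polish with fresh-simplex restarts under a hard
evaluation budget — restarts matter because common random numbers leave a
micro-rugged surface on which a single simplex collapses early. Any
derivative-free global method would do; the scientific content is the
objective, not the optimizer. Non-decision time is set manually, not
fitted. `fit_ddm()` does the same for the bounded accumulator against
per-ratio accuracy and RT quantiles {0.1, 0.25, 0.5, 0.75, 0.9}.

Parameter recovery on synthetic targets recovers D to within ±0.1 and W to
within ±50% (median over replicate fits) at 480 simulations per ratio;
the (R, W, D) objective has a genuine soft ridge — a longer sampling
interval with lower likelihood noise imitates a shorter one with higher —
so individual fits can land on the ridge even when the median is close.
When the gate threshold is freed on targets generated without one, the
objective is flat over small gates (a gate that binds only while
certainty is low changes nothing the brake was not already doing), so the
fit applies a nested-model parsimony rule: if zeroing the fitted gate
changes the loss by less than the resimulation noise, the nested
threshold-free member is reported, with the profile attached. On
threshold-free targets this concludes, correctly, that no positive gate
is supported.

## Known limitations

* Movement time is sampled, not generated: the model does not produce
  $t_f$ from task variables.
* No motor noise, muscle forces, or button-release force dynamics; RT
  differences are purely certainty-driven.
* The bounded accumulator with its published parameters and a literal
  per-ms sampling clock makes decisions within a few ms; the qualitative
  orderings survive but the RT scale is compressed relative to human data.
* Simulations at problem sizes quoted here (480 trials/ratio, 10 seeds,
  budgets of ~150 objective evaluations) were chosen as the package's
  reference conditions; all are configurable.
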