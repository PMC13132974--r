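---
title: "Models, generators, and design choices in numsize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, generators, and design choices in numsize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numsize)
```

## What the pipeline is for

In a numerosity comparison task two dot arrays are shown and the observer
picks the more numerous side. Classical psychophysics explains the
resulting distance and size effects as projections of a single ratio
effect, carried by a noisy analog magnitude system; a statistics-based
account instead derives the distance effect from the association between
values and the "larger" response (a value's rank within the session's set)
and the size effect from the values' frequencies. `numsize` implements the
experimental designs, trial-level generators, and the complete inferential
chain needed to tell these components apart in behavioral data, and to
validate that chain by recovery studies on data whose generator is known.

Two designs anchor everything. The omitted-range design uses
`{5, 10, 15, 35, 40, 45}`: deleting the middle of the range makes value
distance and rank distance disagree (15 vs 35 are 20 apart but adjacent in
rank), so the two accounts make distinguishable predictions about the
distance effect within a single session. The frequency designs present all
pairs of the multiples of 5 up to 45 under everyday (power-law-like),
uniform, or reversed-everyday token counts; only the size effect should
track this manipulation if it is a statistics effect, whereas a genuine
change of the psychophysical process would move distance and size effects
together.

## Generative models

**Diffusion (ratio-driven) observer.** Each trial is a two-boundary Wiener
first passage with unbiased start `z = a/2`, noise scaling `s = 0.1` (the
conventional constant), and drift `v = k·ln(large/small)` — the ratio
effect enters only through the drift. Defaults `k = 0.5` evidence-units/s
per log-ratio unit, `a0 = 0.10`, `ter0 = 0.30` s were chosen so that
simulated sessions land in the empirically ordinary regime for this task
family (single-digit-to-20% error rates, median RTs around 350–550 ms).
Per-participant heterogeneity is a log-normal multiplier on
`(k, a0, ter0)` with coefficient of variation 0.1 — enough to make
participants distinguishable without creating outliers.

**Frequency coupling.** The normalized pair frequency is
`phi(pair) = (f(x1)+f(x2)) / max(f(x1)+f(x2))`, computed from the
condition's base-frequency table; the sum structure mirrors the size
regressor, and phi is invariant to rescaling all token counts. Coupling is
multiplicative with gain `gamma` per targeted parameter and per-block decay
`delta`: threshold `a = a0·(1 − γ_thr·(phi − phi_bar)·δ^(block−1))`, and
analogously for nondecision time; a targeted drift is multiplied by
`(1 + γ_v·(phi − phi_bar)·δ^(block−1))`. Two choices deserve comment:

* *Centering on the session mean* `phi_bar` (the cohort generator's
  default) reads the coupling as adaptation to the session's frequency
  statistics. Without centering, a uniform session — where every pair has
  the maximal normalized frequency — would receive full coupling on every
  trial, compressing its whole RT-by-distance profile and manufacturing a
  between-condition distance-slope difference that has nothing to do with
  differential frequency. With centering, uniform sessions produce no
  differential coupling, the size-slope ordering everyday > uniform >
  reversed emerges, and distance slopes stay put. The single-trial
  simulator keeps the uncentered form (`phi_ref = 0`) for direct control.
* *Clamping*: effective threshold is floored at `0.2·a0` and nondecision at
  0, so extreme gains cannot produce degenerate processes.

The quantitative form of the coupling is one admissible instantiation — the
qualitative direction (frequent stimuli processed with a lower threshold
and/or shorter nondecision time, or a higher drift) is the modeled claim,
not the specific multiplicative algebra.

**Statistics-driven generator.** RT is Gaussian around
`rt_base − w_d·ln(Δbasis) + w_s·(1/u1 + 1/u2)` (truncated positive), and
errors are Bernoulli with a logistic mean using the same two terms. The
distance basis is either the initial numbers (`value/5`) or their ranks;
the size term always uses the initial numbers, because in this account the
size effect is frequency-derived from the values regardless of how the
distance effect is wired. Defaults (`rt_base` 0.62 s, `w_d` 0.06 s,
`w_s` 0.03 s, noise SD 0.10 s, error intercept −2.0, weights 1.0/0.6) put
per-participant R² of the correct distance regressor near the 0.4–0.7 band
typical of clean sessions of this length, while keeping the two regressors'
fits clearly separated in expectation.

## What the generators emulate — and what they do not

They emulate: the exact trial combinatorics of both designs; ratio-graded
accuracy and RT; per-participant parameter spread; frequency coupling with
optional block decay; and (for the statistics generator) distance effects
wired to value or to rank. They do not emulate: sequential effects between
consecutive trials (priming, post-error slowing), within-trial threshold
collapse, trial-to-trial drift/start variability (the full Ratcliff
model), perceptual confounds of dot displays (density, hull — geometry is
generated, but its influence on choice is not modeled), or learning other
than the imposed exponential decay. Passing recovery tests therefore shows
the inferential chain is sound for data of this structure; it does not show
real sessions contain no such unmodeled components.

## Numerical choices

* **First-passage simulation** is Euler–Maruyama at `dt = 1` ms with a
  Brownian-bridge crossing check inside each step (crossing probability
  `exp(−2·d0·d1/(s²·dt))` for the distances to a boundary at the step's
  ends). Plain Euler only detects a crossing at step ends and so
  systematically overshoots the boundary, biasing accuracy upward and
  decision time downward; the bridge check removes almost all of that bias
  and lets the simulator match the closed forms
  `P(correct) = 1/(1+e^{−va/s²})` and mean decision time
  `(a/2v)·tanh(va/2s²)` within Monte-Carlo error at 20,000 trials. Exact
  boundary hits absorb. Trials are censored at 10 s and scored by the sign
  of the accumulated evidence.
* **EZ closed forms.** Forward: `pc = logistic(L)` with `L = av/s²`, mean
  decision time `(a/2v)(1−e^{−L})/(1+e^{−L})`, and the correct-RT variance
  implied by the inversion identity. Inversion follows the standard EZ
  algebra; the round trip is exact to 1e−10 over
  `v ∈ [0.05, 0.4], a ∈ [0.08, 0.2], ter ∈ [0.2, 0.4]`. Perfect accuracy is
  edge-corrected to `1 − 1/(2n)` and flagged; `pc = 0.5` is refused because
  the drift's sign is undefined there.
* **Medians** of even-length samples are the mean of the central pair; no
  slow-RT trimming anywhere (the median is robust to slow outliers).
* **RT units**: seconds internally, integer milliseconds (half-up) on disk.

## Inference-layer choices

* **Model contrast**: paired two-sided Wilcoxon on per-participant R²,
  zeros dropped, exact null up to 25 informative pairs, normal
  approximation with continuity correction above; fewer than five
  informative pairs is refused rather than tested.
* **Slope contrasts**: Shapiro–Wilk at α = .05 per group gates a one-way
  ANOVA (ω² reported) versus Kruskal–Wallis; for the rank test the effect
  size is rank epsilon-squared, labeled explicitly as the rank analogue,
  and Dunn's z post hoc is reported unadjusted by default with Holm
  available — both conventions are exposed because neither is canonical.
* **Mixed 4 × 3 ANOVA** on block-wise slopes uses `aov` with
  `Error(participant/block)` and no sphericity correction by default, with
  a Tukey-adjusted post hoc on blocks via `emmeans`.
* **Power**: smallest N with noncentral-F power ≥ target at
  `ncp = f²·N`, stepped in multiples of the group count (equal per-group
  allocation, the planning convention for this design); an unconstrained
  integer sweep is available and gives N = 41 instead of 42 for
  `f = 0.64, α = .05, power = .95, k = 3`.
* **Exclusions** (all configurable): overall accuracy < 0.60
  ("random/swapped", with < 0.50 additionally marked as likely key swap),
  RT distance-fit R² < 0.20, within-condition size-slope |z| > 3.5. The
  accuracy rule operationalizes "responded randomly", which is otherwise a
  judgment call.

## The frequency-mechanism classifier

Attribution uses the canonical signature table (drift: faster and more
precise; threshold: slower and more precise; nondecision: slower with
unchanged precision; faster without a precision gain: a threshold and/or
nondecision decrease). The behavioral contrast feeding it needs care:
within one condition, pair frequency is a fixed property of the pair, so
any frequency stratification is also a difficulty stratification and a
null cohort would look drift-coupled. The report therefore compares the
two supplied conditions whose frequency tables differ most (everyday vs
reversed-everyday canonically), scoring every participant with the same
pair weights `u(pair) = (phi_A − phi_B) · h(pair)` (h a per-participant
harmonic trial-count precision factor, weights normalized) and testing the
scores between groups. Identical weights make pair difficulty cancel
exactly; simulated null cohorts produce empty attributions at the nominal
rate. Per-stratum EZ estimates are still reported — with an explicit
warning that the unequal per-cell trial counts inherent to frequency
manipulation bias quantitative recovery, which is why the classifier, not
the point estimates, is the supported inference path.

Demonstration gains: threshold coupling is shown at `γ = 0.3`, where the
RT signature is overwhelming (standardized effects around −3). For drift
coupling the same gain yields standardized effects near −0.8 on both
measures, and the joint RT-and-ER significance the drift verdict requires
is only intermittently reached at 20 participants per condition — a real
sensitivity limit of the unequal-cell design, not of the classifier — so
the packaged demonstrations and tests use `γ_drift = 0.5`, where the
verdict is reliable.

## Problem sizes used in the packaged runs

The analysis scripts and the test suite use full-size sessions (600 and
roughly 1,600 trials) with cohorts of 14–28 participants, 50-replicate
recovery loops for the model contrast, and 20,000-trial simulator
validation; the whole suite completes in well under a minute of simulation
time thanks to the compiled first-passage core.

## Known limitations

* The EZ layer assumes an unbiased start and no across-trial parameter
  variability; it is a diagnostic, not a full diffusion fit.
* The frequency classifier requires at least two conditions with different
  frequency tables; a single-condition session cannot separate frequency
  from difficulty by design, and the function says so rather than guessing.
* Block effects are modeled as geometric decay of the coupling only; real
  sessions may drift in speed or caution for other reasons.
* Dot-array geometry is generated and checked (non-overlap, containment,
  balanced colors), but the visual front end that would turn geometry into
  evidence is outside the model: numerosity enters the generators directly.
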