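---
title: "Models and methods in rootabc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rootabc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rootabc)
```

`rootabc` infers the mechanistic parameters of a deliberately coarse-grained
stochastic model of root system architecture from observed or synthetic
summary data, and selects between competing model structures, using
approximate Bayesian computation (ABC) in a sequential Monte Carlo (SMC)
sampler. This vignette records the model, the numerical choices, and the
limits of what the shipped tests demonstrate.

## The generative model

A plant is reduced to a primary root plus first-order laterals; branching
angles, 3-D embedding, higher-order laterals and root radius are outside the
model on purpose — the summaries used for inference are purely topological
and metric, which keeps the approach portable across simulators and imaging
pipelines.

**Elongation.** From an infinitesimal initial condition, the primary root
length follows either the linear law $l(t) = g t$ or the saturating
negative-exponential law
$$ l(t) = l_{\max}\left(1 - e^{-g t / l_{\max}}\right), $$
with $g$ in cm day⁻¹ and $l_{\max}$ in cm. The linear law is the
one-parameter special case ($l_{\max} \to \infty$; implemented with
`expm1`, so the two agree to machine precision in that limit). A lateral
initiated at time $t_0$ has length $l(t - t_0)$ under the same law with rate
$\alpha g$, $0 \le \alpha \le 1$. We read the lateral scaling as applying to
the rate only: laterals share the primary's $l_{\max}$. The alternative
(scaling $l_{\max}$ too) is defensible but adds nothing identifiable at the
data sizes considered here, so we keep the minimal reading.

**Branching.** Three placement mechanisms are provided. Under *uniform*
branching, events arrive as a Poisson process with constant rate $b$ day⁻¹
— per unit time, not per unit root length — and each event places a branch
uniformly on $(0, L(t))$. The *minimum separation* variant discards a
proposal landing within $\delta$ cm of an existing branch; the Poisson
event is consumed, i.e. the Gillespie clock advances past it rather than
re-drawing the position, which makes the realised branching rate
state-dependent. The *fixed spacing* variant emulates spacing-based
simulators: branch $k$ sits at arc position $k d$ and initiates
deterministically when the tip first reaches it (the inverse of the growth
law in time), up to $b_{\max}$ branches. The emergence timing of
spacing-based simulators is not uniquely defined by their published
descriptions; tip-passage is the simplest causal choice and is stated here
as an emulation, not a port.

**Simulation.** Elongation is deterministic between branching events, so
the hybrid algorithm just draws all event times up to the horizon
(exponential waiting times; for uniform branching the positions are
history-independent and the whole event set is vectorised), then evaluates
primary and lateral lengths in closed form at each requested observation
day. Snapshots are cumulative: a branch present at day $t$ is present, with
a longer lateral, at every later day.

## Summaries and distance

An observation is the triple $\{B, L, \hat l\}$: branch count, primary
length and mean lateral length (0 if no branches; a just-initiated,
zero-length lateral still counts towards $B$). Two triples are compared by
the scaled Euclidean distance
$\rho = \sqrt{\tfrac13[(\Delta B)^2 + (\Delta L)^2 + (\Delta \hat l)^2]}$,
optionally with per-feature weights; a dataset distance is the plain sum of
$\rho$ over all matched (plant, day) pairs, with one simulated replicate
per observed plant (no averaging over replicates). Everything is in cm and
days; no internal rescaling is applied, so with unit weights one branch
miscounted trades off against $\sqrt{3} \approx 1.7$ cm of primary length.

Because the dataset distance is a sum, tolerances scale with the number of
(plant, day) pairs: a tolerance tight enough to pin an integer branch count
($\varepsilon < 1/\sqrt{3}$ per pair) is only attainable when the pair
count is small. The synthetic presets therefore consist of a single plant
observed at the 15-day horizon — matching how the emulated experiments were
designed — and the preset final tolerances (0.5 and 0.4) force an exact
branch-count match on that plant. Multi-plant datasets are fully supported;
the analyst should then choose $\varepsilon$ commensurate with the summed
distance.

## Priors, kernel and the SMC sampler

Default priors are uniform: $g, b \in (0, 1.4)$, $\alpha \in (0, 1)$,
$l_{\max} \in (5, 40)$ cm; spacing parameters take uniform priors set per
analysis (e.g. $d \in (0.1, 3)$ cm for the Lupinus-style runs). The
perturbation kernel is component-wise zero-mean Gaussian with standard
deviation $0.1 P$, $P$ the prior width — we read the kernel's "$0.1P$" as a
standard deviation, since as a variance it would imply moves of a quarter
of the prior width and the sampler would barely retain local structure. The
kernel is symmetric, fixed across populations, and proposals leaving the
prior box are rejected via the zero prior density rather than reflected or
truncated, which keeps the importance weights exact.

The SMC follows the standard likelihood-free model-selection scheme: the
model indicator is redrawn from its prior at every proposal (it is never
perturbed), the parameter particle is resampled by weight from the previous
population *of that model*, and the weight of an accepted particle is
$\pi(\theta) / \sum_j w_j K(\theta_j, \theta)$ with the sum over the
previous particles of the same model. Weights are normalised within each
model, and the posterior probability of a model is its particle fraction in
the population. First-population particles get uniform weights — a
"zero weights at $t=0$" convention is sometimes written down for this
scheme, but taken literally it would annihilate every later population, so
uniform initial weights are the only consistent reading. A model that loses
all particles in some population can no longer be proposed (its effective
prior mass is zero); this is reported when verbose. The tolerance schedule
defaults to final-$\varepsilon$ × {5, 3, 2, 1.5, 1}. A configurable
attempts cap (default $10^7$ per population) turns an unattainable
tolerance into an explicit non-convergence error naming it.

Determinism: every stochastic entry point takes a `seed` argument and
restores the caller's RNG state, so a fixed seed reproduces a fit
bit-for-bit in sequential mode.

## Synthetic presets

Two presets emulate published simulator parametrizations used for
validating recovery: *Arabidopsis* (negative-exponential, $g = 0.49$
cm day⁻¹, lateral rate 0.08 cm day⁻¹, spacing $d = 0.2$ cm, growth-rate CV
0.1, spacing CV 0.45, 15 days) and *Lupinus* ($g = 1$ cm day⁻¹, laterals
0.2 cm day⁻¹, $d = 0.9$ cm, same CVs, 15 days). Values not fixed by those
parametrizations were chosen once: $l_{\max} = 20$ cm (Arabidopsis) and 30
cm (Lupinus), plausible asymptotic scales for plate-grown plants of each
species that keep day-15 growth visibly saturating without capping it; a
branch cap $b_{\max} = 50$ that never binds at these spacings; and the
Lupinus CVs reuse the Arabidopsis ones since its source states none.
Per-plant rates are the preset means times truncated-at-zero Gaussian
factors (the emulated simulators publish CVs, not distributions — Gaussian
multiplicative noise is the least-structured choice); spacing noise is
per-gap and multiplicative. Presets default to one plant observed at day
15, the single-instance design of the experiments they emulate;
`fixture_spec()` generalises all of this, and every fixture carries its
ground truth (means and per-plant realised rates) for recovery checks.

What the fixtures do *not* emulate: basal/apical unbranched zones, tropism
and geometry, measurement error from image tracing, and the exact noise
distributions of the emulated simulators. Passing recovery tests therefore
demonstrates that the inference machinery recovers the generative
parameters of *this* model family under realistic variability — not that
the model is adequate for any particular experimental dataset.

## Numerical choices and degenerate inputs

* Weighted quantiles invert the weighted empirical CDF; the posterior mode
  is the midpoint of the heaviest of 30 equal-width bins over the sample
  range (a fully degenerate, single-value posterior returns that value).
* A zero branching rate is a valid model (no events, `Inf` waiting time);
  a zero-length primary accepts branches only at position 0.
* Under the negative-exponential law, positions at or beyond $l_{\max}$
  are never reached (`Inf` emergence time), so fixed-spacing branching
  stops naturally below the asymptote.
* Distance computations match plants and days by key, not row order, and
  reject shape mismatches naming the offending (plant, day) pair.
* Readers validate rather than coerce: exact header, strictly increasing
  days per plant, integral non-negative counts. RSML lengths are summed
  polyline segment lengths converted to cm via the document's
  resolution/unit metadata (assumed cm, with a warning, when absent);
  a lateral's position is the primary arc length at the vertex nearest the
  lateral's first point, since RSML stores geometry, not arc positions.

## Problem sizes in the shipped tests

The test suite and the acceptance script run complete SMC fits at 500
particles for the preset recoveries (the fixed-spacing runs are
deterministic given parameters and complete in seconds; the uniform
branching run on the Arabidopsis preset is the slowest, a few minutes,
because matching a ~30-branch count through a Poisson tail near the upper
edge of the $b$ prior is rare). Property-style checks use reduced sizes —
100–300 particles, single plants, short schedules — chosen to keep each
statistical assertion's Monte-Carlo error well inside its tolerance.

## Known limitations

* The branch-count term dominates the unweighted distance for bushy root
  systems; feature weights exist but defaults follow the cm/count scales.
* With a single observed instance, $g$ and $l_{\max}$ trade off along a
  level set of $l(t_{obs})$; time-course data largely resolves this, and
  $l_{\max}$ posteriors otherwise tend to recover their prior.
* Posterior modes for spacing parameters concentrate on the *realised*
  mean inter-lateral gap of the observed plant, which for one plant with
  per-gap CV 0.45 scatters around the generative $d$ with sd
  $0.45\,d/\sqrt{B}$ — a sampling fact of single-instance designs, not an
  estimator defect.
* Model-selection probabilities inherit Monte-Carlo noise of order
  $1/\sqrt{N}$; with $N = 120$–500 particles, trends across populations are
  meaningful, small differences are not.
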