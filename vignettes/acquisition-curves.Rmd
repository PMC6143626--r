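---
title: "Detecting conformist transmission from acquisition curves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conformist transmission from acquisition curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformsim)
```

## The generative model

`conformsim` simulates a well-mixed population of `n` individuals, each
exhibiting one of two behavioural variants, A or B. Time is a sequence of
asynchronous copying events: each event draws one focal individual
uniformly at random, pairs it with a demonstrator, and applies a learning
rule. This is a Moran-like neutral copying process with absorbing states
at frequency 0 and 1; every implemented rule preserves those absorbing
states, and runs deliberately continue past fixation, because pooled
acquisition data in this literature include the (large) post-fixation
mass of no-change events.

Four rules are implemented (`rule_config()`):

* `random_copy` — the neutral baseline. The demonstrator's variant is
  always adopted. Expected variant frequency is conserved (a martingale),
  which the test suite checks directly across replicate runs.
* `variant_preference` — a direct bias. One variant is preferred by the
  whole population; on exposure it is copied with probability 1, the
  other with probability `p_less` ∈ [0, 1] (default 0.2, the worked-example
  value throughout this literature). The preferred variant is redrawn
  uniformly each repetition unless fixed.
* `demonstrator_subgroup` — a model bias. Demonstrators are drawn
  uniformly from a fixed random subset of size `dm` (default 5);
  subgroup members, when focal, also copy from the subgroup. Because a
  five-member neutral group drifts to internal fixation quickly, the
  subgroup soon broadcasts one variant with certainty.
* `conformist_reference` — a positive control that genuinely implements
  conformity: sample `conformist_sample` (default 3) distinct
  demonstrators and adopt their majority variant. It exists so the
  detection machinery can be validated against a rule that *should* be
  flagged, and is not one of the rules under scrutiny.

Event scheduling is asynchronous (10,000 single-focal events by default)
rather than synchronous rounds; with uniform focal sampling the two are
statistically equivalent for pooled curves, and the event framing matches
how the copying process is described in this literature. Self-copying is
excluded by default — an individual is not a social source for itself —
but `allow_self_as_demonstrator = TRUE` restores the permissive behaviour
for replication purposes, and the mean-field comparisons below use it
deliberately.

### Starting conditions

`run_batch()` supports three start modes, because the starting condition
turns out to be the crux of several published claims:

* `fixed_half` — every run starts with each individual independently A
  with probability 0.5 (a binomial draw; `init_mode = "exact_round"`
  forces exactly half for controlled experiments).
* `uniform_increments` — the initial probability sweeps 0 to 1 in 0.001
  steps. The mapping from run index to grid value is deterministic (the
  grid is thinned evenly when fewer than 1001 runs are requested), so
  coverage of the frequency range is uniform at any replication level.
* `rare` — the initial probability is drawn uniformly from
  {0.01, ..., 0.10} per run: small enough that the variant starts as a
  genuine minority, nonzero so it can occasionally spread. This
  operationalizes "initially rare", which the source analyses leave
  unquantified.

## What is measured, and how that decides the answer

For a tracked variant, two measurement axes are configurable
(`frequency_spec()`, `outcome_spec()`), and most of the package's
substantive results are statements about how conclusions flip along them.

**Frequency of what?** `individual_state` counts individuals currently
exhibiting the variant (optionally excluding the focal);
`behaviour_full_history` counts the variant among *all* behaviours
performed so far in the run; `behaviour_window` counts it among the last
`window_T` performed behaviours (default T = 10, the benchmark window in
the window analyses). The behaviour stream records the focal's post-event
performance, one behaviour per event; the demonstrator's displayed
variant stays in the log so the alternative reading remains computable.
Windowed frequencies are undefined until a full window exists
(`burn_in = "skip_until_full_window"`); such events are excluded from
curves. The window sweep instead defaults to `use_partial`, because a
window as long as the run has no complete-window events at all and the
sweep should converge smoothly to the full-history measure at its top
end.

**What counts as adoption?** Three conventions:

* `copy_event` (default): every demonstrated event counts; success means
  *that variant was demonstrated and copied*. Retaining A against a B
  demonstration is not a success. This convention makes the neutral
  baseline exactly linear — under random copying the success probability
  is the probability of sampling an A demonstrator, i.e. the frequency
  itself — and yields the slope-1 / slope-`p_less` component lines of
  the direct-bias analysis.
* `end_state`: success means the focal *ends the event* exhibiting the
  variant, retention included. This is the convention of the closed-form
  model below.
* `exposure_conditional`: only events demonstrating the variant count;
  success means ending with it. Exposed because the verbal description
  of the disputed original measure is conditional; reported alongside,
  never silently substituted.

## Curves, fits, and the comparison rule

`build_curve()` bins counted events by frequency into left-closed,
right-open bins of width 0.01 — the natural k/N resolution at N = 100, so
state-based frequencies suffer no binning loss — with the last bin closed
so a frequency of exactly 1 is kept. `fit_linear()` is exact closed-form
weighted least squares of per-bin adoption probability on bin centre,
weighted by per-bin event counts; fitting the *plotted curve* (binned,
count-weighted) rather than raw 0/1 outcomes matches how best-fit curves
are drawn in this literature and keeps r² well defined.

`fit_sigmoid()` defaults to a two-parameter logistic so that the
linear-versus-sigmoid comparison is between equal-complexity models and a
raw r² comparison is fair — a four-parameter logistic can mimic any line,
which would make "linear fits better" unobservable by construction. It is
fitted by BFGS from six gain starts (±1, ±5, ±20, intercepts centring the
curve at 0.5) plus a logit-regression start, keeping the best converged
optimum. The one-parameter frequency-bias form
`x^θ / (x^θ + (1−x)^θ)`, with fixed endpoints and θ = 1 as neutrality, is
available as `form = "freq_bias"` and is fitted by 1-D search on log θ.

Numerical conventions, all logged in code where they apply: weighted r²
is defined as 1 when the weighted residual sum of squares is ≤ 1e−12
(exact fits, zero-variance curves), otherwise 1 − SSres/SStot with SStot
floored at 1e−12; `compare_fits()` treats |r²(linear) − r²(sigmoid)| <
1e−6 as a tie and reports it as linear, conservatively refusing to infer
conformity from noise; a failed sigmoid optimization degrades to a
flagged linear-only comparison rather than an error. Degenerate inputs
signal early: curves need at least two (linear) or three (logistic)
nonempty bins; a lone self-excluded subgroup member produces recorded
no-demonstrator events that no convention counts.

`window_sweep()` re-measures the same runs at ~30 log-spaced window sizes
(anchored at 10 and 2000) and `crossover_window()` reports the smallest
window from which the sigmoid stays ahead at every larger sampled window
— isolated small-window sign flips, which occur when one or two bins
exist, do not count.

## The closed-form direct-bias model

With p the frequency of A, q the probability of copying the
less-preferred variant, and r the fraction preferring A,

`Prob(A) = p [p + r (1 − p)(1 − q)] + (1 − p) [r p + (1 − r) p q]`

(`prob_adopt_a()`). The first bracket is retention, the second
switching; the dependent measure is thus the `end_state` convention. The
test suite verifies the collapses (identity at r = ½ and at q = 1,
concavity at r = 1, convexity at r = 0), monotonicity in p, and — the
central oracle equivalence — that simulated end-state curves match the
formula pointwise within binomial error. That comparison is run with
self-copying allowed and grouped by exact frequency value: the analytic
model is mean-field (the observer effectively samples the whole
population, itself included), so with self-exclusion the comparison
would be biased by O(1/N) by construction, and the last 0.01-wide bin
would conflate p = 0.99 with the post-fixation mass at p = 1.

`regime_union_curve()` evaluates the model piecewise — r = 0 below
p = 0.5, r = 1 above — reproducing the artefactual sigmoid that emerges
when data from the two preference regimes, each confined to its half of
the frequency range by 50/50 starts, are pooled. `mixture_of_lines()`
reconstructs the concave-up pooled curve of uniform starts as the
density-weighted average of the slope-1 and slope-q lines; the weight
function the original analyses used is unspecified, so the default is the
empirical per-bin density weighting (computable via
`mixture_weights_from_curves()`), and the reconstruction is asserted
against the simulation itself within Monte-Carlo error.

## What the scenario drivers establish

Each `scenario_*` driver binds simulator, measurement and fitting into
one named analysis and accepts reduced replication for desk-scale runs.
The test suite runs them at 150–500 replicates (and one check at the full
1000) of full-length 10,000-event runs; the acceptance script uses 300
replicates for the window sweep and subgroup boundary and 500 for the
stratified slopes. At those scales the suite establishes, among others:

* neutral copying + state frequency: slope within [0.97, 1.03],
  intercept within ±0.02, linear-better;
* variant preference, uniform starts, stratified by preference: lines
  through the origin with slopes ≈ 1 and ≈ `p_less`; pooled, the curve
  is concave-up (every well-populated interior bin below the identity
  chord), not sigmoidal;
* variant preference, 50/50 starts, pooled: the artefactual sigmoid;
* demonstrator subgroup at Dm = 5: sigmoid-better at 50/50 starts, and
  the largest sigmoid-winning Dm in {5, 10, 20, 50} is 5; under rare
  starts the sigmoid advantage collapses;
* neutral copying measured by full behaviour history: sigmoid-better on
  the same runs whose state-frequency curve is linear; with T = 10
  windows, linear again; the sweep's crossover window exceeds 2000.

Two shape-versus-verdict distinctions deserve note, since they are design
choices. For the subgroup rule under *uniform* starts, the sigmoidal
shape persists — flat boundary segments, central slope above 1 — but its
weighted-r² advantage over a line is a near-tie whose sign is unstable at
any practical replication; the suite therefore asserts the shape
signature, which is what "the sigmoid remains apparent" can honestly
mean. Conversely, for the pooled uniform-start preference curve, a
shifted logistic can fit a convex curve as well as a line, so
"sigmoid-better by r²" would not imply an S-shape; the suite asserts
convexity directly. And one validation is deliberately left failing: the
conformist positive control under *rare* starts. With the tracked variant
starting at ≤10% of a 100-individual population, conformity drives it
extinct in essentially every run, the pooled curve never leaves the
convex lower limb, and the symmetric logistic — which must place its
inflection somewhere — loses to a line there at any stable scale. The
fixed-endpoint frequency-bias sigmoid does detect the conformity on that
restricted range (fitted θ ≈ 1.7), and the suite asserts that alongside
the failing default-form expectation, because a detection machinery that
cannot see conformity in rare-start data is a finding, not a bug to
paper over.

## What the generator does and does not emulate

The simulator reproduces the generative settings of the computational
models under scrutiny: well-mixed interactions, binary variants, fixed
population size, one copying interaction per event, complete and
error-free event logs. It does not emulate network or spatial structure,
demography, more than two variants, observation error, or real-time
(rather than event-count) history windows — all of which shape real
diffusion data. Passing tests therefore validate inference *within* this
model class: they show which measurement conventions manufacture or
destroy sigmoids given the model's own assumptions, not that any
particular empirical dataset is free of such artefacts.

## Reproducibility

All randomness flows from integer seeds: run i of a batch uses
`base_seed + i − 1`, and scenario drivers space their internal batches so
seed ranges never overlap. Rerunning any scenario with the same base seed
reproduces event logs bit-for-bit, and serialized outputs
(`write_outputs()`) carry md5 checksums plus the configuration hash in a
manifest so that reruns are verifiable.
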