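---
title: "Simulating social learning on the virtual arrowhead task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating social learning on the virtual arrowhead task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrowsim)
library(dplyr)
```

## The task and its model

The virtual arrowhead task is a standard laboratory paradigm for
studying the cultural evolution of technology. A participant (or, here,
an agent) repeatedly designs an arrowhead by setting five attributes —
`length`, `width` and `thickness` (integers 1–100) plus `shape` and
`color` (four options each) — and "goes hunting", receiving a score in
hypothetical calories. The score is governed by a hidden fitness
landscape: each attribute contributes **additively and independently**
to the expected score, each continuous attribute's contribution is
**unimodal** with an unknown peak, and the displayed score is the
expected score plus zero-mean Gaussian perception noise (SD 5
calories), hard-bounded to [1, 1000]. A session has three seasons of 30
trials; the landscape changes between seasons and is fixed within one.

`arrowsim` implements this environment, the learning algorithms used to
model behaviour in it, the generator of artificial "other hunter"
exemplars that delivers positive or negative social information, and
the statistical pipeline used to compare experimental conditions.

## The landscape family

The task literature specifies the landscape only through constraints
(additive, independent, unimodal per attribute, expected score 1 to
1000). We therefore use a pluggable single-attribute contribution
function with a Gaussian bump as the default:

$$c_i(x_i) = m_i \exp\!\left(-\frac{(x_i-\mu_i)^2}{2 w_i^2}\right),$$

with peak location $\mu_i$ (the attribute's optimum), peak height $m_i$
(its maximum calorie contribution) and width $w_i$ (attribute units).
`make_landscape()` enforces calibration — the maxima, plus the best
categorical options, must sum to the 1000-calorie ceiling, so the joint
optimum scores exactly 1000 — and rejects non-positive widths. Any
other unimodal family can be supplied through the `contribution`
argument without touching the rest of the package.

Perception noise is added *after* summing contributions and the result
is clamped to [1, 1000], the only reading consistent with a hard
printed score range. Trajectory summaries are computed on the
*expected* ("true") fitness, excluding perception error, which is how
cohort results for this task are conventionally displayed.

### Demo parameter values

The per-season optima and widths used in the original task program are
not published, so `demo_landscapes()` ships an illustrative,
documented set: optima (57, 30, 70), (25, 72, 40), (80, 45, 15) for
seasons 1–3; maxima 500/300/200 calories (attributes matter unequally,
as in the original task where one attribute dominates); widths 12
attribute units; noise SD 5. The width was chosen so that the
informative region of an attribute (within roughly $2w$ of its peak)
covers a minority of the 1–100 range: asocial hill climbers starting
from random designs then plateau well below the ceiling within a
season, which is the qualitative signature of human asocial
performance on this task. No numeric equivalence with the original
program's landscape is claimed, and none of the package's conclusions
depend on these particular values — they are configuration inputs
(`read_landscape_config()` reads a YAML file with the same structure).

## Learning algorithms

**Win-Stay (asocial).** The agent memorizes the previous trial's
perceived score and one modification direction (±) per continuous
attribute. Each trial it picks one of the three attributes uniformly at
random, moves it by $L_i = 5$ units (the median empirical modification
size reported for this task) in the memorized direction, and hunts. If
the perceived score did not decrease, the direction is kept; if it
decreased, it is flipped. Only the focal attribute's direction can
change in a trial. Three boundary decisions are worth stating:

* *Ties keep the direction* — "did not decrease" includes equality.
* *First trial of a season*: the previous score is undefined (the
  landscape just changed), so the score is stored without flipping.
* *Attribute bounds*: a step that would leave [1, 100] is clamped. If
  the clamped move changes nothing, the score does not decrease, so
  under the rule as stated the direction is kept. With noise on, the
  agent escapes such a wall quickly (a lower noise draw flips it); with
  noise off it can pin. The `flip_at_wall` option in `agent_params()`
  flips the direction whenever a clamped step goes nowhere; it is off
  by default because the rule as printed does not include it.

**CSI (copy-successful-individuals).** On a social trial the agent
adopts *all* the single-attribute modifications shown by the exemplar
hunters at once. Because contributions are additive and each hunter
modified exactly one attribute, the combined design's expected fitness
is at least that of every single hunter's design, unless clamping at an
attribute bound interferes — a property the test suite audits directly.

**Reverse (negative observational learning).** The agent moves every
attribute *opposite* to the modification made by the corresponding
unsuccessful hunter: a hunter that changed attribute $j$ by $L_{s,j}$
leads the agent to apply $-L_{s,j}$. Away from a peak this converts
"what made things worse" into an improving move; near a peak, where
moves in both directions worsen fitness, the reversed move overshoots,
so Reverse agents gain early and stall later — the pattern the cohort
simulations reproduce.

## Social information ("other hunters")

Exemplars are generated from the learner's previous design (the
*reference*) and the score actually displayed for it:

1. Draw an absolute magnitude from $|N(10, 10^2)|$ (attribute units,
   rounded to the task's integer grid; a draw that rounds to zero is a
   failed attempt).
2. Choose the sign that *strictly* increases (positive condition) or
   reduces (negative condition) expected fitness; clamp to [1, 100].
3. Add fresh $N(0, 5^2)$ perception noise to the hunter's true fitness
   and clamp to [1, 1000].
4. Accept only if the hunter beats (positive) or trails (negative) the
   reference in **both** true and displayed score, strictly; otherwise
   resample magnitude and noise, up to 10,000 times.
5. If no acceptable combination is found, the hunter is a *fallback*
   copy of the reference — typical at the landscape maximum (positive)
   or at the score floor (negative).

Experiment mode produces four hunters; since there are only three
continuous attributes and the assignment is not published, each
attribute gets one hunter and the fourth modifies a uniformly drawn
attribute, guaranteeing full attribute coverage. Simulation mode
produces exactly one hunter per attribute (three), which is what the
cohort engine uses. When both signs strictly qualify (possible only in
the negative condition), the deterministic tie-break picks the sign
with the larger change in the required direction. Strictness follows
from the fallback clause: if equality were acceptable, a fallback would
never be needed. Two numerical points: acceptance is decided on the
*resulting total fitness* rather than the raw contribution difference,
so a gain smaller than floating-point resolution at the total does not
count as "strictly better"; and attempts are drawn in vectorized blocks
for speed, with the first qualifying attempt in draw order accepted.

## The cohort engine

`run_cohort()` runs `n_agents` independent agents through all seasons.
Social opportunities arrive every third trial of Seasons 2–3, on trials
2, 5, …, 29 (the phase is a config knob; 2 is the earliest trial with a
previous design to reference). On a social trial the social update
*replaces* the Win-Stay modification — one design change per trial,
mirroring one hunt per trial — the new design is hunted, and the
previous-score memory is refreshed; the direction memory is left
untouched, since the Win-Stay rule updates one attribute's sign only on
its own trials. At a season boundary the design carries over but the
previous-score memory resets, because the old score refers to a
landscape that no longer exists. Each agent consumes an independent
substream seeded from the master seed, so cohorts are reproducible
bit-for-bit and agents can be regenerated independently.

## The analysis pipeline

The condition comparison mirrors the standard analysis for this task:
a participant's overall performance in a season is their mean score
over its 30 trials; each social condition is compared with the asocial
baseline per season by **Welch's t-test** (unequal variances,
Satterthwaite degrees of freedom) with **Cohen's d** in the pooled-SD
form; the significance threshold is Bonferroni-corrected for the six
comparisons (two conditions × three seasons), $\alpha = 0.05/6 \approx
0.0083$. `f_variance_test()` (two-sided variance-ratio F-test) and
`one_sample_t()` cover the secondary analyses. All tests are two-sided.
The summary-based implementations are cross-checked in the test suite
against `t.test()` and `var.test()` on raw data with identical moments,
and against numerical integration of the F density.

Recomputing the published statistics of the experiment this package
models from its *rounded* group summaries reproduces them to two
decimals, with two known exceptions inherent to rounding: the Season-1
positive-vs-asocial t (2.04 from rounded summaries vs 2.05 printed) and
the Season-3 negative-vs-asocial d (−0.07 vs −0.08). These are
documented, not "fixed".

## Synthetic datasets

`generate_fixture()` emulates a trial-level experimental dataset so the
pipeline can be exercised without any external download. In target mode
it draws each participant's season mean from per-(condition, season)
normal targets (defaults: `reference_condition_summaries()`) and
scatters per-trial scores around it with SD 50 calories, centred so the
season mean is exact — group summaries of the fixture are then draws
from the stated targets, which makes sampling-distribution checks
exact. Target-mode scores are synthetic summaries and are deliberately
not clamped to [1, 1000]; clamping would bias the group means away from
their targets. In simulate mode the fixture is real engine output per
condition. What fixtures do *not* emulate: human decision heuristics,
attribute trajectories (attributes are constants in target mode), and
any correlation between seasons within a participant. Passing tests on
fixtures therefore validate the statistical pipeline, not claims about
human behaviour.

## Problem sizes and reproducibility

The shipped checks use cohorts of 100 agents per condition for the
trajectory patterns (standard errors around 5–15 calories, separations
of interest hundreds of calories), 500 draws for the hunter
post-condition audit, 1,000 random inputs for the statistics oracle,
about 100 fixture replicates for the recovery checks and several
hundred for the family-wise-error estimate — sizes at which the
qualitative conclusions are far outside Monte-Carlo error. All
randomness flows from master seeds through derived substreams.

## Known limitations

* The exact closed-form landscape and per-season optima of the original
  task program are not published; the Gaussian family here satisfies
  every stated constraint but is not claimed to be numerically
  identical.
* Whether the original simulation flipped direction memory at attribute
  bounds, or performed an additional asocial step on social trials, is
  unstated; both choices are documented options here.
* The simulation ignores the two categorical attributes (as the
  original simulations did); experiment-mode configs may assign them
  nonzero contributions, but no learning rule acts on them.
* Alternative social-learning algorithm variants beyond CSI and Reverse
  are out of scope; the hunter/agent interfaces accept new update rules
  without core changes.
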