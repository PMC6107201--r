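---
title: "An agent-based model of mate choice in a treefrog chorus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of mate choice in a treefrog chorus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chorusim)
```

## The question

Female gray treefrogs (*Hyla versicolor*) choose mates in nocturnal
choruses where males advertise with pulsed calls. Call *pulse number* —
pulses per call — is the quality proxy: females show enhanced phonotaxis
toward longer calls, and preference experiments show they can discriminate
single-pulse differences. Two classic decision rules could generate the
observed behaviour:

* **best-of-n** (fixed-sample or pooled-comparison rule): assess a set of
  `n` candidates, take the best. Because a chorus can be heard from one
  spot ("cluster sampling") but individual calls are hard to separate in
  noise, the biologically plausible set is the `n` spatially closest males,
  with `n` between 1 and 5.
* **minimum threshold** (sequential-search rule): accept the closest male
  whose pulse number meets an internal acceptance threshold `theta`.

`chorusim` implements both rules (plus a random-choice control and a
no-mid-course-switching best-of-n variant) in a spatially and temporally
explicit simulation of a single night, so that the *consequences* of a rule
— mate quality obtained, distance walked, lost mating opportunities,
female–female competition — emerge from the interactions rather than being
assumed.

## The model

**Arena.** A rectangular swamp, 1000 x 2500 cm with hard edges
(`swamp_config()`). Positions are continuous; there is no grid.

**Males.** 25 males are placed sequentially under one of three regimes
(`sample_male_positions()`): `gaussian` (clustered at the swamp centre),
`inverse_gaussian` (density pushed to the edges, as on pond shorelines), or
`random` (uniform). A candidate position closer than 50 cm (a territory
diameter) to an already-placed male is rejected and redrawn, with an
explicit infeasibility error if a packing cannot be found. Each male draws
a pulse number once from `Normal(pop_mean, 2)`, rounded to an integer and
clamped to at least 1; it never changes, and males never move. The study
grid uses population means of 6, 12, 18 and 24 pulses/call.

**Females.** 5–20 females (operational sex ratios 0.2–0.8 against the 25
males) enter at the swamp margin: uniform positions along the full
perimeter (`sample_female_positions()`). All females in one night use the
same strategy. Females hear every male in the swamp — auditory sensitivity
supports this at this arena size — so the threshold and random rules can
target males anywhere.

**The cycle loop.** Time advances in 1-second cycles
(`run_night()` / `run_simulation()`), each with three synchronous phases:

1. *Retarget.* Every searching female re-evaluates per her rule.
   Best-of-n females recompute the `n`-closest set from their current
   position every cycle and abandon a living target only for a strictly
   better one (so every switch not forced by a mating trades up in pulse
   number). Threshold and random females keep their target until it mates.
   The no-switch best-of-n variant also re-chooses only when its target
   mates. A threshold female with no acceptable male left takes a single
   random-walk step and leaves unmated — because males are only ever
   removed, no acceptable male can appear later.
2. *Move.* Each targeted female steps straight toward her target by
   `min(speed, remaining distance)`.
3. *Mate.* For every male with a searching female within the contact
   radius, the nearest such female mates him (exact ties broken at
   random); both leave the pool and are not replaced. Proximity decides,
   not targeting: a female passing within reach of a calling male mates
   him, which occasionally mates a threshold female below her threshold.

The night ends when every female has mated or been removed; a 14,400-cycle
cap (a four-hour chorus) exists but is never approached in practice, which
the test suite monitors.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_males` | 25 | frogs | chorus size of the study design |
| `n_females` | 5–20 | frogs | sex-ratio sweep 0.2–0.8 |
| `pop_mean`, `pop_sd` | 6–24, 2 | pulses/call | empirical call-quality range and spread |
| `min_spacing` | 50 | cm | male territory diameter |
| `speed` | 2 | cm/cycle | a realistic walking pace; see below |
| `contact_radius` | 5 | cm | about one body length |
| `max_cycles` | 14400 | cycles | 4-h chorus; safety cap only |

`speed` and `contact_radius` deserve a caveat: the movement and contact
constants of the original field-calibrated design are not published in a
primary source we can draw on, so these defaults are calibrated choices,
not measurements. The dynamics are deliberately insensitive to `speed` —
all females move at the same pace, so trajectories and mate assignments are
invariant to it up to one-step discretization, a property the test suite
asserts — and absolute cycle counts are therefore reported but never
treated as results.

## The factorial study and its summaries

`sweep_config()` crosses 10 strategy:parameter pairs (best-of-1..5,
thresholds 6/12/18/24, random) with the 4 population means, 4 female
counts and 3 spatial regimes; 100 replicates per cell gives the full
48,000-night design, which `expand_sweep()` enumerates deterministically.
Each cell derives its own seed from the base seed and the cell labels via a
stable string hash, so any cell can be re-run bit-for-bit in isolation and
results cannot depend on execution order.

`summarize_outcomes()` reports the dependent variables — mate pulse number
(over mated females), distance traveled, distinct consecutive targets
(A–B–A counts 3 pursuit episodes), and percent mated — with 1.96 SE
confidence half-widths. **The unit of analysis is the simulation**: each
night's females are averaged first and nights weigh equally. Females
competing in one chorus are not independent, and pooling raw female rows
would additionally over-weight the crowded nights; both conventions are
available (`unit = "female"`), but the simulation unit is the default and
is what the class-level results quote. Distance can be restricted to mated
females (`mated_only_dist`) to separate travel cost from the
lost-opportunity effect: threshold females that give up walk only one step,
which deflates the all-female average.

The per-night fitness measure
(`fitness()`, `fitness_by_class()`) is

```
fitness = (1 - alpha) * (MeanPN - MinPN) / (MaxPN - MinPN)
        +      alpha  * (1 - (MeanDist - MinDist) / (MaxDist - MinDist))
```

with extremes taken over the entire outcome database and unmated females
contributing mate quality 0. `alpha` in [0, 1] encodes the environmental
pressure of the night: near 0 mate quality dominates (ample reserves),
near 1 travel cost dominates (e.g. predation). Effect sizes use
`cohens_d()` (pooled-SD, n−1 weighting), and `anova_report()` is a thin
layer over `stats::aov()` for the four-factor term tables.

```{r}
out <- run_sweep(sweep_config(strategies = c("best_of_n:3", "random"),
                              pop_means = 12, n_females_list = 10,
                              distributions = "random", replicates = 5))
summarize_outcomes(out)
```

## Numerical choices and degenerate inputs

* All ties are deterministic except where noted: equal pulse numbers go to
  the closer male, equal distances to the lower id; only exact
  equal-distance mating conflicts consume randomness. Runs are therefore
  bit-reproducible from their seed, across the R/C++ boundary (the engine
  draws from R's RNG stream).
* The threshold comparison is `pulsenumber >= theta`: qualities are
  integers, and a threshold equal to the population mean is meant to accept
  average males.
* Pulse numbers are rounded and clamped at 1 (a 6 ± 2 population would
  otherwise produce non-positive pulse counts).
* Gaussian placement uses truncated per-axis normals centred on the swamp
  with sd = extent/6 (≈99.7% of mass inside before truncation); the
  inverse-Gaussian regime shifts the same draw by half the extent modulo
  the extent, which moves the density peak to both edges. The true spread
  constants of the original design are unpublished; statistics that hinge
  on how accessible males are from the swamp edge (most visibly the
  *ratio* of travel distances between crowded and sparse nights) are the
  ones sensitive to this choice.
* Placement is sequential rejection sampling with a 10,000-rejection budget
  per male, after which an infeasible packing raises an error rather than
  looping forever.
* A best-of-n parameter larger than the chorus, a non-positive threshold,
  or an empty chorus are rejected at configuration time; an exhausted male
  pool mid-night removes the remaining females unmated.

## What the generator does and does not emulate

The synthetic chorus reproduces the study conditions: chorus size, quality
distributions, spatial regimes, sex ratios, synchronous arrival, and
single-night closure (mated pairs leave, nobody is replaced). It does not
emulate asynchronous arrival and departure over the night, male movement or
chorus-tenure dynamics, acoustic amplitude and masking, satellite males or
"hot-shot" lek structure, multi-night threshold adjustment, or mixed
strategies within one night. Conclusions from passing tests are therefore
about the decision rules under these idealized conditions, not about field
choruses: in real swamps the available pool fluctuates within a night and
perceived quality is confounded with distance through amplitude, neither of
which this model represents.

## Problem sizes

The bundled tests and the acceptance script run the full factorial grid at
20 replicates per cell (9,600 nights, plus 4,800 for the no-switch
variant), a desk-scale choice that keeps class-level means within a few
tenths of a pulse and a few cm of their 100-replicate values while running
in about two minutes on one core. Property-style tests use 10–100 seeded
repetitions per invariant.

## Known limitations

* The movement rate, contact radius and spatial spread constants are
  calibrated, not published; absolute cycle counts and edge-accessibility-
  sensitive ratios inherit that uncertainty (the crowding ratio of travel
  distances reproduces qualitatively — largest for best-of-n, smallest for
  random — but compressed relative to the reported magnitudes).
* Proximity mating means a small fraction of threshold females mate below
  threshold after passing a male closely; with a 5 cm radius this is rare
  but nonzero on long paths.
* The model is one night: lost-opportunity costs cannot be amortized over
  return visits, which the discussion of threshold strategies should keep
  in mind.
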