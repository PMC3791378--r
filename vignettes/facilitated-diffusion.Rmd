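---
title: "Simulating transcription factor target search on crowded DNA"
author: "fdSim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating transcription factor target search on crowded DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdSim)
```

## The model

Transcription factors (TFs) find their operators by *facilitated
diffusion*: cycles of three-dimensional excursions through the cytoplasm
and one-dimensional random walks (sliding and hopping) along the DNA.
`fdSim` implements an event-driven, continuous-time stochastic simulation
of this process in which every DNA-binding molecule is represented
explicitly and the DNA is a string over `{A,C,G,T}` — its 3D organisation
is deliberately disregarded.

The state of each molecule is either *free* or *bound at a left-aligned
position `i`*, where a bound molecule with footprint `f` occludes base
pairs `i .. i + f - 1`. The dynamics are:

* **Binding.** A free molecule carries an exponential clock with rate
  `assocRate` (per free molecule, s⁻¹). When it fires, a candidate
  position is drawn uniformly; if the footprint window is completely
  vacant the molecule binds, otherwise it stays free and redraws its
  clock. The 3D excursion is therefore implicit in the association rate,
  which is how cytoplasmic crowding enters the model.
* **Residence.** A bound molecule stays for an exponential time with mean
  `tau(i) = tau0 * exp(beta * score(i))`, where `score(i)` is the
  position weight matrix (PWM) score of the window — stronger sites hold
  the molecule longer. Non-cognate species are sequence-nonspecific and
  use a flat landscape (`score = 0` everywhere).
* **Moves.** When the residence expires the molecule slides one base pair
  left or right, hops (a uniform displacement on `±1..hopRange`), or
  unbinds, with fixed probabilities. Steric hindrance never allows two
  footprints to share a base pair: a blocked slide leaves the molecule in
  place (with a fresh residence draw), while a hop into an occupied
  window is treated as a micro-dissociation and returns the molecule to
  the free pool.
* **Obstacles.** An *immobile* species is placed at uniform-random
  non-overlapping positions at time zero (rejection sampling) and never
  moves; it may sit on the target. Because of steric exclusion, any
  obstacle whose left edge falls within `f_cognate + f_obstacle - 1` base
  pairs of the target start — 66 bp for the 21-bp repressor and 46-bp
  obstacles — blocks the target for the whole run.

The *target site* is a designated window (by default the 21-bp lac
*O1*-like operator embedded by the genome generator). A cognate molecule
*occupies* the target when its left edge sits exactly at the target
start; this definition is what makes the 66-bp exclusion arithmetic
exact. Per replicate the simulator records the first-passage time (the
first such arrival, censored at the simulated duration if it never
happens), the disjoint occupancy intervals, the occupancy fraction of the
cell cycle, and the time-averaged DNA coverage.

## Calibration and default parameters

The experimental anchor is that a TF molecule is non-specifically bound
to DNA about 90% of the time. On empty DNA a mobile molecule alternates
free periods of mean `1/k` and bound periods of mean `tau0/p_unbind`
(each visit survives a geometric number of residences), so requiring a
stationary bound fraction φ gives

```
k = φ / (1 − φ) · p_unbind / tau0 .
```

The package defaults are chosen once, to make this calibration
self-consistent with the published subsystem parameters:

| parameter | default | why |
|---|---|---|
| `tau0` | 1 ms | genome-average residence of a nonspecific visit in the millisecond range |
| non-cognate `moveProbs` | (0.38, 0.38, 0.04, 0.2) | mean bound period `tau0/0.2 = 5` ms; with φ = 0.9 the calibrated rate is **1800 s⁻¹**, exactly the obstacle-free non-cognate preset |
| cognate `moveProbs` | (≈0.49975, ≈0.49975, 10⁻⁴, 5·10⁻⁴) | second-scale nonspecific bound periods and sliding lengths of roughly 40 bp per visit, consistent with a ~90% bound fraction at the cognate preset rates (≈4.2 s⁻¹) |
| `hopRange` | 100 bp | hops are short-range relocations; the hop kernel is not constrained by the study and is exposed as a parameter |
| footprints | 21 bp cognate, 46 bp non-cognate | the repressor/obstacle geometry; gives the 66-bp exclusion window |
| `specificity` (PWM generator) | 0.25 | see below |

With these defaults and the published association-rate presets
(1800/2000/2571/3600/6000 s⁻¹ for 0/10⁴/3·10⁴/5·10⁴/7·10⁴ non-cognate
molecules), the stationary coverage of the simulated segment lands on the
published 0/9/26/42/55% without any further adjustment: the rising preset
rates compensate the falling acceptance probability of binding attempts
in exactly the proportion the published table implies. A hard-rod gap
analysis of the steric acceptance probability predicts 9.0/25.8/41/54.7%
for these parameters, and the simulator reproduces those values; this was
the design check for the move-probability defaults.

The association-rate *presets* for the cognate species (4.19 … 13.26 s⁻¹
across crowding levels and abundances, and 7.37 s⁻¹ for the immobile
protocol) come from an association-rate scaling model published
separately; they are shipped as data (`loadSubsystemPresets()`), not
re-derived.

## System-size reduction

Simulating a full 4.6 Mbp bacterial genome is not desk-feasible, so
abundances are rescaled to a subsegment with the *copy-number model*:
`N_sub = ceiling(N_full · L_sub / L_full)` with `L_full = 4,639,675` bp.
Ceiling is the rounding rule consistent with every published subsystem
abundance (216, 647, 1078, 1509 and 863); rounding to nearest fails on
the 40,000-copy value (862.13 → 863) and flooring fails everywhere, so
the choice is forced by the data rather than assumed (the test suite
checks this exhaustively).

## Synthetic data

`generateGenome()` draws i.i.d. bases at a requested GC content and
splices a 21-bp operator-like consensus at a known coordinate — a
stand-in for a genomic segment containing the *O1* site. It emulates the
length, alphabet and single-strong-site structure of the real segment but
none of its sequence correlations (repeats, skew, gene structure), so
passing tests demonstrate correctness of the machinery, not genomic
realism.

`generatePWM()` builds a stand-in motif: each column rewards the
consensus base with `+specificity`, penalises the others with
`-specificity·U(0.5, 1.5)`, and is centred so each column averages zero
(log-odds-like under a uniform background). Centring keeps the
genome-average residence near `tau0` (a random window scores ≈ 0 with
variance ∝ `specificity²`) while the consensus window scores about
`1.5 · 21 · specificity` above background — with the default 0.25 the
site residence is `1e-3 · exp(7.9) ≈ 2.7 s` (realised values vary a
little with the drawn penalties). That is a deliberately *scaled-down*
affinity: a real repressor sits on its operator for minutes, which would
pin the occupancy of any desk-scale run at 1. The ranking of windows is
unaffected by centring, and the embedded site is the unique maximum by
construction (one mismatch costs more than one reward).

## Observables and statistics

* `firstPassageStats()` averages uncensored search times; censored
  replicates are counted, never averaged.
* `occupancyStats()` implements both censoring protocols behind an
  explicit flag: the mobile-obstacle protocol keeps censored replicates
  as zero occupancy, the immobile protocol discards them (a blocked
  target would otherwise read as "low occupancy" rather than "never
  reached").
* `reachProbability()` is the uncensored fraction.
* `anovaTukey()` wraps `stats::aov()` + `stats::TukeyHSD()` at a 95%
  family-wise level — the only multiple-testing treatment applied.
* `crowdingCorrelation()` is the plain Pearson product-moment coefficient
  between condition-level crowding and condition-level means; it refuses
  constant inputs rather than returning `NaN`.
* `boxplotSummary()` follows the notched-boxplot description used in the
  study's figures: type-7 interpolated quartiles (the caption fixes no
  convention, so the common default is used and documented), whiskers at
  `max(Q1 − 1.5·IQR, min x)` and `min(Q3 + 1.5·IQR, max x)`, outliers
  beyond them, and notches at `median ± 1.57·IQR/√n` (the standard
  approximate 95% interval for the median; no formula is given in the
  source, so the standard one is used).

## Numerical choices

* **Event queue.** Each molecule owns at most one pending event; a binary
  heap with lazy invalidation (per-molecule version counters) processes
  them in time order. Event-time regression is an internal error, not a
  warning.
* **RNG.** One 64-bit Mersenne Twister per replicate; every draw comes
  from that stream, so a replicate is a pure function of its integer
  seed. Replicate `r` of a grid uses `baseSeed + r`.
* **Topology.** Synthetic genomes are circular by default to avoid end
  artifacts on short segments; linear topology is available, where slides
  at the ends are blocked and hops beyond the ends dissociate.
* **Tie-breaks.** Blocked slide ⇒ stay (sliding is conservative); blocked
  hop ⇒ unbind (a hop is a micro-dissociation that failed to re-land).
  The source study does not specify either rule.
* **Degenerate inputs.** Zero-duration runs return an empty censored
  trajectory whose coverage is the instantaneous (initial) coverage;
  an over-packed immobile placement fails with the achieved coverage in
  the error message rather than looping forever.
* **Audit mode.** `runSimulation(audit = TRUE)` revalidates the full
  steric invariant after every event (used in the tests; far too slow for
  production runs).

## Problem sizes used by the tests and the acceptance script

Full-scale reproduction of the study (100 Kbp, 3000 s cell cycles, up to
1509 obstacle molecules, 50–1000 replicates per condition) is not a
desk-scale computation — single runs of that size took hours to weeks in
the original work. The package therefore checks its claims at three
tiers, and ships the full-scale configuration
(`makeExperimentGrid(scale = 1)`) for users with the budget to run it:

* exact claims (copy-number reduction, the 66-bp exclusion window) are
  checked exactly;
* stationary claims are checked on 10 Kbp segments: the 90% bound
  fraction over >10⁵ binding/unbinding transitions, and the preset
  coverages within ±3 percentage points over repeated 4-s stationary
  windows (1-s burn-in — the exchange time of a molecule is ~6 ms, so a
  second is hundreds of relaxation times);
* the event-driven core is validated against an exact continuous-time
  Markov chain computed by linear solve on a 60-bp genome (2000
  replicates, 3-standard-error agreement);
* the large-scale orderings — search time increasing with mobile
  crowding, occupancy decreasing with mobile crowding, occupancy among
  reached targets increasing with immobile crowding — are asserted on
  2 Kbp segments with 10 (search time) or 1 (occupancy) cognate
  molecules, durations of 120–600 s and 25–150 replicates. The
  search-time and immobile-occupancy orderings separate cleanly at this
  scale under the package defaults. The mobile-occupancy
  decrease is the weakest of the three on a desk-scale segment: with
  millisecond-scale non-cognate visits (forced by the published
  association-rate presets under the per-molecule interpretation),
  obstacles block the operator only transiently, so the decrease —
  consistently observed in the mean across designs — is small relative
  to replicate noise. At full scale the decrease is driven by ten or
  more cognate copies over a whole cell cycle, a regime in which a
  small segment saturates (occupancy ≈ 0.9) instead. The absolute
  search times and occupancies of the full-scale study are *not*
  reproduced at reduced scale.

## Worked example

```{r example, eval = FALSE}
g    <- generateGenome(10000, seed = 1)     # 10 Kbp, operator at 5000
pwm  <- generatePWM(seed = 1)
land <- buildLandscape(pwm, g)

lacI <- cognateSpecies(10, assocRate = 4.63, landscape = land)
nc   <- TFSpecies("nc", copyNumber = copyNumberScale(10000, lSub = 10000),
                  footprint = 46, assocRate = 2000)

traj <- runSimulation(g, list(lacI, nc), duration = 100, seed = 7)
firstPassage(traj)
occupancyFraction(traj)
meanCoverage(traj)
```

## Known limitations

* The 3D organisation of the genome, intersegmental transfer, TF–TF
  cooperativity and nucleosomes are out of scope, as in the source study.
* The non-cognate defaults trade sliding length (~2 bp per visit) for
  desk-scale event counts; the cognate species keeps realistic ~40 bp
  slides. Both satisfy the 90%-bound calibration, which is what the
  stationary observables depend on.
* The PWM and the kinetic parameter set are documented stand-ins, not
  the original (unpublished) supplementary parameterisation; absolute
  search times are therefore comparable only in order of magnitude, and
  the quantitative claims the package reproduces are the
  parameter-independent ones (reduction arithmetic, calibration, coverage,
  orderings).
* Only the forward strand is scored; the landscape is single-valued per
  position, and no reverse-complement target is modelled.
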