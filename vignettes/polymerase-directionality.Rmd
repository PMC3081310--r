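---
title: "Modeling the evolution of polymerase directionality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of polymerase directionality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirpol)
```

## The question and the model

All known nucleotide polymerases add monomers 5′→3′: the activated
triphosphate arrives on the incoming nucleotide. A hypothetical 3′→5′
("reverse") polymerase would instead keep the activated group on the
growing chain terminus. Because nucleotide triphosphates hydrolyze
spontaneously in water, the two strategies pay different prices for the
same accident: a forward polymerase loses one monomer and grabs another,
while a reverse polymerase loses its chain terminus and must repair it
before synthesis can resume. `dirpol` implements a minimal agent-based
model of that asymmetry so the two strategies can be grown in isolation or
competed against each other across environmental conditions.

An organism is a finite state machine with a polymerase (integer rate `r`,
immutable direction) and a genome reduced to three counters: length `L`,
nucleotides copied so far, and errors made. Replicating organisms copy; an
organism whose copy reaches `L` switches to the dividing state and waits
for room; division creates a daughter, resets the mother's counters, and
returns both to replication. The environment holds at most `K` organisms
and culls at random after every step.

## Event probabilities

All chemistry is folded into a dimensionless simulation temperature `T`
(the `kT/ΔG°` factor of a Boltzmann weight; it cannot be mapped onto a
physical temperature, only varied):

* Forward hydrolysis: `p_f = exp(−1/T)`. Time-independent because the
  monomer pool is assumed pre-equilibrated.
* Reverse hydrolysis: `p_r = min(1, (r_max/r)·exp(−1/T))`. The chain
  terminus is exposed for a time inversely proportional to the polymerase
  rate, hence the `r_max/r` factor; it equals 1 at `r = r_max` so the two
  strategies coincide at maximum speed. The product can exceed unity (e.g.
  `r = 1`, `T = 0.6` with the default `r_max = 10`), so it is clamped; a
  clamped value means the slow reverse polymerase is stalled every step.
* Erroneous inclusion: `p_e = exp(−2/T)·g(r)`, drawn at each successful
  addition. The thermal term uses twice the hydrolysis exponent because
  base-pairing discrimination costs roughly twice the free energy of
  triphosphate hydrolysis. The rate factor is `g(r) = sqrt(r/r_max)`: the
  model pictures polymerization speed as volumetric flux through a
  cylindrical tube whose radius sets the geometric fidelity constraint, and
  the radius of a tube scales as the square root of the flux through it.
  Normalization `g(r_max) = 1` keeps the two factors separable. A linear
  alternative `g(r) = r/r_max` is available behind
  `sim_config(rate_factor = "linear")` purely for sensitivity analysis; all
  shipped results use the square-root form. With `mutation_enabled = FALSE`
  the probability is exactly zero.

Within one time step a polymerase runs an addition loop of at most `r`
iterations. Each iteration first draws hydrolysis: a forward polymerase
skips that addition and continues, a reverse polymerase stops for the step.
An erroneous nucleotide is still incorporated (the error counter and the
copy counter both advance). The per-step additions therefore follow a
binomial law `E[added] = r(1−p)` for forward and a truncated-geometric law
`E[added] = (1−p)(1−(1−p)^r)/p` for reverse; the test suite checks both
against exhaustive enumeration of the outcome tree for `r ≤ 6` and against
3×10⁵ simulated steps.

## Inheritance, culling, scheduling

**Inheritance.** At division the daughter's rate is the mother's plus or
minus `Δ = round((r_max − r_min)·min(E/e_max, 1))`, where `E` is the error
fraction of the copy just made and `e_max = 0.34` is the tolerance at which
the perturbation saturates. Rounding is half-away-from-zero. The sign is
uniform when both signs stay in `[r_min, r_max]`, forced when only one
does, and drawn-then-clamped to the nearest bound when neither does (only
reachable for `Δ > (r_max − r_min)/2` from a mid-range mother). Direction
never mutates, and the mother's own phenotype never changes at division.

**Culling.** After all organisms have acted, one culling pass runs:
with probability `min(1, 1/(K − N + ε))` an organism chosen uniformly at
random (any state) is removed and the probability is recomputed; the pass
ends at the first failed draw or an empty environment. `ε = 1` is fixed by
the boundary condition that at least one removal is certain at capacity.
At capacity the pass removes `e − 1 ≈ 1.72` organisms per step in
expectation, which sets the population turnover rate.

**Scheduling.** Organisms act once per step in a freshly shuffled order
(Fisher–Yates), which avoids a systematic first-mover advantage;
an organism that completes its genome divides no earlier than the next
step, and daughters act for the first time the step after their birth.
These choices pin the intra-step order that the underlying model leaves
open; they matter only at the one-step timescale.

**Seeding.** Founders start with a copied count drawn uniformly from
`{0, …, L−1}` so first divisions are desynchronized, with an error counter
of zero (the pre-made fraction carries no replication history). Daughters
always start from zero progress.

**Randomness.** One master seed per ensemble; run `i` uses
`master_seed + i − 1` and a single stream consumed in scheduling order.
The compiled engine and the pure-R reference consume that stream
draw-for-draw identically — including a vacuous error draw per addition
when mutation is off, so the protocol does not depend on the mutation
flag — and a test asserts bit-identical output. Identical configuration
and seed therefore replay byte-identical tables through the CLI.

## Scenario presets and ensemble statistics

Four seeded designs ship as presets, each at its standard size with
overrides for desk-scale work: isolated growth (10 organisms of one
direction, one per rate, 5000 steps sampled every 5), competition during
exponential growth (50+50 organisms, 5 per direction × rate pair, 50000
steps sampled every 50), full-environment competition (seeded exactly at
capacity, 50 per pair at `K = 1000`), and the temperature sweep of the
full-competition design over `T = 0.10, 0.15, …, 0.60`. Every preset seeds
equal multiplicities over rates 1–10, giving the mean starting rate 5.5.

Ensembles average each sampled statistic arithmetically across runs
(`average_runs()`), with per-sample standard deviations appended as extra
columns. A run whose census is zero at a sample has no defined mean rate
and simply drops out of the average at that sample.

The fate of the reverse strategy is summarized by `log_decline_slope()`:
ordinary least squares of `ln(census)` on time. Zero-census samples are
excluded rather than floored — the log is undefined there and the fit
targets the visible decline; a series with fewer than two positive samples
raises a classed condition that `slope_vs_temperature()` converts to an
`NA` row. The regression is deliberately plain OLS (no autocorrelation
correction): the slope is a descriptive summary, and its sign and rough
magnitude are the scientific content.

`generational_rate_change()` reports the mean `|daughter − mother|` rate
difference among births in a window. Under fully random, uniform
inheritance on `{1, …, 10}` its expectation is exactly 3.3 (enumeration of
the 10×10 grid), so values near 3.3 mean the thermal error rate has
destroyed heritability; the largest possible single-birth change is
`r_max − r_min = 9`.

## Problem sizes used by the tests

The shipped checks run the designs at reduced scale — capacity and genome
length 200–300, 5000–10000 steps, 3 replicate runs — sizes chosen so the
full battery exercises every regime (capacity-limited equilibrium at
`T = 0.10`, forward dominance at `T = 0.60`, no-mutation selection) while
a complete run of the suite stays interactive. All structural invariants
(seeding composition, census bound, rate bounds, determinism) are
scale-free, and the presets accept the full standard sizes unchanged.

The regime thresholds were fixed from theory before running: at `T = 0.10`
the two directions are chemically near-identical, so over 10⁴ steps
(~180 generations of turnover at `K = 300`) the averaged `ln(reverse
census)` slope is bounded by neutral drift at a few times 10⁻⁵ per step —
asserted as `|slope| < 2×10⁻⁴`; at `T = 0.60` extinction of the reverse
strategy from half the environment by roughly step 3000 implies a slope
near `−ln(150)/3000 ≈ −2×10⁻³` — asserted as `slope < −5×10⁻⁴`.

## Known limitations

* **Selection is attenuated at carrying capacity.** Once the environment
  is full, turnover is ~1.72 organisms per step regardless of how fast
  anyone replicates, and most organisms wait in the dividing state. Births
  are then allocated nearly in proportion to lineage representation in the
  divider queue, so the per-generation selective advantage of rate 10 over
  rate 9 drops to a few percent. Consequently the no-mutation convergence
  to the maximum rate, which is rapid during exponential growth, completes
  only slowly after the environment fills: at `K = L = 200`, `T = 0.3`,
  the population mean is ≈9.5–9.9 after 5000 steps and reaches 10.0 only
  by ~20000 steps. This is a property of the model's published update
  rules (one action per organism per step; dividers wait; culling repeats
  until first failure), not of the implementation — both engines agree
  exactly.
* The genome is a counter, not a sequence: errors have no loci, no
  phenotype other than the inherited-rate perturbation, and no epistasis.
* Reverse-polymerase repair kinetics are collapsed into "lose the rest of
  the step"; an explicit repair model could change the rate scaling.
* The environment is well-mixed with a hard capacity; there is no spatial
  structure, resource model, or metabolic cost.
* Simulation temperature orders regimes but cannot be mapped to kelvin.
* The synthetic scenarios emulate the study designs, not any empirical
  data set; passing tests demonstrate internal consistency of the model
  and implementation, not biological calibration.
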