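---
title: "Modeling colon-crypt cell dynamics and optimizing chemotherapy dose schedules"
author: "cryptsched"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling colon-crypt cell dynamics and optimizing chemotherapy dose schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptsched)
```

## The scientific problem

Colon cancer begins as abnormal proliferation inside a colon crypt, a
test-tube-shaped invagination of the epithelium holding one to two
thousand cells. Quiescent stem cells occupy a niche at the crypt base,
proliferating cells the middle, and differentiated cells the top, from
which they are shed into the lumen. Chemotherapy of such a lesion is a
scheduling problem: a cytotoxic drug (5-FU-like) kills dividing cells
of every genotype, and an apoptosis-inducing drug (sulindac-like)
removes cells at the crypt/lumen interface, so the clinician must pick,
for each drug, a dose intensity, a duration of exposure, and an
interval between doses that together eliminate the cancer lineage,
spare crypt function, keep cumulative drug exposure tolerable, and fit
the working week of an infusion clinic. The problem is hardest when the
cancer cells are multidrug resistant -- here modeled as a slow-cycling
phenotype that escapes drugs whose kill scales with division rate.

`cryptsched` implements an agent-based crypt simulator, a
simulated-clinical-trial protocol on top of it, exhaustive enumeration
and multi-objective filtering of dose-schedule grids, and an
active-learning loop that trains a neural-network toxicity surrogate so
that combination-schedule spaces far too large for brute force can be
explored by simulating only the informative corner of them.

## The crypt model

The crypt is a cylindrical lattice of `circumference` columns by
`height` rings (default 25 x 80, capacity 2,000). Cells stack
contiguously from the base of each column; normalized height
`h = (ring - 1)/(height - 1)` determines behavior. One simulation step
represents about 4 hours.

Per step, in order: every cell draws a death Bernoulli, survivors draw
a division Bernoulli, daughters are inserted directly above their
parent in the parent's own or an adjacent column (circumferential
neighbor), columns compact, and cells pushed past the top ring are
shed. Division probability declines linearly from `divide_max` (default
0.2 per step, a ~20-hour cycle at full pace) at the base to
`divide_min` (0) at the top, and is flat across the niche; death
probability rises linearly from `die_min` (0.005) to `die_max` (0.20).
These four numbers were calibrated so that the untreated crypt
fluctuates around the homeostatic target of 1,750 cells (measured mean
1,755 over 1,200 steps); the minimum viable size is 1,399 cells, the
smallest count seen in biopsy calibration data at full scale.

Three structural rules carry most of the biology:

* **Quiescent niche with succession.** Normal cells in the bottom 10%
  of the crypt are quiescent stem cells: they do not divide and, being
  out of cycle, are untouched by the S-phase-specific cytotoxic drug.
  When the crypt falls below 90% of its homeostatic target they awaken
  and divide at the full positional rate, which is what lets the crypt
  recover between doses. Bulk compaction never crosses the niche
  boundary from above; instead a stem vacancy is refilled by *niche
  succession* -- the lowest cell above the boundary drops in, at most
  one per column per step. Succession is what lets a mutant clone
  capture the niche and persist (an adenoma), and what lets
  normal cells reclaim it during therapy.
* **Cancer cells neither quiesce nor differentiate.** A cancer-lineage
  cell is proliferating at every height. This is both the phenotype's
  definition and the reason therapy can work: there is no compartment
  in which a cancer cell is sheltered from a drug that targets cycling
  cells.
* **Phenotype kinetics.** Relative to a normal cell at the same
  position, drug-sensitive cancer cells divide 1.16x and die 1.10x;
  multidrug-resistant cancer cells divide 1.08x and die 1.05x. These
  ratios are exact in the probability functions and are recovered by
  Monte-Carlo draws in the test suite.

## Drug action

During an active cytotoxic dose with lethality $L$, a proliferating
cell's death probability is raised *additively* above its positional
baseline:

$$p = \mathrm{clamp}\big(\, p_{\mathrm{die}}(h)\, m_{\mathrm{die}} +
g\,(L-1)\, c^2 \,\big), \qquad
c = m_{\mathrm{div}}\,(0.5 + 0.5\, f(h)),$$

where $f(h)$ is the positional division fraction, $m$ are the
phenotype multipliers, and $g$ = `cytotoxic_gain` (0.06). The additive
form reflects the drug acting on cells directly rather than amplifying
whatever positional hazard they happen to have: no crypt position is a
sanctuary. The cycling activity $c$ enters squared because both the
chance of being caught in S phase during a short exposure and the
chance of dying at the next division scale with cycle rate; the square
is what separates the sensitive (1.16x) from the resistant (1.08x)
phenotype strongly enough to be detected in 20-replicate trials. We
also evaluated purely multiplicative forms ($p_{\mathrm{die}} \times
m \times L$, with and without compartment gating and cycling weights);
they either leave the crypt base effectively drug-free -- producing
anchored clones that no in-range dose can clear -- or let the resistant
phenotype's slower regrowth outweigh its smaller kill, inverting the
expected dose-response ordering. Both defects are absent under the
additive law.

An active apoptotic dose multiplies the death probability of every
cell in the top third of the crypt by `apoptotic_intensity`, whatever
its phenotype: the drug acts at the crypt/lumen interface. A collapsed
crypt transiently has no cells at those heights, so apoptotic exposure
then has no effect until the crypt regrows -- a saturation the schedule
sweep discovers on its own.

The `gradient_params()` defaults *are* the desk calibration; they were
fixed once, before the acceptance checks were frozen, and all reported
behavior below uses them.

## The simulated-trial protocol

`run_trial()` follows a fixed protocol: initialize at homeostasis, run
200 steps, convert proliferating cells to the mutant phenotype (the
test protocol converts 10 cells at the crypt bottom, where clones
establish reliably -- seeded higher, most clones are swept out by the
conveyor before reaching any appreciable size), let the clone grow to
the 50% therapy trigger, then start all drugs simultaneously and run to
cure (no cancer-lineage cells), extinguishment (no cells), or a
2,000-step cap (about 333 days, far beyond every observed cure).
Each replicate runs on its own seeded RNG stream; 20 replicates per
schedule are used in the tests (the full-scale protocol default is 50).
Toxicity is extinguishment; for apoptotic-only schedules a crypt
falling below the 1,399-cell floor also counts as toxic, since that
floor is what bounded the apoptotic dose range.

Under the calibrated model, desk-scale trials reproduce the
qualitative treatment-response structure of the full-scale study:

* an intermittent cytotoxic schedule -- 4-hour pulses of lethality 16
  once per simulated week, `(1, 42, 16)` -- cures 100% of 20
  sensitive-cancer replicates in ~96 steps without extinguishing any
  crypt (minimum size ~620 of 1,750);
* apoptotic-only dosing `(1, 84, 3.5)` cures nothing: it shaves the
  crypt top but never reaches the proliferative zone, and the crypt
  stays above the viability floor;
* resistant mutants are harder on every axis: at a matched
  sub-curative schedule `(1, 84, 16)` the sensitive arm cures 80% of
  replicates against 35% for the resistant arm, and wherever both
  phenotypes cure, the resistant arm takes substantially longer
  (390 vs 230 steps at lethality 12; 119 vs 96 at 16);
* combination therapy `(1, 42, 14)` + apoptotic `(2, 84, 6)` cures
  100% of resistant replicates faster (~100 steps) and at a lower
  accumulated cytotoxic dose (33.5 vs 45.3 lethality units) than
  cytotoxic-alone at its minimal curative intensity, and it passes the
  clinical-practicality policy (infusions of at most 2 steps = 8
  hours; intervals that are whole-week multiples of 42 steps).

Accumulated dose is `lethality x time_to_cure / interval`, computed
per replicate and then averaged; note that applying the formula to the
*mean* time instead gives slightly different numbers, which is why the
per-replicate convention is stated explicitly.

## Schedule grids, sweeps and filtering

`grid_spec()` defaults to the published single-drug sweep extent:
durations 1-48 steps, even intervals 2-96, intensities 0.25-20.00 in
steps of 0.25 -- 48 x 48 x 80 = 184,320 schedules, with the
interval-greater-than-duration constraint applied at execution rather
than enumeration (1,728 admissible duration/interval pairs). The
stated intensity range "1 to 20 in steps of 0.25" would give 77 values
and could not produce the published total; the 80-value grid does, so
the grid starts at 0.25 and the choice is configurable.
`run_sweep()` executes the replicate protocol per schedule and
attaches toxicity and practicality flags; `filter_curative()` keeps
schedules with strict 100% cure and no toxic replicate; and
`select_optimal()` applies the practicality policy and ranks by least
crypt perturbation, then least accumulated dose, then least time to
cure. Desk-scale sweeps use coarsened grids; the package makes no
attempt to reproduce the exact membership of the full-scale curative
sets, which depend on the original model's calibration.

## The active-learning loop

A combination-schedule space is the product of two single-drug grids
(184,320^2 at full scale) and cannot be simulated exhaustively.
`run_active_learning()` trains a probabilistic toxicity classifier --
a single-hidden-layer feed-forward network (16 units, weight decay
1e-4; `nnet`) on standardized 6-vector schedule features, with a
logistic-regression fallback -- on a seeded random sample, predicts
over the whole space, labels the batch whose predicted toxicity
probability is closest to 0.5, retrains, and stops when held-out
sensitivity and specificity both exceed their thresholds (99% by
default). A stratified 10% of the *initial* sample is held out, fixed,
for those metrics: because it is drawn uniformly from the space it
estimates space-wide generalization, whereas holding out part of the
uncertainty-sampled batches would concentrate the evaluation on the
boundary and make the thresholds unreachable. The cost of a small
evaluation set is coarse granularity -- with a few hundred seed points
the loop can stop a round or two before the classifier is equally good
everywhere -- which is tolerated by design: every schedule the final
classifier predicts nontoxic is re-simulated downstream, so surrogate
false positives are caught there, exactly as the workflow prescribes.
No schedule is ever labeled twice, so the labeled count after k
batches is exactly `seed_size + k x batch_size`.

The test suite exercises the loop on a fully enumerable toy space of
10,000 combination schedules with a smooth deterministic oracle
(toxic when the combined delivered dose rate
`L x d / i + 0.5 x A x d' / i'` exceeds 2); with a 500-schedule seed
and batches of 100 it reaches the 99/99 stopping criterion within the
50-iteration cap.

## Verification behaviors

Three qualitative behaviors of real crypts serve as model
verification, all in the test suite: homeostasis (untreated total
stays within 10% of target over 1,000 steps); monoclonal conversion by
neutral drift (a reduced 6 x 12 crypt with tagged lineages fixes to a
single lineage within a few thousand steps); and robust recovery from
perturbation (after one 4-hour cytotoxic pulse of lethality 5.75 the
crypt returns to within 5% -- measured well within 1% -- of its
pre-pulse mean within ~100 steps).

## Numerical and design choices

* Time conversion: one step is 4 hours; days are reported rounded to
  two decimals.
* Update order within a step is death, division, migration, shedding;
  migration ties break by fixed column order. Probabilities are
  clamped to [0, 1] after all factors.
* Quiescence release triggers below 90% of the homeostatic target;
  this, rather than any drug asymmetry, is what makes short pulses
  crypt-sparing: a 1-step pulse ends before the depleted crypt wakes
  its stem cells, while long-duration dosing exposes the awakened
  stem compartment and is how simulated crypts die.
* Calibration (`calibrate_gradients()`) is a seeded stochastic local
  search over `divide_max` and `die_max` with a shrinking perturbation
  width, scoring the relative squared error of simulated compartment
  means and variances against targets.
* `enumerate_combination_grid()` samples huge product spaces without
  materializing them, by drawing distinct flat indices and decoding
  them in mixed radix.
* All stochastic entry points take explicit integer seeds; a crypt
  carries its own RNG stream, so simulations are reproducible
  bit-for-bit and independent of the ambient RNG state.

## Limitations

The synthetic crypt emulates positional gradients, niche dynamics and
clonal competition, but not pharmacokinetics (drug levels switch on
and off instantaneously), mutation accrual during therapy, crypt
fission or metastasis, or toxicity to organs other than the simulated
crypt. Passing the desk-scale checks therefore shows that the
methodology -- trial protocol, sweep, filters, surrogate loop -- behaves
correctly on a calibrated model of the right qualitative structure; it
does not by itself validate predictions for any particular clinical
schedule. Quantities tied to the original full-scale calibration (the
exact curative-set sizes, cure times and crypt-size percentages) are
out of scope at desk scale, and the package reports its own calibrated
values instead.
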