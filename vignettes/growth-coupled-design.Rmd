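---
title: "Growth-coupled biofuel design in photoautotrophs: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled biofuel design in photoautotrophs: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanodesign)
```

## The problem

Cyanobacteria fix CO2 with light energy and can be engineered to excrete
biofuels such as ethanol or isobutanol. In heterotrophs, strain designs that
*couple* growth to product formation are classically found by deleting
competing fermentation pathways. Photoautotrophs need a different principle,
because both ATP and NADPH come from the same photosynthetic electron
transport chain:

* **Linear electron flow (LEF)** through PSII, cytochrome b6f and PSI
  deposits protons in the thylakoid lumen and reduces NADP. With the
  textbook gearing used here (4 photons and 6 lumen protons per NADPH, 3
  ATP per 14 protons at the ATP synthase) LEF delivers ATP and NADPH in the
  fixed ratio 6 x 3/14 = **9/7 (~1.28)**.
* **Alternate electron flows (AEFs)** — NDH-1 and FQR cyclic flow, the
  Mehler water–water cycle, and respiratory oxidases (Cox, Cyd) — recycle
  electrons and make ATP *without* net NADPH, so a cell with AEFs can
  realize any ATP:NADPH ratio above 9/7.
* **Demands**: carbon fixation costs 3 ATP + 2 NADPH per CO2 (ratio 1.5),
  ethanol synthesis from CO2 costs 7 ATP + 6 NADPH (~1.17), isobutanol
  12 + 12 (1.0), and biomass is parameterised to demand ATP:NADPH = 1.51 —
  *above* what LEF alone supplies.

The design principle follows from these four numbers: **block every AEF and
the chain is pinned at 9/7, below the biomass demand of 1.51; the only way
to balance the books is to co-produce a product whose demand ratio is below
9/7** (ethanol, isobutanol). Growth then implies product synthesis at a
guaranteed minimum yield. The package implements the machinery to find,
verify, and analyse such intervention strategies.

## Formal tools

An **elementary mode (EM)** is a support-minimal nonzero steady-state flux
vector respecting irreversibility; conical combinations of EMs span all
steady-state behaviors. A **minimal cut set (MCS)** is a minimal set of
reaction knockouts blocking a target behavior — equivalently a minimal
hitting set of the target EM supports. A **constrained MCS (cMCS)**
additionally keeps at least one desired behavior feasible. Here the design
problem uses *two* desired behaviors: a photoautotrophic day state with
product yield above a threshold and nonzero growth, and a night state that
regenerates ATP from stored glycogen (the diurnal-cycle constraint).

`enumerate_ems()` implements the double-description tableau with exact
integer arithmetic and a combinatorial adjacency test; `mcs_berge()` the
Berge hitting-set iteration; `filter_constrained()` LP-based filtering; and
`smallest_cmcs()` an implicit hitting-set loop (candidate hitting sets of
accumulated witness supports, validated by an LP separation oracle) that
emits cut sets smallest-first without enumerating modes — the route that
scales to models where full enumeration is impossible. On every model where
both routes run, they return identical families (this is a tested
invariant).

## The packaged models

`make_toy()` builds a five-reaction branched example (substrate to products
P1/P2) whose mode and cut-set structure is fully checkable by hand: three
EMs, MCSs {R1}, {R2,R3}, {R4} against P1, of which {R2,R3} and {R4} survive
the constraint that P2 stay producible. Its topology is the unique minimal
one consistent with those facts, and it anchors the test suite's exact
expectations.

`make_photocore()` builds **PhotoCore**, a ~20-reaction core model of the
cyanobacterial chain with exact rational stoichiometry. Tunable parameters
(`photocore_params()`):

| parameter | default | meaning |
|---|---|---|
| `atp_per_proton` | 3/14 | ATP synthase gearing (c14 rotor, 3 ATP/turn) |
| `protons_per_nadph_lef` | 6 | lumen H+ per NADPH by LEF (2 PSII + 4 b6f) |
| `photons_per_nadph` | 4 | 2 quanta per electron |
| `biomass_atp_nadph_ratio` | 151/100 | biomass demand ratio |
| `photon_uptake_max` | 100 | day photon cap, mmol/gDW/h |
| `include_aefs` | all five | NDH1, FQR, MEHLER, COX, CYD |
| `variant` | lumped | lumped net reactions vs mechanistic CBB/glycolysis |
| `regime` | day | day vs night (glycogen) configuration |

The **lumped** variant condenses each carbon pathway into its net cofactor
demand; the **mechanistic** variant resolves CO2 fixation (CBB: 3 CO2 + 9
ATP + 6 NADPH per triose), lower glycolysis, pyruvate decarboxylase and
alcohol dehydrogenase, with a single pooled NAD(P)H (justified by the
transhydrogenase present in genome-scale reconstructions). The mechanistic
ethanol route nets exactly the lumped 7 ATP + 6 NADPH — a tested
cross-variant invariant. For isobutanol the mechanistic chain nets 14 ATP +
12 NADPH while the lumped reaction uses the conventional 12 + 12
bookkeeping; the lumped values are authoritative for yield calculations and
the discrepancy is deliberate and documented here rather than hidden.

The **night** regime closes photon and CO2 uptake and adds glycogen
mobilization (to 2 pyruvate + 3 ATP + 2 NADPH), a respiratory
pyruvate-oxidation lump, and the fermentative decarboxylase/dehydrogenase
pair. Respiratory ATP is then reachable only via NDH-1 and the oxidases —
exactly the reactions the day design wants to cut — so the night constraint
is a genuine filter: designs must leave the fermentative route open, which
makes ethanol a *mandatory* fermentation product at night.

An ATP-maintenance drain (`ATPM`) exists in every variant. Without an ATP
sink the maximum-yield product mode would be blocked by surplus ATP (LEF
makes 54/7 ATP per 6 NADPH, ethanol needs only 7), so `ATPM` is part of the
model's physiology, not a convenience.

## What the generator emulates — and what it does not

PhotoCore reproduces the electron-chain stoichiometry and the
ATP/NADPH-balance logic of genome-scale cyanobacterial reconstructions, and
its headline numbers (1/24 ethanol per photon, 24 photons per ethanol, 48
per isobutanol, minimum coupled yield ~0.0272 per photon, linear rise of
ethanol with an enforced ATP drain) match that logic exactly. It omits
photorespiration, phosphoketolase bypasses, cyanophycin cycling, amino-acid
and cofactor anabolism, and gene–reaction mappings. Consequences: cut sets
here are small (the five AEFs) where genome-scale models need 8–16 cuts to
also block side routes that bend the cofactor balance; and passing tests on
PhotoCore validates the algorithms and the coupling principle, not the
enumeration throughput or biological completeness needed at genome scale.
Genome-scale SBML models can be loaded with `read_sbml()` and run through
the same functions.

## Numerical choices

* **Exact rational arithmetic** (`rq`) throughout mode enumeration, cut-set
  validity and the headline LPs: mode counts and supports are combinatorial
  facts and must not depend on float tolerances. Numerators/denominators are
  integer-valued doubles, gcd-reduced; any excursion past 2^53 aborts loudly.
* **LPs**: a two-phase primal simplex with Bland's rule, in an exact and a
  double (1e-9 tolerance) backend. The double backend drives the
  intervention sweep's thousands of feasibility probes; exact LPs produce
  the quoted fractions (9/7, 7/6, 151/100, 1/24). Both are cross-checked
  against an independent simplex implementation in the tests.
* **Strict inequalities**: the desired condition "yield > theta" is posed as
  `>= theta * (1 + 1e-6)` (`epsilon_strict`), a declared tolerance; targets
  use the closed inequality `<= theta`, so the boundary mode is a target.
* **Normalization**: modes are scaled to photon flux 1; photon-free modes to
  1 at their first nonzero irreversible flux (never flipping irreversible
  directions), else first nonzero. This affects reported flux values only,
  never counts, supports or yields.
* **Rate vs yield scaling**: target and desired day behaviors are probed at
  photon flux pinned to the cap (default 100). Any feasible photon-positive
  behavior scales up to the cap without violating the ATP-maintenance floor
  or the (homogeneous) yield constraints, so this loses no generality while
  making the maintenance bound meaningful.
* **Order and ties**: modes sort lexicographically by support; cut sets by
  size then lexicographically — enumeration output is reproducible
  byte-for-byte.
* **Mode ceiling**: `max_modes` (default 2e5) turns runaway enumerations
  into an error carrying the count reached, instead of exhausting memory.
* **Minimum biomass supply ratio**: with an ATP drain present, the smallest
  feasible external ATP:NADPH supply ratio equals minimal-ATP-supply /
  minimal-NADPH-supply at fixed biomass; `min_biomass_ratio()` therefore
  solves two exact LPs instead of bisecting feasibility, returning 151/100
  exactly rather than a 1e-6-wide bracket.
* **Frozen-flow experiment**: among growth-optimal solutions the
  parsimonious one (minimal total irreversible flux) is frozen, making the
  experiment deterministic; the coupling conclusion does not depend on which
  optimal vertex is chosen.

## Design choices on genuinely open points

* **Yield threshold feasibility.** With the default ethanol threshold 0.03
  and no maintenance floor, PhotoCore has *no* valid design: after cutting
  all five AEFs the coupled biomass+ethanol mode has yield 157/5768 =
  0.0272 <= 0.03, is itself a target, and its support lies inside every
  desired behavior — nothing remains to cut. This is not a defect but the
  model's honest answer: richer networks reach 0.03 by additionally cutting
  side pathways (photorespiration and similar) that PhotoCore deliberately
  omits. Two tested consequences stand in for that behavior: at thresholds
  below 0.0272 the unique smallest design is the five AEF cuts, and the
  0.03 threshold becomes feasible again once a nonzero ATP-maintenance flux
  (>= ~0.58 mmol/gDW/h at the 100 photon cap) raises the guaranteed yield —
  the ATP-wasting principle.
* **CASOP-style scores.** `casop_scores()` uses the yield-weighted
  participation difference between desired and wild-type mode ensembles. It
  has the canonical range, sign semantics and boundary behavior (+1 /
  -1 / 0); the original ensemble-over-knockouts weighting is out of scope,
  so tests assert signs and rankings, not third-party score tables. The
  wild-type ensemble excludes product-forming modes by default
  (`wt_exclude_product`), a configurable choice.
* **Targets are photoautotrophic.** Photon-free internal cycles are neither
  targets nor desired; the target LP pins photon uptake to the cap. Day
  models do not carry glycogen reactions (storage is a night-coupling
  device, not a day pathway).
* **Excludable reactions** default to exchanges, biomass, ATP maintenance
  and photon uptake — pseudo-reactions that no knockout can implement.
* **Grids**: "n equidistant steps from a to b" is read as n values
  including both endpoints (`seq(a, b, length.out = n)`), configurable.

## Problem sizes used by the shipped tests

The suite enumerates modes on networks of 5–21 reactions (toy, PhotoCore
variants, randomized perturbations), cross-checks them against an
exhaustive support-subset oracle on networks up to 12 reactions, validates
cut-set families against an exhaustive hitting-set oracle on 8-element
universes, and runs the maintenance sweep at the full 20 x 20 grid (ATPm 0
to 14 mmol/gDW/h, yield threshold 0.002 to 0.04) with the double-precision
LP backend. These sizes keep the whole suite within about a minute while
exercising every code path; nothing in the algorithms is specialised to
them.

## Known limitations

* Genome-scale enumeration (1e5+ modes) is supported by the code path but
  not by the pure-R tableau's speed; the implicit cut-set route is the
  intended tool at that scale.
* Reaction knockouts are not mapped to genes; isozymes and
  gene–protein–reaction logic are out of scope.
* Kinetics, regulation, thermodynamic feasibility and light-intensity
  effects are not modeled; all statements are stoichiometric.
* The biomass demand ratio 1.51 is a lower bound taken as a parameter; real
  maintenance costs push it higher, which only widens the coupling margin.
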