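---
title: "Methods: enumerating genetic minimal intervention sets in iMR networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enumerating genetic minimal intervention sets in iMR networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmisr)
```

## The problem

A genetic minimal cut set (gMCS) is a minimal set of gene knock-outs that
abolishes an essential metabolic task — conventionally biomass production —
in a genome-scale metabolic model. gmisr generalises this to *genetic
minimal intervention sets* (gMIS), which admit gene **knock-ins** alongside
knock-outs. Knock-ins only become meaningful once the metabolic layer is
integrated with signed regulatory interactions: inhibitory arcs create
situations where *activating* a gene shuts a reaction down. The resulting
catalogue covers five composition classes:

| composition            | class                              |
|------------------------|------------------------------------|
| one knock-out          | essential gene                     |
| ≥ 2 knock-outs         | synthetic lethality (SL)           |
| one knock-in           | tumor suppressor gene (TSG)        |
| 1 knock-out + 1 knock-in | synthetic dosage lethality (SDL) |
| ≥ 2 knock-ins, no knock-out | tumor suppressor gene complex (TSGC) |

Anything else is reported as `mixed`. One classification point was
genuinely open: a TSG *complex* is sometimes described as a length-one
object, yet its defining example involves two jointly required knock-ins.
We classify TSGC as *all-knock-in sets of length ≥ 2*, which matches the
example; singletons are TSGs.

## From GPR rules to extended (eGPR) rules

Each reaction carries a Boolean gene–protein–reaction (GPR) rule. For an
iMR model we extend the rule of each target reaction with up to `depth ∈
{0, 1, 2}` levels of upstream regulation: every gene without a rule is
looked up as a target in the current regulatory layer and receives a
Boolean rule over its regulators. Models deeper than two levels are not
supported — real regulatory networks are then dominated by cycles, and the
whole machinery assumes acyclic rules.

**Sign-combination convention.** How multiple activators `A` and
repressors `R` combine into one Boolean rule is a modelling choice, and the
two natural readings differ materially:

* `"or"` (default): `g = a1 or a2 or ... or (not r1) or (not r2) ...`
* `"and"`: `g = (a1 or ...) and (not r1) and (not r2) ...`

Under `"and"`, forcing a regulated gene OFF needs only a single regulator
intervention; under `"or"` it needs *all* of them (every activator lost,
every repressor induced). Only the `"or"` form reproduces the worked
example bundled with the package, where blocking the regulated gene `g4 =
g7 or not g6` requires the joint pair `{g6+, g7-}` and the printed
three-intervention cut set `{g3-, g6+, g7-}` emerges. The convention is
therefore `"or"` by default and remains a constructor argument
(`convention`) so the stricter reading stays available.

**Cycles.** An edge that would close a dependency cycle inside one rule
set is dropped deterministically — stable edge order, the later-loaded
edge loses — and reported in `dropped_edges`. Every returned rule set is
re-verified acyclic by topological sort.

## The ON/OFF artificial network

Per target reaction the rule set is compiled into an irreversible reaction
network (`build_egpr_network()`):

1. every gene rule `ρ_i` is augmented as `g_i = (ρ_i and y_i) or u_i`;
   input genes get `ρ_i = e_i`, a free external input. Removing the
   `y_iON` input exchange knocks gene *i* out; removing `u_iOFF` knocks it
   in. The two readings of where the free input enters (`(e and y) or u`
   versus OR-ing `e` late) coincide on the feasible space because a gene
   is never knocked out and in simultaneously; the contract is pinned by a
   test rather than by the formula's surface shape.
2. nodes are split into ON and OFF twins, the OFF rule being the
   De Morgan negation of the ON rule, so no negation survives;
3. each OR branch becomes a gate reaction producing its node, each AND one
   multi-substrate gate; shared sub-expressions get content-addressed
   intermediate nodes (identical sub-rules share one node, which also
   makes node naming and solution order deterministic);
4. input exchanges are added for all `e`/`y`/`u` nodes and output
   exchanges for the target's ON/OFF nodes. Stoichiometric coefficients
   are all one; duplicate consumption collapses (Boolean idempotence).

Derivability of the target ON node under an intervention set — the
semantics of "the interventions block the reaction" — is decided by a
least-fixpoint closure (`forward_closure()`), with base facts following
the exactly-one-exchange-per-pair regime: `y_OFF` available iff knocked
out (else `y_ON`), `u_ON` iff knocked in (else `u_OFF`), both `e` sides
always.

One semantic subtlety is intentional: on reconvergent rules where a gene
reaches the target through both a negated and a non-negated path, *flux
derivability* (what the optimisation formulation encodes, and what the
closure oracle mirrors) can disagree with strict Boolean satisfiability,
because the ON and OFF sides of a free input are simultaneously available.
The package implements derivability on both routes, so the two engines
agree by construction on such instances; the divergence from strict
satisfiability is a property of the formulation, not a defect of either
engine.

## Minimal cut sets via the dual program

Blocking is certified through duality. For a fixed set of closed
intervention exchanges, flux through the target is infeasible iff the dual
system

$$ S^\top u + E\,v - t\,w \ge 0,\qquad v \ge \alpha,\; v \le M,\;
   w \ge c/r^* $$

is feasible, where `u` is free (one per node), `v ≥ 0` ranges over the
active intervention exchanges, `w` is the target dual and `t` marks the
target's ON output exchange (Farkas' lemma; the defaults `α = 1e-3`,
`M = 1e3`, `r* = 1`, `c = 1e-3` live in `milp_params()` and are recorded
with every run).

The integer side — which exchanges are closed — obeys pairing
constraints (exactly one of `y_ON`/`y_OFF` and of `u_ON`/`u_OFF` closed
per gene), mutual exclusion (never knock-out *and* knock-in of one gene),
and an at-least-one-intervention constraint; previously found solutions
are excluded by no-good cuts. `enumerate_mcs(engine = "dual")` solves this
mixed program exactly by *implicit enumeration*: binary assignments are
visited in objective order (size, then lexicographic with knock-outs
before knock-ins), assignments dominated by a no-good cut are skipped, and
each remaining assignment is certified by solving the dual feasibility
system as a strictly convex QP (`min ‖x‖²` subject to the constraints,
via quadprog — the solver either returns a point or proves
inconsistency). Size-ordered visiting with superset elimination returns
exactly the minimal blocking sets: a blocking proper subset of a candidate
would have been found at a smaller size and would then dominate the
candidate.

The independent oracle (`engine = "closure"`) decides blocking by the
Boolean fixpoint instead and is guarded by a candidate-count cap. The two
engines share only the candidate order — their blocking certificates are
disjoint code paths (numerical LP duality versus symbolic closure) — and
their agreement on seeded random instances is asserted in the test suite.

`max_size` defaults to 5 interventions: downstream integration discards
rows involving more than five genes anyway, as the contribution of longer
sets to vulnerability prediction is negligible. The per-solution time
budget defaults to 300 s.

## G/F integration and genome-level enumeration

Per-reaction cut sets are integrated into the paired binary matrices `F`
(rows × intervention atoms) and `G` (rows × reactions): row *i* of `G`
marks the reactions blocked by the interventions in row *i* of `F`.
Identical sets from different reactions merge into one row; rows larger
than `row_cap = 5` genes are discarded and counted. Rows whose atom set
contains another row with at least the same blocked reactions are
*dominated* and pruned by default — provably without changing
`blocked_reactions()` on any input (the equivalence is asserted on the
full subset lattice in the tests), and the pruning is toggleable.

A gMIS is a minimal, direction-consistent atom set `I` (|I| ≤
`max_length`, default 5) whose induced deletions `blocked_reactions(gf,
I)` abolish biomass. Candidate atoms are restricted to atoms occurring in
`F` — an atom outside every `F` row cannot change the blocked set, so the
restriction is lossless. Minimality is checked against the full atom
lattice, not only unions of `F` rows, by the same size-ordered visiting
scheme. Two engines certify lethality:

* `"exhaustive"` — primal route: `max_biomass()` under the deletions,
  lethal iff ≤ `1e-6` flux units;
* `"dual"` — Farkas certificate that the biomass flux system is
  infeasible, again a strictly convex QP.

Certificates are memoised per distinct blocked-reaction set.

## Numerical choices

* **LP kernel.** All linear systems run through exact QP feasibility
  (quadprog): strictly convex, compiled, and immune to the degenerate
  pivoting that all-zero right-hand sides (the mass-balance rows) induce
  in dense textbook simplex implementations.
* **Biomass maximum.** `max_biomass()` brackets the optimum by bisection
  on the demanded biomass flux (absolute precision `1e-9`), after quick
  feasibility exits for the blocked and fully-open cases. The base
  polytope is checked first; contradictory bounds raise a model error.
* **Blocking tolerances.** `1e-6` flux units at the biomass level, `1e-6`
  numeric zero in the cut-set program.
* **Dual biomass certificate.** The certificate demands a small positive
  flux (`1e-4`) rather than one full unit so that the primal and dual
  verdicts coincide even when upper bounds cap the achievable maximum
  below one; for models whose maximum lies strictly between `1e-6` and
  `1e-4` the two engines could in principle diverge — such razor-edge
  optima do not arise in the bundled generators, whose fluxes are either
  zero or of order hundreds.
* **Tie-breaks.** All orders are deterministic: atoms sort
  lexicographically, candidate sets by (size, gene combination, direction
  pattern with knock-out before knock-in), output rows by (size, class,
  lexicographic atoms).
* **Degenerate inputs.** Spontaneous reactions (empty GPR) have no eGPR
  network and no cut sets — they simply contribute nothing to `F`. Empty
  layer lists and `depth = 0` reduce to the purely metabolic gMCS run.

## Context-specific prediction

Expression values (log2(TPM+1)) are binarised HIGH/LOW. The published
distribution-based threshold behind this step is defined in external
tooling and not restated in a reproducible form, so the package defaults
to an honest absolute cutoff — HIGH iff log2(TPM+1) ≥ 1, i.e. TPM ≥ 1 —
and exposes the rule as a pluggable function (`threshold =`), recording
the method name in the state object. Unmeasured genes default to LOW,
which is conservative for essentiality calls; this too is configurable.

A knock-out gene of a gMIS is called *potentially essential* in a sample
iff it is the unique HIGH gene among that gMIS's knock-outs and every
knock-in gene of the set is HIGH. Tumor-suppressor calls are the exact
mirror (unique LOW knock-in, all knock-outs LOW); the mirror symmetry is
property-tested.

Every call is screened for an *adaptation mechanism*: unregulated genes
are pinned at their observed states, the intervention overrides its gene,
and the acyclic regulatory rules are propagated in topological order. If a
knock-out partner activates or a knock-in partner deactivates, the call is
discarded. On acyclic rules this deterministic propagation is exact, which
is why it can stand in for an optimisation-based check; cyclic rule
families are rejected rather than approximated.

## What the synthetic generators emulate — and what they do not

`random_imr_model()` draws substrate-to-biomass chains (import, one or two
parallel conversions per pool, biomass sink) with one-to-two-gene GPRs and
fresh-gene regulatory DAG layers; `random_rule_set()` draws three-level
acyclic rule sets for the cut-set engines; `random_expression()` draws a
silent/log-normal mixture so both HIGH and LOW states occur. All are
seeded and byte-reproducible; infeasible draws regenerate deterministically
with an incremented sub-seed.

These fixtures exercise the combinatorics (parallel routes, AND/OR
nesting, inhibition, two-layer depth) at a scale where brute-force oracles
stay exact. They do **not** emulate genome-scale features: thousands of
reactions with isozyme/complex-rich GPRs, network compression, highly
reconvergent regulation, gene-identifier ambiguity, or realistic
expression covariance. Passing tests therefore certify algorithmic
correctness — soundness, minimality, engine agreement — not biological
calibration on real models.

**Problem sizes.** The suite runs the oracle-equivalence check on 100
seeded rule sets of 2–6 genes, the engine-equivalence check on 50 random
toys (≤ 8 reactions, `max_size = 3` per reaction, gMIS length ≤ 3), and
ten negation-free models for the no-knock-in property; the worked example
runs everywhere in full. These sizes keep every brute-force oracle within
its exactness guard while covering all rule shapes the compiler emits.

## Known limitations

* Acyclic regulation only; at most two layers, cycles dropped edge-wise.
* The G/F formalism treats reactions independently: a gene shared by two
  reactions may be required ON by one blocking argument and OFF by
  another, and the framework does not arbitrate such cross-reaction state
  coupling — this is inherent to the matrix-based approach.
* No gene-identifier mapping, model curation, kinetic or multi-valued
  logic.
* The exhaustive engines refuse instances beyond their candidate guards
  instead of silently truncating; the implicit-enumeration engine scales
  with `3^|B(k)|` in the worst case and is meant for per-reaction rule
  supports, not for whole-genome atom spaces.
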