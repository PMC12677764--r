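---
title: "Verifying simulation experiments across independent ODE engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying simulation experiments across independent ODE engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedverify)
```

## The problem

A kinetic model published as SBML is, in principle, an unambiguous
mathematical object: species, compartments, parameters, and reactions whose
kinetic laws assemble into a system of ordinary differential equations. A
SED-ML file alongside it describes how to *run* an experiment on that model:
which values to change, what simulation to perform, and which quantities to
export. In practice, archives bundling the two accumulate defects — model
references that point nowhere, element pointers with broken XPath syntax,
simulations that nothing uses, duplicated elements, absurd output-grid
requests, parameters initialized to infinity — and a file that has never been
executed by anything has usually never been *checked* by anything.

`sedverify` makes such archives verifiable. It lints and repairs a catalogue
of defect classes, generates a template experiment for models that ship
without one, executes experiments on two genuinely independent ODE backends,
and declares cross-engine replication with an element-wise tolerance
criterion summarized as a single match score. Verification here means
agreement between independent implementations of the same specified
computation; it says nothing about whether the model describes its biology
well.

## The verification model

### Match criterion and score

Two result sets are compared column by column (a column being one exported
quantity, e.g. one species' trajectory). For column $v$ the absolute
tolerance is scaled by the value range of that column over both results,

$$\mathrm{atol}_v = \alpha \,\bigl(\max v - \min v\bigr), \qquad
r_i = \frac{|a_i - b_i|}{\mathrm{atol}_v + \rho\,\max(|a_i|, |b_i|)},$$

with relative tolerance $\rho = 10^{-4}$ and range scale $\alpha = 10^{-4}$
by default, and $0/0$ defined as 0. The **match score** of a pair of runs is
the maximum $r_i$ over all elements of all columns, so *score ≤ 1 is exactly
the match cutoff*: a pair matches precisely when every element is inside its
tolerance envelope. Scores slightly above 1 identify near-misses worth
inspecting by hand; oscillatory outputs can score poorly from tiny phase
shifts alone (a 2 % time shift of an oscillating fixture fails the criterion
here), which is a known limitation of element-wise comparison, not a defect
of either engine.

Using $\max(|a|,|b|)$ in the denominator makes the criterion symmetric in
its operands, so the score cannot depend on comparison order. This is a
deliberate design choice: the conventional allclose-style test is asymmetric,
and an order-dependent verdict is unattractive for a verification tool. The
range-scale constant $\alpha$ mirrors $\rho$; both are configurable in
`comparison_config()`.

Runs that failed, report sets with differing shapes or labels, and any
non-finite value make a pair *incomparable* rather than mismatched — a crash
is evidence of nothing except a crash.

### Aggregation and reproducibility levels

For one model run on $S$ succeeding engines, all $\binom{S}{2}$ unordered
pairs are compared (five engines, ten comparisons). The *agreement size* is
the largest engine subset in which **every** pair matched — a maximum clique
on the match graph, computed by exact enumeration (intended for ≤ 8 engines).
A clique was chosen over a connected component deliberately: transitive
chains of barely-matching pairs should not inflate the agreement count. A
model is *verified* when at least one pair matched, and classified:

| level | meaning |
|---|---|
| functional | verified under a generated template experiment: the model itself is robust to interpretation |
| end_to_end | verified under a curation-derived experiment description |
| unverified | no matched pair (including fewer than two successful runs) |

Unknown provenance is treated as template-like, the weaker claim.

## The two engines

Cross-engine verification is only meaningful if the backends share as little
as possible. `sedverify` ships two:

* **`rk`** — an adaptive Dormand–Prince 4(5) pair written in R inside the
  package: FSAL, error norm
  $\sqrt{\mathrm{mean}\,(e_i / (\mathrm{atol}_i + \mathrm{rtol}\cdot\max(|y_i|,|y'_i|)))^2}$,
  step factor $0.9\,\mathrm{err}^{-1/5}$ clamped to $[0.2, 5]$. Output times
  are hit exactly by clamping the step, never by interpolation, so the
  reported time column is the constructed uniform grid bit for bit.
* **`stiff`** — a BDF implicit multistep method delegated to `deSolve`
  (`method = "bdf"`), i.e. a completely separate integration code path in
  compiled Fortran.

Both honor `tolerance_settings()`: relative tolerance (default $10^{-6}$)
and an absolute-tolerance base factor (default $10^{-12}$).

### The absolute-tolerance vector

A scalar absolute tolerance is a trap for stiff kinetic models whose species
span many orders of magnitude: any species living far below the scalar atol
is effectively exempt from error control, and explicit integrators will
happily drive it negative. The remedy is the per-variable vector

$$\mathrm{atol}_i = f \cdot |x_i(0)|, \qquad \mathrm{atol}_i = f
\;\text{ when } x_i(0) = 0,$$

with adjustment factor $f = 10^{-12}$: the base factor scaled by each
state's initial value, floored at the bare factor for states starting at
zero so that no state ever receives a zero tolerance (the zero-start
behavior is this package's choice; reasonable alternatives exist). The
SED-ML algorithm parameter KiSAO:0000571 ("absolute tolerance adjustment
factor") selects this behavior per experiment; KiSAO:0000209/0000211 set the
plain relative/scalar-absolute tolerances.

The included Robertson-type stiff fixture (`gen_stiff()`, rates 0.04,
3·10⁷, 10⁴) demonstrates the phenotype directly: with the vector enabled
both engines stay nonnegative within $10^{-9}$ and match; with a
deliberately coarse scalar atol of $10^{-2}$ the explicit run loses at least
one of those properties. The implicit engine needs well under a tenth of
the explicit engine's accepted steps on this system, which is the practical
definition of stiffness.

## SBML-to-ODE compilation

Species amounts form the state vector; each amount's derivative is the
stoichiometry-weighted sum of kinetic-law rates. Species appearing in
mathematics are read in concentration framing (amount / compartment size)
unless flagged substance-only, and reported the same way. Assignment rules
are re-evaluated before every right-hand-side evaluation in dependency
order; rate-rule targets are appended as extra states; initial assignments
are applied at $t_0$ in topological order, with cycles reported as errors
naming their members. Constant and boundary species are held fixed unless a
rule drives them.

Two transforms mirror the workarounds real simulator wrappers need:
`promote_local_params()` turns each reaction-local parameter `p` of reaction
`R` into a global `R_p` (suffixing `_2`, `_3`, … on collision) and rewrites
the kinetic law, with XPath targets to the local re-resolving to the
promoted global; `fold_initial_assignments()` replaces initial-assignment
constructs by their evaluated values. Neither changes simulation semantics.

Features outside core ODE semantics — events (delayed or not), the `delay`
csymbol, algebraic rules, fast reactions, assigned stoichiometries — are
*detected and tagged* during SBML introspection, and any engine whose
capability set lacks a tag refuses the model with `failed_unsupported`
naming the tags. Non-integer stoichiometries are tagged too but both
built-in engines accept them, since a real-valued stoichiometry matrix
handles them naturally.

## The defect catalogue

Ten rule classes cover the observed failure modes of curated archives:

| rule | defect | repair |
|---|---|---|
| R1 | model source names no archive entry | resolve against the archive |
| R2 | pointer to a nonexistent model element | drop the change, or the variable with its dependent generators/datasets/curves |
| R3 | unused models/simulations/tasks/generators | prune to a fixpoint |
| R4 | semantically duplicate data generators | merge, rewrite references |
| R5 | malformed / non-canonical element pointer | rewrite to canonical XPath |
| R6 | inconsistent simulation settings | clamp start to initial time; drop unparseable algorithm parameters; grids below one point are raised to one; end before start is *unrepairable* |
| R7 | output grid beyond the point cap | warn; clamp only when opted in |
| R8 | unused parameter initialized to Inf/NaN | set to 0 |
| R9 | file hygiene (zero-length, illegal characters, wrong extension) | remove / rename, rewriting references |
| R10 | annotation resources in URN form | rewrite to identifiers.org URLs |

Repair applies enabled rules in the fixed order R1, R5, R2, R4, R3, R6, R7,
R8, R10, R9 — targets cannot be validated before the model source resolves,
canonicalization must precede dangling-reference checks, and renames run
last so that rewritten documents are already final. Decisions that were
genuinely open: dead content is *removed* rather than speculatively
reconstructed (runnable files beat guessed intent); duplicates are *merged*
rather than deleted to preserve references; the point cap defaults to
10,000 — large enough for any plausible publication figure, far below the
pathological millions — and clamping is opt-in because it changes the
experiment's output grid; R8 uses 0 because any finite value is
observationally equivalent for an unused parameter and 0 is deterministic;
a grid below one point is raised to one (with a logged action) rather than
rejected, favoring runnable output. Unparseable files are themselves
reported as (unrepairable) hygiene-class issues rather than exceptions.

Source resolution (R1) is trivial with a single SBML candidate. With
several, candidates are scored by *reference coverage* — the fraction of
element ids mentioned by the document's pointers that exist in the
candidate — tie-broken by the longest common substring between the stated
source and the candidate filename; only a strict winner resolves, and ties
remain errors listing all candidates and scores.

## Template experiments

`generate_template()` encodes the canonical smoke test for a model with no
experiment of its own: load the model unchanged, run a deterministic ODE
time course (KiSAO:0000019) from 0 to 10 time units, and export time plus
every *variable* species — not constant, not boundary-without-rule — both
as a report and as a 2D plot. Ten time units is the defining duration of
the template contract; the 101-point grid (100 intervals) is this package's
choice of a plotting-friendly default, as only the duration is contractual.
`number_of_points` follows the SED-ML convention of counting intervals, so
N yields N+1 reported points. Species are exported in their native SBML
framing. Documents carry a provenance annotation (`template` vs
`curation`); `is_template()` treats absence as unknown, not template.

## Synthetic fixtures and what they show

All tests run on generated archives; nothing is downloaded:

* `gen_decay_chain(n, rates)` — a linear chain X0 → … → Xn with the exact
  Bateman closed form (`analytic_solution()`) as oracle; X0(10) for k = 0.1
  is 10·e⁻¹ ≈ 3.678794.
* `gen_mass_action_network()` — random conversion and reversible-binding
  reactions, log-uniform rates in [10⁻², 1], constructed so an integer
  weighting of species (1 for monomers, 2 for complexes) is exactly
  conserved; the weights and total ship inside the archive as
  `conservation.json`, and the weights provably lie in the left null space
  of the stoichiometry matrix.
* `gen_stiff()` — the Robertson-type system above.
* `gen_oscillator()` — a Lotka–Volterra mass-action scheme with period of
  order one over the ten-unit window, used to demonstrate the phase
  sensitivity of element-wise comparison.
* `corrupt_archive(a, rule)` — injects exactly one defect of a chosen rule
  class, enabling exact sensitivity/specificity accounting: lint flags the
  injected rule and nothing else, and valid fixtures lint clean.

These fixtures emulate the *structure* of curated kinetic models — mass
action kinetics, conservation, stiffness, oscillation — at desk scale. They
do not emulate the diversity of a real curated corpus: deep rule networks,
exotic annotation layouts, SBML packages, or models whose correct behavior
is itself contested. A green suite here demonstrates that the machinery is
correct on systems with known answers, not that any particular public model
reproduces.

Problem sizes were chosen so the full test suite and the acceptance script
each complete in a few minutes: template contract over 20 fixtures × 2
engines, 1000-case property tests for the comparator and the MathML
evaluator, and the 9-rule corruption matrix over two fixture families.

## Numerical and design notes

* The Dormand–Prince initial step uses the standard $0.01\,d_0/d_1$ norm
  heuristic, capped at a tenth of the span; integration failure (step-size
  collapse, non-finite states, step budget) is reported as
  `failed_numeric` with a log, never thrown.
* Steady-state simulations integrate in growing chunks (10, 100, …) until
  $\max_i |\dot x_i| < 10^{-8}(1 + |x_i|)$, with a time budget of $10^6$
  units; no Newton refinement — robust and engine-uniform, if slower than a
  root-finder. Repeated tasks support uniform and vector ranges, applying
  per-iteration set-values, resetting state only when `reset_model` is set,
  and stacking each iteration's output along the outer dimension;
  functional ranges are detected and reported unsupported.
* The comparator treats 0/0 as 0 and is property-tested for symmetry,
  scale covariance, and monotonicity in the element-wise deviation.
* Emitted SED-ML defaults to L1V3 (broadest legacy support; L1V4
  selectable, switching to `numberOfSteps`). Unknown top-level elements are
  carried as opaque blobs; unknown children inside known containers are not
  preserved.
* Results export is CSV (one file per report, header = labels) plus a JSON
  sidecar, via `write_results()`. The CLI config file format is YAML, with
  explicit flags taking precedence.
* The ZIP layer writes store-only (uncompressed) members with fixed
  timestamps, so identical inputs yield byte-identical archives — which is
  what makes the fixture generators' determinism contract testable.
* Events are wholly out of scope in this version (detected, tagged,
  refused); the verification logic is independent of that choice. The atol
  vector is computed once at $t_0$ and not rescaled mid-run.

## Known limitations

Element-wise comparison penalizes phase error harshly; a phase-aware method
would be needed for oscillatory corpora. Rate rules on concentration-framed
species in non-unit compartments are handled in native framing without
cross-framing conversion. SBML packages (layout, render, comp, fbc) are
carried opaquely, never validated. Only tolerance-level agreement is
promised across platforms, not bit reproducibility — except that a single
engine re-running the same repaired archive is deterministic, which is what
the repair-semantics tests rely on.
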