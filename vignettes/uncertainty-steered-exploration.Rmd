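---
title: "Uncertainty-aware, kinetics-steered exploration of reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware, kinetics-steered exploration of reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsteer)
```

## The problem

Automated exploration of chemical reaction networks produces thousands of
species (compounds and multi-molecule *flasks*) and elementary reactions,
but only a small subset carries the kinetics.  Two questions drive an
exploration campaign: *which species deserve further reaction trials*, and
*which free-energy parameters deserve a more accurate (and far more
expensive) electronic-structure treatment*.  `kinsteer` implements the
feedback loop that answers both from microkinetic simulation and
sensitivity analysis, with every quantum-chemistry call replaced by a
pluggable multi-fidelity energy oracle so that the steering logic itself
can be developed, tested and benchmarked at desk scale.

## Microkinetic model

Each species $n$ carries a free energy $G_n$ and each reaction $I$ a
forward activation free energy $\Delta G^\ddagger_I$ (both kJ mol$^{-1}$,
1 mol L$^{-1}$ standard state).  Mass-action kinetics give forward and
backward rates

$$f^+_I = k^+_I \prod_n c_n^{S^-_{nI}}, \qquad
  f^-_I = k^-_I \prod_n c_n^{S^+_{nI}},$$

with Eyring rate constants $k^+_I = (k_B T/h)\,
e^{-\Delta G^\ddagger_I/RT}$ (transmission coefficient 1) and
$k^-_I = k^+_I / K_I$, $K_I = e^{-\Delta G_{r,I}/RT}$, so detailed balance
holds by construction.  Concentrations follow
$\dot c_n = \sum_I (S^+_{nI} - S^-_{nI})(f^+_I - f^-_I)$, integrated with
a stiff-capable solver (`deSolve::lsoda`).  Two summary outputs feed the
steering: the maximum concentration $c^{\max}_n$ and the concentration
flux $c^{\text{flux}}_n = \sum_I (S^+_{nI}+S^-_{nI}) F_I$ with
$F_I = \int (f^+_I + f^-_I)\,dt$.  $F_I$ integrates the *sum* of forward
and backward rates, not the net rate; this choice makes $c^{\max}_n$ a
lower bound on $c^{\text{flux}}_n$ for species that start at zero
concentration, which the tests assert.

Free energies aggregate from structure-level records: $G_n$ is the
minimum total free energy (electronic + vibrational + rotational +
translational + solvation components) over the species' structures *at
the highest fidelity rank available* — a higher rank always wins, even if
a lower-rank structure lies lower, because energies from different ranks
are not comparable.  Barriers are the minimum transition-state total
minus the left-hand-side free energy; barrierless reactions take the
maximum of the two side free energies as their effective transition
state, so their forward barrier is $\max(0, \Delta G_r)$.

### Numerical choices

* Default solver tolerances `rel_tol = 1e-8`, `abs_tol = 1e-12` mol/L.
  Negative excursions are clipped at zero on output; an excursion beyond
  `10 * abs_tol` is treated as solver failure.
* The output grid is linear over the first second and logarithmic beyond
  (≥ 512 points) so that flux integrals resolve fast transients;
  trapezoidal quadrature runs on that grid.
* Effective forward barriers are clamped at evaluation time to
  $\max(\Delta G^\ddagger, 0, \Delta G_r)$: a transition state below the
  reactants caps the rate at $k_BT/h$, and a barrier below the reaction
  free energy (which would imply a negative *backward* barrier) is raised
  until the backward barrier is exactly zero.  The same rule is applied
  inside every sensitivity perturbation and every Morris sample.
* Barrierless reactions keep one parameter entry per reaction (the
  uniform contract for the parameter vector), but the entry is derived —
  re-computed as $\max(0,\Delta G_r)$ from the current species free
  energies — carries zero uncertainty and the top rank, and is therefore
  never independently perturbed or refined.  Perturbing the endpoint
  $G_n$ already moves it.

## Sensitivity analysis

Every parameter $x_i$ (a $G_n$ or a $\Delta G^\ddagger_I$) carries an
uncertainty $u(x_i)$ set by its fidelity rank: 10 / 15 kJ mol$^{-1}$ for
rank-1 species / barrier parameters, 5 kJ mol$^{-1}$ for rank-2 species
parameters, and $\max(\delta_{\text{PNO}}, 5)$ kJ mol$^{-1}$ for rank-3
barriers, where $\delta_{\text{PNO}}$ is the energy difference between
normal and tight PNO truncation settings of the coupled-cluster rank.

**Local OAT.**  Each screened parameter is set to $x_i \pm u(x_i)$ and
the model re-run; the score is
$\delta c^{\max}_i = \max_{n,\,\pm} |c^{\max}_n(X_i^{\pm}) -
c^{\max}_n(X_{\text{base}})|$.  Screening keeps only parameters of
species with $c^{\text{flux}}_n > \tau^{\text{kin}}_{\text{flux}}$ and
reactions with $F_I > \tau^{\text{kin}}_{\text{flux}}$; the default ties
$\tau^{\text{kin}}_{\text{flux}}$ to the exploration threshold
$\tau_{\text{flux}}$, since refining anything quieter cannot change the
steering.  Cost: $1 + 2|{\text{screened}}|$ model evaluations.

**Morris elementary effects.**  A grid of $p$ levels (default 4) spans
each parameter's $[x_i - u, x_i + u]$ interval; $N$ trajectories (default
20) change every parameter exactly once, in random order, by the
normalized step $\Delta = p/(2(p-1))$ (the standard choice, $2/3$ for
$p=4$).  The elementary effect divides the output change by the *signed
step in kJ mol$^{-1}$*, so $\mu^*_{ni}$ — the mean absolute effect over
trajectories — has units mol L$^{-1}$ per kJ mol$^{-1}$, and
$\mu^{*\max}_i = \max_n \mu^*_{ni}$.  For comparison against the
refinement threshold $\tau_{\text{ref}}$ (a concentration), $\mu^{*\max}$
is multiplied by the parameter's full grid step, i.e. it is read as "the
expected change in some maximum concentration per grid move".  Whether
the per-unit-energy or per-grid-step convention matches the original
choice is undecidable from the description; ours is isolated in
`select_refinement()` and documented here.  A spread-maximizing
trajectory variant draws a pool of $50N$ random candidates and greedily
selects $N$ maximizing summed squared pairwise trajectory distances;
exact subset selection is combinatorially infeasible.  Models with more
than 1000 parameters are screened by the same flux rule with the much
lower threshold $10^{-9}$ mol/L before the design is built.  The ensemble
of all $N(k+1)$ simulations additionally yields the mean and sample
standard deviation of every $c^{\max}_n$ and $c^{\text{flux}}_n$ — the
uncertainty measure used by the uncertainty-aware steering.

## Steering and refinement

Classic criteria queue species with $c^{\text{flux}}_n > \tau_{\text{flux}}$
for unimolecular exploration and unordered pairs (self-pairs included)
with $c^{\max}_n c^{\max}_m > \tau_{\max}$ for bimolecular exploration
(defaults $10^{-2}$ mol/L and $10^{-3}$ mol$^2$/L$^2$).  Uncertainty-aware
criteria replace each point value with the ensemble mean plus one
standard deviation and operate at the deliberately higher thresholds
$10^{-1}$ / $10^{-2}$; with zero spread the two modes coincide exactly,
which is a tested invariant.

Refinement upgrades flagged species free energies to rank 2 and flagged
barriers directly to rank 3 — barriers skip rank 2, mirroring a ladder in
which the middle rank re-optimizes structures but only the top rank
re-computes barrier energetics (that is also why rank-2 barrier and
rank-3 species uncertainties are undefined).  Flagging uses
$\delta c^{\max}_i \ge 10^{-2}$ mol/L (OAT) or $\mu^{*\max}_i$ per grid
step $> \tau_{\text{ref}} = 5\times10^{-2}$ mol/L (Morris).  A parameter
already at its top rank is never re-refined; if it remains sensitive, a
warning is emitted and the exploration proceeds.

The loop — discover incident reactions for the frontier, simulate, run
the configured sensitivity, refine, re-select targets — terminates when
an iteration yields no new targets and no refinements, or at
`max_iterations` (returned flagged as unconverged).  Already-explored
targets re-queue only if their criterion value has grown by more than
10 %, which prevents thrashing on borderline species; the exact guard
value is a free design choice.

## The synthetic oracle and what it does (not) emulate

`generate_network()` plants a dominant route: two seed fragments
associate to the first path species and a chain of exergonic, low-barrier
(45–60 kJ mol$^{-1}$) isomerizations leads to the product, surrounded by
higher-barrier (95–130 kJ mol$^{-1}$) side isomerizations that never
connect two path species directly — so the planted route is the
lowest-cost path by construction, which the exhaustive-enumeration tests
confirm.  All reactions are elementally balanced by construction and the
generator is bit-reproducible from its seed.

`synthetic_oracle()` serves discovery (reactions whose left-hand side
matches the explored species or pair) and rank-dependent energies:
truth + rank bias + normal noise, deterministic per (entity, rank, seed).
The error model acts on *activation* free energies — noisy transition-state
totals are anchored at the same rank's noisy left-hand-side free energy —
so that pushing rank-1 and rank-2 copies of a network through the
cross-rank delta machinery reproduces the configured statistics exactly.
Default calibration: rank-1 barrier errors mean $-4.5$ / MAD 15.1
kJ mol$^{-1}$ (the cheap rank overestimates barriers), rank-2 mean $+9.1$
/ MAD 10.3 (the middle rank underestimates), rank-1 free-energy errors
mean 12.0 / MAD 15.8, in the convention $\Delta =$ reference $-$
approximate.  Only mean and MAD are reported quantities, so the noise is
taken normal and its spread solved numerically from the folded-normal
expected MAD.

What the generator does *not* emulate: real discovery chemistry (reaction
trials, graph rules), correlated errors between related species (each
entity's error is independent), rank-dependent *discovery* failure, and
conformational complexity (one structure per species and rank).  Passing
tests therefore demonstrate the correctness of the steering, sensitivity
and refinement logic under known error statistics — not that those
statistics transfer to any particular chemistry.

## Worked example fixtures

Two hand-coded networks reproduce the free-energy profile of the
Eschenmoser–Claisen rearrangement (allyl- and furfuryl-alcohol variants):
methanol elimination, alcohol addition, second elimination, the
[3,3]-sigmatropic Claisen step, and (furfuryl only) a rearomatizing
H-shift.  The profile values are pinned exactly — e.g. allyl transition
states at 132.9, 138.8 and 140.8 kJ mol$^{-1}$ above the reactants and an
overall reaction free energy of $-122.7$ kJ mol$^{-1}$; the furfuryl
H-shift at 183.7 kJ mol$^{-1}$ above the post-Claisen intermediate, which
is why that intermediate accumulates.  Intermediate well depths are not
pinned by the profile; they are chosen mildly endergonic (+10 to +20
kJ mol$^{-1}$) so no intermediate accumulates and the highest transition
state controls the conversion — the published profile fixes transition
states and endpoints, and shallow wells are the choice that does not
introduce kinetics the profile does not assert.  A 24-h simulation of the
allyl fixture at 423.15 K then yields the rearrangement product as the
dominant species apart from the reactants and the methanol co-product
(two equivalents of methanol are released per product molecule, so
methanol's concentration is necessarily about twice the product's and is
excluded from the dominance comparison).

```{r fixture}
net <- eschenmoser_network("allyl")
params <- assemble_parameters(net)
sim <- simulate_network(net, params,
                        simulation_settings(T = 423.15, t_max = 24 * 3600))
round(sim$c_max, 3)
find_path(net, params, "amide_acetal", "amide_product", T = 423.15)
```

## Pathfinding

`find_path()` runs Dijkstra on a bipartite species/reaction digraph with
one node per reaction direction.  The edge into a reaction direction
costs $\max(\Delta G^\ddagger, 0)/RT$ plus the *compound costs* of every
co-reactant the step consumes (default: 1.0 for species with a positive
starting concentration, 10.0 otherwise, overridable per species) —
co-reactant availability is what distinguishes a cheap association from
an expensive one.  This weight is a monotone stand-in for the original
shortest-path analysis it is modeled after, not a reproduction of that
tool's exact cost recursion; all assertions in this package are about the
weight defined here (verified against exhaustive path enumeration on
small instances).  The step report traces cumulative free energies
relative to the source side, adding co-reactant free energies as they
enter, so the printed levels match the fixture profile values above.

## Problem sizes and test design

The test suite and acceptance script run everything at small scale by
choice: toy networks of 2–10 species for closed-form and brute-force
comparisons, a 120-species / 300-reaction ground truth with ~330 noisy
copies (≥ $10^5$ deltas) for the calibration statistics, and a 10-species
planted-path exploration for end-to-end recovery.  Oracles are
independent implementations: a fixed-step RK4 integrator for the ODE
path, naive re-simulation for OAT, exhaustive finite differencing for
Morris, and exhaustive path enumeration for Dijkstra.

## Known limitations

* Isothermal, well-mixed batch reactor only; no volume/pressure dynamics.
* `c_max` is read off the (dense) output grid, not from a root-finder on
  the interpolant; with ≥ 512 log-spaced points the residual error is far
  below every threshold the steering uses.
* The Morris σ of elementary effects (interaction diagnostic) is stored
  but not used by any criterion.
* The SBML writer is export-only and not validated against the full SBML
  schema; it targets mass-action interchange.
* With zero-concentration co-reactants the compound-cost default (10.0)
  is a blunt instrument; supply explicit costs for serious path analysis.
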