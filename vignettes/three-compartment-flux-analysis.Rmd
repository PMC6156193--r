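---
title: "Methods: three-compartment host-symbiont flux analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-compartment host-symbiont flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbioflux)
```

## The model

`symbioflux` analyzes symbioses in which an insect host harbors two
intracellular bacteria — a primary and a co-primary symbiont — that together
supply the essential amino acids (EAAs) missing from the diet. The analysis
object is a single stoichiometric network spanning four compartments: host,
primary symbiont, co-primary symbiont, and the external medium. Each
organism contributes its metabolites (compartment-suffixed ids such as
`gln[h]`) and bounded reactions; the compartments are joined exclusively by
1:1 transport reactions that move one metabolite species between two
compartments and carry no ATP or proton stoichiometry. Cost-free transport
is an explicit modeling assumption, made because transporter annotation and
transport energetics are essentially unknown for these unculturable
symbionts; its consequence — metabolite transfer is never rate- or
yield-limited by the transfer itself — should be kept in mind when
interpreting maintenance costs, which it can underestimate.

Flux inference is plain flux balance analysis: maximize the host objective
$c \cdot v$ subject to steady state $S v = 0$ and bounds
$lb \le v \le ub$ (all fluxes in mmol gDW$^{-1}$ h$^{-1}$). Flux
variability analysis then re-solves $\min v_r$ and $\max v_r$ for each
reaction $r$ with the objective pinned at its optimum, which is how we
quantify how tightly the optimum determines each flux.

Assumptions inherited by every analysis:

- **Steady state.** No metabolite accumulates; the bacteriocyte is treated
  as a well-mixed chemostat-like system.
- **A single host objective.** The host "grows" by consuming EAAs (weighted
  by the amino-acid composition of whole-insect protein) plus B vitamins at
  a nominal coefficient; maximizing it stands in for host fitness.
- **Symbionts as constrained passengers.** Each symbiont's biomass reaction
  has a fixed lower bound rather than an objective of its own, i.e. the host
  "farms" the symbionts at a set growth rate.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| oxygen uptake cap | 20 | mmol gDW⁻¹ h⁻¹ | aerobic condition on the medium |
| other nutrient uptake cap | 100 | mmol gDW⁻¹ h⁻¹ | generous ceiling for glucose/ammonia/sulfate uptake |
| amino acids in medium | excluded | — | the symbiosis, not the diet, must supply EAAs |
| symbiont biomass floor | 0.01 | mmol gDW⁻¹ h⁻¹ | equal biomass proportions for both symbionts; forces their maintenance to be paid |
| exchange threshold | 10⁻⁶ | mmol gDW⁻¹ h⁻¹ | below this a transport flux is treated as numerically zero; minerals/cofactor-pathway species are exempt because they are genuinely required in trace amounts |
| default host bound | 10 | mmol gDW⁻¹ h⁻¹ | host reactions with no matching transcript |
| B-vitamin objective coefficient | 0.00005 | mmol gDW⁻¹ | keeps vitamins required but quantitatively negligible; applied per vitamin |
| FVA range threshold | 1 | mmol gDW⁻¹ h⁻¹ | summary statistic for "tightly determined" reactions |
| transport variation threshold | 1 | % of optimal flux | summary statistic for transport reactions |

Expression-derived bounds: bacteriocyte TPM values are normalized by
substituting each replicate's lowest nonzero TPM for zeros, averaging
replicates, dividing by the lowest nonzero mean and rounding to the nearest
integer (half-up, fixed for reproducibility), so the least-expressed
transcript has level 1. A gene–protein–reaction rule is evaluated with
OR = sum and AND = min — isozymes add capacity, a complex is limited by its
scarcest subunit. This mapping is a design choice of this package: the level
is used directly as the flux bound (the scale is configurable), consistent
with the default bound 10 living on the same scale. Genes missing from the
table contribute 0 to OR and are ignored by AND; a rule with no matched gene
falls back to the default bound.

Two further conventions are fixed and documented rather than configurable:
exchange reactions are written export-positive (uptake is negative flux, so
a medium cap appears as a lower bound), and transport reactions are
reversible by default with direction resolved by FBA, since directionality
is not annotated for these systems.

## What the synthetic generator emulates — and what it does not

`generate_toy_symbiosis()` builds a miniature symbiosis with the same
architecture as the real models: host uptake of glucose and ammonia, a host
precursor pool, linear EAA-synthesis pathways partitioned between the two
symbionts (7 + 3 by default), a designed cross-fed intermediate made by the
primary symbiont and consumed only by the co-primary, ammonia overflow from
the co-primary, biomass drains on both symbionts, and the full medium with
the default caps and floors above. Its chemistry uses a small C/H/N/O
alphabet (precursor C₃H₆O₃, all EAAs C₃H₉NO₃, an amino-donor carrier
C₃H₍₆₊₃ₘ₎NₘO₃), chosen so that **every internal reaction is exactly
elementally balanced** and the nitrogen ledger must close. The ammonia
overflow rate $r$ is realized through the integer nitrogen stoichiometry
$m = \mathrm{round}(1/(1-r))$ of the carrier: each co-primary EAA returns
$m-1$ of its $m$ nitrogen atoms as ammonia.

The crucial property is that the FBA optimum is available in closed form as
a minimum over three bottlenecks — per-EAA pathway capacities, the
glucose/precursor budget, and the nitrogen budget:

$$z^\* = \min\Big(\min_i \mathrm{cap}_i,\;
  \frac{2\,g_{\max} - f(a_A + a_B)}{n_A + n_B},\;
  \frac{n_{\max} - f(b_A + b_B)}{n_A + n_B}\Big)$$

with $f$ the biomass floor and $a_X, b_X$ the symbionts' precursor and
ammonia drains per unit biomass. The generator computes this — and the
expected exchange tables, cross-feeding records, nitrogen ledgers and
maintenance costs — by arithmetic, never by the LP engine, so the test suite
checks the solver against a genuinely independent expectation. Randomness
enters only through the capacity draws; topology is deterministic, which is
what keeps the closed form valid. Per-EAA capacities default to the
interval [15, 30], placing the nitrogen budget strictly below every other
bottleneck so the optimal flux pattern is a unique vertex and the expected
exchange tables are well-defined; narrower or shifted intervals (used in
the tests) exercise the capacity- and glucose-limited regimes, where only
the objective value is compared because alternate optima then exist.

What the toys do **not** emulate: genome-scale topology (loops, cofactor
cycling, redundant pathways beyond the designed ones), realistic flux
magnitudes (the toys run at their caps, about 40-fold above the deposited
models' EAA fluxes), curation noise (orphan reactions, gap-fills), or
thermodynamic constraints. A green property suite therefore demonstrates
that every pipeline stage computes its defined quantity correctly; it does
not validate the biology of any particular reconstruction.

## Numerical choices

- **LP engine.** A two-phase bounded-variable primal simplex with Bland's
  smallest-index rule. Stoichiometric LPs are heavily degenerate (most
  fluxes sit at bounds or at zero) and rank-deficient (conserved moieties);
  Bland's rule guarantees termination, and redundant balance rows are
  dropped by QR factorization while phase-1 artificials pinned at zero
  absorb any remaining dependence. The basis inverse is maintained by
  product-form updates and refactorized every 64 iterations to control
  drift. Everything is deterministic for a fixed reaction ordering (the
  model's own), so reported optimal fluxes are reproducible even where
  alternate optima exist.
- **Tolerances.** Feasibility and zero-flux tolerance 10⁻⁹; the FVA
  objective pin is $c \cdot v \ge z^\* - \max(10^{-9}, 10^{-6}|z^\*|)$
  because exact equality is numerically brittle.
- **Bounds must be finite**; ±1000 is the conventional "unbounded"
  placeholder, which keeps every LP bounded and lets phase 1 decide
  feasibility cleanly.
- **Alternate optima.** Plain FBA reports an arbitrary (but deterministic)
  optimal vertex, matching the original analysis style; an optional
  stabilized mode (`stabilize = TRUE`) minimizes total absolute flux at the
  fixed optimum, removing futile cycles from reports. Default is off.
- **Degenerate inputs.** Infeasible models are a status, not an error, from
  `solve_fba()`; an empty objective, a transported metabolite without an
  elemental formula (nitrogen ledger), a biomass floor above its upper
  bound, and an all-zero expression table are hard errors with named
  offenders. `degenerate_case_suite()` packages these fixtures.
- **Net exchange accounting.** Opposing transports of one species into one
  compartment are summed before thresholding, so a species is never listed
  as both import and export; a metabolite relayed through the host
  (symbiont → host → symbiont) counts as cross-fed exactly when the host's
  net flux for it is below threshold.
- **Rounding.** Percent shares and report floats are rounded only at output
  (6 significant digits); stored values are exact, and reports are
  byte-identical across reruns.

## Problem sizes

The default toy bundle has 41 reactions and 38 metabolites across four
compartments. The property suite runs the solver-vs-enumeration oracle on
100 random models of up to 8 reactions (the oracle is exponential in the
reaction count, which is what makes 8 the practical ceiling), 50 toy bundles
across five design regimes for the closed-form checks, and full FVA (2×41
LPs) plus both maintenance-cost simulations on single bundles. These sizes
were chosen to exercise every code path with exhaustive independent oracles;
the package itself has no size-dependent logic, and the same pipeline runs
unchanged on the deposited genome-scale models (≈350–880 reactions) when
they are supplied.

## Known limitations

- Charge balance, protons and pH, and thermodynamic feasibility are out of
  scope; mass balance is checked elementally only.
- The SBML support is the Level 3 core + fbc subset needed for
  constraint-based models (species formulas, flux-bound parameters,
  objectives, gene-product associations); groups, units, rules and events
  are ignored.
- Maintenance costs inherit the cost-free-transport assumption and are
  therefore lower bounds on the true cost of carrying a symbiont.
- The exempt-metabolite list for exchange classification (minerals,
  cofactor-pathway species) is tag-driven and editable; membership is a
  curation decision, not something the package infers.
- Reported fluxes from plain FBA are one optimal solution among possibly
  many; FVA ranges and the stabilized mode are provided to judge and
  control that ambiguity, and conclusions should lean on quantities FVA
  shows to be tight.
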