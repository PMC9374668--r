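---
title: "Modelling 2N+/PACC eco-evolutionary dynamics"
author: "paccsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 2N+/PACC eco-evolutionary dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paccsim)
```

## The model

`paccsim` couples the ecology of a two-state cancer cell population with the
adaptive dynamics of a continuous resistance trait. The proliferative
aneuploid state (2N+, density `x1`) grows logistically, is killed by
chemotherapy, and transitions into the polyaneuploid state (PACC, density
`x2`) both at a constant (obligate) rate and facultatively in proportion to
the drug-induced stress it experiences. PACCs do not divide and are fully
drug-resistant; they return to the 2N+ state by depolyploidization, each
event yielding two aneuploid daughters. Collecting the per-capita rates
gives a 2×2 population projection matrix `A` (see `assemble_ppm()`), and the
population equations are exactly `d(x1,x2)/dt = A (x1,x2)'`.

Because 2N+ and PACC are life-history states of one cell lineage — not
separate species — fitness must be assigned to the lineage across states.
The package uses the spectral bound `ρ(A)`, the asymptotic per-capita growth
rate of the structured population, as the fitness-generating function, and
evolves the mean resistance trait by

$$\frac{dv}{dt} = k\,\frac{d\rho(A)}{dv},$$

the product of evolvability and selection gradient. This is a mean-field
description of a trait distribution: all cells within a state share the
mean trait, and there is no explicit sensitive/resistant subdivision.

Drug kill follows Michaelis–Menten kinetics `μ = m/(λ + b v)`. Two
deliberate structural assumptions are inherited from the modelling
tradition this belongs to: the trait is unbounded and carries no cost, so
sufficient evolution can neutralize any dose.

### Hypotheses and targeted drugs

* **Single state** (`"single_state"`): no PACC compartment; fitness is the
  scalar per-capita growth rate and the gradient has the closed form
  `b m/(λ + b v)²`.
* **Non-proliferation** (`"non_proliferation"`): PACCs are a refuge. When
  `μ ≥ 1` (the shut-off threshold, `np_threshold`), depolyploidization
  stops: `c12` is zeroed in both matrix entries it occupies, freezing the
  PACC compartment. The matrix becomes triangular with eigenvalues
  `{a11, 0}`; while the 2N+ eigenvalue is negative the dominant eigenvalue
  is the constant 0, the selection gradient vanishes, and no resistance
  evolves. At the kink `a11 = 0` the gradient is defined as the
  subgradient 0.
* **Evolutionary triage** (`"evolutionary_triage"`): evolvability is the
  density-weighted mean `k = (k1 x1 + k2 x2)/(x1 + x2)` with `k2 > k1`, so
  therapy-induced PACC enrichment accelerates resistance evolution. At zero
  total density the weighted mean is defined as 0 — an empty population has
  no trait motion — which keeps the coupled system well-defined as
  extinction is approached.

Targeted drugs each modify one matrix entry: the KIFC1 inhibitor scales the
depolyploidization *inflow* `a12` by `(1 - n)` while transitioning PACCs
still leave at `c12` (blocked transitions are lethal); the cyclin/CDK
inhibitor scales PACC formation `a21` by `(1 - n)`; the metabolic modulator
adds `-n` to `a22`. The selection gradient is always taken on the
currently-modified matrix: an active targeted drug is part of the selective
environment. Setting `n = 0` recovers the baseline matrix bitwise.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `r` | 2N+ intrinsic growth rate | 0.6 | 1/time |
| `K` | carrying capacity | 100 | density |
| `gamma` | obligate 2N+→PACC rate | 0.02 | 1/time |
| `m` | chemotherapy dose (schedule) | 1 | – |
| `lam` | baseline resistance | 1 | – |
| `b` | resistance efficacy | 1 | – |
| `c21` | facultative transition scaling | 0.7 | – |
| `c12` | depolyploidization rate | 0.2 | 1/time |
| `zeta` | transition success probability | 0.7 | – |
| `n` | targeted-drug dose (schedule) | 0.8 | – |
| `k_const`, `k1` | evolvability (non-triage / 2N+) | 0.01 | trait²/time |
| `k2` | PACC evolvability (triage) | 0.5 | trait²/time |
| `np_threshold` | refuge shut-off kill rate | 1 | 1/time |
| `extinction_eps` | extinction threshold | 1e-3 | density |

The ecological rates and doses are the baseline simulation values of the
modelling framework this package implements. The evolvabilities have no
canonical values; the defaults here are calibration choices: `k_const`
small enough that the single-state model cannot rescue itself under
full-dose therapy (extinction wins the race against trait growth), `k2`
large enough that evolutionary triage rescues under continuous full-dose
therapy. The qualitative verdict battery (`run_scenario_battery()`) is the
calibration's acceptance surface.

`extinction_eps` exists because a continuous ODE never reaches zero: a
compartment is declared extinct, and clamped to exactly 0, when it falls
below `1e-3` density units at an integration-segment boundary. Verdicts are
insensitive to the exact value over roughly two orders of magnitude for the
refuge scenarios, but see "Limitations" for where the threshold becomes the
load-bearing modelling choice.

## Scenarios and schedules

All dose functions are piecewise constant with half-open windows
`[start, end)`. The standard protocols are continuous chemotherapy on
`[200, 800)`, intermittent chemotherapy alternating every 100 time units
(ON `[200,300)`, `[400,500)`, `[600,700)` — the alternation phase is a
convention; the construction allows overrides), and 50-unit targeted-drug
windows before (`[150,200)`), during (`[200,250)`) or after (`[250,300)`)
chemotherapy onset, at dose `n = 0.8`. Initial conditions default to
`x1 = 100`, `x2 = 0`, `v = 0`; the 200 time units before therapy reach the
no-therapy quasi-equilibrium (the PACC relaxation time is `1/c12 = 5`, far
shorter than the burn-in), so every scenario starts therapy from the same
baseline PACC level.

## Numerics

Integration is segment-by-segment between schedule breakpoints with lsoda
(`deSolve`), relative tolerance `1e-8`, absolute `1e-10`; doses are constant
within a segment, so the integrator never sees a discontinuity. Segments
are capped at 100 time units, and extinction clamping happens only at
segment ends, leaving the solver's error control untouched within a
segment. The non-proliferation trigger depends on the evolving trait, not
on the schedule, so it is evaluated inside the right-hand side. The
spectral bound uses the closed form `(tr + √(tr² − 4 det))/2`, which the
Metzler structure of `A` (nonnegative off-diagonals) keeps real; the
analytic gradient differentiates the characteristic polynomial,
`ds/dv = (s·a11' − det')/(2s − tr)`, falling back to central finite
differences within `1e-12` of an eigenvalue collision. The closed-form
single-state resistance trajectory
`v(t) = ((λ³ + 3 k b² m t)^{1/3} − λ)/b` and the algebraic no-therapy
equilibrium (`x2*/x1* = γζ/c12`, `x1* + x2* = K(1 − γ(1 − 2ζ)/r)`) serve as
independent anchors for the integrator in the test suite. Problem sizes
throughout (horizons of 1000 time units, 25-scenario battery) run in
seconds.

## Design choices where the design was open

* **Refuge shut-off scope.** The shut-off is described as stopping the
  PACC→2N+ transition; naively zeroing only the diagonal PACC entry while
  keeping the inflow `2 c12 x2` would create cells from nothing. Both
  `c12` occurrences are zeroed, which also produces the observed flat PACC
  plateau under therapy.
* **Which matrix the gradient differentiates.** Under a targeted drug the
  variant-modified matrix is used, treating the drug as part of the current
  selective environment.
* **Outcome semantics.** "Eradicated" means every compartment extinct at
  the horizon; "evolutionary rescue" is simply non-extinction. A
  compartment clamped to zero can be recolonized by the other state (e.g.
  2N+ regrown from persisting PACCs), in which case its extinction record
  is cleared.

## What the simulations do and do not show

The scenario battery reproduces the qualitative structure of the
hypotheses' predictions: single-state populations persist untreated, rescue
under half dose and die under full dose; the refuge persists through any
chemotherapy-only schedule with zero resistance evolution; triage
populations rescue by evolving resistance; and metabolic PACC killing
during or after chemotherapy eradicates the refuge-governed population.

Two caveats matter when reading those verdicts.

First, **the trait dynamics are density-independent** (evolvability weights
are frequencies, not densities), so a vanishingly small population evolves
as fast as a large one. Under evolutionary triage the spectral bound turns
positive already at `v ≈ 0.184` (full dose), so once a targeted-drug window
closes, rescue races extinction with a generous head start: the baseline
decay rate under full-dose chemotherapy is only `|ρ| ≈ 0.017` because of
the PACC refuge loop. With the default calibration the transient minima in
the triage/targeted-window scenarios sit around `0.02–0.15` density units
— biologically negligible, but above `extinction_eps`, so those runs
classify as rescued. A threshold-free reading of the same trajectories
("the population collapses to well under one cell") would call them
eradicated. This is an honest structural sensitivity of ODE models of
near-extinction dynamics, and it is the main place where conclusions depend
on the extinction operationalization rather than on the ecology.

Second, **the single-state reduction has a regime of validity**. With
`gamma = c21 = 0` and no PACCs the structured model still carries the inert
PACC eigenvalue `-c12`; when the dose is strong enough that `a11 < -c12`,
the spectral bound saturates at `-c12` and the trait freezes, whereas the
scalar model's gradient does not. The reduction identity therefore holds
exactly for doses keeping `a11 > -c12` along the trajectory (tested at
`m = 0` and `m = 0.15`). Relatedly, the selection gradient is provably
nonnegative only at ecologically admissible densities (total up to the
no-therapy equilibrium, `≈ 101.3`); far above carrying capacity the true
derivative can reverse sign, because weaker kill also means weaker
sheltering into the refuge. The package returns the true derivative rather
than clipping.

The model also inherits the simplifications of its framework: no cost of
resistance and no strategy bounds (so resistance can grow without limit),
within-state homogeneity, no background mortality, deterministic dynamics
(no demographic stochasticity, which dominates real near-extinction
behavior), and piecewise-constant pharmacology.

## Session

```{r}
sessionInfo()
```
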