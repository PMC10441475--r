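---
title: "Supervised sampling and binding kinetics for m6A recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised sampling and binding kinetics for m6A recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumdkin)
```

## Scope

The METTL3–METTL14 heterodimer writes N6-methyladenosine (m6A) on GGACU
RNA motifs and, through a cryptic product-binding pocket gripped by an
arginine clasp (METTL3 R471, METTL14 R298), also senses the methylation
status of the swiveled base. Two computational strands accompany that
biology: an adaptive-sampling scheme that accelerates ligand binding in
molecular dynamics without biasing forces, and a family of binding-kinetics
models for the SPR, fluorescence-polarization and base-de-stacking assays
that quantify how wild-type and clasp-mutant enzymes engage structured and
linear RNA. `sumdkin` implements both strands at desk scale: the sampling
algorithm runs on toy Langevin dynamics over parametric funnel landscapes,
and the kinetic models run on synthetic or user-supplied tables. Nothing in
the package requires all-atom simulation, structure files or instrument
binaries.

## The supervised-sampling algorithm

The engine (`run_sumd()`) iterates short windows of unbiased dynamics. For
each window it records the supervision metric — a ligand-to-pocket distance
— at every stored frame, fits an ordinary least-squares line of distance
against time (`fit_slope()`), and applies one rule:

* slope < 0: the window is **accepted**; its final state (coordinates,
  velocities, and the RNG token) becomes the next initial state;
* slope >= 0: the window is **rejected** and discarded; the next window
  restarts from the last accepted state with fresh noise.

A zero slope counts as a failure: only a strictly negative trend is
evidence of approach. After 10 consecutive failures (configurable) the
ligand is considered stuck; one longer unsupervised *escape* segment — 5
windows by default — is run and its final state adopted *unconditionally*,
resetting the failure counter. The escape segment is not slope-checked;
adopting its endpoint regardless of direction is what lets the algorithm
back out of dead ends.

Supervision proceeds in stages. The default two-stage plan for a funnel
landscape watches the particle-to-pocket-center distance down to
`2 * well_width`, then the mean of the distances to two anchor points at
`center ± 0.25 * well_width` (the toy analog of gating on two key
atom-pair distances; the mean was chosen because it is symmetric and
monotone in both distances) down to `0.5 * well_width`. Reaching the final
threshold switches supervision off — outcome `"bound"`. Design choices
worth stating explicitly:

* rejected windows consume fresh RNG draws; re-using the noise of a
  rejected window would deterministically repeat the failure;
* the slope uses every stored frame in the window, not just endpoints;
* the first-passage time reported for a supervised run counts **all**
  simulated time, including rejected windows and escape segments — the
  honest basis for comparing against plain dynamics;
* `run_swarm()` runs seeded replicas and returns the first k (by replica
  index) that bound, mirroring swarm-style usage.

Because acceptance only filters *which* stochastic excursions are kept and
never adds a force, the ensemble inside the well after switch-off should be
indistinguishable from an undisturbed equilibrium run. The test suite
checks this with a two-sample Kolmogorov–Smirnov test (below).

## Toy dynamics

`advance()` integrates overdamped Euler–Maruyama dynamics by default:
`dx = F/γ dt + sqrt(2 kT dt / γ) ξ`, with kT = 1, friction γ = 1 (so the
diffusion coefficient D = kT/γ = 1), timestep 1e-3 toy time, one stored
frame per 10 steps. An underdamped BAOAB-style scheme (unit mass) is
available as `mode = "langevin"`; it exists because the supervision restart
rule is defined on coordinates *and* velocities, and the underdamped mode
preserves that semantic. The integrator uses R's RNG stream, and every
returned `toy_state` carries the generator state as an opaque token, so a
split run is bit-identical to an uninterrupted one — the restart contract
the supervision loop relies on.

Boundaries are reflecting walls, not periodic: on a toy funnel, periodic
wrap-around would let a particle "bind" by leaving the far side of the box,
which defeats the purpose of a directional search. There is no equilibration
protocol to inherit at this scale; where an equilibrated start is needed
(histogram tests), a fixed burn-in of 1e3 steps is used.

Euler–Maruyama carries an O(dt) sampling bias; at the default timestep and
the well curvatures used here the bias is far below every tolerance tested,
and comparisons between two runs of the same integrator cancel it exactly.

## Landscapes

`gen_landscape()` builds a Gaussian well truncated (and shifted to
continuity) at 5 well widths,

`U(r) = -depth · (exp(-r²/2w²) - e_c) / (1 - e_c)` for `r < 5w`, else 0,

so the center energy is exactly `-depth` and the background exactly zero.
An optional radial Gaussian barrier shell models a gated entry. The
reference landscape `m6a_funnel()` is 2D with depth 8 kT, width 1, start at
distance 8 in a box of half-width 10 — deep enough that spontaneous binding
is rare on short runs but observable, which is exactly the regime where a
supervision speed-up is measurable. Units are toy units throughout (kT = 1,
dimensionless lengths); no conversion to physical units is implied.

## Binding-kinetics models

**1:1 Langmuir.** `dR/dt = kon·C(t)·(Rmax − R) − koff·R`, `KD = koff/kon`.
Each constant-concentration phase has a closed-form mono-exponential
solution, applied piecewise over the injection schedule with the response
continuous across boundaries.

**Two-state reaction (conformational change).** `A + B ⇌ AB ⇌ AB*` with

```
d[AB]/dt  = kon1·C·(Rmax − AB − AB*) − koff1·AB − kon2·AB + koff2·AB*
d[AB*]/dt = kon2·AB − koff2·AB*,   R = AB + AB*
```

and overall `KD = (koff1/kon1) · koff2/(kon2 + koff2)`. Each phase is an
affine-linear 2x2 system solved exactly via the closed-form matrix
exponential written in the stable eigenvalue basis (both eigenvalues are
non-positive for admissible rates; the cos/sin branch covers a complex
pair). A test cross-checks the propagator against `deSolve::lsoda`.

The conformational step is first-order, so `kon2` is a rate in s⁻¹ even
though instrument reports sometimes print it with second-order units; only
with `kon2` in s⁻¹ does the KD algebra reproduce the reported dissociation
constants, which it does for all eight mutant rows within 1 %
(`spr_reference_two_state()`). Among the wild-type 1:1 rows
(`spr_reference_1to1()`), the methylated linear substrate row is internally
inconsistent — its printed off-rate and KD cannot both hold under
`KD = koff/kon` — and is flagged `consistent = FALSE` rather than silently
"corrected".

**Schedules.** The standard single-cycle protocol is interpreted as five
sequential injections of an ascending five-fold series (2.4, 12, 60, 300,
1500 nM), 120 s association and 120 s inter-injection dissociation each,
1200 s final dissociation, sampled at 10 Hz. The protocol sentence this
derives from is ambiguous about the inter-injection dissociations; the
interpretation lives in `single_cycle_schedule()` and is fully overridable
through `injection_schedule()`.

**Saturation assays.** Fluorescence-polarization binding uses
`Y = Bmax·X/(Kd+X)`; the 2-aminopurine de-stacking assay uses the same
hyperbola with Michaelis–Menten naming `Y = Vmax·X/(Km+X)`. Replicates are
fitted independently and summarized as mean ± sd, the n = 3 convention.

## Fitting

`fit_sensorgram()` minimizes weighted residuals with Levenberg–Marquardt
(`minpack.lm::nls.lm`). All rates and Rmax are fitted in log space:
positivity is structural and the reference rates span four orders of
magnitude. The first start is data-driven (Rmax from the trace maximum,
koff from a log-linear fit of the final dissociation tail, kon from koff
and the mid-schedule concentration); the remaining starts perturb it
log-uniformly under a fixed seed, guarding against the two-state model's
local minima. Standard errors come from the Gauss–Newton approximation
(finite-difference Jacobian at the optimum, delta method back from log
space). Non-convergence is reported in the result object, never thrown.
A `decimate` argument thins dense traces before fitting; recovery
experiments here fit at 1 Hz, which loses nothing measurable on these
time scales and keeps 50-repeat experiments inside a coffee break.

## Synthetic data

Generators exist for every input: funnel landscapes, sensorgrams under
either kinetic model with i.i.d. Gaussian read noise (default 0.5 RU — a
package choice of realistic instrument read noise, not a reported value)
and optional linear drift, and titration curves with per-replicate noise.
True parameters always travel in metadata. One honest caveat: with a
symmetric noise model a baseline near zero necessarily produces slightly
negative samples, so generated traces are *not* clipped at zero; the
noise-envelope guarantee is `|R − clean − drift·t| ≤ 5·noise_sd`. What the
generators deliberately do not emulate: bulk refractive-index jumps,
injection spikes, reference-channel artifacts, mass-transport limitation.
Recovery results on this synthetic data therefore demonstrate correctness
of the models and optimizer, not robustness to real instrument pathology.

## Statistical validation choices

* **Einstein relation**: free-diffusion MSD equals `2 d D t` within three
  standard errors at n = 1e4 particles.
* **Boltzmann sampling**: a 1D quartic double well (2 kT barrier) is run
  for 4e6 steps and compared to `exp(-U/kT)` by a chi-squared test. The
  slow mode is barrier hopping (Kramers time ~4 toy-time units), so frames
  are thinned to 2-time-unit spacing first; a goodness-of-fit test on
  strongly autocorrelated frames would reject for reasons that have
  nothing to do with the integrator.
* **Switch-off unbiasedness**: a bound state produced by the supervised
  engine is continued unsupervised for 1e5 frames and compared (two-sample
  KS on the x coordinate) with a never-supervised run started at the
  pocket center. Both samples are conditioned on in-well frames
  (center distance ≤ 2) and thinned to ~6 relaxation times: the claim is
  about the bound ensemble, and the rare box excursions any 8 kT well
  permits contribute random heavy tails that differ between finite runs
  regardless of supervision.
* **Acceleration**: 20 supervised vs 20 unsupervised seeded replicas on
  `m6a_funnel()`, compared by one-sided Mann–Whitney on first-passage
  times (unbound replicas censored at the 4000-time-unit cap, which is
  conservative for the comparison). Typical speed-ups are five- to
  ten-fold in median first-passage time.

These problem sizes (20 + 20 replicas, 1e5 frames, 4e6 steps) are the
package's chosen defaults for a laptop-scale validation run.

## Limitations

The toy system is a single particle in a parametric field: no force
fields, no solvent, no topology, and its distances are toy lengths — the
all-atom center-of-mass distances (~1.5 Å) and pose RMSDs (~2 Å) of the
real complex are not reproducible here and are not attempted. The kinetic
fitters assume plain 1:1 or two-state mechanisms without mass-transport
limitation or avidity. The KD algebra reproduces reported tables exactly
because it is the same algebra those tables were derived with; that is a
consistency check on implementation and units, not new evidence about the
chemistry.
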