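---
title: "Methods: model, classification protocol, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, classification protocol, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`metanest` simulates a meta-ecosystem of `n` local ecosystems (patches),
each a three-compartment food chain: inorganic nutrients `N_i`, primary
producers `P_i`, consumers `C_i`. Locally,

* nutrients arrive at a constant rate `I_N` and are exported at rate
  `e_N` (both per patch, so patches are open systems even when
  uncoupled);
* producers take up nutrients with a saturating (Monod) response
  `f_P(N) = a_P N / (b_P + N)` and consumers graze with
  `f_C(P) = a_C P / (b_C + P)`;
* producer and consumer biomass is lost at linear rates `m_P`, `m_C`;
  fractions `r_P`, `r_C` of those losses are recycled into the local
  nutrient pool and the remainders leave the meta-ecosystem entirely.

Patches are coupled by two kinds of passive spatial flow, each encoded in
an `n x n` connectivity matrix with zero column sums (nothing is created
or destroyed in transit): inorganic resource flows at rate `d_N` through
`S_N`, and consumer dispersal at per-patch rates `d_C[i]` through `S_C`.
A producer matrix `S_P` exists as a hook but is zero by default: producer
movement is taken to happen within an ecosystem, not between them. The
per-patch derivative is implemented twice -- a reference R version
(`meta_derivative()`) that defines the model, and an equivalent C version
used by the integrator; the test suite holds them to each other.

The default parameterization (`meta_params()`) is
`I_N = 0.05, e_N = 0.01, m_P = 0.05, m_C = 0.24, a_P = 1, b_P = 10,
a_C = 0.6, b_C = 6, r_P = r_C = 0.8`. Under these rates an uncoupled
patch has the interior fixed point `P* = b_C m_C / (a_C - m_C) = 4`
exactly, with `N* ~ 0.584`, `C* ~ 0.0866` from a quadratic
(`closed_equilibrium()`); that point is the package's analytic oracle.

## Topologies and the scale contrast

The object of study is the *spatially nested* arrangement: two locations,
each holding one ecosystem of type A and one of type B. Resource flows
act at the small scale (within a location, across types: `A1 <-> B1`,
`A2 <-> B2`), dispersal at the large scale (across locations, within a
type: `A1 <-> A2`, `B1 <-> B2`). The control topology keeps dispersal
identical but lets resource flows connect every pair of patches
(`fully_connected_topology()`). The scale contrast is expressed purely
through which links exist; there are no distance-decay kernels. Swept
resource-flow rates extend up to an order of magnitude above dispersal
rates, matching the empirical contrast between the two kinds of flow.

Because the main text of the connectivity formalism leaves open whether
`d_N` is a per-link or a total-outflow rate, both normalizations are
implemented. The default, `donor_split`, fixes each patch's total
emigration rate at `d_N` (or `d_C[i]`) and splits it equally among
receivers; this keeps the nested and fully connected topologies
comparable at equal `d_N`, which the state-diagram comparison
presupposes. For the 4-patch nested topology every patch has one link
per compartment, so the two conventions coincide there and results on
the nested topology are convention-robust.

## Stable-state protocol

For each parameter combination the package draws a seeded ensemble of
random positive initial conditions (`sample_initial_conditions()`),
integrates each past a long transient, classifies each trajectory, and
forms an ensemble consensus (`run_ensemble()`). Initial conditions are
uniform on `(0, 2 x closed-ecosystem equilibrium]` per compartment; that
range brackets the attractors at baseline rates and reliably discovers
both branches of the bistable heterogeneous equilibrium. The ensemble
size is 50 in the replication presets and 10 in the transect protocol
used by the acceptance script; with fewer than ~8 draws, discovery of
both mirror branches is no longer near-certain (each draw falls on one
of the two with roughly equal probability).

Integration uses `deSolve::lsoda`, an adaptive solver that switches
between non-stiff and stiff methods automatically, at `rtol = 1e-8`,
`atol = 1e-10`. The evaluation window is sampled at unit spacing, better
than 100 points per cycle for the 120--160 time-unit periods that occur
here.

### Classification

A trajectory's window is labelled on two axes
(`classify_trajectory()`):

* **equilibrium vs. oscillation**: equilibrium iff every state
  variable's peak-to-peak amplitude over the window is below
  `tol_eq = 1e-5`. The value sits a factor of a few above the amplitude
  noise floor left by solver interpolation at the default tolerances
  (about 3e-6) and many orders below the O(1) amplitudes of the model's
  limit cycles, so the binary decision is insensitive to its exact
  placement.
* **homogeneous vs. heterogeneous**: heterogeneous iff the spread of
  time-averaged stocks across patches of the same ecosystem type exceeds
  `tol_het = 1e-3` for any compartment. Averages (trapezoidal, on the
  solver grid) rather than instantaneous stocks are compared, so
  heterogeneous oscillations are detected even when patches cycle with
  equal amplitude around different means. A secondary amplitude-spread
  criterion (5% relative) catches the converse degenerate case of equal
  means with unequal cycles; on the model's own attractors it never
  decides the label.

If the window is shorter than twice the dominant period (estimated from
mean-crossings of the meta-level consumer stock) the report is flagged
inconclusive rather than silently labelled. A phase-lag diagnostic
(cross-correlation between same-type consumer series) is recorded but
never used for labelling.

`classify_ensemble()` groups reports into attractors by matching
time-averaged stocks (relative tolerance 1e-3), counts groups *before*
symmetry reduction, and flags bistability when two groups are images of
one another under the location swap. Disagreement between conclusive
reports yields `MIXED`, which marks boundary cells in sweeps.

### Why the long horizon

The central numerical subtlety of this system is critical slowing down
around the symmetry-breaking threshold in `d_N`. Just below the
threshold, the asymmetric component of a random initial condition decays
with time constants of 1e5--1e6 time units; after a burn-in of only 1e4
units the same-type spread of window averages is still of order 0.1--1
-- transient asymmetry that a naive protocol would classify as a
heterogeneous attractor, moving the apparent onset far below its true
location. The sweep protocol therefore uses `t_transient = 1e6` with a
2e4-unit evaluation window. At that horizon the measured spread on the
homogeneous side of the threshold is below ~1e-4 while genuinely
heterogeneous states sit at 0.05--4, and `tol_het = 1e-3` separates the
two with an order of magnitude of margin on either side. The same
reasoning applies to the amplitude axis near the oscillation-stabilizing
threshold, where damped oscillations die out slowly; cells whose decay
has not completed by the horizon are reported as oscillatory, which
makes the reported stabilization threshold a faithful finite-horizon
statement of the same kind the original state diagrams make. These
horizons are cheap because the right-hand side is compiled: a
1e6-unit oscillatory run costs well under two seconds, and equilibrium
cells far less.

`simulate_meta()` itself defaults to a much shorter horizon
(`t_transient = 1e4`, `t_end = 1.5e4`), appropriate for interactive
exploration of transients and cycles; the sweep spec overrides it.

## Emergent metrics

* `net_flows()`: time-averaged spatial term `d_x sum_j S_x[i,j] x_j` per
  patch and compartment. Negative = net exporter = *source*; positive =
  net importer = *sink* (net-flow sense, not self-sustainability). Sums
  to zero over the meta-ecosystem, and within each same-rate dispersal
  group, up to quadrature error.
* `trophic_effect()`: `E_i`, the shift in secondary minus primary
  production relative to an uncoupled reference run of the identical
  system (`E_i > 0`: spatial flows impose net top-down pressure on
  producers; `< 0`: net bottom-up). Time-averaged, which reduces to the
  equilibrium value at fixed points; whether to average over cycles or
  evaluate only at equilibria was an open choice, and averaging was
  chosen because it specializes correctly and extends to the oscillatory
  regions.
* `local_functions()` / `meta_functions()`: primary and secondary
  production, and nutrient retention as a turnover time -- total stocks
  divided by the instantaneous rate at which nutrients leave the
  *meta-ecosystem* through the patch (`e_N N + (1-r_P) m_P P +
  (1-r_C) m_C C`). Spatial transfers are deliberately not counted as
  losses: they stay in the system. Local retention averages the ratio
  (`<stocks/loss>`); the meta level uses the pooled ratio. On equilibria
  the two orderings coincide.

## Sweeps

`state_diagram()`, `bifurcation_transect()`, `dispersal_plane()` and
`functions_transect()` run the ensemble protocol over grids, row-major,
each cell seeded deterministically from the spec's base seed (so reruns
are bit-identical and execution order is irrelevant), with per-cell
failures logged and coded `FAILED` rather than aborting, and optional
incremental CSV output that makes interrupted sweeps resumable. Default
grid steps are 0.05 in `d_N` (fine enough to resolve the thresholds near
2.6--3.0) and 0.02 in `d_C`. Threshold extraction
(`heterogeneity_threshold()`, `state_threshold()`) simply reads the
smallest grid value carrying a state code; there is no continuation or
root-polishing of bifurcation points, by design -- thresholds are
reported at grid resolution.

## What the replication runs show

On the nested topology at `d_C = 0.4` the transect passes from a
homogeneous equilibrium through homogeneous oscillations to
heterogeneous oscillations (onset near `d_N ~ 2.6` at grid resolution)
and then to a stable spatially heterogeneous equilibrium (near 2.9), in
which each location pairs a nutrient source/consumer sink with a
nutrient sink/consumer source, with opposite orientation at the two
locations, and the mirror-image equilibrium is reached from roughly half
of all random initial conditions. The fully connected control needs
substantially higher resource-flow rates before heterogeneity appears
(near 3.65--3.7) and never stabilizes it within the swept range. At the
heterogeneous equilibrium, meta-level primary production and nutrient
retention exceed their homogeneous-equilibrium values while secondary
production is lower. All of these statements are computed by the test
suite and the acceptance script, not asserted from memory.

## Known limitations

* The generator of initial conditions emulates only the protocol's
  uniform positive draws; real ecosystems are not uniformly distributed
  around the uncoupled equilibrium, so passing ensembles say nothing
  about basins far outside the sampled box.
* Attractor taxonomy covers fixed points and cycles; no Lyapunov or
  Floquet machinery, no chaos detection.
* Thresholds are grid-resolution statements under a finite (if long)
  horizon; states whose transients outlive 1e6 time units would be
  misread, and the stabilization threshold in particular is a
  finite-horizon quantity.
* No demographic or environmental stochasticity, no stage structure,
  at most three trophic compartments, dense matrices only (fine for the
  tens of patches the builders produce).
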