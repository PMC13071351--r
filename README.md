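# metanest

Ecosystems exchange material with their surroundings in two very
different ways: inorganic resources (nutrients, detritus) drift between
*nearby* ecosystems of *different* types — an island fertilizing its
fringing reef, a forest shedding litter into a pond — while many
organisms disperse between *distant* ecosystems of the *same* type. When
both happen at once, the short-range resource links are embedded inside a
longer-range dispersal network: a **spatially nested topology** of
coupled ecosystems.

`metanest` implements a minimal model of that situation and the analysis
pipeline around it, for theoretical ecologists studying meta-ecosystem
dynamics. Four patches form two locations; each location holds one
ecosystem of type A and one of type B. Every patch runs a
nutrient–producer–consumer chain

```
dN_i/dt = I_N − e_N N_i + m_P r_P P_i + m_C r_C C_i − P_i f_P(N_i) + d_N Σ_j S_N[i,j] N_j
dP_i/dt = P_i f_P(N_i) − m_P P_i − C_i f_C(P_i)
dC_i/dt = C_i f_C(P_i) − m_C C_i + d_C[i] Σ_j S_C[i,j] C_j
```

with Monod uptake `f_P(N) = a_P N/(b_P+N)`, `f_C(P) = a_C P/(b_C+P)`, and
conservative connectivity matrices `S_x` (column sums zero; donor-split
normalization by default). Resource flows (`d_N`, through `S_N`) connect
A↔B within a location; consumer dispersal (`d_CA`, `d_CB`, through `S_C`)
connects same-type patches across locations. A control topology with
fully connected resource flows isolates the effect of the nesting.

The package provides:

* topology builders and validators (`nested_topology()`,
  `fully_connected_topology()`, `validate_topology()`);
* a compiled integrator with seeded initial-condition ensembles
  (`simulate_meta()`, `sample_initial_conditions()`, `run_ensemble()`);
* attractor classification into homogeneous/heterogeneous ×
  equilibrium/oscillation, with bistability detection
  (`classify_trajectory()`, `classify_ensemble()`);
* emergent source–sink and trophic-regulation metrics (`net_flows()`,
  `trophic_effect()`), local and meta-ecosystem functions
  (`local_functions()`, `meta_functions()`);
* sweep pipelines — state diagrams, bifurcation transects, dispersal
  planes, function transects — with presets, incremental CSV output and
  JSON run manifests (`state_diagram()`, `bifurcation_transect()`,
  `dispersal_plane()`, `functions_transect()`, `replication_preset()`), plus a
  thin CLI in `inst/cli/metanest-cli.R`.

## Worked example: the cross-scale source–sink state

At high resource flow and sufficient dispersal (`d_N = 5`,
`d_C = 0.4`), the nested meta-ecosystem settles into a spatially
heterogeneous *equilibrium* organized by emergent source–sink roles:

```r
library(metanest)
topo <- nested_topology()
p <- meta_params(d_N = 5, d_C = 0.4)      # baseline local rates
res <- run_ensemble(p, topo, seed = 1, n_ic = 10,
                    t_transient = 1e6, t_end = 1e6 + 2e4,
                    keep_trajectories = TRUE)
res$verdict
#> <ensemble_verdict> HET_EQ, 2 attractor(s), bistable
```

Every initial condition converges to a heterogeneous point equilibrium,
but to one of two mirror images (4 vs. 6 of the 10 draws here): the
system is bistable, and which location plays which role is decided by
history. The emergent flow structure of one attractor:

```r
net_flows(res$representatives[[1]])
#>   patch type location net_resource_flow net_dispersal role_N role_C
#> 1    A1    A        1       -0.02646646    0.00259559 source   sink
#> 2    B1    B        1        0.02646646   -0.00259559   sink source
#> 3    A2    A        2        0.02646646   -0.00259559   sink source
#> 4    B2    B        2       -0.02646646    0.00259559 source   sink
```

Each patch that exports nutrients imports consumers and vice versa
(opposite signs in the two columns), and the orientation flips between
locations — nutrients and consumers circulate around the meta-ecosystem
in opposite senses. The trophic consequence, measured against an
uncoupled reference run:

```r
ref <- simulate_meta(meta_params(), topo,
                     sample_initial_conditions(2, 1)$draws[[1]],
                     t_transient = 1e5, t_end = 1.2e5)
round(trophic_effect(res$representatives[[1]], ref), 4)
#>      A1      B1      A2      B2
#>  0.1035 -0.1340 -0.1340  0.1035
```

Consumer sinks (A1, B2) are under net top-down control (`E > 0`, lower
producer stocks); consumer sources (B1, A2) under net bottom-up control.
At the meta level this state carries higher primary production and
nutrient retention — and lower secondary production — than the
homogeneous equilibrium found at low `d_N`:

```r
meta_functions(res$representatives[[1]])
#>   primary_production secondary_production nutrient_retention    N        P         C
#> 1          0.8906231           0.02964267           97.65329 2.19 17.21961 0.1235111
```

Sweeps condense this into state diagrams; on a `d_N` transect at
`d_C = 0.4` the nested topology passes HOM_EQ → HOM_OSC → HET_OSC →
HET_EQ as resource flows increase, while the fully connected control
reaches heterogeneity only at distinctly higher `d_N` and never
stabilizes it:

```r
tr <- bifurcation_transect(sweep_spec("nested",
        d_N = seq(2, 3.5, by = 0.05), d_C = 0.4, n_ic = 10, seed = 1))
heterogeneity_threshold(tr)    # onset of spatial heterogeneity
state_threshold(tr, "HET_EQ")  # onset of the stabilized state
```

The long `t_transient` is not decorative: near the heterogeneity
threshold, symmetric transients decay on 1e5–1e6 time-unit scales, and
classifying too early mistakes transient asymmetry for a heterogeneous
attractor. See the methods vignette (`vignettes/metanest-methods.Rmd`)
for the full protocol and tolerance rationale.

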