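# actogel

Kinetic Flory–Stockmayer theory of actomyosin network gelation.

Actin networks switch between liquid-like (sol) and solid-like (gel)
behavior as actin-binding proteins — α-actinin crosslinkers (L), non-muscle
myosin II minifilaments (M, 22.5 myosin molecules per unit), and the
branching Arp2/3 complex (B) — connect the filaments. `actogel` is for
quantitative cell biologists and biophysical modelers who want to predict,
from concentrations and rate constants alone, *when* such a network
percolates, *which* species connect it, and *whether* the resulting gel is
rigid.

The package couples three layers:

1. **Mass-action kinetics.** Each F-actin monomer exposes a plus site
   *p*, a minus site *m*, and a binding site *c*. Five reversible reaction
   families (plus/minus-end polymerization, branching, linker and motor
   crosslinking) are integrated as a stiff ODE system with exact
   conservation of every species total.
2. **Connectivity percolation.** Concentration ratios give bond
   probabilities θ<sub>α→β</sub> = [α·β]/[α]<sub>T</sub>; a multi-type
   branching process on the loop-free (Bethe-lattice) cluster yields the
   fraction of monomers in finite clusters, P<sub>s</sub> =
   B<sub>p</sub>B<sub>m</sub>B<sub>c</sub>. A gel exists when
   P<sub>s</sub> < 1.
3. **Rigidity percolation.** Maxwell counting with per-bond constraint
   counts b ∈ [0, 6]: floppy modes per gel monomer
   f = 6 − ½ Σ b·θ·w with w = (1 − v<sub>α</sub>v<sub>β</sub>)/(1 − P<sub>s</sub>);
   f ≤ 0 marks a rigid gel.

A seedable Monte-Carlo branching-process oracle (`empirical_ps()`,
`empirical_maxwell()`) validates both analytic layers. The two-step
non-cooperative linker-binding equilibrium (`equilibrium_fractions()`)
explains the re-entrant sol at linker excess: two sol–gel transitions
along the linker axis.

## Worked example

```r
library(actogel)

comp <- abp_composition(G_total = 25, L_total = 0.05, M_total = 0.02,
                        n_seed = 0.1, len_seed = 10)   # uM
traj <- simulate_kinetics(initial_state(comp), default_rates(),
                          times = seq(0, 600, by = 2))
ps <- ps_timeseries(traj)
ps[c(1, 16, 301), ]
#> # A tibble: 3 x 3
#>    time    Ps gel
#>   <dbl> <dbl> <lgl>
#> 1     0 1     FALSE
#> 2    30 0.233 TRUE
#> 3   600 0.233 TRUE
```

The seeds polymerize, binding sites appear, and once enough crosslinks
form the network percolates: P<sub>s</sub> drops below 1 (here 23% of
monomers remain in finite clusters at steady state; with the shipped
literature-style default rates the transition happens within the first
couple of seconds — `gel_time(traj)` reports the bracketing grid
midpoint, 1 s on this grid).

```r
st  <- steady_state(initial_state(comp), default_rates())
th  <- bond_probabilities(st)
fit <- finite_cluster_probability(th)
glance(fit)
#> # A tibble: 1 x 4
#>      Ps gel   spectral_radius iterations
#>   <dbl> <lgl>           <dbl>      <int>
#> 1 0.233 TRUE             1.01        512
classify_regime(st)
#> [1] 3
```

Regime 3 means the linkers alone already connect the network (a
structural gel); regime 2 would mean motors are required (the contractile
regime), regime 1 a sol. With flexible α-actinin-like crosslinks the gel
is still (barely) floppy:

```r
glance(floppy_modes(th, fit, flexibility_map(b_cLc = 1)))
#> # A tibble: 1 x 4
#>         f rigid constraints    Ps
#>     <dbl> <lgl>       <dbl> <dbl>
#> 1 0.00790 FALSE        5.99 0.233
```

And the two-step linker equilibrium shows the crosslink maximum at
intermediate linker concentration (saturation by singly-bound linkers
destroys crosslinks at excess):

```r
argmax_linker(Fc_total = 25, K = 1)
#> # A tibble: 1 x 3
#>   L_star FcLFc_max crosslink_pairs_max
#>    <dbl>     <dbl>               <dbl>
#> 1   13.5      9.43               0.377
```

`autoplot()` methods draw trajectories, crosslink surfaces and regime
scans; `run_figure_workflow("fig5")` etc. write the standard analysis
grids as CSV. A thin command-line wrapper lives at
`inst/cli/actogel.R` (`simulate-kinetics`, `percolation-scan`,
`rigidity-scan`, `oracle-validate`, `figure`, ...), driven by YAML/JSON
configuration files.

Default rate constants are documented literature-style placeholders
(`?default_rates`); replication of a specific experimental system should
supply its own constants via the config. See the vignette
(`vignettes/actomyosin-gelation.Rmd`) for the model, its assumptions, and
every numerical policy.

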