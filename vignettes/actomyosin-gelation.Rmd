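---
title: "Kinetic gelation of actomyosin networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic gelation of actomyosin networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actogel)
```

## The problem

Actomyosin networks — actin filaments crosslinked by α-actinin, connected
and contracted by non-muscle myosin II minifilaments, and branched by the
Arp2/3 complex — switch between liquid-like (sol) and solid-like (gel)
behavior as their composition changes. `actogel` models this transition in
three coupled layers:

1. **Chemical kinetics.** A mass-action ODE system tracks the
   concentrations of free and bound species as filaments polymerize and
   actin-binding proteins (ABPs) attach.
2. **Connectivity percolation.** At any instant the bound/free
   concentration ratios define per-site bond probabilities; a generalized
   Flory–Stockmayer (multi-type branching process) calculation converts
   them into the fraction of actin monomers in finite clusters, $P_s$. A
   gel exists when $P_s < 1$.
3. **Rigidity percolation.** Maxwell constraint counting on the infinite
   cluster, with a per-bond-type flexibility $b \in [0,6]$, decides whether
   the gel is floppy or elastically stable.

A Monte-Carlo branching-process oracle validates the analytic layers.

## The kinetic model

Each F-actin monomer exposes three interfaces: a plus site $p$, a minus
site $m$, and an ABP binding site $c$. Five reaction families act on them
(concentrations in µM, time in s):

| reaction | stoichiometry |
|---|---|
| plus-end polymerization | $F_p + G \rightleftharpoons F_p\!\cdot\!F_m + F_p + F_c$ |
| minus-end polymerization | $F_m + G \rightleftharpoons F_p\!\cdot\!F_m + F_m + F_c$ |
| branching | $F_c + B + G \rightleftharpoons F_c\!\cdot\!B\!\cdot\!F_m + F_p + F_c$ |
| linker crosslinking | $F_c + L + F_c \rightleftharpoons F_c\!\cdot\!L\!\cdot\!F_c$ |
| motor crosslinking | $F_c + M + F_c \rightleftharpoons F_c\!\cdot\!M\!\cdot\!F_c$ |

Elongation keeps the end species constant (the end migrates to the new
terminal monomer) while adding one backbone bond and one fresh binding
site. Branching consumes a mother binding site, a brancher, and one
G-actin; the daughter monomer arrives with a free plus end and a free
binding site and an Arp2/3-capped minus end, so free minus ends are
conserved by every reaction — `d[Fm]/dt = 0` identically, a property the
tests assert.

Design choices worth stating explicitly:

* **Depolymerization rate law.** A literal mass-action reading of the
  reverse elongation step would be third order. We use the standard
  first-order-in-ends law, $k_p^- [F_p]$ and $k_m^- [F_m]$, reversing the
  forward stoichiometry. The reaction table is a stoichiometric statement,
  not a rate law, and first-order off-rates are how actin kinetics are
  universally parameterized.
* **Debranching** is first order in the junction concentration and
  restores G-actin, the free brancher, and the mother binding site while
  removing the daughter's plus end — the mean-field reverse of branching.
* **Termolecular crosslinking** uses the rate $k^+[L][F_c]^2$ with no
  additional symmetry factor. Conventions differ between sources; the
  constant absorbs the factor, and the two-step mode sidesteps the issue.
* **No length guard.** The mean-field model has no filament identity, so
  depolymerization is not prevented from acting on "length-one filaments";
  with seed filaments of length ≥ 2 and ordinary parameters this never
  manifests, but it is a documented limitation near full depolymerization.
* **Rate constants.** `default_rates()` ships literature-style placeholder
  values (barbed end 11.6 µM⁻¹s⁻¹ on / 1.4 s⁻¹ off, pointed end
  1.3/0.8, α-actinin-like linker 0.7 µM⁻²s⁻¹ on / 0.3 s⁻¹ off, motor
  0.2/0.017, brancher 0.1 µM⁻²s⁻¹ on / 10⁻³ s⁻¹ off). They define this
  package's default study conditions; quantitative replication of a
  specific experimental system requires an explicit configuration.

The integrator is `deSolve::lsoda` (stiff-capable) at `rtol = 1e-8`,
`atol = 1e-12`. Four linear conservation laws (total actin, linker, motor,
brancher) and three site-bookkeeping identities on the polymerized monomer
count have exactly zero analytic time derivative; along integrated
trajectories they hold to better than $10^{-8}$ relative (in practice
$\sim 10^{-15}$). `steady_state()` integrates over doubling horizons until
`max |dy/dt| · t / scale < 1e-9` and raises an error rather than returning
a non-plateau.

Default composition: 25 µM total actin with 0.1 µM of 10-mer seed
filaments as nucleators (1 µM of actin in seeds, giving a mean steady-state
filament length of ~250 monomers when branching is absent). Seeds are
needed because the model contains no spontaneous nucleation pathway.

## Two-step linker binding

The two-reaction scheme $F_c + L \rightleftharpoons F_c\!\cdot\!L$,
$F_c\!\cdot\!L + F_c \rightleftharpoons F_c\!\cdot\!L\!\cdot\!F_c$ with
association constants $K_1, K_2$ describes non-cooperative binding of the
two linker heads. `equilibrium_fractions()` reduces the two mass balances
to one strictly monotone scalar equation in the free-site concentration
(monotonicity is provable by differentiation) and bisects it, so the
returned root is unique and the balances are satisfied to $10^{-10}$
relative.

The crosslink concentration is unimodal in total linker: singly-bound
linkers saturate the sites at high $[L]_T$, so a system that gels on the
rising flank re-enters the sol at linker excess — two sol–gel transitions
along one axis. For chains of $N$ binding sites, `percolation_curve()`
places the transition where the per-site crosslink probability
$p = 2[F_c\!\cdot\!L\!\cdot\!F_c]/[F_c]_T$ crosses the classical
vulcanization threshold $p_c(N) = 1/(N-1)$.

**Head-counting convention.** With the default $K_1 = K_2 = K_c$ (the
literal two-reaction scheme, no head-multiplicity factors) the computed
maximum sits near $[L]_T \approx 0.54\,[F_c]_T$ at $K_c [F_c]_T = 25$,
not at $[L]_T = [F_c]_T$. Statistical-factor conventions (e.g. $2K, K/2$
for independent heads) shift the peak; because no single convention is
canonical, the package exposes $K_1$ and $K_2$ separately and always
reports the *computed* maximizer rather than hard-coding a claimed one.

## Connectivity percolation

Bond probabilities are site-occupancy fractions
$\theta_{\alpha\to\beta} = [\alpha\cdot\beta]/[\alpha]_T$, evaluated
per site class:

$$\theta_{p\to m} = \frac{[F_pF_m]}{[F_pF_m]+[F_p]},\qquad
  \theta_{m\to p} = \frac{[F_pF_m]}{[F_pF_m]+[F_cBF_m]+[F_m]},$$
$$\theta_{c\to c} = \frac{2[F_cLF_c]+2[F_cMF_c]}{D_c},\qquad
  \theta_{c\to m} = \frac{[F_cBF_m]}{D_c},\qquad
  \theta_{m\to c} = \frac{[F_cBF_m]}{[F_pF_m]+[F_cBF_m]+[F_m]},$$

with $D_c = 2[F_cLF_c]+2[F_cMF_c]+[F_cBF_m]+[F_c]+[F_cL]+[F_cM]$. Sites
with an empty class give $\theta = 0$. Under the `linker_only` edge set,
motor (and by default brancher) pairs are removed from numerators but kept
in denominators: an occupied site cannot form a different bond even if its
bond does not transmit connectivity.

On the loop-free Bethe lattice the cluster of a monomer is a multi-type
branching process. With $v_s$ the probability that the subtree entered
through a bond arriving at site $s$ is finite, and $B_s$ the probability
that site $s$ does not lead to an infinite branch,

$$B_p = 1-\theta_{pm}(1-v_m),\quad
  B_m = 1-\theta_{mp}(1-v_p)-\theta_{mc}(1-v_c),\quad
  B_c = 1-\theta_{cc}(1-v_c)-\theta_{cm}(1-v_m),$$
$$v_p = B_m B_c,\qquad v_m = B_p B_c,\qquad v_c = B_p B_m,$$

and $P_s = B_p B_m B_c$. Numerical policy:

* The spectral radius of the $3\times3$ Jacobian of the $v$-map at
  $v = 1$ decides criticality first: radius $< 1$ gives $P_s = 1$ exactly
  (this also makes threshold bisections crisp). The boundary case falls
  through to iteration because a deterministic bond structure (e.g.
  $\theta_{pm}=\theta_{mp}=1$ chains) is infinite at radius exactly 1.
* Otherwise the smallest fixed point is reached by monotone iteration
  from $v = 0$ (tolerance $10^{-12}$), with a damped-Newton polish every
  512 sweeps because plain iteration slows to a crawl near the threshold;
  a Newton result is accepted only if its local Jacobian radius is ≤ 1,
  which rejects the spurious all-ones root.
* The gel flag is $P_s < 1 - 10^{-9}$.

`gel_boundary()` bisects the gel predicate along scan lines in
log-concentration (relative tolerance $10^{-3}$); `classify_regime()`
labels steady states sol (1), gel only with motor connections (2), or gel
by linkers alone (3). Because linker-only edges are a subset of all edges,
regime 3 implies gel under the full edge set, and the three regions are
ordered along both composition axes.

## Rigidity percolation

Within the infinite cluster, floppy modes per monomer are counted as

$$f = 6 - \tfrac12 \sum_{\alpha\to\beta} b_{\alpha\to\beta}\,
        \theta_{\alpha\to\beta}\, w_{\alpha\to\beta},\qquad
  w_{\alpha\to\beta} = \frac{1 - v_\alpha v_\beta}{1-P_s},$$

summing over directed bond types as seen from one monomer, with the
$c\to c$ term split into linker and motor contributions so that each can
carry its own $b$. The weight $w$ is the exact conditional probability
that a bond at that site exists *and* connects into the infinite cluster,
given that the monomer is in the infinite cluster: the joint event has
probability $\theta(1 - v_\alpha v_\beta)$, since the cluster stays finite
only if the subtree across the bond ($v_\beta$) and the branches through
the monomer's other two sites ($\prod_{\gamma\ne\alpha} B_\gamma =
v_\alpha$) are all finite. Two consequences pin the form down: $w \to 1$
deep in the gel, and with all $b = 6$ the $f = 0$ crossing lands exactly
on the connectivity threshold (a tree of $n$ monomers has $n-1$ bonds, so
constraints per monomer approach six exactly at the threshold — the
symmetric case gives $w \to 4/3$ and $f \to 6 - 9\cdot\tfrac12\cdot
\tfrac43 = 0$). The Monte-Carlo oracle confirms it to within Monte-Carlo
error on arbitrary mixed-flexibility draws.

Sol-phase calls are domain errors rather than silently returning $f = 6$:
the count is defined per infinite-cluster monomer. `rigidity_boundary()`
bisects on "gel and $f \le 0$"; softer crosslinks ($b_{cLc} < 6$) move the
boundary to strictly higher linker concentrations. Per-bond flexibility is
a scalar constraint count; decomposing *which* degrees of freedom a bond
removes is out of scope, as is pebble-game rigidity on loopy networks.

## The Monte-Carlo oracle

`sample_branching_cluster()` grows clusters site by site with exactly the
theory's branching rule (fresh neighbor per bond, no loops), so it
validates the fixed-point algebra rather than the Bethe-lattice
assumption itself. `empirical_ps()` reports the finite fraction of
`n_roots` clusters with a binomial standard error; clusters exceeding the
size cap count as infinite, making the estimate a one-sided overestimate
of finiteness whose magnitude is tracked by a reported tail proxy
(fraction of finite clusters above a tenth of the cap).

For the Maxwell count, note that a truncated tree always has $n-1$ edges,
so a naive whole-cluster edge count converges to $6 - \bar b$, dominated
by unexpanded frontier monomers. `empirical_maxwell()` instead uses only
the root of each cluster that exceeds the cap: such a root is distributed
exactly as a uniformly chosen gel monomer, so
$\hat f = 6 - \tfrac12\,\overline{\sum_{\text{root bonds}} b}$ is an
unbiased estimate (up to the one-sided cap bias) with a clean standard
error. Samplers are driven by R's RNG; a `seed` argument gives
bit-for-bit reproducibility and is recorded in every output.

## What the built-in conditions do and do not show

The default composition, rate set, and scan grids emulate a
well-mixed, spatially homogeneous, infinite system: no diffusion limits,
no filament bundling, no mechanochemical feedback, no closed loops, no
cooperative linker binding, and no explicit filament length distribution
(mean-field species only). Tests passing under these conditions validate
the internal consistency of the kinetics–percolation–rigidity pipeline
and its agreement with exact small cases and the tree-exact oracle; they
do not by themselves validate the mean-field assumptions against spatially
resolved simulation or experiment. In particular, boundary locations in
µM depend on the placeholder rate constants and shift when real ones are
supplied.

Problem sizes used by the shipped analyses (chosen as comfortable
desk-scale settings): oracle comparisons use $10^5$ roots with caps of
$10^4$–$10^5$ monomers; boundary traces use 9-point log grids per line
with $10^{-3}$ relative bisection; phase-diagram scans use $7\times7$ to
$9\times9$ log grids over $10^{-4}$–$10$ µM.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from a fresh
session against the installed package: the classical symmetric gel
threshold (bisection, expected $1/2$), the hand-solvable symmetric
$P_s = 1/27$, oracle agreement fractions for $P_s$ and for the Maxwell
count, the worst conservation error along full-model trajectories, the
maximum relative gap between rigid-bond rigidity and connectivity
boundaries, the rigidity-boundary ordering fraction across $b_{cLc}$, the
number and ordering consistency of regimes in the (linker, motor) scan,
the brancher threshold ratio and high-brancher gel fraction, and the
two-step crosslink peak location and saturation tail.
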