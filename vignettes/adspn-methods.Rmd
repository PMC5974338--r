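---
title: "Methods: extended stochastic Petri nets for Alzheimer's disease pathway models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extended stochastic Petri nets for Alzheimer's disease pathway models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adspn)
```

## The formalism

A stochastic Petri net here is a bipartite graph of places (species with
integer token counts) and transitions (reactions) with four arc kinds.
Relative to the arc weight $w$ and the pre-place count $m(p)$, a standard
arc enables at $m \ge w$ and consumes $w$ tokens on firing; read ($m \ge
w$), inhibitor ($m < w$) and equal ($m = w$) arcs gate enabling without
ever consuming. Each transition $T_i$ carries a rate $\mu_i$; its delay is
exponential, so the marking process is a homogeneous continuous-time Markov
chain (CTMC) on the reachability graph, and the simulator (`simulate()`,
`spn_ensemble()`) samples it exactly with Gillespie's direct method:
total propensity $\Lambda$, waiting time $\sim \mathrm{Exp}(\Lambda)$,
winner chosen with probability proportional to its propensity. Delays are
implicitly resampled after every jump, which is exact because exponentials
are memoryless. A state with $\Lambda = 0$ is a deadlock and is recorded as
such. Rate 0 means "permanently disabled" and is how interventions switch
reactions off.

### Hazard semantics

Two propensity semantics are implemented. Under `constant_hazard` an
enabled transition fires at its bare rate $\mu_i$, exactly as the
exponential-delay definition reads. Under `mass_action` the hazard is
$\mu_i \prod_p \binom{m(p)}{w_{p}}$ over standard input arcs — the
combinatorial counting used by stochastic biochemical simulators; read,
inhibitor and equal arcs never scale a propensity in either semantics.
`constant_hazard` is the package default for generic nets. The shipped
disease bundles, however, declare `mass_action` as part of their study
conditions, and this is a deliberate design decision: with the published
rate table (oligomerization at $\mu = 0.005$, plaque deposition at $\mu =
0.02$) a constant-hazard race cannot produce a plaque lag phase shorter
than $1/0.005 + 1/0.02 = 250$ time units, whereas the documented lag is
60–80 units. Under mass-action hazards the lag emerges naturally: the
oligomerization propensity $0.005\binom{m_{A\beta}}{4}$ is negligible
until free amyloid-beta accumulates, then accelerates. The biochemical
SPN tools this class of models is built in likewise simulate
marking-dependent mass-action hazards.

### Reproducibility

All randomness flows through R's RNG, also inside the C++ kernel, so a
seed fixes the event sequence bitwise. Ensemble run $i$ uses seed
`base_seed + i`; any run is reproducible standalone from its own seed.

## The CTMC oracle

`reachability_graph()` explores markings breadth-first; successors with any
count above a per-place cap (default 8 for oracle work) are redirected to a
single absorbing overflow state, so truncated probability mass is tracked,
never dropped; a hard state-count limit (default $2\times10^5$) aborts with
a diagnostic. `transient_distribution()` solves the master equation by
uniformization: $p(t) = \sum_k \mathrm{Pois}(k; qt)\, p_0 P^k$ with $P = I
+ Q/q$, truncating when the remaining Poisson tail is below $10^{-9}$ and
halving the horizon recursively whenever $qt > 400$ so the weights never
underflow. `stationary_distribution()` solves global balance directly and
refuses reducible chains (checked by forward/backward reachability). The
oracle is deliberately an independent code path from the simulator — dense
linear algebra on the explicit state space versus event sampling — so the
test suite can compare the two as implementation versus oracle.

## Place invariants

`p_invariants()` computes minimal-support non-negative integer left null
vectors of the incidence matrix by Farkas-style column elimination
(positive/negative row combination, gcd normalization, duplicate removal,
minimal-support filtering at the end), with a cap (default 20000) on
intermediate rows. On the crosstalk net this recovers the expected
conservation laws — the Calpain pool (pCalp + mC + CLP + cC), the CAST pool
(all six forms plus degraded fragments), total calcium including
pump-loaded and PKC-bound tokens, sodium with the 3-token pump load,
potassium, and every receptor/enzyme cycle — and the suite asserts
$y^\top m$ constant along simulated trajectories of every shipped model.

## The disease models and their calibration

Transition rates are the published parameter tables, used verbatim; the
test suite asserts every table entry against the bundles. Three aspects of
the encodings are necessarily the package's own, and each element carries a
provenance note (`stated`, `inferred` or `calibrated`) in
`ad_model(...)$notes`:

* **Arc topology.** The pathway descriptions name the places and assign
  transition ranges to channels, but do not print complete arc lists.
  Reconstructed arcs follow the prose (e.g. NCX extrudes one calcium ion
  while admitting three sodium ions — a weight-3 arc pair; the
  membrane complex mC breaks into CLP + cCT when cytosolic calcium rises —
  a read arc from Ca_In). Where the prose is silent, the minimal
  biologically standard mechanism was chosen and marked `inferred`:
  receptor/enzyme cycles get explicit deactivation transitions, the
  gamma-secretase pool turns over (g1/g2), phosphatases recycle (c14).
* **Initial markings.** No initial marking is published anywhere, so the
  shipped defaults are calibrated: a large extracellular calcium pool
  (80) against a small cytosolic one (2), an ATP pool of 40 balanced
  against pump consumption, Calpain predominantly pre-bound in the
  membrane complex (mC = 8, as the resting description has it), zero
  plaques and oligomers, and a basal free amyloid-beta pool of 6 monomers
  (healthy neurons secrete amyloid-beta constitutively). Calibration
  targeted the documented qualitative behaviours — calcium homeostasis in
  the standalone channel model, the 60–80 unit plaque lag, sAPPa
  dominance in health and its reversal under crosstalk, dysregulation
  onset after 60 units — and the acceptance suite re-measures all of them
  from these defaults.
* **Unprinted thresholds.** Two couplings are described only
  qualitatively. Amyloid-beta "inhibits the Energy transition": encoded as
  an inhibitor arc whose weight (default 6) is calibrated so ATP
  starvation sets in during the simulated disease course — under
  mass-action buffering free amyloid-beta plateaus near 6–8 monomers, so
  a much larger threshold would never trigger. Oligomer membrane pores:
  a read arc of weight 5 (`pore_threshold`) gating direct
  extracellular-to-cytosolic calcium flow. Oligomer and plaque
  stoichiometries are `n_oligo = n_plaq = 4` by default, configurable,
  since only "gathers into large quantity" is stated.

Two further design decisions deserve note. First, the Calpain-CAST table
prints c4 = 0.02 / c5 = 0.5, while the crosstalk table prints c4 = 0.5 /
c5 = 0.02, the narrative calls c5 "a very low rate", and the intervention
experiment perturbs c5 downward to 0.005; the bundles therefore adopt
c4 = 0.5, c5 = 0.02 in both models (`raw_table_rates = TRUE` restores the
unswapped pair). Second, the Calpain-to-BACE "two-fold" enhancement is one
extra transition `b2`, gated by read arcs from CLP and BACE, producing
sAPPb + CTF99 at the baseline `b` rate of 0.3 — i.e. the additional APP
routed through the amyloidogenic pathway. Duplicating only the cleavage
step would not double the product flux (it is supply-limited), so the
lumped form is the faithful encoding of "twice than normal".

## Fixtures: what they emulate and what they do not

The fixture generator (`spn_fixture()`) provides nets with known behaviour:
a Poisson source (counts exactly Poisson), a capped birth–death queue
(geometric stationary law under constant hazards), a two-state toggle
(closed-form occupancy), an enzyme–substrate motif E + S ⇌ ES → E + P
(rates 1 / 0.5 / 1 are package defaults — the reference example describes
the motif without printing parameters), the receptor–ligand binding net,
and seeded random conservative nets (every transition consumes and
produces equal total weight, so total token count is conserved and the
oracle cap never binds; about 10% of transitions get an extra inhibitor or
read arc). These exercise every engine feature against closed forms or the
oracle, but they are small and conservative by construction: passing them
shows the engine is exact, not that the disease models are biologically
validated — the models' own support is the qualitative agreement of their
ensemble behaviour with the documented trajectories, under calibrated
initial conditions.

## Metrics

"Accumulation starts" is operationalized as first passage of a place to a
token threshold (default 1), aggregated over the ensemble
(`onset_time()`); on grid-recorded runs passages resolve to the next grid
point. `dominance_ratio()` is the ratio of window-averaged ensemble means
(window [20, 200] in the shipped analyses, past the initial transient).
Calcium dysregulation onset is the first grid time at which the ensemble
mean of Ca_In reaches that of Ca_Out — a package definition, stated in the
output, since the sources describe the event only visually on averaged
traces; grid means (default `grid_dt = 0.5`) rather than single runs match
the averaged plotting of those traces. Oscillation metrics use a burn-in
(default 10 units) and call a dominant period only when an autocorrelation
peak clears the white-noise floor $2/\sqrt{n}$. `depletion_fraction()`
reports degraded-to-total pool shares and flags monotonicity.

## Problem sizes and numerical tolerances

The shipped analyses use ensembles of 100 runs over 200 time units on a
0.5-unit grid (the documented horizon), 1000-run ensembles for
engine-versus-oracle and Poisson-law checks at 3 Monte-Carlo standard
errors, oracle tolerance $10^{-9}$ with total-variation convergence checks
at $10^{-6}$, and 20 random conservative nets per oracle sweep. The whole
suite, including these, runs in well under a minute on one CPU; the C++
direct-method kernel makes individual crosstalk ensembles sub-second.

## Known limitations

Model time is dimensionless "unit time"; any mapping to patient age is
interpretive documentation, never computed with. The crosstalk net is
open (APP synthesis sources, plaque sinks), so the oracle cannot be run on
it — oracle validation lives on the bounded fixtures. The equal-arc
reading "may fire when counts equal the weight" is implemented as a pure
enabling condition symmetric with read/inhibitor arcs; no alternative
interpretation is provided. Tau pathology, coloured/hierarchical nets,
timed-deterministic semantics, tau-leaping and parameter fitting to
kinetic data are out of scope.
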