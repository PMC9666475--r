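---
title: "Socio-spatial analysis of within-nest tracking data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Socio-spatial analysis of within-nest tracking data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestnet)
```

## The problem

Social-insect colonies divide their nest into partially overlapping task
zones: nurses aggregate on the brood, foragers near the entrance,
patrollers along the walls. Automated tracking yields per-frame positions
(typically 2 frames per second) for every individually tagged worker, and
the analytical question is twofold: (i) how to *describe* the colony's
socio-spatial organisation objectively — who shares space with whom, and
where — and (ii) which individual *movement rules* are sufficient to
maintain that organisation. `nestnet` implements both halves: a
bipartite-network description of spatial organisation, and a
correlated-random-walk (CRW) agent simulator whose pluggable mechanisms
generate synthetic colonies with known ground truth, so the whole
pipeline can be validated by planted-structure recovery.

## From trajectories to a site-visit network

The nest interior is discretised into a pointy-top hexagonal lattice
whose flat-to-flat width defaults to one quarter of the mean worker body
length, so that spatial resolution scales across species from millimetre
ants to centimetre bees. Orientation of the lattice and its origin (the
lower-left corner of the nest bounding box) are fixed conventions;
coordinates are millimetres, x rightward, y upward, angles in
\[-&pi;, &pi;) with 0 along +x. Two-sided combs are modelled as two site
layers sharing x/y geometry; a side switch is a site change. Hexagons are
the Voronoi cells of their centres, so point location reduces to
nearest-centre search (cube-rounding plus a 7-candidate check in
compiled code); boundary-straddling hexagons whose centres fall inside
the nest are included whole, and exact ties resolve to the lowest site
id.

A visit to a site opens when a worker's fix enters it and closes on
exit, regardless of duration. To stop a worker parked on a border from
accumulating single-frame visits, a re-entry within 20 s of the previous
exit extends that visit instead of opening a new one; tracking gaps
longer than the window close the visit. The visit counts
\(n_i^s\) weight the edges of an undirected bipartite network linking
workers to sites. Isolated nodes are dropped before partitioning.

## Modules, fuzzy scores and labelling

Community structure is scored by weighted bipartite (Barber) modularity

\[ Q = \frac{1}{F}\sum_{i,s}\Big(A_{is} - \frac{k_i d_s}{F}\Big)\,
\delta(g_i, g_s), \]

with \(A\) the weight matrix, \(F\) its total, \(k_i, d_s\) the margins.
The optimiser is a stochastic label-propagation algorithm for weighted
bipartite networks: workers start with unique (or randomised) labels,
workers and sites alternately adopt the label with the largest marginal
modularity gain (ties broken uniformly at random from the seeded
stream), and converged partitions are refined by agglomerative merging
of module pairs while \(Q\) improves, under repeated randomised restarts
(default 20). The number of modules is an output, not an input. On small
networks the implementation is routinely checked against exhaustive
search over worker set-partitions with optimal site assignment.

Because the optimiser is stochastic, it is applied many times (default
1000) to form a partition ensemble. Each partition's modules are then
labelled by fixed geometric rules: the module whose sites lie on average
closest to the entrance is the forager module; the module(s) overlapping
the brood outline most (fraction of member-site centres inside the brood
polygon — "greatest spatial overlap" needs an operationalisation, and
site-centre counting is the unbiased discrete version) are nurse
module(s), two being allowed on two-sided combs where a separate
broodnest sits on each face; one leftover module is peripheral; with two
leftovers the one nearer the walls (mean distance of member sites to the
boundary polygon) is peripheral and the other intermediate; any further
modules — in practice tiny — are left unclassified for that iteration.
A node's *module score* for label \(M\) is the proportion of iterations
assigning it to an \(M\)-labelled module; iterations where the node fell
in an unclassified module leave that node's denominator. Two readings of
the ensemble are possible — proportions over all iterations, or over
unique partitions only — and both are implemented
(`unique_partitions`); proportions over all iterations are the default
because they weight partitions by how often the optimiser finds them.
The two nurse modules of a two-sided nest are matched across iterations
by broodnest side. Scores sum to 1 per node; the argmax defines the
primary module; workers (sites) with exactly one nonzero score are
specialists (non-overlapping sites).

## Mixing statistics

Typical profiles are visit- (or contact-) weighted means of score
vectors: the typical visitor of a site, the typical site of a worker,
the typical contacted nestmate. Mixing is the normalised Shannon entropy
\(D = H/H_{\max}\) of such a profile (natural logarithms; \(0\log 0 :=
0\)), ranging from 0 (single-module specialists only) to 1 (uniform
mix). \(H_{\max}\) uses the number of labelled module categories present
for that colony, so three-module colonies are normalised by \(\log 3\).
Worker-site affinity is the cosine similarity of score vectors, in
\[0, 1\] for nonnegative scores. Sites visited once are included in
visitor diversity by default; a minimum-visit filter is a matter of
downstream subsetting, not of the statistic.

## Movement statistics

Activity segmentation decomposes each trajectory into alternating
active/inactive bouts: penalised binary segmentation (mean-shift model,
penalty `penalty_mult` &times; variance &times; log n, minimum segment
4 frames) on the per-frame displacement series, followed by two-cluster
thresholding of segment mean speeds. Clustering is done on a log scale
so the split falls between the resting mode near zero and the moving
modes, not between slow- and fast-moving regimes, and an inactive
cluster is only accepted if its mean speed is under 20% of the moving
cluster's — otherwise the trajectory is homogeneous and forms a single
bout. These two free parameters (penalty multiplier, minimum segment)
are exposed; the defaults recover square-wave speed profiles to within
two frames.

Per worker-site pair, `P` is the proportion of time active (all fixes),
while mean speed `v` (body lengths per second) and mean unsigned turn
angle `θ` use active fixes only, so they measure properties of movement
rather than the probability of moving. First-passage times (time to
leave a circle of given radius centred on the current fix, censored at
trajectory end) support the task rules: guarding (within 2 BL of the
entrance, facing it within &pi;/2, first-passage time beyond 2 BL above
500 s), patrolling (active, first-passage time beyond 4 BL under
5 min), queen attendance (queen inside a parameterised front-of-body
trapezoid and faced within &pi;/2 — trapezoid length and widths are
config parameters since no canonical dimensions exist), and foraging
(fix outside the nest polygon). Task totals and bout counts are
normalised by the worker's fix count.

The taxis index measures long-range attraction: per worker, site and
focal module (for sites outside the module), it is the projection of the
mean resultant of unit headings of segments starting at the site onto
the unit vector toward the nearest boundary-site centre of the module,
hence always in \[-1, 1\]. "Segments" are single frame-pair
displacements, the finest consistent reading. The boundary of a fuzzy
module is operationalised through primary modules: boundary sites are
sites of the module adjacent to sites with a different primary module.
Resident/non-resident contrasts are permutation-tested within
1-BL distance bins with Benjamini-Hochberg correction across bins.

## Gradient fields and boundary-relative turning

Module score landscapes are differentiated by local least-squares
planes: for each site, scores of all sites within one body length
(inclusive, unweighted — no weighting scheme is canonical and the
uniform choice is testable) are regressed on their centre coordinates;
the coefficient vector \(g = (a, b)\) points up the steepest score
increase and its magnitude is the transition steepness. Uniform or
degenerate neighbourhoods give magnitude 0 with undefined direction.
Headings with a positive dot product with \(g\) are up-gradient;
exactly perpendicular headings count as down-gradient (a measure-zero
tie that must be fixed deterministically). Relative turn angles subtract
the pooled all-worker mean turn at the same site and heading class from
the individual's mean, separately down- and up-gradient in the
individual's primary-module field; positive down-gradient values mean a
resident turns harder than average when about to leave its module.
Steepness effects are summarised in equal-count quantile bins (default
5) of \(|g|\) with sign-flip permutation intervals.

## The agent-based simulator

Agents perform independent CRWs at the 2 fps frame cadence inside an
axis-aligned rectangular nest with specular wall reflection: each step
draws a wrapped-normal turn (spread `sigma`) and an exponential length
(mean `lambda`, body lengths), and is traversed at constant speed
length/`tau` over as many frames as needed, so logged fixes resemble
empirical data, including within-step straight runs. Because a step's
speed is its length over a fixed traversal time, contexts with shorter
steps are automatically slower — the single lever the locomotion
adjustment mechanism needs. Activity alternates through a two-state
Markov switch with a fixed mean active bout (60 s) and a stationary
activity probability `pact`; the inactive state does not move. This
activity extension is switchable (`pact = 1` disables it) and exists
because activity probability is one of the three diffusivity statistics
the pipeline measures.

The three mechanisms modify this base walk:

* **Focal-point attraction (FPA, global):** outside its primary module
  an agent's step direction becomes the direction of
  \((1-w)\,\vec v_{CRW} + w\,\vec v_{bias}\), with \(\vec v_{bias}\) the
  unit vector to the nearest primary-module boundary point. `w = 0`
  reduces exactly to the CRW.
* **Locomotion adjustment (LA, local):** `lambda`, `sigma` and `pact`
  switch between inside values (short, tortuous, inactive) and outside
  values (long, straight, active) according to whether the current
  site's primary module matches the agent's.
* **Boundary effect (BE, local):** within a trigger distance (default
  2 BL) of the primary-module boundary, the drawn turn's magnitude is
  increased by `sigma_be` when the current heading points down the
  module's score gradient (leaving) and decreased, floored at zero,
  when pointing up it (entering). `sigma_be = 0` reduces to the CRW.

Simulation landscapes carry per-site module scores summing to 1; the
built-in two-module landscape uses a logistic "distance score" in the
distance to the nest centre, and the planted four-zone landscape places
a nurse zone on a circular brood pile, a forager zone at the entrance,
a wall-following peripheral ring and an intermediate ring between them,
mirroring empirical module maps. Gradients and nearest-boundary targets
are precomputed per site from the same functions the analysis pipeline
uses.

### Default parameters

Defaults are chosen once as plausible study conditions for a 4-mm ant in
a 70 &times; 40 mm nest and are not tuned per experiment: base
`lambda` 1 BL, `sigma` 0.6 rad, `pact` 0.8, step time `tau` 1 s, mean
active bout 60 s; LA pairs 0.4/1.6 BL, 1.2/0.35 rad, 0.45/0.95 —
a strong inside/outside diffusivity contrast of the kind seen in
empirical activity/speed/turn maps; FPA weight 0.3; BE modulation
1.0 rad with a 2 BL trigger. The default planted colony has 60 workers
(22 N, 9 I, 9 P, 20 F — nurses and foragers in the majority), runs 12
simulated hours, and switches LA and BE on, the combination that
suffices for full spatial segregation.

## Validation strategy and problem sizes

Every operation with a closed form or an independent brute-force route
is tested against it: point location against exhaustive nearest-centre
search, modularity against a dense double-loop evaluation and the
optimiser against exhaustive set-partition search (&le;12-node
networks), the margin-preserving null (delegated to Patefield's
algorithm in `r2dtable`) against an event-shuffling oracle and exact
margin checks, entropy/cosine against hand values, kinematic statistics
against scripted trajectories, and the CRW against the wrapped-normal
resultant \(e^{-\sigma^2/2}\) and the exponential mean.

End-to-end validation is by planted recovery: simulated LA+BE colonies
at the default conditions are pushed through discretisation, visits,
network, a 50-run ensemble and labelling, and must recover a modal
module count of 4 with &ge;90% worker assignment accuracy across seeds.
Mechanism discrimination uses 32-worker, 3-hour colonies per mechanism
and a five-metric signature panel (long-range taxis;
P/v/&theta;-versus-similarity; direction &times; steepness turning),
with group-label permutation p-values: each mechanism must light up
only its own metrics, judged by sign, significance and relative effect
size. Ensemble sizes and durations in tests are deliberately smaller
than the 1000-run analysis defaults; they are the package's choice of
problem size for validation, and the recovery results are insensitive
to raising them.

## What the generator does and does not emulate

The simulator reproduces multi-worker 2 fps trajectories in a bounded
nest, group-specific occupancy produced by the stated movement
mechanisms, activity/inactivity bouts, and (via a proximity-and-facing
detector) contact events. It does not emulate tag loss beyond simple
missing-fix injection, agent-agent interactions or collisions, combs
with two faces, multi-chamber or three-dimensional nests, or
density-dependent behaviour. Passing planted-recovery tests therefore
shows the pipeline recovers structure generated by these mechanisms in
clean data; it does not by itself certify performance under heavy
tracking noise or interaction-driven organisation.

## Numerical choices and degenerate inputs

Exact ties in point location go to the lowest site id; heading exactly
perpendicular to a gradient counts as down-gradient; turn-angle means
need a minimum number of active turns (default 3) or report `NA`;
empty trajectories yield empty visit tables; a single-row or
single-column network is its own (unique) margin-preserving null; the
optimiser accepts moves only when \(Q\) improves beyond 1e-12, and a
returned partition's \(Q\) never falls below any intermediate one.
Per-stage seeds derive from the master seed through a multiplicative
congruential step, so every pipeline stage is reproducible from
(inputs, config, master seed) while local RNG use never disturbs the
caller's random stream.

One caveat the taxis statistics inherit from bounded nests: near a
reflecting wall the recorded headings of *any* walker are folded
inward, so even an isotropic walk shows apparent directional bias at
wall-adjacent sites. Isotropy nulls and taxis contrasts are therefore
evaluated away from the nest boundary (segments from sites within
two body lengths of a wall are excluded in the validation tests); the
same filter is advisable on empirical data, where thigmotaxis plays the
analogous role.

Task profiles report, per task, the total time and the number of bouts,
each normalised by the worker's total fix count; normalised time is
thus seconds per fix (at most one frame interval), which keeps workers
with different tracking coverage comparable.

## Known limitations

Fix-resolution visit detection misses sub-frame border crossings, an
unavoidable property of 2 fps data. The labelling rules assume a
brood outline and an entrance; colonies lacking either need the
corresponding labels interpreted with care. The simulator's rectangular
nest is a deliberate simplification — the analysis side accepts
arbitrary simple polygons. Statistical contrasts are permutation-based
group comparisons; they do not model worker identity or density as
random effects, so datasets with strong repeated-measures structure
should be summarised per colony before cross-colony inference.
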