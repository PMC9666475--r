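# nestnet

Socio-spatial network analysis and movement simulation for social-insect
nests.

Automated tracking of individually tagged ants and bees produces
per-frame positions for every worker in a colony. `nestnet` turns those
trajectories into a quantitative description of the colony's
socio-spatial organisation and asks which individual movement rules are
sufficient to maintain it:

* the nest floor is discretised into hexagonal sites (width = 1/4 of
  the worker body length) and each worker's visits to each site are
  counted under a 20 s re-entry rule;
* the visit counts define a **weighted bipartite site-visit network**
  (workers x sites), which is partitioned into spatial *modules* —
  a worker group plus the sites it favours — by maximising Barber's
  bipartite modularity

  Q = (1/F) &Sigma;<sub>i,s</sub> ( A<sub>is</sub> − k<sub>i</sub> d<sub>s</sub> / F ) &delta;(g<sub>i</sub>, g<sub>s</sub>)

  with a stochastic label-propagation optimiser (restarted label
  propagation plus agglomerative merging; the module count is not fixed
  a priori);
* repeating the stochastic optimiser (default 1000 runs) yields fuzzy
  per-node **module scores** — the proportion of runs assigning a node
  to the Nurse, Intermediate, Peripheral or Forager module, labelled by
  geometry (brood overlap, entrance distance, wall distance);
* the scores support mixing and movement statistics: entropy-based
  module-score diversity of visitors / visited sites / contact
  partners, worker-site cosine similarity, taxis indices toward module
  boundaries, module-score gradient fields from local spatial
  regression, and gradient-relative turning statistics;
* a **correlated-random-walk agent simulator** with three pluggable
  mechanisms — focal-point attraction, locomotion adjustment, boundary
  effect — generates synthetic colonies with planted ground truth, so
  the full pipeline is validated by recovering what was planted.

The package is aimed at behavioural ecologists analysing within-nest
tracking data (or any dense 2-D trajectory data with candidate home
ranges) and at modellers studying how local movement rules generate
collective spatial patterns.

## Worked example

Simulate a 24-worker colony with four planted groups (locomotion
adjustment + boundary effect on, two simulated hours) and run the
pipeline on it:

```r
library(nestnet)

spec <- planted_colony_spec(n_workers = c(N = 8, I = 4, P = 4, F = 8),
                            duration_s = 7200, seed = 42)
colony <- make_planted_colony(spec)

cfg <- pipeline_config(ensemble_size = 50, restarts = 2, seed = 42)
res <- run_colony_pipeline(colony$trajectories, colony$nest, cfg)
res
#> Colony pipeline run
#> Site-visit network: 24 workers x 3304 sites, 18347 edges, total weight 79578
#>   modal module count: 4 (100.0% of 50 runs)
#>   specialist workers: 1.00; non-overlapping sites: 1.00

head(round(res$scores$workers, 2), 4)
#>     N I P F
#> F01 0 0 0 1
#> F02 0 0 0 1
#> F03 0 0 0 1
#> F04 0 0 0 1
```

Every one of the 50 ensemble runs found four modules, and the forager
agents score 1 for the forager module: the ensemble is unanimous about
this colony. Checking recovery against the planted truth:

```r
seg <- segregation_metrics(colony$trajectories, colony$truth,
                           res$grid, res$scores)
seg$accuracy          # detected primary module vs planted group
#> [1] 1
round(seg$overlap, 2) # pairwise Bhattacharyya occupancy overlap
#>      F    I    N    P
#> F 1.00 0.03 0.04 0.06
#> I 0.03 1.00 0.05 0.09
#> N 0.04 0.05 1.00 0.10
#> P 0.06 0.09 0.10 1.00
```

All 24 workers are assigned to their planted group, and the four
groups occupy almost disjoint parts of the nest (off-diagonal overlaps
below 0.10): the two local mechanisms alone produce full spatial
segregation. `plot(res$scores, res$grid)` maps the primary module of
every site; `mechanism_signature_panel()` computes the five movement
metrics that discriminate the three candidate mechanisms.

See the vignette (`vignettes/nestnet-methods.Rmd`) for the models,
parameter conventions and design decisions.

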