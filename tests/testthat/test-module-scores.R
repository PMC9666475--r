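# build a bipartite_partition by assigning site groups from geometry
make_partition <- function(grid, nest, site_groups, worker_groups) {
  structure(list(
    workers = worker_groups,
    sites = site_groups,
    Q = 0.5, n_modules = max(c(site_groups, worker_groups))),
    class = "bipartite_partition")
}

# site group vector over a set of probe sites: forager near entrance,
# nurse on the brood, peripheral at walls, intermediate elsewhere
probe_sites <- function(grid, nest, k = 4) {
  ids <- seq_len(n_sites(grid))
  ctr <- site_centers(grid, ids)
  d_ent <- distance_to_feature(grid, nest, "entrance")
  d_br <- distance_to_feature(grid, nest, "brood")
  d_w <- distance_to_feature(grid, nest, "wall")
  g <- rep(NA_integer_, length(ids))
  g[d_ent < 2] <- 1L                       # forager candidates
  g[is.na(g) & d_br == 0] <- 2L            # nurse candidates
  if (k >= 3) g[is.na(g) & d_w < 0.5] <- 3L
  if (k >= 4) g[is.na(g)] <- 4L else g[is.na(g)] <- 3L
  sel <- unlist(lapply(seq_len(k), function(m) which(g == m)[1:40]))
  sel <- sel[!is.na(sel)]
  stats::setNames(g[sel], sel)
}

test_that("geometric labelling rules assign F, N, P, I as planted", {
  nest <- toy_nest(); grid <- toy_grid()
  sg <- probe_sites(grid, nest, 4)
  wg <- stats::setNames(rep(1:4, each = 3), paste0("w", 1:12))
  p <- make_partition(grid, nest, sg, wg)
  lab <- label_partition(p, grid, nest)
  expect_equal(lab, c("F", "N", "P", "I"))
})

test_that("three-module partitions get F, N, P and no intermediate", {
  nest <- toy_nest(); grid <- toy_grid()
  sg <- probe_sites(grid, nest, 3)
  wg <- stats::setNames(rep(1:3, each = 3), paste0("w", 1:9))
  lab <- label_partition(make_partition(grid, nest, sg, wg), grid, nest)
  expect_equal(lab, c("F", "N", "P"))
  expect_false("I" %in% lab)
})

test_that("supernumerary small modules are left unclassified", {
  nest <- toy_nest(); grid <- toy_grid()
  sg <- probe_sites(grid, nest, 4)
  # a 5th module: one interior site, one worker
  extra_site <- setdiff(which(
    distance_to_feature(grid, nest, "entrance") > 5 &
      distance_to_feature(grid, nest, "brood") > 2 &
      distance_to_feature(grid, nest, "wall") > 2), names(sg))[1]
  sg5 <- c(sg, stats::setNames(5L, extra_site))
  wg5 <- stats::setNames(c(rep(1:4, each = 3), 5L), paste0("w", 1:13))
  lab <- label_partition(make_partition(grid, nest, sg5, wg5), grid, nest)
  expect_equal(lab[1:4], c("F", "N", "P", "I"))
  expect_equal(lab[5], "U")
})

test_that("labelling needs a brood outline", {
  nest <- toy_nest(brood = FALSE); grid <- build_hex_grid(nest)
  sg <- stats::setNames(rep(1:2, each = 5), seq_len(10))
  wg <- stats::setNames(rep(1:2, each = 2), paste0("w", 1:4))
  expect_error(label_partition(make_partition(grid, nest, sg, wg),
                               grid, nest), "brood")
})

test_that("module scores are proportions over labelled iterations", {
  nest <- toy_nest(); grid <- toy_grid()
  sg <- probe_sites(grid, nest, 4)
  wg1 <- stats::setNames(c(1L, 2L, 3L, 4L), paste0("w", 1:4))
  wg2 <- wg1; wg2["w2"] <- 4L    # w2 flips N -> I in half the runs
  ens <- structure(list(partitions = list(
    make_partition(grid, nest, sg, wg1),
    make_partition(grid, nest, sg, wg2)),
    n_runs = 2L, seed = 1L), class = "partition_ensemble")
  sc <- compute_scores(ens, grid, nest)
  expect_true(all(abs(rowSums(sc$workers) - 1) < 1e-12))
  expect_equal(unname(sc$workers["w1", "F"]), 1)
  expect_equal(unname(sc$workers["w2", c("N", "I")]), c(0.5, 0.5))
  expect_equal(unname(sc$workers["w3", "P"]), 1)
  expect_equal(unname(primary_module(sc, "workers")["w1"]), "F")
})

test_that("scores are invariant to relabelling module indices", {
  nest <- toy_nest(); grid <- toy_grid()
  sg <- probe_sites(grid, nest, 4)
  wg <- stats::setNames(c(1L, 2L, 3L, 4L), paste0("w", 1:4))
  perm <- c(2L, 3L, 4L, 1L)
  ens1 <- structure(list(partitions = list(
    make_partition(grid, nest, sg, wg)), n_runs = 1L, seed = 1L),
    class = "partition_ensemble")
  ens2 <- structure(list(partitions = list(
    make_partition(grid, nest, stats::setNames(perm[sg], names(sg)),
                   stats::setNames(perm[wg], names(wg)))),
    n_runs = 1L, seed = 1L), class = "partition_ensemble")
  s1 <- compute_scores(ens1, grid, nest)
  s2 <- compute_scores(ens2, grid, nest)
  expect_equal(s1$workers, s2$workers)
  expect_equal(s1$sites, s2$sites)
})

test_that("unclassified iterations drop out of the denominator", {
  nest <- toy_nest(); grid <- toy_grid()
  sg <- probe_sites(grid, nest, 4)
  extra_site <- setdiff(which(
    distance_to_feature(grid, nest, "entrance") > 5 &
      distance_to_feature(grid, nest, "brood") > 2 &
      distance_to_feature(grid, nest, "wall") > 2), names(sg))[1]
  sg5 <- c(sg, stats::setNames(5L, extra_site))
  wg1 <- stats::setNames(c(1:4, 5L), paste0("w", 1:5))  # w5 unclassified
  wg2 <- stats::setNames(c(1:4, 1L), paste0("w", 1:5))  # w5 forager
  ens <- structure(list(partitions = list(
    make_partition(grid, nest, sg5, wg1),
    make_partition(grid, nest, sg5, wg2)),
    n_runs = 2L, seed = 1L), class = "partition_ensemble")
  sc <- compute_scores(ens, grid, nest)
  # w5: one U iteration excluded -> F score 1 over the counted iteration
  expect_equal(unname(sc$workers["w5", "F"]), 1)
  expect_equal(unname(sc$unclassified_workers["w5"]), 0.5)
})

test_that("specialist and non-overlap proportions match a direct scan", {
  sc <- structure(list(
    workers = rbind(w1 = c(N = 1, I = 0, P = 0, F = 0),
                    w2 = c(0.5, 0.5, 0, 0),
                    w3 = c(0, 0, 0, 1)),
    sites = rbind(`1` = c(N = 0.2, I = 0.4, P = 0.4, F = 0),
                  `2` = c(0, 0, 0, 1)),
    labels = c("N", "I", "P", "F")), class = "module_scores")
  sp <- summarize_specialists(sc)
  expect_equal(sp$specialist_workers, 2 / 3)
  expect_equal(sp$nonoverlapping_sites, 1 / 2)
  # brute-force scan oracle
  expect_equal(sp$specialist_workers,
               mean(apply(sc$workers, 1, function(r) sum(r > 0) == 1)))
})

test_that("nurse pooling sums N1 and N2 and preserves the simplex", {
  sc <- structure(list(
    workers = rbind(w1 = c(N1 = 0.4, N2 = 0.4, P = 0.2, F = 0)),
    sites = rbind(`1` = c(N1 = 0.1, N2 = 0.3, P = 0.1, F = 0.5)),
    labels = c("N1", "N2", "P", "F")), class = "module_scores")
  pooled <- pool_nurse_modules(sc)
  expect_equal(unname(pooled$workers["w1", c("N", "P")]), c(0.8, 0.2))
  expect_equal(rowSums(pooled$sites), c(`1` = 1))
  expect_false(any(c("N1", "N2") %in% pooled$labels))
  # pooling changes the specialist count for split nurses
  expect_warning(pool_nurse_modules(pooled), "fewer than two")
})

test_that("ensembles are reproducible and tabulate module counts", {
  net <- build_network(block_counts(k = 2, noise = 1L, seed = 14))
  e1 <- run_ensemble(net, n_runs = 5, seed = 9, restarts = 2)
  e2 <- run_ensemble(net, n_runs = 5, seed = 9, restarts = 2)
  expect_identical(lapply(e1$partitions, `[[`, "workers"),
                   lapply(e2$partitions, `[[`, "workers"))
  expect_equal(sum(module_count_table(e1)), 5L)
  sig <- partition_signatures(e1)
  expect_equal(length(sig), 5L)
})
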