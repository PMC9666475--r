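#' Pipeline configuration
#'
#' Stage parameters for [run_colony_pipeline()]. Defaults follow the
#' standard analysis conditions: hexagon width a quarter body length,
#' 20 s visit refractory window, a 1000-run partition ensemble, guard /
#' patrol first-passage thresholds of 500 s / 300 s, a 1-body-length
#' gradient neighbourhood, and Benjamini-Hochberg correction at 0.05.
#'
#' @param hex_width_factor hexagon width as a fraction of body length.
#' @param refractory_s visit re-entry window (s).
#' @param ensemble_size partition ensemble size.
#' @param restarts label-propagation restarts per ensemble run.
#' @param taxis_bin_bl taxis distance bin width (body lengths).
#' @param steepness_bins quantile bins for gradient steepness.
#' @param gradient_radius_bl gradient neighbourhood radius (body lengths).
#' @param n_perm permutations for contrasts.
#' @param bh_alpha significance level after BH correction.
#' @param seed master seed; stage seeds are derived from it by counter.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(hex_width_factor = 0.25, refractory_s = 20,
                            ensemble_size = 1000L, restarts = 20L,
                            taxis_bin_bl = 1, steepness_bins = 5L,
                            gradient_radius_bl = 1,
                            n_perm = 1000L, bh_alpha = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the socio-spatial analysis pipeline on one colony
#'
#' Chains the core stages: hexagonal discretisation, visit extraction,
#' bipartite network construction, stochastic partition ensemble,
#' functional module labelling, fuzzy module scores, and mixing
#' summaries. Movement statistics (activity segmentation, per-site
#' locomotion, gradient fields, relative turn angles, taxis tables) are
#' computed when `movement = TRUE`. Every stochastic stage derives its
#' seed from the config master seed, so a rerun with the same inputs and
#' config is identical.
#'
#' @param traj a [trajectories()] table.
#' @param nest a [nest_geometry()] (with brood outline for labelling).
#' @param config a [pipeline_config()].
#' @param contacts optional symmetric contact-count matrix.
#' @param two_nurse allow two nurse modules (default: two-sided nests).
#' @param movement also compute movement-level statistics (slower).
#' @return list of class `colony_pipeline` with stage outputs.
#' @export
run_colony_pipeline <- function(traj, nest, config = pipeline_config(),
                                contacts = NULL,
                                two_nurse = nest$sides == 2L,
                                movement = FALSE) {
  seed <- config$seed
  grid <- build_hex_grid(nest, width = config$hex_width_factor *
                           nest$body_length)
  events <- extract_visits(traj, grid, refractory = config$refractory_s)
  counts <- count_visits(events)
  network <- build_network(counts)
  ensemble <- run_ensemble(network, n_runs = config$ensemble_size,
                           seed = .derive_seed(seed, 11L),
                           restarts = config$restarts)
  scores <- compute_scores(ensemble, grid, nest, two_nurse = two_nurse)
  out <- list(
    grid = grid, events = events, network = network, ensemble = ensemble,
    scores = scores,
    module_counts = module_count_table(ensemble),
    specialists = summarize_specialists(scores),
    primary = primary_module(scores, "workers"),
    covariates = site_covariates(grid, nest, network, scores),
    visited_diversity = visited_diversity(network, scores),
    config = config)
  if (!is.null(contacts))
    out$contact_diversity <- contact_diversity(contacts, scores)
  if (movement) {
    out$activity <- segment_activity(traj)
    out$locomotion <- site_locomotion(out$activity, grid)
    site_sc <- scores$sites
    site_ids <- as.integer(rownames(site_sc))
    ok <- rowSums(is.na(site_sc)) == 0
    out$field <- fit_gradient_field(site_sc[ok, , drop = FALSE], grid,
                                    sites = site_ids[ok],
                                    radius_bl = config$gradient_radius_bl)
    prim_sites <- rep(NA_character_, n_sites(grid))
    prim_sites[site_ids] <- primary_module(scores, "sites")
    out$taxis <- taxis_table(traj, grid, prim_sites)
    out$relative_turns <- relative_turn_angles(
      out$activity, grid, out$field, out$primary)
  }
  class(out) <- "colony_pipeline"
  out
}

#' @export
print.colony_pipeline <- function(x, ...) {
  cat("Colony pipeline run\n")
  print(x$network)
  k <- x$module_counts
  cat(sprintf("  modal module count: %s (%.1f%% of %d runs)\n",
              names(k)[which.max(k)], 100 * max(k) / sum(k), sum(k)))
  cat(sprintf("  specialist workers: %.2f; non-overlapping sites: %.2f\n",
              x$specialists$specialist_workers,
              x$specialists$nonoverlapping_sites))
  invisible(x)
}

#' Two-group permutation contrast
#'
#' Difference of group means with a label-permutation two-sided p-value.
#' Families of contrasts are corrected with [stats::p.adjust()]
#' (method "BH") by the caller or via [contrast_family()].
#'
#' @param values numeric vector.
#' @param labels two-level grouping vector.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `diff` (mean of first level minus mean of second,
#'   by factor order), `p`.
#' @export
group_contrast <- function(values, labels, n_perm = 1000L, seed = 1L) {
  f <- factor(labels)
  if (nlevels(f) != 2) stop("group_contrast needs exactly two groups")
  ok <- !is.na(values) & !is.na(f)
  values <- values[ok]; f <- f[ok]
  obs <- mean(values[f == levels(f)[1]]) - mean(values[f == levels(f)[2]])
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs))
  perm <- vapply(seq_len(n_perm), function(i) {
    g <- sample(f)
    mean(values[g == levels(f)[1]]) - mean(values[g == levels(f)[2]])
  }, numeric(1))
  list(diff = obs, p = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1))
}

#' Family of permutation contrasts with BH correction
#'
#' @param family named list; each element a list with `values` and
#'   `labels` as in [group_contrast()].
#' @param n_perm,seed as in [group_contrast()].
#' @return data.frame with `contrast`, `diff`, `p`, `p_bh`.
#' @export
contrast_family <- function(family, n_perm = 1000L, seed = 1L) {
  res <- lapply(seq_along(family), function(i)
    group_contrast(family[[i]]$values, family[[i]]$labels, n_perm,
                   .derive_seed(seed, i)))
  out <- data.frame(contrast = names(family),
                    diff = vapply(res, `[[`, numeric(1), "diff"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Mechanism signature panel
#'
#' Computes the five movement metrics that discriminate the three
#' candidate movement mechanisms on a simulated colony with known
#' landscape and planted groups:
#' \enumerate{
#'   \item `taxis_long`: resident minus non-resident mean taxis index at
#'     sites at least `long_range_bl` body lengths outside the focal
#'     module (long-range attraction; positive only under focal-point
#'     attraction);
#'   \item `P_sim`, `v_sim`, `theta_sim`: correlation of the per
#'     (worker, site) activity probability, active speed and active turn
#'     angle with the worker-site cosine similarity (negative, negative
#'     and positive only under locomotion adjustment);
#'   \item `dtheta_steep`: difference between the slopes of the relative
#'     down- and up-gradient turn angles on field steepness (positive
#'     only under the boundary effect).
#' }
#' Significance comes from permuting the planted group labels across
#' workers and recomputing each metric.
#'
#' @param traj simulated [trajectories()].
#' @param simnest the [sim_nest()] the colony was simulated on.
#' @param groups named vector mapping worker id to planted module label.
#' @param long_range_bl long-range threshold (body lengths; default 5).
#' @param n_perm group-label permutations (default 199).
#' @param seed integer seed.
#' @return data.frame: `metric`, `effect`, `p`, `n`.
#' @export
mechanism_signature_panel <- function(traj, simnest, groups,
                                      long_range_bl = 5, n_perm = 199L,
                                      seed = 1L) {
  grid <- simnest$grid
  labels <- simnest$labels
  workers <- names(groups)
  gidx <- match(groups, labels)
  prim_sites <- labels[simnest$primary]
  site_sc <- simnest$scores
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs))
  perms <- lapply(seq_len(n_perm), function(i)
    stats::setNames(sample(gidx), workers))

  # -- metric 1: long-range taxis -------------------------------------
  full_map <- rep(NA_character_, n_sites(grid))
  full_map[seq_len(grid$n_base)] <- prim_sites
  tab <- taxis_table(traj, grid, full_map)
  tab <- tab[tab$dist_bl >= long_range_bl, , drop = FALSE]
  tmod <- match(tab$module, labels)
  widx <- match(as.character(tab$worker_id), workers)
  taxis_stat <- function(gi) {
    res <- gi[widx] == tmod
    if (sum(res) == 0 || sum(!res) == 0) return(NA_real_)
    mean(tab$taxis[res]) - mean(tab$taxis[!res])
  }
  e1 <- taxis_stat(gidx)
  p1 <- .perm_p(e1, vapply(perms, function(g)
    taxis_stat(g[workers]), numeric(1)))

  # -- metrics 2-4: locomotion vs worker-site similarity --------------
  activity <- segment_activity(traj)
  loco <- site_locomotion(activity, grid)
  loco <- loco[loco$site_id <= grid$n_base, , drop = FALSE]
  nrm <- sqrt(rowSums(site_sc^2))
  simAll <- site_sc / nrm            # cosine of one-hot worker vs site
  lw <- match(loco$worker_id, workers)
  sim_for <- function(gi) simAll[cbind(loco$site_id, gi[lw])]
  s_obs <- sim_for(gidx)
  cor_stat <- function(v, s) {
    ok <- !is.na(v) & !is.na(s)
    if (sum(ok) < 10 || stats::sd(v[ok]) == 0 || stats::sd(s[ok]) == 0)
      return(NA_real_)
    stats::cor(v[ok], s[ok])
  }
  eff <- numeric(3); pv <- numeric(3)
  vars <- list(loco$P, loco$v_bl_s, loco$theta_rad)
  for (k in 1:3) {
    eff[k] <- cor_stat(vars[[k]], s_obs)
    pv[k] <- .perm_p(eff[k], vapply(perms, function(g)
      cor_stat(vars[[k]], sim_for(g[workers])), numeric(1)))
  }

  # -- metric 5: direction x steepness in the gradient field ----------
  field <- fit_gradient_field(site_sc, grid, sites = seq_len(grid$n_base))
  rel <- relative_turn_angles(activity, grid, field, primary = NULL)
  slope_stat <- function(gi) {
    res <- gi[match(rel$worker_id, workers)] == match(rel$module, labels)
    d <- rel[res & rel$mag > 0, , drop = FALSE]
    bd <- .slope(d$mag[d$direction == "down"], d$dtheta[d$direction == "down"])
    bu <- .slope(d$mag[d$direction == "up"], d$dtheta[d$direction == "up"])
    bd - bu
  }
  e5 <- slope_stat(gidx)
  p5 <- .perm_p(e5, vapply(perms, function(g)
    slope_stat(g[workers]), numeric(1)))

  data.frame(
    metric = c("taxis_long", "P_sim", "v_sim", "theta_sim", "dtheta_steep"),
    effect = c(e1, eff, e5),
    p = c(p1, pv, p5),
    n = c(nrow(tab), rep(nrow(loco), 3), nrow(rel)))
}

.slope <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || stats::var(x[ok]) == 0) return(NA_real_)
  stats::cov(x[ok], y[ok]) / stats::var(x[ok])
}

.perm_p <- function(obs, perm) {
  perm <- perm[is.finite(perm)]
  if (!is.finite(obs) || length(perm) == 0) return(NA_real_)
  (1 + sum(abs(perm) >= abs(obs))) / (length(perm) + 1)
}
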