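#' Agent movement configuration
#'
#' Parameters of the correlated random walk (CRW) and its three optional
#' movement mechanisms. The base CRW draws a turn angle from a wrapped
#' normal with spread `sigma` and a step length from an exponential with
#' mean `lambda` body lengths; each step is traversed at constant speed
#' (length / `tau`) and logged at the 2 fps frame cadence. Agents
#' alternate active and inactive bouts via a two-state Markov switch with
#' stationary activity probability `pact` and mean active bout
#' `mean_active_bout` seconds.
#'
#' Mechanisms:
#' \itemize{
#'   \item focal-point attraction (`fpa`): outside its primary module, an
#'     agent's step direction becomes the direction of
#'     `(1 - w) v_CRW + w v_bias`, where `v_bias` is the unit vector
#'     toward the nearest point of its primary-module border.
#'   \item locomotion adjustment (`la`): `lambda`, `sigma` and `pact`
#'     switch between `*_in` values (inside the primary module: shorter
#'     steps, larger turns, less activity) and `*_out` values.
#'   \item boundary effect (`be`): within `be_trigger` body lengths of
#'     the primary-module border, the magnitude of the drawn turn angle
#'     is increased by `sigma_be` when heading down-gradient (leaving)
#'     and decreased (floored at 0) when heading up-gradient (entering).
#' }
#'
#' @param lambda mean step length (body lengths).
#' @param sigma wrapped-normal turn spread (radians).
#' @param pact stationary activity probability in [0, 1].
#' @param tau step traversal time (s).
#' @param mean_active_bout mean active bout duration (s).
#' @param fpa,la,be logical mechanism switches.
#' @param w focal-point attraction bias weight in [0, 1].
#' @param lambda_in,lambda_out,sigma_in,sigma_out,pact_in,pact_out
#'   locomotion-adjustment parameter pairs (defaults give a strong
#'   inside/outside diffusivity contrast when `la = TRUE`; ignored
#'   otherwise).
#' @param sigma_be boundary-effect turn modulation (radians).
#' @param be_trigger boundary-effect trigger distance (body lengths).
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(lambda = 1, sigma = 0.6, pact = 0.8,
                         tau = 1, mean_active_bout = 60,
                         fpa = FALSE, la = FALSE, be = FALSE,
                         w = 0.3,
                         lambda_in = 0.4, lambda_out = 1.6,
                         sigma_in = 1.2, sigma_out = 0.35,
                         pact_in = 0.45, pact_out = 0.95,
                         sigma_be = 1.0, be_trigger = 2) {
  stopifnot(lambda > 0, sigma >= 0, pact >= 0, pact <= 1,
            w >= 0, w <= 1, sigma_be >= 0, be_trigger >= 0, tau > 0)
  cfg <- list(lambda = lambda, sigma = sigma, pact = pact, tau = tau,
              mean_active_bout = mean_active_bout,
              fpa = fpa, la = la, be = be, w = w,
              lambda_in = lambda_in, lambda_out = lambda_out,
              sigma_in = sigma_in, sigma_out = sigma_out,
              pact_in = pact_in, pact_out = pact_out,
              sigma_be = sigma_be, be_trigger = be_trigger)
  if (!la) {
    cfg$lambda_in <- cfg$lambda_out <- lambda
    cfg$sigma_in <- cfg$sigma_out <- sigma
    cfg$pact_in <- cfg$pact_out <- pact
  }
  structure(cfg, class = "agent_config")
}

#' Simulation nest with planted module landscape
#'
#' Bundles a rectangular nest, its hexagonal grid, and a per-site module
#' score landscape (rows sum to 1) whose argmax defines the planted
#' primary module of every site.
#'
#' @param nest a [nest_geometry()] with an axis-aligned rectangular
#'   boundary.
#' @param grid the matching `hex_grid`.
#' @param scores numeric matrix, base sites x modules, rows summing to 1.
#' @return An object of class `sim_nest`.
#' @export
sim_nest <- function(nest, grid, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != grid$n_base)
    stop("one score row per base site required")
  if (any(abs(rowSums(scores) - 1) > 1e-8))
    stop("site module scores must sum to 1")
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("M", seq_len(ncol(scores)))
  structure(list(nest = nest, grid = grid, scores = scores,
                 labels = colnames(scores),
                 primary = max.col(scores, ties.method = "first")),
            class = "sim_nest")
}

#' @export
print.sim_nest <- function(x, ...) {
  cat(sprintf("Simulation nest: %d sites, modules: %s\n", x$grid$n_base,
              paste(sprintf("%s (%d)", x$labels,
                            tabulate(x$primary, length(x$labels))),
                    collapse = ", ")))
  invisible(x)
}

#' Rectangular nest geometry
#'
#' @param width_mm,height_mm internal nest dimensions (mm).
#' @param body_length worker body length (mm).
#' @param entrance entrance point; default middle of the right wall.
#' @param brood optional brood outline polygon.
#' @param sides number of comb faces.
#' @return a [nest_geometry()].
#' @export
rect_nest <- function(width_mm, height_mm, body_length,
                      entrance = c(width_mm, height_mm / 2),
                      brood = NULL, sides = 1L) {
  nest_geometry(rbind(c(0, 0), c(width_mm, 0), c(width_mm, height_mm),
                      c(0, height_mm)),
                entrance = entrance, body_length = body_length,
                brood = brood, sides = sides)
}

#' Two-module radial landscape
#'
#' A central and a peripheral spatial module on a rectangular nest: the
#' peripheral "distance score" increases logistically with each site's
#' distance to the nest centre and the central score is its complement.
#'
#' @param width_bl,height_bl nest dimensions in body lengths.
#' @param body_length body length (mm).
#' @param r0_bl logistic midpoint (body lengths from the nest centre);
#'   default 60% of the smaller half-dimension.
#' @param k_bl logistic width (body lengths).
#' @return a `sim_nest` with modules "central" and "peripheral".
#' @export
sim_nest_radial <- function(width_bl = 16, height_bl = 10, body_length = 4,
                            r0_bl = 0.3 * min(width_bl, height_bl),
                            k_bl = 1) {
  nest <- rect_nest(width_bl * body_length, height_bl * body_length,
                    body_length)
  grid <- build_hex_grid(nest)
  ctr <- site_centers(grid, seq_len(grid$n_base))
  cx <- width_bl * body_length / 2; cy <- height_bl * body_length / 2
  d <- sqrt((ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2) / body_length
  per <- 1 / (1 + exp(-(d - r0_bl) / k_bl))
  scores <- cbind(central = 1 - per, peripheral = per)
  sim_nest(nest, grid, scores)
}

# precompute per-module boundary targets and gradients for the stepper;
# only for the modules and mechanisms actually in use
.simnest_fields <- function(simnest, modules = seq_along(simnest$labels),
                            need_boundary = TRUE, need_gradient = TRUE) {
  grid <- simnest$grid
  K <- length(simnest$labels)
  nbx <- nby <- matrix(0, grid$n_base, K)
  dbnd <- matrix(Inf, grid$n_base, K)
  ctr <- site_centers(grid, seq_len(grid$n_base))
  if (need_boundary) for (m in modules) {
    bs <- module_boundary_sites(grid, simnest$primary, m)
    if (length(bs) == 0) next
    bctr <- site_centers(grid, bs)
    # chunked nearest-boundary search (vectorised over sites)
    step <- max(1L, floor(2e6 / length(bs)))
    for (lo in seq(1L, grid$n_base, by = step)) {
      hi <- min(lo + step - 1L, grid$n_base)
      d2 <- outer(ctr[lo:hi, 1], bctr[, 1], "-")^2 +
        outer(ctr[lo:hi, 2], bctr[, 2], "-")^2
      j <- max.col(-d2, ties.method = "first")
      nbx[lo:hi, m] <- bctr[j, 1]; nby[lo:hi, m] <- bctr[j, 2]
      dbnd[lo:hi, m] <- sqrt(d2[cbind(seq_len(hi - lo + 1L), j)])
    }
  }
  if (need_gradient) {
    field <- fit_gradient_field(simnest$scores, grid,
                                sites = seq_len(grid$n_base))
    gx <- field$gx; gy <- field$gy
  } else {
    gx <- gy <- matrix(0, grid$n_base, K)
  }
  list(nbx = nbx, nby = nby, dbnd = dbnd, gx = gx, gy = gy)
}

#' Simulate a colony of independent CRW agents
#'
#' Runs the agent stepper for every worker in a planted module landscape
#' and returns frame-level fixes in the standard trajectory format, so
#' simulated and empirical data are interchangeable throughout the
#' pipeline. Agents are independent (no collisions or interactions);
#' walls reflect specularly; the logged body orientation is the movement
#' heading.
#'
#' @param simnest a [sim_nest()].
#' @param groups named vector mapping worker id to primary-module label
#'   (a label of `simnest`, or `NA` for agents without a planted module).
#' @param config an [agent_config()], or a named list of configs keyed by
#'   module label (plus optionally an `"default"` entry).
#' @param duration_s simulated duration (s).
#' @param seed integer seed.
#' @param dt frame interval (s); default 0.5 (2 fps).
#' @param start "module" (start at a random site of the agent's primary
#'   module) or "uniform".
#' @return a [trajectories()] table.
#' @export
simulate_colony <- function(simnest, groups, config, duration_s,
                            seed = 1L, dt = 0.5,
                            start = c("module", "uniform")) {
  start <- match.arg(start)
  if (duration_s <= 0)
    return(trajectories(data.frame(worker_id = character(),
                                   time_s = numeric(), x_mm = numeric(),
                                   y_mm = numeric())))
  grid <- simnest$grid
  nest <- simnest$nest
  bb <- apply(nest$boundary, 2, range)
  if (nrow(nest$boundary) != 4 ||
      !all(nest$boundary[, 1] %in% bb[, 1]) ||
      !all(nest$boundary[, 2] %in% bb[, 2]))
    stop("the simulator requires an axis-aligned rectangular nest")
  n_frames <- as.integer(round(duration_s / dt))
  bl <- nest$body_length
  get_cfg <- function(m) {
    if (inherits(config, "agent_config")) return(config)
    if (!is.na(m) && !is.null(config[[m]])) return(config[[m]])
    if (!is.null(config[["default"]])) return(config[["default"]])
    stop("no agent_config for module ", m)
  }
  # precompute boundary targets / gradients only where a mechanism uses them
  used <- unique(groups[!is.na(groups)])
  cfgs <- lapply(used, get_cfg)
  any_fpa <- any(vapply(cfgs, `[[`, logical(1), "fpa"))
  any_be <- any(vapply(cfgs, `[[`, logical(1), "be"))
  fields <- .simnest_fields(simnest, modules = match(used, simnest$labels),
                            need_boundary = any_fpa || any_be,
                            need_gradient = any_be)
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs))
  ctr <- site_centers(grid, seq_len(grid$n_base))
  out <- vector("list", length(groups))
  tvec <- (seq_len(n_frames) - 1) * dt
  for (a in seq_along(groups)) {
    m <- groups[a]
    mi <- if (is.na(m)) 0L else match(m, simnest$labels)
    if (!is.na(m) && is.na(mi)) stop("unknown module label: ", m)
    cfg <- get_cfg(if (is.na(m)) NA_character_ else m)
    if (start == "module" && !is.na(m)) {
      cand <- which(simnest$primary == mi)
      s0 <- if (length(cand) > 0) cand[sample.int(length(cand), 1)] else
        sample.int(grid$n_base, 1)
      x0 <- ctr[s0, 1] + stats::runif(1, -grid$width / 4, grid$width / 4)
      y0 <- ctr[s0, 2] + stats::runif(1, -grid$width / 4, grid$width / 4)
    } else {
      x0 <- stats::runif(1, bb[1, 1], bb[2, 1])
      y0 <- stats::runif(1, bb[1, 2], bb[2, 2])
    }
    h0 <- stats::runif(1, -pi, pi)
    midx <- if (mi > 0) mi else 1L
    tr <- abm_agent_cpp(
      n_frames, dt, x0, y0, h0,
      bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2],
      grid$origin[1], grid$origin[2], grid$size, grid$lookup,
      as.integer(simnest$primary), as.integer(mi),
      fields$nbx[, midx], fields$nby[, midx], fields$dbnd[, midx],
      fields$gx[, midx], fields$gy[, midx],
      cfg$fpa && mi > 0, cfg$la && mi > 0, cfg$be && mi > 0,
      cfg$w,
      cfg$lambda_in * bl, cfg$lambda_out * bl,
      cfg$sigma_in, cfg$sigma_out, cfg$pact_in, cfg$pact_out,
      cfg$tau, cfg$mean_active_bout,
      cfg$sigma_be, cfg$be_trigger * bl)
    out[[a]] <- data.frame(worker_id = names(groups)[a], time_s = tvec,
                           x_mm = tr[, 1], y_mm = tr[, 2],
                           orientation_rad = tr[, 3], side = 1L,
                           valid = TRUE)
  }
  trajectories(do.call(rbind, out))
}

#' Wrapped-normal CRW turn-angle sample
#'
#' Draws turn angles from the simulator's turning distribution (a normal
#' with spread `sigma` wrapped to \[-pi, pi)). The circular resultant
#' length of this distribution is `exp(-sigma^2 / 2)`.
#'
#' @param n number of draws.
#' @param sigma spread (radians).
#' @param seed integer seed.
#' @return numeric vector of angles in \[-pi, pi).
#' @export
crw_turn_sample <- function(n, sigma, seed = 1L) {
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs))
  .wrap_angle(stats::rnorm(n, 0, sigma))
}

#' Exponential CRW step-length sample
#'
#' @param n number of draws.
#' @param lambda mean step length.
#' @param seed integer seed.
#' @return numeric vector of step lengths.
#' @export
crw_step_sample <- function(n, lambda, seed = 1L) {
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs))
  stats::rexp(n, rate = 1 / lambda)
}

#' Spatial segregation metrics for planted colonies
#'
#' Pairwise Bhattacharyya overlap of the group occupancy distributions
#' over sites (1 = identical occupancy, 0 = disjoint), plus, when module
#' scores from the detection pipeline are supplied, the proportion of
#' non-overlapping sites and the ground-truth assignment accuracy
#' (proportion of workers whose detected primary module equals their
#' planted group).
#'
#' @param traj a [trajectories()] table.
#' @param groups named vector mapping worker id to planted group label.
#' @param grid a `hex_grid`.
#' @param scores optional `module_scores` from the pipeline.
#' @return list with `overlap` (group x group matrix),
#'   `nonoverlapping_sites` and `accuracy` (NA without `scores`).
#' @export
segregation_metrics <- function(traj, groups, grid, scores = NULL) {
  t <- traj[traj$valid, , drop = FALSE]
  site <- locate_site(grid, t$x_mm, t$y_mm, t$side)
  g <- groups[as.character(t$worker_id)]
  ok <- !is.na(site) & !is.na(g)
  tab <- table(g[ok], site[ok])
  occ <- sweep(tab, 1, rowSums(tab), "/")
  K <- nrow(occ)
  ov <- matrix(1, K, K, dimnames = list(rownames(occ), rownames(occ)))
  for (i in seq_len(K)) for (j in seq_len(K))
    ov[i, j] <- sum(sqrt(occ[i, ] * occ[j, ]))
  acc <- NA_real_; nov <- NA_real_
  if (!is.null(scores)) {
    pm <- primary_module(scores, "workers")
    common <- intersect(names(pm), names(groups))
    acc <- mean(pm[common] == groups[common], na.rm = TRUE)
    nov <- summarize_specialists(scores)$nonoverlapping_sites
  }
  list(overlap = ov, nonoverlapping_sites = nov, accuracy = acc)
}
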