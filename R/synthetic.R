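#' Planted-colony specification
#'
#' Study conditions for a synthetic colony with ground-truth worker
#' groups: a rectangular single-sided nest with the entrance on the right
#' wall and a circular brood pile toward the left, carrying four planted
#' spatial zones laid out as in empirical module maps (nurse zone on the
#' brood, forager zone at the entrance, wall-following peripheral ring,
#' intermediate ring between nurse and forager zones).
#'
#' @param n_workers named integer vector of group sizes over the labels
#'   N, I, P, F (groups with 0 workers are dropped).
#' @param body_length worker body length (mm); default 4.
#' @param width_bl,height_bl nest dimensions in body lengths (defaults
#'   17.5 x 10, a 70 x 40 mm nest at 4 mm body length).
#' @param duration_s simulated duration (s); default 43200 (12 h at
#'   2 fps).
#' @param mechanisms named logical vector with entries `fpa`, `la`, `be`.
#' @param config optional [agent_config()] overriding the default
#'   movement parameters (mechanism switches are taken from
#'   `mechanisms`).
#' @param seed master seed.
#' @return An object of class `planted_colony_spec`.
#' @export
planted_colony_spec <- function(n_workers = c(N = 22, I = 9, P = 9, F = 20),
                                body_length = 4,
                                width_bl = 17.5, height_bl = 10,
                                duration_s = 43200,
                                mechanisms = c(fpa = FALSE, la = TRUE,
                                               be = TRUE),
                                config = NULL, seed = 1L) {
  stopifnot(all(names(n_workers) %in% c("N", "I", "P", "F")),
            sum(n_workers) >= 1)
  structure(list(n_workers = n_workers[n_workers > 0],
                 body_length = body_length,
                 width_bl = width_bl, height_bl = height_bl,
                 duration_s = duration_s,
                 mechanisms = mechanisms, config = config, seed = seed),
            class = "planted_colony_spec")
}

# four-zone planted landscape on a rectangular nest; returns sim_nest
.zone_landscape <- function(nest, grid, labels = c("N", "I", "P", "F")) {
  bl <- nest$body_length
  ctr <- site_centers(grid, seq_len(grid$n_base))
  d_ent <- .dist(ctr, nest$entrance) / bl
  d_brood <- distance_to_feature(grid, nest, "brood",
                                 sites = seq_len(grid$n_base))
  d_wall <- distance_to_feature(grid, nest, "wall",
                                sites = seq_len(grid$n_base))
  lg <- function(d, r0, k) 1 / (1 + exp((d - r0) / k))
  aN <- lg(d_brood, 1.2, 0.5)
  aF <- lg(d_ent, 3.5, 0.7)
  aP <- lg(d_wall, 1.0, 0.4) * (1 - aF) * (1 - aN)
  aI <- 0.55 * (1 - aN) * (1 - aF) * (1 - lg(d_wall, 0.8, 0.4))
  A <- cbind(N = aN, I = aI, P = aP, F = aF)[, labels, drop = FALSE]
  A <- A + 1e-6
  sim_nest(nest, grid, A / rowSums(A))
}

.dist <- function(m, p) sqrt((m[, 1] - p[1])^2 + (m[, 2] - p[2])^2)

#' Generate a planted colony
#'
#' Simulates a full colony from a [planted_colony_spec()]: builds the
#' nest, grid and planted four-zone landscape, assigns each worker its
#' group's zone as primary module, and delegates to [simulate_colony()].
#'
#' @param spec a [planted_colony_spec()].
#' @return list with `nest`, `grid`, `simnest`, `trajectories`, `truth`
#'   (named vector worker -> planted group) and `spec`.
#' @export
make_planted_colony <- function(spec) {
  stopifnot(inherits(spec, "planted_colony_spec"))
  bl <- spec$body_length
  W <- spec$width_bl * bl; H <- spec$height_bl * bl
  brood_c <- c(0.27 * W, 0.5 * H)
  brood_r <- 0.22 * min(W, H / 0.9)
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  brood <- cbind(brood_c[1] + brood_r * cos(th),
                 brood_c[2] + brood_r * sin(th))
  nest <- rect_nest(W, H, bl, entrance = c(W, H / 2), brood = brood)
  grid <- build_hex_grid(nest)
  simnest <- .zone_landscape(nest, grid)
  labels <- names(spec$n_workers)
  truth <- rep(labels, spec$n_workers)
  names(truth) <- sprintf("%s%02d", truth, stats::ave(
    seq_along(truth), truth, FUN = seq_along))
  base <- if (is.null(spec$config)) agent_config(la = spec$mechanisms[["la"]])
          else spec$config
  cfg <- base
  cfg$fpa <- isTRUE(spec$mechanisms[["fpa"]])
  cfg$la <- isTRUE(spec$mechanisms[["la"]])
  cfg$be <- isTRUE(spec$mechanisms[["be"]])
  if (!cfg$la) {
    cfg$lambda_in <- cfg$lambda_out <- cfg$lambda
    cfg$sigma_in <- cfg$sigma_out <- cfg$sigma
    cfg$pact_in <- cfg$pact_out <- cfg$pact
  }
  traj <- simulate_colony(simnest, truth, cfg, spec$duration_s,
                          seed = spec$seed)
  list(nest = nest, grid = grid, simnest = simnest, trajectories = traj,
       truth = truth, spec = spec)
}

#' Scripted deterministic trajectory
#'
#' Builds a piecewise trajectory from a list of segments, each a list
#' with `duration` (s), `speed` (body lengths per second) and `turn`
#' (radians added to the heading per frame; a vector recycles, so
#' `c(pi/2, -pi/2)` gives a 90-degree zig-zag). Useful ground truth for
#' visit extraction, first-passage times, activity segmentation and
#' turn-angle statistics.
#'
#' @param script list of segments.
#' @param start starting point (mm).
#' @param heading0 initial heading (radians).
#' @param body_length body length (mm).
#' @param worker_id worker id for the output table.
#' @param dt frame interval (s).
#' @param t0 start time (s).
#' @return a [trajectories()] table; orientation equals the heading.
#' @export
make_scripted_trajectory <- function(script, start = c(0, 0), heading0 = 0,
                                     body_length = 4, worker_id = "w1",
                                     dt = 0.5, t0 = 0) {
  stopifnot(length(script) > 0)
  x <- start[1]; y <- start[2]; h <- heading0
  xs <- x; ys <- y; hs <- h
  for (seg in script) {
    n <- round(seg$duration / dt)
    turn <- rep(if (is.null(seg$turn)) 0 else seg$turn, length.out = n)
    for (k in seq_len(n)) {
      h <- .wrap_angle(h + turn[k])
      x <- x + seg$speed * body_length * dt * cos(h)
      y <- y + seg$speed * body_length * dt * sin(h)
      xs <- c(xs, x); ys <- c(ys, y); hs <- c(hs, h)
    }
  }
  trajectories(data.frame(
    worker_id = worker_id,
    time_s = t0 + (seq_along(xs) - 1) * dt,
    x_mm = xs, y_mm = ys, orientation_rad = hs, side = 1L, valid = TRUE))
}

#' Pairwise contact counts from trajectories
#'
#' Counts contact events between worker pairs: a contact frame has the
#' two workers within `range_bl` body lengths with at least one facing
#' the other (bearing within pi/2 of its body orientation); a contact
#' event is a maximal run of contact frames. The resulting count matrix
#' is symmetric with a zero diagonal.
#'
#' @param traj a [trajectories()] table with >= 2 workers.
#' @param range_bl contact range (body lengths).
#' @param body_length body length (mm).
#' @return symmetric integer matrix of contact counts.
#' @export
make_contact_table <- function(traj, range_bl = 1, body_length = 4) {
  t <- traj[traj$valid, , drop = FALSE]
  ids <- sort(unique(as.character(t$worker_id)))
  if (length(ids) < 2) stop("need at least 2 workers")
  C <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  split_t <- split(t, as.character(t$worker_id))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    a <- split_t[[ids[i]]]; b <- split_t[[ids[j]]]
    k <- match(a$time_s, b$time_s)
    ok <- !is.na(k)
    if (!any(ok)) next
    ax <- a$x_mm[ok]; ay <- a$y_mm[ok]
    bx <- b$x_mm[k[ok]]; by <- b$y_mm[k[ok]]
    d <- sqrt((ax - bx)^2 + (ay - by)^2)
    near <- d <= range_bl * body_length
    face_ab <- abs(.wrap_angle(atan2(by - ay, bx - ax) -
                                 a$orientation_rad[ok])) <= pi / 2
    face_ba <- abs(.wrap_angle(atan2(ay - by, ax - bx) -
                                 b$orientation_rad[k[ok]])) <= pi / 2
    contact <- near & (face_ab | face_ba)
    contact[is.na(contact)] <- FALSE
    r <- rle(contact)
    C[i, j] <- C[j, i] <- sum(r$values)
  }
  C
}
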