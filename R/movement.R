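#' @useDynLib nestnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# Per-worker frame-to-frame kinematics.
# Returns `intervals` (one row per consecutive valid fix pair with
# dt <= max_gap): worker, t0, t1, x0, y0, dt, dist, speed (mm/s), heading;
# and `turns` (one row per interior fix with contiguous intervals either
# side): worker, t, x, y, turn (unsigned heading change), heading (incoming),
# it0 (t0 of the incoming interval).
.kinematics <- function(traj, max_gap = 0.75) {
  t <- traj[traj$valid & is.finite(traj$x_mm) & is.finite(traj$y_mm), ,
            drop = FALSE]
  ints_l <- list(); turns_l <- list()
  for (w in unique(as.character(t$worker_id))) {
    d <- t[t$worker_id == w, , drop = FALSE]
    n <- nrow(d)
    if (n < 2) next
    dt <- diff(d$time_s)
    ok <- dt <= max_gap
    dx <- diff(d$x_mm); dy <- diff(d$y_mm)
    heading <- atan2(dy, dx)
    dist <- sqrt(dx^2 + dy^2)
    iv <- data.frame(worker_id = w,
                     t0 = d$time_s[-n][ok], t1 = d$time_s[-1][ok],
                     x0 = d$x_mm[-n][ok], y0 = d$y_mm[-n][ok],
                     side = d$side[-n][ok],
                     dt = dt[ok], dist = dist[ok],
                     speed = (dist / dt)[ok], heading = heading[ok])
    ints_l[[w]] <- iv
    # turns: interval k and k+1 both retained and contiguous, both moving
    k <- seq_len(n - 2)
    good <- ok[k] & ok[k + 1] & dist[k] > 0 & dist[k + 1] > 0
    if (any(good)) {
      tr <- data.frame(worker_id = w,
                       t = d$time_s[k + 1][good],
                       x = d$x_mm[k + 1][good], y = d$y_mm[k + 1][good],
                       side = d$side[k + 1][good],
                       turn = abs(.wrap_angle(heading[k + 1] - heading[k]))[good],
                       heading = heading[k][good],
                       it0 = d$time_s[k][good])
      turns_l[[w]] <- tr
    }
  }
  ints <- if (length(ints_l)) do.call(rbind, ints_l) else NULL
  turns <- if (length(turns_l)) do.call(rbind, turns_l) else NULL
  if (is.null(ints))
    ints <- data.frame(worker_id = character(), t0 = numeric(),
                       t1 = numeric(), x0 = numeric(), y0 = numeric(),
                       side = integer(), dt = numeric(), dist = numeric(),
                       speed = numeric(), heading = numeric())
  if (is.null(turns))
    turns <- data.frame(worker_id = character(), t = numeric(),
                        x = numeric(), y = numeric(), side = integer(),
                        turn = numeric(), heading = numeric(),
                        it0 = numeric())
  rownames(ints) <- NULL; rownames(turns) <- NULL
  list(intervals = ints, turns = turns)
}

# exact 1-D 2-means: threshold split of the sorted values minimising
# within-cluster sum of squares; returns TRUE for the upper cluster
.two_means_upper <- function(v) {
  o <- order(v); s <- v[o]; n <- length(s)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  ss <- vapply(seq_len(n - 1), function(j) {
    (cs2[j] - cs[j]^2 / j) +
      ((cs2[n] - cs2[j]) - (cs[n] - cs[j])^2 / (n - j))
  }, numeric(1))
  j <- which.min(ss)
  upper <- logical(n)
  upper[o[(j + 1):n]] <- TRUE
  upper
}

# penalised binary segmentation on a mean-shift model (one series)
.binseg_means <- function(x, penalty_mult = 3, min_seg = 4L) {
  n <- length(x)
  if (n < 2 * min_seg) return(integer(0))
  v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(integer(0))
  pen <- penalty_mult * v * log(n)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  rss <- function(l, r) {
    s <- cs[r + 1] - cs[l]; s2 <- cs2[r + 1] - cs2[l]
    s2 - s^2 / (r - l + 1)
  }
  cps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    l <- seg[1]; r <- seg[2]
    if (r - l + 1 < 2 * min_seg) next
    ms <- (l + min_seg - 1):(r - min_seg)
    gain <- rss(l, r) - vapply(ms, function(m) rss(l, m) + rss(m + 1, r),
                               numeric(1))
    best <- which.max(gain)
    if (gain[best] > pen) {
      m <- ms[best]
      cps <- c(cps, m)
      stack <- c(stack, list(c(l, m)), list(c(m + 1L, r)))
    }
  }
  sort(cps)
}

#' Segment trajectories into active and inactive bouts
#'
#' Decomposes each worker's trajectory into an alternating sequence of
#' active and inactive bouts: penalised binary segmentation (mean-shift
#' model) on the per-frame displacement series, followed by 2-means
#' clustering of the segment mean speeds; the lower-mean cluster is the
#' inactive state. A trajectory whose segment means are indistinguishable
#' forms a single bout, active when its mean speed exceeds `floor_speed`.
#'
#' @param traj a [trajectories()] table.
#' @param penalty_mult penalty multiplier for the segmentation (larger =
#'   fewer change points); default 3.
#' @param min_seg minimum segment length in frames; default 4.
#' @param floor_speed speed (mm/s) below which a homogeneous trajectory
#'   counts as inactive; default 0.
#' @param max_gap maximum frame gap (s) for a displacement to be used.
#' @return Object of class `activity_bouts`: `bouts` (worker, state,
#'   t_start, t_end) and `intervals` (per frame pair, with an `active`
#'   flag), plus the `turns` table with per-turn activity.
#' @export
segment_activity <- function(traj, penalty_mult = 3, min_seg = 4L,
                             floor_speed = 0, max_gap = 0.75) {
  kin <- .kinematics(traj, max_gap = max_gap)
  iv <- kin$intervals
  if (nrow(iv) == 0)
    return(structure(list(bouts = data.frame(), intervals = iv,
                          turns = kin$turns), class = "activity_bouts"))
  iv$active <- NA
  bouts <- NULL
  for (w in unique(iv$worker_id)) {
    idx <- which(iv$worker_id == w)
    x <- iv$speed[idx]
    cps <- .binseg_means(x, penalty_mult, min_seg)
    bnd <- c(0, cps, length(x))
    seg_id <- rep(seq_len(length(bnd) - 1), diff(bnd))
    means <- as.numeric(tapply(x, seg_id, mean))
    # cluster segment means on a log scale, so the split lands between
    # the near-zero (resting) mode and the moving modes rather than
    # between slow- and fast-moving regimes; accept an inactive cluster
    # only if it is genuinely near zero relative to the moving cluster
    act_seg <- NULL
    if (diff(range(means)) >= 1e-9) {
      eps <- 0.05 * max(means)
      upper <- .two_means_upper(log(means + eps))
      if (any(upper) && any(!upper) &&
          mean(means[!upper]) < 0.2 * mean(means[upper]))
        act_seg <- upper
    }
    if (is.null(act_seg))
      act_seg <- rep(mean(x) > floor_speed, length(means))
    act <- act_seg[seg_id]
    iv$active[idx] <- act
    r <- rle(act)
    ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
    bouts <- rbind(bouts, data.frame(
      worker_id = w, state = ifelse(r$values, "active", "inactive"),
      t_start = iv$t0[idx][starts], t_end = iv$t1[idx][ends]))
  }
  # a turn is active when both flanking intervals are active
  tr <- kin$turns
  if (nrow(tr) > 0) {
    key <- function(w, t) paste(w, format(t, digits = 12), sep = "\r")
    amap <- stats::setNames(iv$active, key(iv$worker_id, iv$t0))
    tr$active <- amap[key(tr$worker_id, tr$it0)] &
      amap[key(tr$worker_id, tr$t)]
    tr$active[is.na(tr$active)] <- FALSE
  }
  structure(list(bouts = bouts, intervals = iv, turns = tr),
            class = "activity_bouts")
}

#' @export
print.activity_bouts <- function(x, ...) {
  cat(sprintf("Activity segmentation: %d bouts over %d workers; P(active) = %.3f\n",
              nrow(x$bouts), length(unique(x$bouts$worker_id)),
              with(x$intervals, sum(dt[active]) / sum(dt))))
  invisible(x)
}

#' Per individual-site locomotion statistics
#'
#' For every visited (worker, site) pair: the activity probability
#' `P` (proportion of time in the active state while at the site, from
#' all fixes), the mean speed while active `v_bl_s` (body lengths per
#' second) and the mean unsigned turn angle while active `theta_rad`
#' (radians, from turns whose flanking displacements are both active).
#' Speed and turning are computed from active fixes only so they capture
#' properties of movement rather than the probability of moving.
#'
#' @param activity an `activity_bouts` object from [segment_activity()].
#' @param grid a `hex_grid`.
#' @param body_length body length (mm) for speed scaling; defaults to the
#'   grid's.
#' @param min_turns minimum active turns for `theta_rad` (default 3;
#'   fewer gives `NA`).
#' @return data.frame: `worker_id`, `site_id`, `P`, `v_bl_s`,
#'   `theta_rad`, `n_fixes`.
#' @export
site_locomotion <- function(activity, grid, body_length = grid$body_length,
                            min_turns = 3L) {
  iv <- activity$intervals
  iv$site <- locate_site(grid, iv$x0, iv$y0, iv$side)
  iv <- iv[!is.na(iv$site), , drop = FALSE]
  grp <- paste(iv$worker_id, iv$site, sep = "\r")
  P <- tapply(iv$dt * iv$active, grp, sum) / tapply(iv$dt, grp, sum)
  va <- tapply(ifelse(iv$active, iv$speed, NA), grp,
               function(z) mean(z, na.rm = TRUE))
  nfix <- tapply(iv$dt, grp, length)
  ids <- do.call(rbind, strsplit(names(P), "\r", fixed = TRUE))
  out <- data.frame(
    worker_id = ids[, 1],
    site_id = as.integer(ids[, 2]),
    P = as.numeric(P), v_bl_s = as.numeric(va) / body_length,
    theta_rad = NA_real_, n_fixes = as.integer(nfix))
  tr <- activity$turns
  if (!is.null(tr) && nrow(tr) > 0) {
    tr <- tr[tr$active, , drop = FALSE]
    if (nrow(tr) > 0) {
      tr$site <- locate_site(grid, tr$x, tr$y, tr$side)
      tr <- tr[!is.na(tr$site), , drop = FALSE]
      g2 <- paste(tr$worker_id, tr$site, sep = "\r")
      th <- tapply(tr$turn, g2, mean)
      nn <- tapply(tr$turn, g2, length)
      th[nn < min_turns] <- NA
      key <- paste(out$worker_id, out$site_id, sep = "\r")
      out$theta_rad <- as.numeric(th[key])
    }
  }
  rownames(out) <- NULL
  out
}

#' First passage time beyond a circle
#'
#' For each valid fix, the time until the worker first moves beyond a
#' circle of radius `radius_bl` body lengths centred on that fix; `Inf`
#' when the trajectory ends (or `cap` seconds pass) without leaving it.
#'
#' @param traj a [trajectories()] table (one worker, or use `worker`).
#' @param radius_bl circle radius in body lengths.
#' @param body_length body length (mm).
#' @param worker optional worker id to select.
#' @param cap search horizon in seconds (default `Inf`); times beyond the
#'   cap report as `Inf` (censored).
#' @return data.frame `worker_id`, `time_s`, `fpt_s`.
#' @export
first_passage_time <- function(traj, radius_bl, body_length,
                               worker = NULL, cap = Inf) {
  t <- traj[traj$valid & is.finite(traj$x_mm), , drop = FALSE]
  if (!is.null(worker)) t <- t[t$worker_id %in% worker, , drop = FALSE]
  out <- lapply(split(t, as.character(t$worker_id)), function(d) {
    data.frame(worker_id = d$worker_id, time_s = d$time_s,
               fpt_s = fpt_cpp(d$time_s, d$x_mm, d$y_mm,
                               radius_bl * body_length,
                               if (is.finite(cap)) cap else 1e12))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify task-related behaviour per worker
#'
#' Flags each fix for four task behaviours and aggregates them into a
#' task profile:
#' \itemize{
#'   \item guarding: within `guard_dist_bl` of the entrance, body
#'     orientation diverging from the direct heading to the entrance by at
#'     most pi/2, and "on station" (first passage time beyond
#'     `guard_radius_bl` exceeding `guard_fpt_s` seconds);
#'   \item patrolling: active and "roaming" (first passage time beyond
#'     `patrol_radius_bl` under `patrol_fpt_s` seconds);
#'   \item queen attendance: within the front-of-body contact trapezoid of
#'     the queen and facing her (needs `queen_id`);
#'   \item foraging: located outside the nest boundary polygon.
#' }
#' Total time and bout counts per task are each normalised by the
#' worker's total number of trajectory fixes.
#'
#' @param traj a [trajectories()] table.
#' @param nest a [nest_geometry()].
#' @param activity an `activity_bouts` object for the same trajectories.
#' @param queen_id optional id of the queen in `traj`.
#' @param guard_dist_bl,guard_radius_bl,guard_fpt_s guarding rule
#'   parameters (defaults 2 BL, 2 BL, 500 s).
#' @param patrol_radius_bl,patrol_fpt_s patrolling rule parameters
#'   (defaults 4 BL, 300 s).
#' @param trapezoid contact trapezoid for queen attendance: numeric
#'   `c(length, width_near, width_far)` in body lengths.
#' @return data.frame with one row per worker and task: `worker_id`,
#'   `task`, `total_time_s`, `n_bouts`, `norm_time`, `norm_bouts`.
#' @export
classify_tasks <- function(traj, nest, activity, queen_id = NULL,
                           guard_dist_bl = 2, guard_radius_bl = 2,
                           guard_fpt_s = 500,
                           patrol_radius_bl = 4, patrol_fpt_s = 300,
                           trapezoid = c(1, 0.5, 1)) {
  bl <- nest$body_length
  t <- traj[traj$valid & is.finite(traj$x_mm), , drop = FALSE]
  t$worker_id <- as.character(t$worker_id)
  if (!is.null(queen_id)) {
    queen <- t[t$worker_id == as.character(queen_id), , drop = FALSE]
  } else queen <- NULL
  iv <- activity$intervals
  key <- paste(iv$worker_id, format(iv$t0, digits = 12), sep = "\r")
  active_map <- stats::setNames(iv$active, key)
  rows <- NULL
  for (w in setdiff(unique(t$worker_id), as.character(queen_id))) {
    d <- t[t$worker_id == w, , drop = FALSE]
    n <- nrow(d)
    if (n == 0) next
    dtf <- c(diff(d$time_s), 0.5)  # last fix gets one nominal frame
    fpt_g <- fpt_cpp(d$time_s, d$x_mm, d$y_mm, guard_radius_bl * bl,
                     guard_fpt_s + 1)
    fpt_p <- fpt_cpp(d$time_s, d$x_mm, d$y_mm, patrol_radius_bl * bl,
                     patrol_fpt_s + 1)
    d_ent <- sqrt((d$x_mm - nest$entrance[1])^2 +
                    (d$y_mm - nest$entrance[2])^2)
    to_ent <- atan2(nest$entrance[2] - d$y_mm, nest$entrance[1] - d$x_mm)
    facing <- abs(.wrap_angle(d$orientation_rad - to_ent)) <= pi / 2
    facing[is.na(facing)] <- FALSE
    act <- active_map[paste(w, format(d$time_s, digits = 12), sep = "\r")]
    act[is.na(act)] <- FALSE
    guard <- d_ent <= guard_dist_bl * bl & facing & fpt_g > guard_fpt_s
    patrol <- act & fpt_p < patrol_fpt_s
    forage <- !.points_in_polygon(d$x_mm, d$y_mm, nest$boundary)
    attend <- rep(FALSE, n)
    if (!is.null(queen) && nrow(queen) > 0) {
      qi <- match(d$time_s, queen$time_s)
      has_q <- !is.na(qi)
      if (any(has_q)) {
        qx <- queen$x_mm[qi[has_q]]; qy <- queen$y_mm[qi[has_q]]
        attend[has_q] <- .in_front_trapezoid(
          d$x_mm[has_q], d$y_mm[has_q], d$orientation_rad[has_q],
          qx, qy, trapezoid * bl)
      }
    }
    flags <- list(guarding = guard, patrolling = patrol,
                  queen_attendance = attend, foraging = forage)
    if (is.null(queen)) flags$queen_attendance <- NULL
    for (task in names(flags)) {
      f <- flags[[task]]
      r <- rle(f)
      rows <- rbind(rows, data.frame(
        worker_id = w, task = task,
        total_time_s = sum(dtf[f]),
        n_bouts = sum(r$values),
        norm_time = sum(dtf[f]) / n,
        norm_bouts = sum(r$values) / n))
    }
  }
  if (is.null(queen_id) )
    rows <- rows[rows$task != "queen_attendance", , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

# is target point inside the front-of-body trapezoid of the focal worker?
# trap = c(length, half-width at the head, half-width at the far end), mm
.in_front_trapezoid <- function(x, y, ori, tx, ty, trap) {
  dx <- tx - x; dy <- ty - y
  fwd <- dx * cos(ori) + dy * sin(ori)
  lat <- -dx * sin(ori) + dy * cos(ori)
  ok <- fwd >= 0 & fwd <= trap[1]
  halfw <- trap[2] + (trap[3] - trap[2]) * (fwd / trap[1])
  ok & abs(lat) <= halfw
}

#' Taxis indices toward module boundaries
#'
#' For each worker, visited site, and focal module whose primary area
#' excludes that site: the projection of the mean resultant of the unit
#' headings of all trajectory segments starting at the site onto the unit
#' vector from the site centre to the nearest boundary-site centre of the
#' focal module. Positive values indicate a tendency to head toward the
#' module; the index always lies in [-1, 1].
#'
#' @param traj a [trajectories()] table.
#' @param grid a `hex_grid`.
#' @param module_map vector of primary-module identifiers per site (`NA`
#'   allowed); defines module membership and boundaries.
#' @param modules focal modules to evaluate (default: all in
#'   `module_map`).
#' @param max_gap maximum frame gap (s) for segments.
#' @return data.frame: `worker_id`, `site_id`, `module`, `taxis`,
#'   `dist_bl` (site distance to the module boundary, body lengths),
#'   `n_segments`.
#' @export
taxis_table <- function(traj, grid, module_map,
                        modules = sort(unique(module_map[!is.na(module_map)])),
                        max_gap = 0.75) {
  kin <- .kinematics(traj, max_gap = max_gap)
  iv <- kin$intervals
  iv <- iv[iv$dist > 0, , drop = FALSE]
  iv$site <- locate_site(grid, iv$x0, iv$y0, iv$side)
  iv <- iv[!is.na(iv$site), , drop = FALSE]
  if (nrow(iv) == 0) return(data.frame())
  grp <- paste(iv$worker_id, iv$site, sep = "\r")
  ux <- tapply(cos(iv$heading), grp, mean)
  uy <- tapply(sin(iv$heading), grp, mean)
  nseg <- tapply(iv$heading, grp, length)
  ids <- do.call(rbind, strsplit(names(ux), "\r", fixed = TRUE))
  per_ws <- data.frame(worker_id = ids[, 1], site_id = as.integer(ids[, 2]),
                       ux = as.numeric(ux), uy = as.numeric(uy),
                       n_segments = as.integer(nseg))
  ctr_all <- site_centers(grid)
  bl <- grid$body_length
  out <- NULL
  for (M in modules) {
    bs <- module_boundary_sites(grid, module_map, M)
    if (length(bs) == 0) next
    bctr <- site_centers(grid, bs)
    outside <- is.na(module_map[per_ws$site_id]) |
      module_map[per_ws$site_id] != M
    sub <- per_ws[outside, , drop = FALSE]
    if (nrow(sub) == 0) next
    usite <- unique(sub$site_id)
    near <- vapply(usite, function(s) {
      d2 <- (bctr[, 1] - ctr_all[s, 1])^2 + (bctr[, 2] - ctr_all[s, 2])^2
      which.min(d2)
    }, integer(1))
    nb <- bctr[near, , drop = FALSE]
    dx <- nb[, 1] - ctr_all[usite, 1]; dy <- nb[, 2] - ctr_all[usite, 2]
    dd <- sqrt(dx^2 + dy^2)
    dir <- cbind(ifelse(dd > 0, dx / dd, 0), ifelse(dd > 0, dy / dd, 0))
    m <- match(sub$site_id, usite)
    out <- rbind(out, data.frame(
      worker_id = sub$worker_id, site_id = sub$site_id, module = M,
      taxis = sub$ux * dir[m, 1] + sub$uy * dir[m, 2],
      dist_bl = dd[m] / bl, n_segments = sub$n_segments))
  }
  if (is.null(out))
    out <- data.frame(worker_id = character(), site_id = integer(),
                      module = character(), taxis = numeric(),
                      dist_bl = numeric(), n_segments = integer())
  rownames(out) <- NULL
  out
}

#' Resident vs non-resident taxis contrast by distance
#'
#' Bins the taxis table by distance to the focal module boundary and, per
#' bin, contrasts the mean taxis index of residents (workers whose
#' primary module is the focal module) against non-residents. The null
#' distribution comes from permuting residency labels within the bin;
#' p-values are Benjamini-Hochberg corrected across bins.
#'
#' @param tab output of [taxis_table()].
#' @param primary named vector mapping worker id to primary module
#'   (same identifier type as `tab$module`).
#' @param bin_width distance bin width in body lengths (default 1).
#' @param n_perm permutations per bin (default 1000).
#' @param seed integer seed.
#' @return data.frame per bin: `bin_lo`, `bin_hi`, `diff` (resident minus
#'   non-resident mean), `ci_lo`, `ci_hi` (null 95% band), `p`, `p_bh`,
#'   `n_resident`, `n_nonresident`.
#' @export
taxis_contrast <- function(tab, primary, bin_width = 1, n_perm = 1000L,
                           seed = 1L) {
  tab$resident <- primary[as.character(tab$worker_id)] == tab$module
  tab <- tab[!is.na(tab$resident), , drop = FALSE]
  tab$bin <- floor(tab$dist_bl / bin_width)
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs))
  rows <- NULL
  for (b in sort(unique(tab$bin))) {
    d <- tab[tab$bin == b, , drop = FALSE]
    n1 <- sum(d$resident); n0 <- sum(!d$resident)
    if (n1 == 0 || n0 == 0) next
    obs <- mean(d$taxis[d$resident]) - mean(d$taxis[!d$resident])
    perm <- vapply(seq_len(n_perm), function(i) {
      r <- sample(d$resident)
      mean(d$taxis[r]) - mean(d$taxis[!r])
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
    rows <- rbind(rows, data.frame(
      bin_lo = b * bin_width, bin_hi = (b + 1) * bin_width, diff = obs,
      ci_lo = stats::quantile(perm, 0.025, names = FALSE),
      ci_hi = stats::quantile(perm, 0.975, names = FALSE),
      p = p, n_resident = n1, n_nonresident = n0))
  }
  if (!is.null(rows)) rows$p_bh <- stats::p.adjust(rows$p, method = "BH")
  rows
}
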