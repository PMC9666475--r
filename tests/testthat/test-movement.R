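big_nest <- function() rect_nest(400, 400, 4, entrance = c(400, 200))

test_that("square-wave speed profiles segment at the planted switches", {
  nest <- big_nest()
  script <- rep(list(list(duration = 60, speed = 1, turn = c(0.6, -0.6)),
                     list(duration = 60, speed = 0)), 3)
  tr <- make_scripted_trajectory(script, start = c(50, 200),
                                 body_length = 4)
  act <- segment_activity(tr)
  b <- act$bouts
  expect_equal(nrow(b), 6L)
  expect_equal(b$state, rep(c("active", "inactive"), 3))
  # change points within +/- 2 frames (1 s) of the planted 60 s switches
  expect_true(all(abs(b$t_start[-1] - seq(60, 300, 60)[1:5]) <= 1))
})

test_that("homogeneous trajectories form a single bout of the right state", {
  tr <- make_scripted_trajectory(list(list(duration = 120, speed = 0.5,
                                           turn = 0.1)),
                                 start = c(100, 100), body_length = 4)
  act <- segment_activity(tr)
  expect_equal(nrow(act$bouts), 1L)
  expect_equal(act$bouts$state, "active")
  still <- make_scripted_trajectory(list(list(duration = 120, speed = 0)),
                                    start = c(100, 100), body_length = 4)
  act2 <- segment_activity(still)
  expect_equal(nrow(act2$bouts), 1L)
  expect_equal(act2$bouts$state, "inactive")
})

test_that("whole-trajectory activity probability equals active share", {
  nest <- big_nest()
  script <- list(list(duration = 90, speed = 1, turn = c(0.6, -0.6)),
                 list(duration = 30, speed = 0))
  tr <- make_scripted_trajectory(script, start = c(50, 200),
                                 body_length = 4)
  act <- segment_activity(tr)
  P <- with(act$intervals, sum(dt[active]) / sum(dt))
  expect_equal(P, 0.75, tolerance = 0.02)
})

test_that("site locomotion has exact anchors for P, v and theta", {
  nest <- big_nest()
  grid <- build_hex_grid(nest, width = 8)
  # half moving (tiny back-and-forth, stays in one site), half still
  tr <- make_scripted_trajectory(
    list(list(duration = 60, speed = 0.3, turn = c(pi, pi)),
         list(duration = 60, speed = 0)),
    start = c(202, 202), body_length = 4)
  act <- segment_activity(tr)
  loco <- site_locomotion(act, grid, body_length = 4)
  main <- loco[which.max(loco$n_fixes), ]
  expect_equal(main$P, 0.5, tolerance = 0.03)
  expect_equal(main$v_bl_s, 0.3, tolerance = 0.02)
  # straight active motion: zero turn angle
  tr2 <- make_scripted_trajectory(list(list(duration = 200, speed = 0.1)),
                                  start = c(100, 100), body_length = 4)
  act2 <- segment_activity(tr2)
  loco2 <- site_locomotion(act2, grid, body_length = 4)
  expect_true(all(abs(loco2$theta_rad) < 1e-10, na.rm = TRUE))
  expect_true(any(!is.na(loco2$theta_rad)))
  # 90-degree zig-zag: mean unsigned turn is pi/2
  tr3 <- make_scripted_trajectory(
    list(list(duration = 300, speed = 0.1, turn = c(pi / 2, -pi / 2))),
    start = c(100, 100), body_length = 4)
  act3 <- segment_activity(tr3)
  loco3 <- site_locomotion(act3, grid, body_length = 4)
  th <- loco3$theta_rad[!is.na(loco3$theta_rad)]
  expect_true(length(th) > 0)
  expect_equal(mean(th), pi / 2, tolerance = 1e-8)
})

test_that("first passage times follow straight-line kinematics", {
  tr <- make_scripted_trajectory(list(list(duration = 400, speed = 0.1)),
                                 start = c(10, 200), body_length = 4)
  f <- first_passage_time(tr, radius_bl = 2, body_length = 4)
  # distance/speed = 20 s, observed at fix resolution (0.5 s frames)
  expect_equal(f$fpt_s[1], 20, tolerance = 0.5)
  still <- make_scripted_trajectory(list(list(duration = 60, speed = 0)),
                                    start = c(10, 10), body_length = 4)
  f2 <- first_passage_time(still, radius_bl = 2, body_length = 4)
  expect_true(all(is.infinite(f2$fpt_s)))
  # FPT is non-decreasing in the radius
  f4 <- first_passage_time(tr, radius_bl = 4, body_length = 4)
  expect_true(all(f4$fpt_s >= f$fpt_s))
})

test_that("task rules classify scripted guards, patrollers, foragers", {
  nest <- big_nest()
  # guard: parked 1 BL from the entrance, facing it, for 10 min
  guard <- trajectories(data.frame(
    worker_id = "g", time_s = seq(0, 600, 0.5),
    x_mm = 396, y_mm = 200, orientation_rad = 0))
  # patroller: fast roamer far from the entrance
  patrol <- make_scripted_trajectory(
    list(list(duration = 600, speed = 1, turn = c(0.3, -0.3))),
    start = c(60, 200), body_length = 4, worker_id = "p")
  # forager: outside the nest polygon
  forager <- trajectories(data.frame(
    worker_id = "f", time_s = seq(0, 600, 0.5),
    x_mm = 450, y_mm = 200, orientation_rad = 0))
  traj <- trajectories(rbind(guard, patrol, forager))
  act <- segment_activity(traj)
  tasks <- classify_tasks(traj, nest, act)
  # norm_time is seconds per fix: ~0.5 when a task fills the trajectory
  get <- function(w, task)
    tasks$norm_time[tasks$worker_id == w & tasks$task == task]
  expect_gt(get("g", "guarding"), 0.2)
  expect_equal(get("p", "guarding"), 0)
  expect_gt(get("p", "patrolling"), 0.45)
  expect_equal(get("g", "patrolling"), 0)
  expect_gt(get("f", "foraging"), 0.49)
  expect_equal(get("g", "foraging"), 0)
  expect_false("queen_attendance" %in% tasks$task)
})

test_that("queen attendance requires contact range and facing", {
  nest <- big_nest()
  queen <- trajectories(data.frame(
    worker_id = "Q", time_s = seq(0, 60, 0.5),
    x_mm = 200, y_mm = 200, orientation_rad = 0))
  # attendant 2 mm in front of own head direction toward the queen
  att <- trajectories(data.frame(
    worker_id = "a", time_s = seq(0, 60, 0.5),
    x_mm = 198, y_mm = 200, orientation_rad = 0))
  # nearby but facing away
  away <- trajectories(data.frame(
    worker_id = "b", time_s = seq(0, 60, 0.5),
    x_mm = 202, y_mm = 200, orientation_rad = 0))
  traj <- trajectories(rbind(queen, att, away))
  act <- segment_activity(traj)
  tasks <- classify_tasks(traj, nest, act, queen_id = "Q")
  get <- function(w) tasks$norm_time[tasks$worker_id == w &
                                       tasks$task == "queen_attendance"]
  expect_gt(get("a"), 0.45)
  expect_equal(get("b"), 0)
})

test_that("taxis index anchors: toward +1, away -1, split 0", {
  nest <- rect_nest(60, 40, 4)
  grid <- build_hex_grid(nest, width = 4)
  ctr <- site_centers(grid, seq_len(n_sites(grid)))
  mod <- ifelse(ctr[, 1] < 20, 1L, 2L)
  p0 <- c(40, 20)
  s <- locate_site(grid, p0[1], p0[2])
  bs <- module_boundary_sites(grid, mod, 1L)
  bctr <- site_centers(grid, bs)
  d2 <- (bctr[, 1] - ctr[s, 1])^2 + (bctr[, 2] - ctr[s, 2])^2
  dir <- c(bctr[which.min(d2), 1] - ctr[s, 1],
           bctr[which.min(d2), 2] - ctr[s, 2])
  dir <- dir / sqrt(sum(dir^2))
  seg_traj <- function(id, headings) {
    pos <- matrix(p0, 1)
    for (h in headings) pos <- rbind(pos, pos[nrow(pos), ] + 0.3 * h)
    trajectories(data.frame(worker_id = id,
                            time_s = (seq_len(nrow(pos)) - 1) / 2,
                            x_mm = pos[, 1], y_mm = pos[, 2]))
  }
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  toward <- seg_traj("t", list(dir))
  awayt <- seg_traj("a", list(-dir))
  split <- seg_traj("s", list(rot(dir, pi / 2), rot(dir, -pi / 2)))
  tab <- taxis_table(trajectories(rbind(toward, awayt, split)), grid, mod,
                     modules = 1L)
  getT <- function(w) tab$taxis[tab$worker_id == w & tab$site_id == s]
  expect_equal(getT("t"), 1, tolerance = 1e-6)
  expect_equal(getT("a"), -1, tolerance = 1e-6)
  expect_equal(getT("s"), 0, tolerance = 1e-6)
  expect_true(all(tab$taxis >= -1 - 1e-12 & tab$taxis <= 1 + 1e-12))
  expect_false(any(tab$site_id[tab$module == 1L] %in% which(mod == 1L)))
})

test_that("an isotropic walker shows no taxis at any distance", {
  snr <- sim_nest_radial(width_bl = 16, height_bl = 10, body_length = 4)
  traj <- simulate_colony(snr, c(w1 = NA, w2 = NA, w3 = NA),
                          agent_config(pact = 1), duration_s = 4000,
                          seed = 31, start = "uniform")
  mod <- snr$labels[snr$primary]
  tab <- taxis_table(traj, snr$grid, mod, modules = "central")
  # wall reflections fold headings inward for any walker, so the
  # isotropy check applies away from the nest boundary
  wd <- distance_to_feature(snr$grid, snr$nest, "wall",
                            sites = tab$site_id)
  tab <- tab[wd >= 2, , drop = FALSE]
  tab$bin <- floor(tab$dist_bl)
  for (b in unique(tab$bin)) {
    x <- tab$taxis[tab$bin == b]
    if (length(x) < 30) next
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x)), 3 * se + 1e-12)
  }
})

test_that("taxis contrast is null for identical groups", {
  set.seed(6)
  tab <- data.frame(worker_id = rep(paste0("w", 1:20), each = 10),
                    site_id = rep(1:10, 20), module = "A",
                    taxis = rnorm(200, 0, 0.3),
                    dist_bl = runif(200, 0, 6), n_segments = 5L)
  primary <- stats::setNames(rep(c("A", "B"), each = 10),
                             paste0("w", 1:20))
  res <- taxis_contrast(tab, primary, n_perm = 200, seed = 3)
  expect_true(all(res$p > 0.01))
  expect_true(all(abs(res$diff) < 0.5))
})

test_that("site-aggregated P reproduces the whole-trajectory statistic", {
  col <- tiny_colony(seed = 8, duration_s = 1200,
                     n_workers = c(N = 3, F = 3))
  act <- segment_activity(col$trajectories)
  loco <- site_locomotion(act, col$grid)
  for (w in unique(loco$worker_id)) {
    d <- loco[loco$worker_id == w, ]
    overall <- with(act$intervals,
                    sum(dt[active & worker_id == w]) /
                      sum(dt[worker_id == w]))
    expect_equal(sum(d$P * d$n_fixes) / sum(d$n_fixes), overall,
                 tolerance = 1e-6)
  }
})
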