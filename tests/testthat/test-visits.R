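# trajectories hopping between two well-separated site centres at
# scripted times, to exercise the re-entry rule precisely
hop_traj <- function(times_at_B, t_end = 40, id = "w1") {
  g <- toy_grid()
  ctr <- site_centers(g, c(100L, 1500L))
  tt <- seq(0, t_end, by = 0.5)
  at_B <- rep(FALSE, length(tt))
  for (iv in times_at_B) at_B[tt >= iv[1] & tt <= iv[2]] <- TRUE
  trajectories(data.frame(
    worker_id = id, time_s = tt,
    x_mm = ifelse(at_B, ctr[2, 1], ctr[1, 1]),
    y_mm = ifelse(at_B, ctr[2, 2], ctr[1, 2])))
}

test_that("re-entry within the refractory window extends the visit", {
  g <- toy_grid()
  # in A during [0,5] and [10,...]: gap 5 s < 20 s -> one visit to A
  tr <- hop_traj(list(c(5.5, 9.5)))
  ev <- extract_visits(tr, g)
  evA <- ev[ev$site_id == 100L, ]
  expect_equal(nrow(evA), 1L)
  expect_equal(evA$t_start, 0)
  expect_equal(evA$t_end, 40)
})

test_that("re-entry after the refractory window opens a new visit", {
  g <- toy_grid()
  # in A during [0,5] and from 30.5: gap 25.5 s >= 20 s -> two visits
  tr <- hop_traj(list(c(5.5, 30)))
  ev <- extract_visits(tr, g)
  expect_equal(nrow(ev[ev$site_id == 100L, ]), 2L)
  expect_equal(nrow(ev[ev$site_id == 1500L, ]), 1L)
})

test_that("a worker that never leaves one site makes exactly one visit", {
  g <- toy_grid()
  tr <- hop_traj(list())
  ev <- extract_visits(tr, g)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$site_id, 100L)
})

test_that("decreasing the refractory window never decreases counts", {
  g <- toy_grid()
  set.seed(11)
  ctr <- site_centers(g, c(100L, 1500L, 2000L))
  tt <- seq(0, 300, 0.5)
  pick <- cumsum(c(1, sample(c(0, 0, 0, 1), length(tt) - 1, TRUE))) %% 3 + 1
  tr <- trajectories(data.frame(worker_id = "w1", time_s = tt,
                                x_mm = ctr[pick, 1], y_mm = ctr[pick, 2]))
  for (r2 in c(10, 5, 0)) {
    n20 <- count_visits(extract_visits(tr, g, refractory = 20))
    nr <- count_visits(extract_visits(tr, g, refractory = r2))
    common <- intersect(colnames(n20), colnames(nr))
    expect_true(all(nr[, common] >= n20[, common]))
  }
})

test_that("visit time is conserved within the trajectory span", {
  g <- toy_grid()
  tr <- hop_traj(list(c(3, 8), c(15, 22), c(30, 33)))
  ev <- extract_visits(tr, g)
  # per site, total visit time cannot exceed the trajectory duration
  expect_lte(sum(ev$t_end - ev$t_start), 2 * 40)
  for (s in unique(ev$site_id))
    expect_lte(sum(ev$t_end[ev$site_id == s] - ev$t_start[ev$site_id == s]),
               40)
})

test_that("counts match a hand enumeration on a scripted toy", {
  g <- toy_grid()
  # w1: A[0,5], B[5.5,30], A[30.5,40] with 25 s gap -> A:2, B:1
  tr1 <- hop_traj(list(c(5.5, 30)), id = "w1")
  # w2: stays in B throughout
  ctr <- site_centers(g, 1500L)
  tr2 <- trajectories(data.frame(worker_id = "w2", time_s = seq(0, 40, 0.5),
                                 x_mm = ctr[1], y_mm = ctr[2]))
  ev <- extract_visits(trajectories(rbind(tr1, tr2)), g)
  n <- count_visits(ev)
  expect_equal(n["w1", "100"], 2L)
  expect_equal(n["w1", "1500"], 1L)
  expect_equal(n["w2", "1500"], 1L)
  # row sums equal accepted event counts
  expect_equal(unname(rowSums(n)), as.vector(table(ev$worker_id)[rownames(n)]))
})

test_that("counts are invariant to event ordering", {
  g <- toy_grid()
  ev <- extract_visits(hop_traj(list(c(5.5, 30), c(35, 38))), g)
  set.seed(5)
  shuf <- ev[sample(nrow(ev)), ]
  expect_equal(count_visits(shuf), count_visits(ev))
})

test_that("invalid-fix gaps close visits and long gaps block merging", {
  g <- toy_grid()
  ctr <- site_centers(g, 100L)
  tt <- seq(0, 60, 0.5)
  valid <- !(tt > 10 & tt < 35)   # 24.5 s tracking hole
  tr <- trajectories(data.frame(worker_id = "w1", time_s = tt,
                                x_mm = ctr[1], y_mm = ctr[2],
                                valid = valid))
  ev <- extract_visits(tr, g)
  expect_equal(nrow(ev), 2L)      # gap exceeds the 20 s window
  valid2 <- !(tt > 10 & tt < 20)  # 9.5 s hole: visit extends
  tr2 <- trajectories(data.frame(worker_id = "w1", time_s = tt,
                                 x_mm = ctr[1], y_mm = ctr[2],
                                 valid = valid2))
  expect_equal(nrow(extract_visits(tr2, g)), 1L)
})

test_that("side switches are counted as consecutive differing labels", {
  tr <- trajectories(data.frame(
    worker_id = "w1", time_s = seq(0, 2, 0.5),
    x_mm = 1, y_mm = 1, side = c(1L, 1L, 2L, 2L, 1L)))
  expect_equal(unname(count_side_switches(tr)), 2L)
  tr2 <- trajectories(data.frame(worker_id = "w1", time_s = 0:4,
                                 x_mm = 1, y_mm = 1, side = 1L))
  expect_equal(unname(count_side_switches(tr2)), 0L)
  set.seed(9)
  s <- sample(1:2, 200, TRUE)
  tr3 <- trajectories(data.frame(worker_id = "w1",
                                 time_s = seq_len(200) / 2,
                                 x_mm = 1, y_mm = 1, side = s))
  expect_equal(unname(count_side_switches(tr3)), sum(diff(s) != 0))
})

test_that("empty and all-invalid trajectories give empty events", {
  g <- toy_grid()
  empty <- trajectories(data.frame(worker_id = character(),
                                   time_s = numeric(), x_mm = numeric(),
                                   y_mm = numeric()))
  expect_equal(nrow(extract_visits(empty, g)), 0L)
  inv <- trajectories(data.frame(worker_id = "w1", time_s = 1:3,
                                 x_mm = 1, y_mm = 1, valid = FALSE))
  expect_equal(nrow(extract_visits(inv, g)), 0L)
  expect_error(count_visits(extract_visits(inv, g)), "no visit")
})

test_that("trajectory CSV round-trips", {
  tr <- hop_traj(list(c(5.5, 30)))
  f <- tempfile(fileext = ".csv")
  write_trajectories_csv(tr, f)
  back <- read_trajectories_csv(f)
  expect_equal(back$time_s, tr$time_s)
  expect_equal(back$x_mm, tr$x_mm)
  unlink(f)
})
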