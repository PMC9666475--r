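test_that("simulations are bit-identical under the same seed", {
  snr <- sim_nest_radial(body_length = 4)
  groups <- c(a = "central", b = "peripheral")
  cfg <- agent_config(la = TRUE, be = TRUE)
  t1 <- simulate_colony(snr, groups, cfg, 600, seed = 5)
  t2 <- simulate_colony(snr, groups, cfg, 600, seed = 5)
  expect_identical(t1, t2)
  t3 <- simulate_colony(snr, groups, cfg, 600, seed = 6)
  expect_false(identical(t1$x_mm, t3$x_mm))
})

test_that("zero turn spread gives straight-line motion between walls", {
  snr <- sim_nest_radial(width_bl = 50, height_bl = 50, body_length = 4)
  # a central start leaves >= 90 mm to the nearest wall; 20 s at
  # 4 mm/s covers 80 mm, so no reflection can occur
  tr <- simulate_colony(snr, c(w = "central"),
                        agent_config(sigma = 0, pact = 1), 20, seed = 2,
                        start = "module")
  kin <- nestnet:::.kinematics(tr)
  moved <- kin$intervals[kin$intervals$dist > 1e-9, ]
  expect_gt(nrow(moved), 10)
  expect_lt(diff(range(moved$heading)), 1e-9)
})

test_that("step lengths and turn angles match their distributions", {
  L <- crw_step_sample(1e5, lambda = 2.5, seed = 8)
  expect_equal(mean(L), 2.5, tolerance = 0.01)
  th <- crw_turn_sample(1e5, sigma = 0.7, seed = 9)
  expect_lt(abs(mean(sin(th))), 0.01)
  # circular resultant length of the wrapped normal: exp(-sigma^2/2)
  expect_equal(mean(cos(th)), exp(-0.7^2 / 2), tolerance = 0.01)
})

test_that("disabled mechanisms reproduce the plain CRW exactly", {
  snr <- sim_nest_radial(body_length = 4)
  groups <- c(a = "central")
  base <- simulate_colony(snr, groups, agent_config(), 300, seed = 3)
  w0 <- simulate_colony(snr, groups, agent_config(fpa = TRUE, w = 0),
                        300, seed = 3)
  expect_identical(base$x_mm, w0$x_mm)
  la_same <- agent_config(la = TRUE)
  la_same$lambda_in <- la_same$lambda_out <- la_same$lambda
  la_same$sigma_in <- la_same$sigma_out <- la_same$sigma
  la_same$pact_in <- la_same$pact_out <- la_same$pact
  t_la <- simulate_colony(snr, groups, la_same, 300, seed = 3)
  expect_identical(base$x_mm, t_la$x_mm)
  be0 <- simulate_colony(snr, groups, agent_config(be = TRUE,
                                                   sigma_be = 0),
                         300, seed = 3)
  expect_identical(base$x_mm, be0$x_mm)
})

test_that("full-weight attraction homes in on the primary module", {
  snr <- sim_nest_radial(width_bl = 30, height_bl = 20, body_length = 4,
                         r0_bl = 3)
  cfg <- agent_config(fpa = TRUE, w = 1, sigma = 0, pact = 1, lambda = 0.5)
  tr <- simulate_colony(snr, c(w = "central"), cfg, 300, seed = 12,
                        start = "uniform")
  cx <- 30 * 4 / 2; cy <- 20 * 4 / 2
  d <- sqrt((tr$x_mm - cx)^2 + (tr$y_mm - cy)^2) / 4
  # on the initial approach from outside, distance strictly decreases
  first_in <- which(d < 4)[1]
  expect_false(is.na(first_in))
  if (first_in > 5)
    expect_true(all(diff(d[seq_len(first_in)]) < 1e-6))
  # the walker reaches its module
  expect_lt(min(d), 3)
})

test_that("locomotion adjustment concentrates occupancy inside", {
  snr <- sim_nest_radial(width_bl = 16, height_bl = 10, body_length = 4,
                         r0_bl = 3)
  area_frac <- mean(snr$primary == which(snr$labels == "central"))
  cfg <- agent_config(la = TRUE)
  tr <- simulate_colony(snr, c(a = "central", b = "central"), cfg,
                        7200, seed = 4)
  site <- locate_site(snr$grid, tr$x_mm, tr$y_mm)
  inside_frac <- mean(snr$primary[site] == which(snr$labels == "central"),
                      na.rm = TRUE)
  expect_gt(inside_frac, area_frac + 0.2)
})

test_that("agents never leave the nest and zero duration is empty", {
  snr <- sim_nest_radial(body_length = 4)
  tr <- simulate_colony(snr, c(a = "central", b = NA),
                        agent_config(lambda = 3), 900, seed = 7,
                        start = "uniform")
  bb <- apply(snr$nest$boundary, 2, range)
  expect_true(all(tr$x_mm >= bb[1, 1] & tr$x_mm <= bb[2, 1]))
  expect_true(all(tr$y_mm >= bb[1, 2] & tr$y_mm <= bb[2, 2]))
  expect_equal(nrow(simulate_colony(snr, c(a = "central"),
                                    agent_config(), 0, seed = 1)), 0L)
})

test_that("occupancy overlap metrics hit their anchors", {
  g <- toy_grid()
  left <- trajectories(data.frame(worker_id = "L",
                                  time_s = seq(0, 50, 0.5),
                                  x_mm = runif(101, 1, 25),
                                  y_mm = runif(101, 1, 39)))
  right <- trajectories(data.frame(worker_id = "R",
                                   time_s = seq(0, 50, 0.5),
                                   x_mm = runif(101, 35, 59),
                                   y_mm = runif(101, 1, 39)))
  both <- trajectories(rbind(left, right))
  seg <- segregation_metrics(both, c(L = "g1", R = "g2"), g)
  expect_equal(seg$overlap["g1", "g2"], 0)
  expect_equal(diag(seg$overlap), c(g1 = 1, g2 = 1))
  # identical occupancy: same fixes under two ids
  right2 <- left; right2$worker_id <- "R"
  same <- segregation_metrics(trajectories(rbind(left, right2)),
                              c(L = "g1", R = "g2"), g)
  expect_equal(same$overlap["g1", "g2"], 1, tolerance = 1e-12)
})

test_that("occupancy overlap falls as the diffusivity contrast grows", {
  ratios <- c(1.2, 3, 8)
  ov <- vapply(seq_along(ratios), function(i) {
    r <- ratios[i]
    cfg <- agent_config(la = TRUE, lambda_in = 0.8 / sqrt(r),
                        lambda_out = 0.8 * sqrt(r),
                        sigma_in = 0.8 * sqrt(r) / 2,
                        sigma_out = 0.8 / sqrt(r) / 2,
                        pact_in = 0.8, pact_out = 0.8)
    snr <- sim_nest_radial(width_bl = 16, height_bl = 10,
                           body_length = 4, r0_bl = 3)
    tr <- simulate_colony(snr, c(a = "central", b = "peripheral"),
                          cfg, 5400, seed = 40 + i)
    segregation_metrics(tr, c(a = "c", b = "p"),
                        snr$grid)$overlap["c", "p"]
  }, numeric(1))
  expect_gt(ov[1], ov[3])
  expect_true(all(diff(ov) < 0.05))   # monotone within noise
})
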