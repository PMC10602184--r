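test_that("num_scanlines implements the ceiling rule and its constraint", {
  expect_equal(num_scanlines(8, 10, 2), 1L)
  expect_equal(num_scanlines(16, 10, 2), 2L)    # ceil(16/8)
  expect_error(num_scanlines(16, 10, 6), class = "roct_constraint_error")
  expect_error(num_scanlines(16, 10, 0), class = "roct_constraint_error")
  expect_error(num_scanlines(-1, 10, 2), class = "roct_constraint_error")
})

test_that("entry poses follow the printed matrix", {
  plan <- scan_plan(x_st = 1, y_st = 2, z_st = 3, L = 5, W = 20,
                    W_ol = 2, W_OCT = 10)
  p1 <- entry_pose(1, plan)
  expect_equal(p1$T[1:3, 1:3], diag(c(1, -1, -1)))
  expect_equal(p1$T[1:3, 4], c(1, 2, 3))
  p2 <- entry_pose(2, plan)
  expect_equal(p2$T[1:3, 4], c(1, 2 + 8, 3))
  # consecutive entries differ only by W_OCT - W_ol in y
  for (i in seq_len(plan$n - 1)) {
    d <- entry_pose(i + 1, plan)$T[1:3, 4] - entry_pose(i, plan)$T[1:3, 4]
    expect_equal(d, c(0, plan$W_OCT - plan$W_ol, 0))
  }
  expect_error(entry_pose(0, plan), class = "roct_out_of_range")
  expect_error(entry_pose(plan$n + 1, plan), class = "roct_out_of_range")
})

test_that("compute_nsd measures the highest surface point", {
  a <- c(0.01, 0.01, 0.03)
  img <- matrix(0, 700, 40)
  img[176:700, ] <- 1          # flat surface at 0-based row 175
  b <- bscan(img, a, pose_rt())
  expect_equal(compute_nsd(b, 0.5), 1 - 175 / 700)   # 0.75

  img2 <- matrix(0, 100, 40)
  img2[51:100, ] <- 1          # surface at half depth
  expect_equal(compute_nsd(bscan(img2, a, pose_rt()), 0.5), 0.5)

  expect_true(is.na(compute_nsd(bscan(matrix(0, 50, 20), a, pose_rt()),
                                0.5)))
})

test_that("compute_nsd is invariant to joint intensity/threshold rescaling", {
  withr::with_seed(3, {
    img <- matrix(stats::runif(80 * 30, 0, 0.2), 80, 30)
    img[41:80, ] <- img[41:80, ] + 1
    b1 <- bscan(img, c(0.01, 0.01, 0.01), pose_rt())
    b2 <- bscan(img * 37.5, c(0.01, 0.01, 0.01), pose_rt())
    expect_equal(compute_nsd(b1, 0.6), compute_nsd(b2, 0.6 * 37.5))
  })
})

test_that("nsd_velocity evaluates the filtered proportional law", {
  s <- nsd_controller(mu_ref = 0.75, K_p = 1, w_s = 1, v_prev = 0)
  expect_equal(nsd_velocity(0.75, s)$v_z, 0)
  expect_equal(nsd_velocity(0.5, s)$v_z, 0.25)

  s2 <- nsd_controller(mu_ref = 0.75, K_p = 2, w_s = 0.5, v_prev = 0.1)
  step <- nsd_velocity(0.65, s2)
  expect_equal(step$v_z, 0.5 * 2 * 0.1 + 0.5 * 0.1)   # 0.15
  expect_equal(step$state$v_prev, 0.15)
})

test_that("nsd_velocity with w_s = 1 has its unique fixed point at mu_ref", {
  for (kp in c(0.5, 1, 4)) {
    s <- nsd_controller(K_p = kp, w_s = 1, v_prev = 0.3)
    expect_equal(nsd_velocity(0.75, s)$v_z, 0)
    expect_true(abs(nsd_velocity(0.74, s)$v_z) > 0)
  }
})

test_that("landing terminates within the one-step overshoot bound", {
  s <- make_flat_sample(height = 0, mu_t = 2)
  cfg <- desk_cfg()
  H_OCT <- cfg$H_px * cfg$alpha_ax
  pose0 <- pose_rt(diag(c(1, -1, -1)), c(0, 0, 10))
  res <- land_probe(s, pose0, cfg)
  expect_gte(res$mu, cfg$mu_land)
  expect_lte(res$mu, cfg$mu_land + cfg$v_land / (cfg$fps * H_OCT) + 1e-9)

  # already landed: terminates immediately (zero descent steps)
  pose1 <- pose_rt(diag(c(1, -1, -1)), c(0, 0, 0.3))  # mu approx 0.81
  res1 <- land_probe(s, pose1, cfg)
  expect_equal(res1$steps, 0L)
  expect_equal(res1$pose$T[3, 4], 0.3)

  # no sample within the travel limit: abort
  s_deep <- make_flat_sample(height = -100, mu_t = 2)
  expect_error(land_probe(s_deep, pose0, scan_config(max_travel = 5)),
               class = "roct_landing_abort")
})

test_that("run_scanline emits the exact frame count", {
  s <- make_flat_sample()
  plan <- scan_plan(L = 3, W = 4, W_ol = 1, W_OCT = 5.4)
  cfg <- scan_config(v_x = 0.6, fps = 20)
  landed <- land_probe(s, entry_pose(1, plan), cfg)
  sl <- run_scanline(s, landed$pose, plan, cfg)
  expect_length(sl$frames, ceiling(3 * 20 / 0.6))    # 100
})

test_that("closed loop on a flat sample converges to the NSD setpoint", {
  s <- make_flat_sample()
  plan <- scan_plan(L = 6, W = 4, W_ol = 1, W_OCT = 5.4, z_st = 10)
  cfg <- desk_cfg()
  landed <- land_probe(s, entry_pose(1, plan), cfg)
  sl <- run_scanline(s, landed$pose, plan, cfg)
  tail_mu <- utils::tail(sl$mu, 50)
  expect_lt(max(abs(tail_mu - 0.75)), 0.01)
  # z-trajectory essentially constant after the transient
  zs <- vapply(sl$frames, function(b) b$pose$T[3, 4], numeric(1))
  expect_lt(diff(range(utils::tail(zs, 50))), 2 * cfg$alpha_ax)
})

test_that("ramp sample steady-state NSD offset matches the scalar recursion", {
  slope <- 0.05
  s <- virtual_sample(function(x, y) slope * x,
                      function(x, y, z) rep_len(2, length(x)))
  plan <- scan_plan(L = 9, W = 4, W_ol = 1, W_OCT = 5.4, z_st = 5)
  cfg <- desk_cfg()
  ctrl <- nsd_controller()
  landed <- land_probe(s, entry_pose(1, plan), cfg)
  sl <- run_scanline(s, landed$pose, plan, cfg, ctrl)
  measured <- mean(utils::tail(sl$mu, 60)) - ctrl$mu_ref

  # independent oracle: the discrete-time closed-loop recursion on the
  # continuous (unquantized) NSD, run to steady state
  H_OCT <- cfg$H_px * cfg$alpha_ax
  dt <- 1 / cfg$fps
  mu <- ctrl$mu_ref; v <- 0
  for (t in 1:4000) {
    v <- ctrl$w_s * ctrl$K_p * (ctrl$mu_ref - mu) + (1 - ctrl$w_s) * v
    # probe moves down by v*dt; surface rises by slope*v_x*dt
    mu <- mu + (v * dt + slope * cfg$v_x * dt) / H_OCT
  }
  oracle <- mu - ctrl$mu_ref
  expect_gt(measured * oracle, 0)               # same sign
  expect_lt(abs(measured - oracle), 0.2 * abs(oracle))
})

test_that("run_scan concatenates scanlines with the expected frame count", {
  s <- make_flat_sample()
  plan <- scan_plan(L = 1.5, W = 12, W_ol = 1, W_OCT = 5.4, z_st = 2)
  cfg <- desk_cfg()
  expect_equal(plan$n, 3L)
  log <- run_scan(s, plan, cfg)
  per <- ceiling(plan$L * cfg$fps / cfg$v_x)
  expect_length(log$frames, plan$n * per)
  expect_equal(as.integer(table(log$scanline)), rep(per, 3))

  # doubling v_x halves the per-scanline frame count
  log2 <- run_scan(s, plan, scan_config(v_x = 1.2))
  expect_equal(sum(log2$scanline == 1), per / 2)
})
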