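test_that("extract_surface_depth reads per-column depths", {
  a <- c(0.01, 0.01, 0.03)
  img <- matrix(0, 300, 30)
  img[101:300, ] <- 1
  sd <- extract_surface_depth(bscan(img, a, pose_rt()), 0.5)
  expect_equal(sd$depth_mm, rep(1.0, 30))

  img2 <- matrix(0, 300, 30)
  img2[101:300, 1:12] <- 1
  img2[201:300, 13:30] <- 1
  sd2 <- extract_surface_depth(bscan(img2, a, pose_rt()), 0.5)
  expect_setequal(unique(sd2$depth_mm), c(1.0, 2.0))
  expect_equal(sum(diff(sd2$depth_mm) != 0), 1L)   # one transition

  sd3 <- extract_surface_depth(bscan(matrix(0, 50, 8), a, pose_rt()), 0.5)
  expect_false(any(sd3$valid))
})

test_that("DEPM recovers phantom extrusion height and width", {
  ph <- square_phantom()
  cfg <- desk_cfg()
  plan <- scan_plan(x_st = 1, y_st = 3, z_st = 3, L = 6, W = 4, W_ol = 1,
                    W_OCT = 5.4)
  log <- run_scan(ph, plan, cfg)
  depm <- build_depm(log)
  v <- depm$grid[depm$validity]

  # height: difference of the two surface levels vs ground truth
  lo <- stats::median(v[v < 0.15]); hi <- stats::median(v[v > 0.15])
  expect_lt(abs((hi - lo) - 0.3), cfg$alpha_ax)    # within 1 axial voxel

  # width along the lateral axis at the glyph middle vs rasterized truth
  gt <- ph$ground_truth
  x_mid <- (gt$boxes$x0[1] + gt$boxes$x1[1]) / 2
  j <- round((x_mid - depm$origin[1]) / depm$res[2]) + 1
  col <- depm$grid[, j]
  ys <- depm$origin[2] + (seq_len(nrow(depm$grid)) - 1) * depm$res[1]
  on_glyph <- depm$validity[, j] & col > 0.15
  width_map <- diff(range(ys[on_glyph])) + depm$res[1]
  truth_mask <- gt$mask[round(x_mid / gt$pitch) + 1, ]
  width_true <- sum(truth_mask) * gt$pitch
  expect_lt(abs(width_map - width_true), depm$res[1] + depm$res[2])
})

test_that("DEPM compensates probe altitude motion", {
  # flat sample scanned with a deliberately wavy z-trajectory
  s <- make_flat_sample()
  a <- c(0.03, 0.01, 0.03)
  frames <- lapply(0:59, function(f) {
    z <- 0.4 + 0.1 * sin(2 * pi * f / 15)
    synthesize_bscan(s, pose_rt(diag(c(1, -1, -1)),
                                c(f * 0.03, 0, z), timestamp = f / 20),
                     120, 160, a)
  })
  depm <- build_depm(oct_log(frames))
  v <- depm$grid[depm$validity]
  expect_lt(diff(range(v)), a[2] + 1e-12)   # flat within one axial voxel
})

test_that("fit_extinction matches the closed-form log-linear fit", {
  z <- (0:120) * 0.01
  I <- 3 * exp(-2 * 2.0 * z)
  a_scan <- c(rep(0, 10), I)
  ft <- fit_extinction(a_scan, surface_row = 10, window_mm = 1,
                       alpha_ax = 0.01)
  expect_lt(abs(ft$mu_t - 2.0), 1e-9)
  expect_gt(ft$r2, 0.999)
  expect_true(ft$valid)

  # constant intensity: zero slope
  ft0 <- fit_extinction(rep(1, 200), 10, 1, 0.01)
  expect_equal(ft0$mu_t, 0)

  # window out of the image: invalid
  ftw <- fit_extinction(rep(1, 20), 18, 1, 0.01)
  expect_false(ftw$valid)
})

test_that("fit_extinction is scale invariant", {
  withr::with_seed(8, {
    z <- (0:100) * 0.01
    I <- exp(-2 * 1.3 * z) * stats::rgamma(101, 16, 16)
    for (sc in c(1e-3, 1, 400)) {
      ft <- fit_extinction(sc * c(rep(0, 5), I), 5, 1, 0.01)
      ft1 <- fit_extinction(c(rep(0, 5), I), 5, 1, 0.01)
      expect_equal(ft$mu_t, ft1$mu_t, tolerance = 1e-12)
    }
  })
})

test_that("speckled columns recover mu_t within 10% RMSE", {
  s <- make_flat_sample(height = 0, mu_t = 2.0)
  s$noise <- list(speckle_shape = 16, background = 0, seed = 0L)
  a <- c(0.01, 0.01, 0.01)
  mu_hat <- numeric(0)
  n_frames <- ceiling(1000 / 200)
  for (f in seq_len(n_frames)) {
    p <- pose_rt(diag(c(1, -1, -1)), c(f * 0.05, 0, 0.4))
    b <- synthesize_bscan(s, p, 200, 160, a, seed = f)
    sr <- extract_surface_depth(b, 0.3)
    mu_hat <- c(mu_hat, vapply(seq_len(200), function(j) {
      fit_extinction(b$pixels[, j], sr$row[j], 1, 0.01)$mu_t
    }, numeric(1)))
  }
  expect_gte(length(mu_hat), 1000)
  rmse <- sqrt(mean((mu_hat - 2.0)^2))
  expect_lt(rmse / 2.0, 0.10)
})

test_that("ATCM separates a two-region sample at the true boundary", {
  s <- virtual_sample(function(x, y) rep_len(0, length(x)),
                      function(x, y, z) ifelse(y < 2, 1, 3))
  cfg <- desk_cfg()
  plan <- scan_plan(x_st = 0, y_st = 2, z_st = 2, L = 2, W = 4, W_ol = 1,
                    W_OCT = 5.4)
  log <- run_scan(s, plan, cfg)
  atcm <- build_atcm(log)
  ys <- atcm$origin[2] + (seq_len(nrow(atcm$grid)) - 1) * atcm$res[1]
  left <- atcm$grid[ys < 2 - atcm$res[1], ]
  right <- atcm$grid[ys > 2 + atcm$res[1], ]
  expect_lt(max(abs(left[!is.na(left)] - 1)), 0.02)
  expect_lt(max(abs(right[!is.na(right)] - 3)), 0.02)

  # uniform region: coefficient of variation below 1%
  expect_lt(stats::sd(right[!is.na(right)]) / mean(right[!is.na(right)]),
            0.01)
})

test_that("a low-attenuation tube leaves a low-mu_t streak in the ATCM", {
  lum <- data.frame(y = 2.5, depth = 0.45, radius = 0.12, x0 = 0, x1 = 10,
                    factor = 0.05, mu_scale = 0.1)
  s <- virtual_sample(function(x, y) rep_len(0, length(x)),
                      function(x, y, z) rep_len(2.5, length(x)),
                      lumens = lum)
  cfg <- desk_cfg()
  plan <- scan_plan(x_st = 0, y_st = 2.5, z_st = 2, L = 2, W = 4,
                    W_ol = 1, W_OCT = 5.4)
  log <- run_scan(s, plan, cfg)
  atcm <- build_atcm(log)
  ys <- atcm$origin[2] + (seq_len(nrow(atcm$grid)) - 1) * atcm$res[1]
  inside <- abs(ys - 2.5) < 0.12 - atcm$res[1]
  outside <- abs(ys - 2.5) > 0.12 + 2 * atcm$res[1] & abs(ys - 2.5) < 1
  mu_in <- rowMeans(atcm$grid[inside, , drop = FALSE], na.rm = TRUE)
  mu_out <- rowMeans(atcm$grid[outside, , drop = FALSE], na.rm = TRUE)
  expect_lt(max(mu_in), min(mu_out))
})

test_that("DIAM grid means equal the brute-force per-cell averages", {
  withr::with_seed(31, {
    vox <- array(0, c(40, 60, 5))
    mv <- mask_volume(vox, c(0.01, 0.01, 0.01), c(0, 0, 0))
    n <- 25
    meas <- data.frame(
      centroid_x_mm = stats::runif(n, 0, 0.4),
      centroid_y_mm = stats::runif(n, 0, 0.6),
      diameter_mm = stats::runif(n, 0.015, 0.030))
    k <- 10
    dm <- build_diam(mv, meas, k = k)
    cell <- attr(dm, "grid_k")
    # brute-force double loop over the k x k cells
    for (iy in seq_len(k)) {
      for (ix in seq_len(k)) {
        sel <- ceiling(meas$centroid_y_mm / 0.6 * k) == iy &
          ceiling(meas$centroid_x_mm / 0.4 * k) == ix
        if (any(sel)) {
          expect_equal(cell[iy, ix], mean(meas$diameter_mm[sel]))
        } else {
          expect_true(is.na(cell[iy, ix]))
        }
      }
    }
  })
})

test_that("DIAM handles constant fields, averaging, and bad k", {
  vox <- array(0, c(30, 30, 3))
  mv <- mask_volume(vox, c(0.01, 0.01, 0.01), c(0, 0, 0))
  # single lumen diameter d spanning all slices: every valid cell equals d
  meas <- data.frame(centroid_x_mm = rep(0.15, 5),
                     centroid_y_mm = rep(0.15, 5),
                     diameter_mm = rep(0.02, 5))
  dm <- build_diam(mv, meas, k = 10)
  expect_equal(unique(dm$grid[dm$validity]), 0.02)

  # two lumens in one cell: stated averaging
  meas2 <- data.frame(centroid_x_mm = c(0.13, 0.14),
                      centroid_y_mm = c(0.13, 0.14),
                      diameter_mm = c(0.01, 0.03))
  dm2 <- build_diam(mv, meas2, k = 10)
  expect_equal(unique(dm2$grid[dm2$validity]), 0.02)

  expect_error(build_diam(mv, meas, k = 40),
               class = "roct_constraint_error")
})

test_that("stitch averages overlaps and is order-free", {
  res <- c(0.1, 0.1)
  mk <- function(val, x0, y0, nr = 10, nc = 12) {
    parameter_map("ATCM", matrix(val, nr, nc), res, c(x0, y0))
  }
  a <- mk(1, 0, 0)
  b <- mk(3, 0, 0.5)   # overlap rows: half the lateral extent
  st <- stitch(list(a, b))
  ys <- st$origin[2] + (seq_len(nrow(st$grid)) - 1) * st$res[1]
  overlap <- ys >= 0.5 & ys <= 0.9 + 1e-9
  expect_true(all(st$grid[overlap, ] == 2))
  expect_true(all(st$grid[ys < 0.5, ] == 1))
  expect_true(all(st$grid[ys > 0.95, ] == 3))

  # commutative/associative
  cc <- mk(5, 0, 1.0)
  s1 <- stitch(list(a, b, cc))
  s2 <- stitch(list(cc, a, b))
  s3 <- stitch(list(stitch(list(a, b)), cc))
  expect_equal(s1$grid, s2$grid)
  # nested stitching differs (mean of means), but geometry must agree
  expect_equal(dim(s1$grid), dim(s3$grid))

  # identical overlapping maps: idempotent
  expect_equal(stitch(list(a, a))$grid, a$grid)

  # mixed kinds rejected
  d <- parameter_map("DEPM", matrix(1, 10, 12), res, c(0, 0))
  expect_error(stitch(list(a, d)), class = "roct_invalid_input")
})

test_that("three-scanline stitched DEPM has the planned footprint width", {
  ph <- make_flat_sample()
  cfg <- desk_cfg()
  plan <- scan_plan(x_st = 0, y_st = 0, z_st = 2, L = 1.5, W = 12,
                    W_ol = 1, W_OCT = 5.4)
  expect_equal(plan$n, 3L)
  log <- run_scan(ph, plan, cfg)
  depm <- build_depm(log)
  width <- nrow(depm$grid) * depm$res[1]
  want <- plan$W_OCT + 2 * (plan$W_OCT - plan$W_ol)
  expect_lt(abs(width - want), 2 * depm$res[1] + 1e-9)
})
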