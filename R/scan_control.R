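#' Scan plan
#'
#' Parameters of a raster scan: start coordinate of the first scanline in
#' \code{{F_base}}, scanline length L along x, lateral extent W to cover
#' along y, desired lateral overlap W_ol between adjacent scanlines, and the
#' B-scan lateral FOV W_OCT. The number of scanlines n is derived as
#' ceil(W / (W_OCT - W_ol)) under the constraint W_OCT > 2 W_ol > 0.
#'
#' @param x_st,y_st,z_st start coordinate, mm.
#' @param L scanline length, mm (> 0).
#' @param W lateral extent to cover, mm (> 0).
#' @param W_ol desired lateral overlap, mm.
#' @param W_OCT lateral FOV of one B-scan, mm.
#' @return An object of class \code{scan_plan} with derived field \code{n}.
#' @export
scan_plan <- function(x_st = 0, y_st = 0, z_st = 10, L = 5, W = 10,
                      W_ol = 1, W_OCT = 5.4) {
  if (L <= 0 || W <= 0) {
    stop_roct("scan_plan: L and W must be positive", "roct_constraint_error")
  }
  n <- num_scanlines(W, W_OCT, W_ol)
  structure(list(x_st = x_st, y_st = y_st, z_st = z_st, L = L, W = W,
                 W_ol = W_ol, W_OCT = W_OCT, n = n),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan> %d scanline(s), L = %g mm, W = %g mm, step = %g mm\n",
              x$n, x$L, x$W, x$W_OCT - x$W_ol))
  invisible(x)
}

#' Number of scanlines needed to cover a lateral extent
#'
#' n = ceil(W / (W_OCT - W_ol)), valid only under W_OCT > 2 W_ol > 0.
#'
#' @param W lateral extent to cover (mm, > 0).
#' @param W_OCT B-scan lateral FOV (mm).
#' @param W_ol desired overlap between adjacent scanlines (mm).
#' @return Integer count >= 1.
#' @export
num_scanlines <- function(W, W_OCT, W_ol) {
  if (!(W_OCT > 2 * W_ol && W_ol > 0)) {
    stop_roct("num_scanlines: constraint W_OCT > 2*W_ol > 0 violated",
              "roct_constraint_error")
  }
  if (W <= 0) {
    stop_roct("num_scanlines: W must be positive", "roct_constraint_error")
  }
  as.integer(ceiling(W / (W_OCT - W_ol)))
}

#' Entry pose of the i-th scanline
#'
#' Rotation diag(1, -1, -1) (probe axial axis pointing down), translation
#' (x_st, y_st + (i - 1)(W_OCT - W_ol), z_st).
#'
#' @param i scanline index, 1-based, 1 <= i <= plan$n.
#' @param plan a \code{scan_plan}.
#' @param timestamp seconds.
#' @return A \code{probe_pose}.
#' @export
entry_pose <- function(i, plan, timestamp = 0) {
  if (i < 1 || i > plan$n) {
    stop_roct("entry_pose: scanline index out of range", "roct_out_of_range")
  }
  pose_rt(diag(c(1, -1, -1)),
          c(plan$x_st, plan$y_st + (i - 1) * (plan$W_OCT - plan$W_ol),
            plan$z_st),
          timestamp)
}

#' Acquisition/motion configuration
#'
#' @param v_x along-scanline speed, mm/s.
#' @param v_land landing descent speed, mm/s.
#' @param fps B-scan acquisition rate, frames/s; the simulator's control
#'   loop also updates once per frame.
#' @param mu_land landing termination NSD threshold.
#' @param W_px,H_px synthesized image size.
#' @param alpha_lat,alpha_ax lateral/axial pixel pitch, mm/px (elevational
#'   pitch is v_x / fps by construction).
#' @param surface_threshold absolute intensity threshold for surface
#'   detection, or NULL to estimate per frame (mean + 5 sd of the top 5% of
#'   rows, floored at 1e-6).
#' @param max_travel landing travel limit, mm.
#' @return An object of class \code{scan_config}.
#' @export
scan_config <- function(v_x = 0.6, v_land = 1, fps = 20, mu_land = 0.75,
                        W_px = 180, H_px = 160,
                        alpha_lat = 0.03, alpha_ax = 0.01,
                        surface_threshold = NULL, max_travel = 50) {
  if (v_x <= 0 || fps <= 0 || v_land <= 0) {
    stop_roct("scan_config: speeds and fps must be positive",
              "roct_constraint_error")
  }
  if (!(mu_land > 0 && mu_land < 1)) {
    stop_roct("scan_config: mu_land must lie in (0,1)",
              "roct_constraint_error")
  }
  structure(list(v_x = v_x, v_land = v_land, fps = fps, mu_land = mu_land,
                 W_px = as.integer(W_px), H_px = as.integer(H_px),
                 alpha_lat = alpha_lat, alpha_ax = alpha_ax,
                 surface_threshold = surface_threshold,
                 max_travel = max_travel),
            class = "scan_config")
}

# pixel pitch vector for a config: elevational pitch = frame spacing
cfg_alpha <- function(cfg) c(cfg$alpha_lat, cfg$alpha_ax, cfg$v_x / cfg$fps)

#' NSD proportional controller state
#'
#' Regulates the normalized surface depth via
#' v_z[t] = w_s K_p (mu_ref - mu) + (1 - w_s) v_z[t-1]. A positive v_z moves
#' the probe toward the sample (base-frame z decreases).
#'
#' @param mu_ref desired NSD (default 0.75).
#' @param K_p proportional gain, mm/s per unit NSD error (> 0).
#' @param w_s low-pass weight in [0, 1].
#' @param v_prev previous commanded velocity, mm/s.
#' @return An object of class \code{nsd_controller}.
#' @export
nsd_controller <- function(mu_ref = 0.75, K_p = 1, w_s = 0.5, v_prev = 0) {
  if (!(mu_ref > 0 && mu_ref < 1)) {
    stop_roct("nsd_controller: mu_ref must lie in (0,1)",
              "roct_constraint_error")
  }
  if (K_p <= 0 || w_s < 0 || w_s > 1) {
    stop_roct("nsd_controller: need K_p > 0 and w_s in [0,1]",
              "roct_constraint_error")
  }
  structure(list(mu_ref = mu_ref, K_p = K_p, w_s = w_s, v_prev = v_prev),
            class = "nsd_controller")
}

#' Normalized surface depth of a B-scan
#'
#' Per A-scan column the surface is the shallowest pixel at or above the
#' intensity threshold; h_tis is the minimum surface depth over columns
#' (the highest detected surface point), and mu = 1 - h_tis / H_OCT.
#' Columns with no detection are ignored; if every column fails the frame
#' carries no surface and NA is returned.
#'
#' @param bscan a \code{bscan}.
#' @param threshold absolute intensity threshold (> 0), or NULL to estimate
#'   from the top 5% of rows (assumed to be background): mean + 5 sd,
#'   floored at 1e-6.
#' @return mu in (0, 1), or NA_real_ when no surface is detected.
#' @export
compute_nsd <- function(bscan, threshold = NULL) {
  r <- surface_rows(bscan$pixels, threshold)
  if (all(is.na(r))) return(NA_real_)
  h_tis <- min(r, na.rm = TRUE) * bscan$alpha_res[2]
  1 - h_tis / bscan$H_OCT
}

# per-column 0-based surface row indices (NA where no pixel >= threshold)
surface_rows <- function(pixels, threshold = NULL) {
  if (is.null(threshold)) {
    top <- pixels[seq_len(max(1L, floor(nrow(pixels) * 0.05))), , drop = FALSE]
    threshold <- max(mean(top) + 5 * stats::sd(as.numeric(top)), 1e-6,
                     na.rm = TRUE)
  }
  if (threshold <= 0) {
    stop_roct("surface detection threshold must be positive",
              "roct_constraint_error")
  }
  hit <- pixels >= threshold
  r <- apply(hit, 2, function(col) which(col)[1])
  as.numeric(r) - 1
}

#' One controller step
#'
#' @param mu measured NSD in [0, 1].
#' @param state an \code{nsd_controller}.
#' @return list(v_z = commanded velocity mm/s, state = updated controller).
#' @export
nsd_velocity <- function(mu, state) {
  if (!is.finite(mu) || mu < 0 || mu > 1) {
    stop_roct("nsd_velocity: mu must lie in [0,1]", "roct_constraint_error")
  }
  v <- state$w_s * state$K_p * (state$mu_ref - mu) +
    (1 - state$w_s) * state$v_prev
  state$v_prev <- v
  list(v_z = v, state = state)
}

#' Landing motion
#'
#' Descends vertically at v_land from the given pose, synthesizing one
#' B-scan per 1/fps step, until the measured NSD reaches cfg$mu_land.
#' Orientation is unchanged. Termination is checked after each step, so a
#' one-step overshoot of at most v_land / (fps * H_OCT) in NSD is possible.
#'
#' @param sample a \code{virtual_sample}.
#' @param pose0 starting \code{probe_pose} (probe above the sample).
#' @param cfg a \code{scan_config}.
#' @return list(pose = terminal pose, mu = terminal NSD, steps = frames
#'   used). Raises a \code{roct_landing_abort} error if the travel limit is
#'   exceeded without surface detection.
#' @export
land_probe <- function(sample, pose0, cfg) {
  dt <- 1 / cfg$fps
  a <- cfg_alpha(cfg)
  pose <- pose0
  travelled <- 0
  step <- 0L
  repeat {
    b <- synthesize_bscan(sample, pose, cfg$W_px, cfg$H_px, a,
                          seed = sample$noise$seed + step)
    mu <- compute_nsd(b, cfg$surface_threshold)
    if (!is.na(mu) && mu >= cfg$mu_land) {
      return(list(pose = pose, mu = mu, steps = step))
    }
    if (travelled >= cfg$max_travel) {
      stop_roct("land_probe: travel limit exceeded without surface detection",
                "roct_landing_abort")
    }
    T <- pose$T
    T[3, 4] <- T[3, 4] - cfg$v_land * dt
    pose <- probe_pose(T, pose$timestamp + dt)
    travelled <- travelled + cfg$v_land * dt
    step <- step + 1L
  }
}

#' Simulate one scanline with closed-loop altitude regulation
#'
#' Starting from a landed pose, advances the probe along +x at v_x,
#' capturing a B-scan every 1/fps and applying one NSD-controller step per
#' frame to the probe altitude. Emits exactly ceil(L * fps / v_x) frames.
#' If a frame has no detectable surface the altitude is held and a warning
#' logged.
#'
#' @param sample a \code{virtual_sample}.
#' @param pose0 landed starting \code{probe_pose}.
#' @param plan a \code{scan_plan} (provides L).
#' @param cfg a \code{scan_config}.
#' @param ctrl an \code{nsd_controller}.
#' @param seed0 base RNG seed offset for per-frame noise.
#' @return list(frames = list of \code{bscan}, mu = per-frame NSD vector,
#'   ctrl = final controller state, pose = final pose).
#' @export
run_scanline <- function(sample, pose0, plan, cfg,
                         ctrl = nsd_controller(), seed0 = 0L) {
  dt <- 1 / cfg$fps
  a <- cfg_alpha(cfg)
  n_frames <- as.integer(ceiling(plan$L * cfg$fps / cfg$v_x))
  frames <- vector("list", n_frames)
  mus <- numeric(n_frames)
  pose <- pose0
  for (f in seq_len(n_frames)) {
    b <- synthesize_bscan(sample, pose, cfg$W_px, cfg$H_px, a,
                          seed = sample$noise$seed + seed0 + f)
    frames[[f]] <- b
    mu <- compute_nsd(b, cfg$surface_threshold)
    mus[f] <- mu
    if (is.na(mu)) {
      warning("run_scanline: no surface in frame ", f, "; holding altitude")
      v_z <- 0
    } else {
      stp <- nsd_velocity(mu, ctrl)
      v_z <- stp$v_z
      ctrl <- stp$state
    }
    T <- pose$T
    T[1, 4] <- T[1, 4] + cfg$v_x * dt
    T[3, 4] <- T[3, 4] - v_z * dt
    pose <- probe_pose(T, pose$timestamp + dt)
  }
  list(frames = frames, mu = mus, ctrl = ctrl, pose = pose)
}

#' Run a full raster scan
#'
#' For each scanline i = 1..n: position at the entry pose, land, then run
#' the closed-loop scanline. Returns the acquisition log consumed by the
#' map-building stage.
#'
#' @param sample a \code{virtual_sample}.
#' @param plan a \code{scan_plan}.
#' @param cfg a \code{scan_config}.
#' @param ctrl controller template (fresh state per scanline).
#' @return An \code{oct_log}: list(frames = list of \code{bscan},
#'   scanline = integer index per frame, mu = NSD per frame, plan, cfg).
#' @export
run_scan <- function(sample, plan, cfg = scan_config(),
                     ctrl = nsd_controller()) {
  frames <- list()
  scanline <- integer(0)
  mus <- numeric(0)
  t0 <- 0
  for (i in seq_len(plan$n)) {
    ep <- entry_pose(i, plan, timestamp = t0)
    landed <- land_probe(sample, ep, cfg)
    c0 <- nsd_controller(ctrl$mu_ref, ctrl$K_p, ctrl$w_s, v_prev = 0)
    sl <- run_scanline(sample, landed$pose, plan, cfg, c0,
                       seed0 = i * 1000000L)
    frames <- c(frames, sl$frames)
    scanline <- c(scanline, rep.int(i, length(sl$frames)))
    mus <- c(mus, sl$mu)
    t0 <- sl$pose$timestamp + 1
  }
  oct_log(frames, scanline, mus, plan, cfg)
}

#' Acquisition log container
#'
#' @param frames list of \code{bscan}s in acquisition order.
#' @param scanline integer scanline index per frame.
#' @param mu per-frame NSD (NA allowed).
#' @param plan,cfg the plan/config used (may be NULL for loaded logs).
#' @return An object of class \code{oct_log}.
#' @export
oct_log <- function(frames, scanline = rep.int(1L, length(frames)),
                    mu = rep(NA_real_, length(frames)), plan = NULL,
                    cfg = NULL) {
  if (length(frames) == 0) {
    stop_roct("oct_log: empty frame list", "roct_empty_input")
  }
  if (length(scanline) != length(frames)) {
    stop_roct("oct_log: scanline index length mismatch",
              "roct_count_mismatch")
  }
  structure(list(frames = frames, scanline = as.integer(scanline),
                 mu = mu, plan = plan, cfg = cfg),
            class = "oct_log")
}

#' @export
print.oct_log <- function(x, ...) {
  cat(sprintf("<oct_log> %d frames over %d scanline(s)\n",
              length(x$frames), length(unique(x$scanline))))
  invisible(x)
}
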