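#' Velocity sweep specification
#'
#' @param v0 baseline scan speed, mm/s.
#' @param v_list strictly increasing velocities >= v0; default 0.6 to 5.1
#'   mm/s in steps of 0.5 (10 points).
#' @param fps fixed frame rate, frames/s.
#' @param n0 baseline frame count (optional bookkeeping).
#' @return An object of class \code{sweep_spec}.
#' @export
sweep_spec <- function(v0 = 0.6, v_list = seq(0.6, 5.1, by = 0.5),
                       fps = 20, n0 = NULL) {
  if (v0 <= 0 || any(v_list < v0)) {
    stop_roct("sweep_spec: need all velocities >= v0 > 0",
              "roct_constraint_error")
  }
  if (any(diff(v_list) <= 0)) {
    stop_roct("sweep_spec: v_list must be strictly increasing",
              "roct_constraint_error")
  }
  structure(list(v0 = v0, v_list = v_list, fps = fps, n0 = n0),
            class = "sweep_spec")
}

#' Frame count after a velocity change
#'
#' Same trajectory and frame rate at a higher speed v yields
#' floor(n0 * v0 / v) frames.
#'
#' @param n0 baseline frame count at speed v0.
#' @param v0 baseline speed, mm/s.
#' @param v target speed, mm/s (>= v0; decimation only).
#' @param fps frame rate (unused in the count; kept for the interface).
#' @return Integer frame count.
#' @export
frames_at_velocity <- function(n0, v0, v, fps = 20) {
  if (v < v0 || v0 <= 0) {
    stop_roct("frames_at_velocity: need v >= v0 > 0",
              "roct_constraint_error")
  }
  as.integer(floor(n0 * v0 / v))
}

#' Decimate an acquisition log to emulate a faster scan
#'
#' Per scanline, frames are retained at a fractional stride v/v0 with an
#' accumulator starting at frame 0 (so v/v0 = 2 keeps every other frame
#' starting with the first). Retained frame poses are untouched: the same
#' trajectory sampled more coarsely.
#'
#' @param log an \code{oct_log}.
#' @param v0 baseline speed, mm/s.
#' @param v emulated speed, mm/s (>= v0).
#' @return A decimated \code{oct_log}.
#' @export
decimate_log <- function(log, v0, v) {
  if (v < v0) {
    stop_roct("decimate_log: v must be >= v0", "roct_constraint_error")
  }
  stride <- v / v0
  keep <- logical(length(log$frames))
  for (i in unique(log$scanline)) {
    idx <- which(log$scanline == i)
    pos <- seq(0, length(idx) - 1e-9, by = stride)
    keep[idx[unique(floor(pos)) + 1]] <- TRUE
  }
  oct_log(log$frames[keep], log$scanline[keep], log$mu[keep],
          log$plan, log$cfg)
}

#' Map-quality degradation over a velocity sweep
#'
#' For each velocity: decimate the log, rebuild the map, resize it back to
#' the baseline geometry by nearest-neighbour replication along the
#' elevational axis (so decimation artifacts are measured, not smoothed
#' away), and score it with mean local structural similarity against the
#' baseline map. With \code{normalize = TRUE} the curve is divided by its
#' value at v0, pinning the baseline point to 1.
#'
#' @param map_builder function(log) -> \code{parameter_map} (e.g.
#'   \code{build_atcm}).
#' @param log full-resolution \code{oct_log}.
#' @param spec a \code{sweep_spec}.
#' @param normalize divide by the v0 score (default TRUE).
#' @param window SSIM window.
#' @return A \code{quality_curve}: data.frame(velocity, n_frames, quality).
#' @export
quality_curve <- function(map_builder, log, spec = sweep_spec(),
                          normalize = TRUE, window = 7) {
  base_map <- map_builder(log)
  base_grid <- base_map$grid
  base_grid[!base_map$validity] <- 0
  rng <- diff(range(base_grid))
  n <- length(spec$v_list)
  qual <- numeric(n)
  nfr <- integer(n)
  for (s in seq_len(n)) {
    v <- spec$v_list[s]
    dl <- decimate_log(log, spec$v0, v)
    nfr[s] <- length(dl$frames)
    m <- map_builder(dl)
    g <- m$grid
    # irregular retained-frame spacing can leave whole elevational columns
    # unsampled on the regular grid; a decimated scan has fewer columns,
    # not holes, so gap columns take the nearest sampled column
    empty <- colSums(m$validity) == 0
    if (any(empty) && !all(empty)) {
      src <- which(!empty)
      for (j in which(empty)) {
        jn <- src[which.min(abs(src - j))]
        g[, j] <- g[, jn]
        m$validity[, j] <- m$validity[, jn]
      }
    }
    g[!m$validity] <- 0
    g <- .resample_to(g, m, base_map)
    qual[s] <- ssim(base_grid, g, window = window, data_range = rng)
  }
  if (normalize) {
    q0 <- qual[which.min(abs(spec$v_list - spec$v0))]
    if (q0 > 0) qual <- qual / q0
  }
  qual <- pmin(pmax(qual, 0), 1)
  structure(data.frame(velocity = spec$v_list, n_frames = nfr,
                       quality = qual),
            class = c("quality_curve", "data.frame"))
}

# nearest-neighbour resampling of a map grid onto the pixel centres of a
# reference map, using base-frame coordinates (no cumulative index drift)
.resample_to <- function(g, map, ref) {
  ri <- pmin(pmax(round((ref$origin[2] +
                           (seq_len(nrow(ref$grid)) - 1) * ref$res[1] -
                           map$origin[2]) / map$res[1]) + 1, 1), nrow(g))
  ci <- pmin(pmax(round((ref$origin[1] +
                           (seq_len(ncol(ref$grid)) - 1) * ref$res[2] -
                           map$origin[1]) / map$res[2]) + 1, 1), ncol(g))
  g[ri, ci, drop = FALSE]
}
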