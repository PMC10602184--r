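#' En-face parameter map
#'
#' A 2D top-view (x-y plane of \code{{F_base}}) map of one scalar tissue
#' parameter. The grid is stored lateral x elevational:
#' \code{grid[i, j]} covers base-frame
#' y = origin[2] + (i - 1) * res[1], x = origin[1] + (j - 1) * res[2].
#'
#' @param kind one of "DEPM" (surface altitude, mm), "ATCM" (extinction,
#'   mm^-1), "DIAM" (lumen diameter, mm).
#' @param grid numeric matrix (lateral rows x elevational cols).
#' @param res c(lateral, elevational) pixel pitch, mm.
#' @param origin base-frame c(x, y) of pixel (1, 1), mm.
#' @param validity logical matrix, same shape: TRUE where data present.
#' @param units value units string.
#' @return An object of class \code{parameter_map}.
#' @export
parameter_map <- function(kind, grid, res, origin,
                          validity = is.finite(grid),
                          units = c(DEPM = "mm", ATCM = "1/mm",
                                    DIAM = "mm")[[kind]]) {
  kind <- match.arg(kind, c("DEPM", "ATCM", "DIAM"))
  grid <- as.matrix(grid)
  if (!all(dim(validity) == dim(grid))) {
    stop_roct("parameter_map: grid/validity shape mismatch",
              "roct_invalid_map")
  }
  if (any(res <= 0)) {
    stop_roct("parameter_map: res must be positive", "roct_invalid_map")
  }
  if (kind == "ATCM" && any(grid[validity] < 0, na.rm = TRUE)) {
    stop_roct("parameter_map: negative extinction values",
              "roct_invalid_map")
  }
  structure(list(kind = kind, grid = grid, res = as.numeric(res),
                 origin = as.numeric(origin), validity = validity,
                 units = units),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map %s> %d x %d px (lat x elev), %.3g%% valid, res = %.4g x %.4g mm\n",
              x$kind, nrow(x$grid), ncol(x$grid),
              100 * mean(x$validity), x$res[1], x$res[2]))
  invisible(x)
}

#' @export
plot.parameter_map <- function(x, ...) {
  g <- x$grid
  g[!x$validity] <- NA
  xs <- x$origin[1] + (seq_len(ncol(g)) - 1) * x$res[2]
  ys <- x$origin[2] + (seq_len(nrow(g)) - 1) * x$res[1]
  graphics::image(xs, ys, t(g), xlab = "x (mm)", ylab = "y (mm)",
                  main = x$kind, useRaster = TRUE, ...)
  invisible(x)
}

#' Per-column surface depth of a B-scan
#'
#' @param bscan a \code{bscan}.
#' @param threshold intensity threshold (NULL = per-frame estimate, see
#'   \code{\link{compute_nsd}}).
#' @return list(depth_mm = per-column depth below the image top (NA where
#'   none), row = 0-based surface row, valid = logical).
#' @export
extract_surface_depth <- function(bscan, threshold = NULL) {
  r <- surface_rows(bscan$pixels, threshold)
  list(depth_mm = r * bscan$alpha_res[2], row = r, valid = !is.na(r))
}

# shared scaffolding: per-scanline scatter -> gridded map.
# pts: data.frame(x, y, value); res c(lat, elev)
.grid_map <- function(pts, kind, res) {
  ymin <- min(pts$y); xmin <- min(pts$x)
  i <- round((pts$y - ymin) / res[1]) + 1
  j <- round((pts$x - xmin) / res[2]) + 1
  ni <- max(i); nj <- max(j)
  lin <- i + ni * (j - 1)
  sums <- rowsum(pts$value, lin)
  cnts <- rowsum(rep(1, length(lin)), lin)
  g <- matrix(NA_real_, ni, nj)
  g[as.integer(rownames(sums))] <- sums / cnts
  parameter_map(kind, g, res, c(xmin, ymin), validity = !is.na(g))
}

# elevational pixel pitch of a set of frames: mean |delta x| of the pose
# log (exact for fractional-stride decimated logs, where the median of the
# alternating integer spacings would drift), falling back to the stated
# alpha_res component
.elev_pitch <- function(frames) {
  xs <- vapply(frames, function(b) b$pose$T[1, 4], numeric(1))
  dx <- abs(diff(xs))
  dx <- dx[dx > 1e-12]
  if (length(dx) == 0) frames[[1]]$alpha_res[3] else mean(dx)
}

#' Build the depth-encoded map (DEPM)
#'
#' For every frame and A-scan column the detected surface pixel is mapped
#' through the frame's pose into \code{{F_base}}; the map stores the
#' absolute surface altitude (base-frame z) per en-face pixel, so probe
#' altitude motion is compensated by construction. Multi-scanline logs are
#' assembled per scanline and stitched.
#'
#' @param log an \code{oct_log}.
#' @param threshold surface threshold (NULL = per-frame estimate).
#' @return A \code{parameter_map} of kind "DEPM".
#' @export
build_depm <- function(log, threshold = NULL) {
  .build_per_scanline(log, function(frames) {
    pts <- lapply(frames, function(b) {
      sd <- extract_surface_depth(b, threshold)
      jj <- which(sd$valid) - 1
      if (length(jj) == 0) return(NULL)
      p <- pixel_to_base(jj, sd$row[jj + 1], b)
      data.frame(x = p[, 1], y = p[, 2], value = p[, 3])
    })
    pts <- do.call(rbind, pts)
    if (is.null(pts) || nrow(pts) == 0) {
      stop_roct("build_depm: no surface detected anywhere",
                "roct_empty_input")
    }
    .grid_map(pts, "DEPM", c(frames[[1]]$alpha_res[1],
                             .elev_pitch(frames)))
  })
}

#' Fit the single-scattering model to one A-scan
#'
#' Ordinary least squares on ln I(z) = c - 2 mu_t z over a depth window
#' anchored 2 pixels below the detected surface (skipping the specular
#' peak). Non-positive intensities are floored to the smallest positive
#' double before the log. Negative slopes map to mu_t >= 0; a negative
#' fitted mu_t is clamped to 0 and the fit flagged. Fits with r^2 < 0.2
#' are flagged invalid.
#'
#' @param a_scan intensity vector (one column, top to bottom).
#' @param surface_row 0-based detected surface row.
#' @param window_mm depth window length below the surface, mm.
#' @param alpha_ax axial pitch, mm/px.
#' @param skip_px pixels skipped below the surface (default 2).
#' @param r2_min minimum r^2 for a valid fit.
#' @return list(mu_t, r2, valid, window = c(z_start, z_end) mm).
#' @export
fit_extinction <- function(a_scan, surface_row, window_mm = 1,
                           alpha_ax, skip_px = 2, r2_min = 0.2) {
  n <- length(a_scan)
  k0 <- surface_row + skip_px
  k1 <- min(k0 + round(window_mm / alpha_ax) - 1, n - 1)
  if (k1 >= n || k0 < 0 || (k1 - k0 + 1) < 4) {
    return(list(mu_t = NA_real_, r2 = NA_real_, valid = FALSE,
                window = c(NA_real_, NA_real_)))
  }
  z <- ((k0:k1) - surface_row) * alpha_ax
  I <- pmax(a_scan[(k0:k1) + 1], .Machine$double.xmin)
  y <- log(I)
  zc <- z - mean(z)
  slope <- sum(zc * (y - mean(y))) / sum(zc^2)
  fitted <- mean(y) + slope * zc
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-20) 1 else 1 - ss_res / ss_tot
  mu <- -slope / 2
  clamped <- mu < 0
  if (clamped) mu <- 0
  list(mu_t = mu, r2 = r2, valid = (r2 >= r2_min) && !clamped,
       window = c(z[1], z[length(z)]))
}

#' Build the attenuation-coefficient map (ATCM)
#'
#' Each A-scan of every frame is compressed to its fitted extinction
#' coefficient; the 1D vectors are placed at their pose-resolved en-face
#' coordinates. Columns with no surface or an invalid fit are left invalid.
#'
#' @param log an \code{oct_log}.
#' @param window_mm fit window below the surface, mm (default 1).
#' @param threshold surface threshold (NULL = per-frame estimate).
#' @return A \code{parameter_map} of kind "ATCM".
#' @export
build_atcm <- function(log, window_mm = 1, threshold = NULL) {
  .build_per_scanline(log, function(frames) {
    a_ax <- frames[[1]]$alpha_res[2]
    pts <- lapply(frames, function(b) {
      sd <- extract_surface_depth(b, threshold)
      jj <- which(sd$valid)
      if (length(jj) == 0) return(NULL)
      mu <- vapply(jj, function(j) {
        ft <- fit_extinction(b$pixels[, j], sd$row[j], window_mm, a_ax)
        if (ft$valid) ft$mu_t else NA_real_
      }, numeric(1))
      ok <- !is.na(mu)
      if (!any(ok)) return(NULL)
      p <- pixel_to_base(jj[ok] - 1, sd$row[jj[ok]], b)
      data.frame(x = p[, 1], y = p[, 2], value = mu[ok])
    })
    pts <- do.call(rbind, pts)
    if (is.null(pts) || nrow(pts) == 0) {
      stop_roct("build_atcm: no valid fits", "roct_empty_input")
    }
    .grid_map(pts, "ATCM", c(frames[[1]]$alpha_res[1],
                             .elev_pitch(frames)))
  })
}

# build one map per scanline and stitch
.build_per_scanline <- function(log, builder) {
  ids <- unique(log$scanline)
  maps <- lapply(ids, function(i) builder(log$frames[log$scanline == i]))
  if (length(maps) == 1) maps[[1]] else stitch(maps)
}

#' Build the lumen-diameter map (DIAM)
#'
#' The top-view projection of the binary mask volume is divided into a
#' k x k grid; within each grid cell the diameters of the lumen
#' measurements whose centroids fall inside are averaged; the k x k grid is
#' then upsampled to the projection size by bicubic interpolation. Cells
#' containing no lumen are invalid (not zero); before interpolation they
#' are filled from the nearest valid cell and masked back afterwards.
#'
#' @param mask_vol a \code{mask_volume} (see
#'   \code{\link{build_mask_volume}}).
#' @param measurements data.frame of lumen measurements with columns
#'   \code{centroid_x_mm}, \code{centroid_y_mm}, \code{diameter_mm}.
#' @param k grid subdivision (default 10, both axes).
#' @return A \code{parameter_map} of kind "DIAM" at the projection
#'   resolution, plus attribute \code{grid_k} holding the k x k cell means.
#' @export
build_diam <- function(mask_vol, measurements, k = 10) {
  vox <- mask_vol$voxels
  d <- dim(vox)
  n_elev <- d[1]; n_lat <- d[2]   # volume axes: (x, y, z)
  if (k > n_elev || k > n_lat) {
    stop_roct("build_diam: k exceeds the projection size",
              "roct_constraint_error")
  }
  res <- c(mask_vol$voxel_size[2], mask_vol$voxel_size[1])
  origin <- mask_vol$origin[1:2]
  cell <- matrix(NA_real_, k, k)   # lat x elev cells
  if (nrow(measurements) > 0) {
    iy <- pmin(pmax(ceiling((measurements$centroid_y_mm - origin[2]) /
                              (n_lat * res[1]) * k), 1), k)
    ix <- pmin(pmax(ceiling((measurements$centroid_x_mm - origin[1]) /
                              (n_elev * res[2]) * k), 1), k)
    lin <- iy + k * (ix - 1)
    sums <- rowsum(measurements$diameter_mm, lin)
    cnts <- rowsum(rep(1, length(lin)), lin)
    cell[as.integer(rownames(sums))] <- sums / cnts
  }
  filled <- .fill_nearest(cell)
  up <- bicubic_resize(filled, c(n_lat, n_elev))
  # validity: projection pixels whose k-cell had data
  vi <- pmin(floor((seq_len(n_lat) - 0.5) / n_lat * k) + 1, k)
  vj <- pmin(floor((seq_len(n_elev) - 0.5) / n_elev * k) + 1, k)
  valid <- !is.na(cell)[vi, vj, drop = FALSE]
  up[!valid] <- NA_real_
  m <- parameter_map("DIAM", up, res, origin, validity = valid)
  attr(m, "grid_k") <- cell
  m
}

# replace NA cells by the value of the nearest (Euclidean, cell units)
# non-NA cell
.fill_nearest <- function(m) {
  nas <- which(is.na(m), arr.ind = TRUE)
  ok <- which(!is.na(m), arr.ind = TRUE)
  if (nrow(nas) == 0 || nrow(ok) == 0) {
    if (nrow(ok) == 0) m[] <- 0
    return(m)
  }
  for (t in seq_len(nrow(nas))) {
    d2 <- (ok[, 1] - nas[t, 1])^2 + (ok[, 2] - nas[t, 2])^2
    m[nas[t, 1], nas[t, 2]] <- m[ok[which.min(d2), , drop = FALSE]]
  }
  m
}

#' Stitch per-scanline parameter maps
#'
#' Maps are placed on a common grid by their base-frame origins; pixels
#' covered by several maps take the unweighted mean of the valid
#' contributors, pixels covered by one are copied, validity is the union.
#' Commutative and associative by construction (running sum + count).
#'
#' @param maps list of \code{parameter_map}s of identical kind and
#'   resolution.
#' @return A \code{parameter_map}.
#' @export
stitch <- function(maps) {
  if (length(maps) == 0) {
    stop_roct("stitch: no maps", "roct_empty_input")
  }
  kinds <- unique(vapply(maps, `[[`, "", "kind"))
  if (length(kinds) != 1) {
    stop_roct("stitch: mixed map kinds", "roct_invalid_input")
  }
  res <- maps[[1]]$res
  for (m in maps) {
    if (max(abs(m$res - res)) > 1e-9) {
      stop_roct("stitch: mixed resolutions", "roct_invalid_input")
    }
  }
  ox <- min(vapply(maps, function(m) m$origin[1], numeric(1)))
  oy <- min(vapply(maps, function(m) m$origin[2], numeric(1)))
  ni <- max(vapply(maps, function(m) {
    round((m$origin[2] - oy) / res[1]) + nrow(m$grid)
  }, numeric(1)))
  nj <- max(vapply(maps, function(m) {
    round((m$origin[1] - ox) / res[2]) + ncol(m$grid)
  }, numeric(1)))
  sums <- matrix(0, ni, nj)
  cnts <- matrix(0, ni, nj)
  for (m in maps) {
    di <- round((m$origin[2] - oy) / res[1])
    dj <- round((m$origin[1] - ox) / res[2])
    ii <- seq_len(nrow(m$grid)) + di
    jj <- seq_len(ncol(m$grid)) + dj
    v <- m$validity
    g <- m$grid
    g[!v] <- 0
    sums[ii, jj] <- sums[ii, jj] + g
    cnts[ii, jj] <- cnts[ii, jj] + v
  }
  grid <- matrix(NA_real_, ni, nj)
  hit <- cnts > 0
  grid[hit] <- sums[hit] / cnts[hit]
  parameter_map(kinds, grid, res, c(ox, oy), validity = hit,
                units = maps[[1]]$units)
}
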