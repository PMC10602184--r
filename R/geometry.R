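#' Rigid probe pose
#'
#' A timestamped rigid-body transform from the OCT probe frame \code{{F_OCT}}
#' to the robot base frame \code{{F_base}}. The probe frame convention is:
#' x = elevational (scan travel), y = lateral (B-scan width), z = axial
#' (into the tissue). The base frame is x = scanline travel, y = lateral
#' stepping between scanlines, z = up.
#'
#' @param T 4x4 homogeneous transform; rotation block must be orthonormal
#'   with determinant +1, translation in mm.
#' @param timestamp acquisition time in seconds (non-negative).
#' @return An object of class \code{probe_pose}.
#' @export
probe_pose <- function(T, timestamp = 0) {
  T <- as.matrix(T)
  if (!all(dim(T) == c(4L, 4L))) {
    stop_roct("probe_pose: T must be a 4x4 matrix", "roct_invalid_pose")
  }
  R <- T[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
    stop_roct("probe_pose: rotation block is not a proper rotation",
              "roct_invalid_pose")
  }
  if (any(abs(T[4, ] - c(0, 0, 0, 1)) > 1e-12)) {
    stop_roct("probe_pose: last row must be (0,0,0,1)", "roct_invalid_pose")
  }
  if (!is.finite(timestamp) || timestamp < 0) {
    stop_roct("probe_pose: timestamp must be non-negative",
              "roct_invalid_pose")
  }
  structure(list(T = T, timestamp = as.numeric(timestamp)),
            class = "probe_pose")
}

#' Build a pose from rotation and translation
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (mm).
#' @param timestamp seconds.
#' @return A \code{probe_pose}.
#' @export
pose_rt <- function(R = diag(3), t = c(0, 0, 0), timestamp = 0) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  probe_pose(T, timestamp)
}

#' @export
print.probe_pose <- function(x, ...) {
  cat("<probe_pose> t =", format(x$timestamp), "s, translation =",
      paste(signif(x$T[1:3, 4], 6), collapse = ", "), "mm\n")
  invisible(x)
}

#' A single OCT B-scan
#'
#' One 2D intensity image, stored as a matrix with axial rows and lateral
#' columns (\code{pixels[k + 1, j + 1]} is axial index k, lateral index j,
#' both 0-based in the coordinate conventions), together with its per-axis
#' pixel pitch and the probe pose at acquisition time.
#'
#' @param pixels numeric matrix, H_px x W_px, non-negative intensities.
#' @param alpha_res length-3 pixel pitch in mm/pixel: (lateral, axial,
#'   elevational).
#' @param pose a \code{probe_pose}.
#' @return An object of class \code{bscan} with fields \code{pixels},
#'   \code{alpha_res}, \code{pose}, and convenience fields \code{W_px},
#'   \code{H_px}, \code{W_OCT}, \code{H_OCT} (physical FOV, mm).
#' @export
bscan <- function(pixels, alpha_res, pose) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1 || ncol(pixels) < 1) {
    stop_roct("bscan: empty image", "roct_invalid_bscan")
  }
  if (any(pixels < 0)) {
    stop_roct("bscan: negative intensities", "roct_invalid_bscan")
  }
  alpha_res <- as.numeric(alpha_res)
  if (length(alpha_res) != 3 || any(!is.finite(alpha_res)) ||
      any(alpha_res <= 0)) {
    stop_roct("bscan: alpha_res must be three positive pitches",
              "roct_invalid_bscan")
  }
  if (!inherits(pose, "probe_pose")) {
    stop_roct("bscan: pose must be a probe_pose", "roct_invalid_bscan")
  }
  structure(list(
    pixels = pixels,
    alpha_res = alpha_res,
    pose = pose,
    W_px = ncol(pixels),
    H_px = nrow(pixels),
    W_OCT = ncol(pixels) * alpha_res[1],
    H_OCT = nrow(pixels) * alpha_res[2]
  ), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d x %d px (axial x lateral), FOV %.3g x %.3g mm\n",
              x$H_px, x$W_px, x$H_OCT, x$W_OCT))
  invisible(x)
}

#' Transform B-scan pixel indices to base-frame coordinates
#'
#' Maps pixel (j, k) of a B-scan into \code{{F_base}} via
#' p_base = T (p_OCT * alpha_res). The image origin sits at the top centre
#' of the B-scan: the probe-frame point of pixel (j, k) is
#' (0, (j - W_px/2) * alpha_lat, k * alpha_ax).
#'
#' @param j lateral pixel index (0-based), vectorised.
#' @param k axial pixel index (0-based), vectorised (recycled with j).
#' @param bscan a \code{bscan}.
#' @return n x 3 matrix of base-frame coordinates in mm.
#' @export
pixel_to_base <- function(j, k, bscan) {
  n <- max(length(j), length(k))
  j <- rep_len(as.numeric(j), n)
  k <- rep_len(as.numeric(k), n)
  if (any(j < 0) || any(j >= bscan$W_px) || any(k < 0) ||
      any(k >= bscan$H_px)) {
    stop_roct("pixel_to_base: pixel index out of range", "roct_out_of_range")
  }
  a <- bscan$alpha_res
  p_oct <- cbind(0, (j - bscan$W_px / 2) * a[1], k * a[2], 1)
  out <- p_oct %*% t(bscan$pose$T)
  out[, 1:3, drop = FALSE]
}

#' Voxelized tissue volume
#'
#' @param voxels 3D array indexed (x, y, z) in base-frame axis order;
#'   untouched voxels are NA (the explicit empty marker).
#' @param voxel_size length-3 voxel pitch (mm).
#' @param origin base-frame coordinate (mm) of the corner of voxel (1,1,1).
#' @return An object of class \code{tissue_volume}.
#' @export
tissue_volume <- function(voxels, voxel_size, origin) {
  if (any(voxel_size <= 0)) {
    stop_roct("tissue_volume: voxel_size must be positive",
              "roct_invalid_volume")
  }
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "tissue_volume")
}

#' @export
print.tissue_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tissue_volume> %d x %d x %d voxels, %.3g%% occupied\n",
              d[1], d[2], d[3], 100 * mean(!is.na(x$voxels))))
  invisible(x)
}

#' Voxelize a sequence of tracked B-scans
#'
#' Every pixel of every scan is mapped into \code{{F_base}} with
#' \code{pixel_to_base} and binned into a regular voxel grid. A voxel's value
#' is the arithmetic mean of all pixels that fall inside it; voxels no pixel
#' touches are NA. Grid bounds come from the transformed pixel cloud, not a
#' preallocated extent.
#'
#' @param scans list of \code{bscan}s sharing \code{alpha_res}.
#' @param voxel_size length-3 voxel pitch in mm; default \code{alpha_res} of
#'   the first scan.
#' @return A \code{tissue_volume}.
#' @export
voxelize <- function(scans, voxel_size = NULL) {
  if (length(scans) == 0) {
    stop_roct("voxelize: no scans supplied", "roct_empty_input")
  }
  a0 <- scans[[1]]$alpha_res
  for (s in scans) {
    if (max(abs(s$alpha_res - a0)) > 1e-12) {
      stop_roct("voxelize: scans must share alpha_res", "roct_invalid_input")
    }
  }
  if (is.null(voxel_size)) voxel_size <- a0
  voxel_size <- rep_len(as.numeric(voxel_size), 3)

  jj <- rep(seq_len(scans[[1]]$W_px) - 1, each = scans[[1]]$H_px)
  kk <- rep(seq_len(scans[[1]]$H_px) - 1, times = scans[[1]]$W_px)
  pts <- vector("list", length(scans))
  val <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    pts[[i]] <- pixel_to_base(jj, kk, s)
    val[[i]] <- as.numeric(s$pixels)
  }
  pts <- do.call(rbind, pts)
  val <- unlist(val)

  # half-voxel slack so points sitting exactly on the max bound stay inside
  mins <- apply(pts, 2, min)
  idx <- floor(sweep(sweep(pts, 2, mins), 2, voxel_size, "/") + 1e-9) + 1
  dims <- apply(idx, 2, max)
  lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
  sums <- rowsum(val, lin)
  cnts <- rowsum(rep(1, length(lin)), lin)
  vox <- array(NA_real_, dim = dims)
  vox[as.integer(rownames(sums))] <- sums / cnts
  tissue_volume(vox, voxel_size, mins)
}

# internal: classed errors so callers can test on condition class
stop_roct <- function(msg, class) {
  stop(structure(class = c(class, "roct_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
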