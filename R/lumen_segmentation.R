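#' Contrast enhancement of one B-scan slice
#'
#' Contrast-limited adaptive histogram equalization, range-normalized to
#' [0, 1]. A constant slice maps to a constant zero slice.
#'
#' @param slice 2D intensity matrix.
#' @param n_tiles CLAHE tile grid.
#' @param clip_limit histogram clip fraction.
#' @return Matrix in [0, 1].
#' @export
enhance_contrast <- function(slice, n_tiles = c(8, 8), clip_limit = 0.02) {
  if (length(slice) == 0) {
    stop_roct("enhance_contrast: empty slice", "roct_empty_input")
  }
  clahe(slice, n_tiles = n_tiles, clip_limit = clip_limit)
}

#' Segmenter configuration
#'
#' Tuning of the classical intensity/shape lumen segmenter that stands in
#' for a trained network (whose weights are not shipped). Externally
#' computed masks can bypass it entirely, see
#' \code{\link{build_mask_volume}}.
#'
#' @param rel_threshold candidate pixels are darker than
#'   \code{rel_threshold} x the local (per-column, below-surface) tissue
#'   median.
#' @param depth_band c(min, max) depth below the surface (mm) searched for
#'   lumens.
#' @param min_area,max_area component pixel-area gates.
#' @param max_eccentricity reject elongated components above this
#'   (sqrt(1 - (b/a)^2) of the second-moment ellipse).
#' @param exclude_border drop components touching the first/last lateral
#'   column (lumens clipped by the FOV measure short).
#' @param close_area,open_area morphological cleanup areas, px.
#' @return list of class \code{segmenter_config}.
#' @export
segmenter_config <- function(rel_threshold = 0.35,
                             depth_band = c(0.05, 1.2),
                             min_area = 12, max_area = 5000,
                             max_eccentricity = 0.95,
                             exclude_border = TRUE,
                             close_area = 25, open_area = 9) {
  structure(list(rel_threshold = rel_threshold, depth_band = depth_band,
                 min_area = min_area, max_area = max_area,
                 max_eccentricity = max_eccentricity,
                 exclude_border = exclude_border,
                 close_area = close_area, open_area = open_area),
            class = "segmenter_config")
}

#' Segment lumen candidates in one enhanced slice
#'
#' Candidate lumens are connected dark regions lying below the detected
#' surface inside a configured depth band: a pixel is dark when its
#' intensity falls below \code{rel_threshold} times the slice-wide median
#' intensity at the same depth below the surface (which compensates the
#' exponential axial decay). Components are gated on area and
#' eccentricity. Rows above the surface never contribute.
#'
#' @param slice enhanced 2D intensity (axial rows x lateral cols).
#' @param surface_row per-column 0-based surface rows (NA = none), as from
#'   \code{\link{extract_surface_depth}}.
#' @param alpha_ax axial pitch mm/px (for the depth band).
#' @param cfg a \code{segmenter_config}.
#' @return Logical mask of the slice.
#' @export
segment_lumens <- function(slice, surface_row, alpha_ax,
                           cfg = segmenter_config()) {
  H <- nrow(slice); W <- ncol(slice)
  mask <- matrix(FALSE, H, W)
  if (all(is.na(surface_row))) return(mask)
  rows <- matrix(seq_len(H) - 1, H, W)
  surf <- matrix(rep(surface_row, each = H), H, W)
  depth <- (rows - surf) * alpha_ax
  band <- !is.na(depth) & depth >= cfg$depth_band[1] &
    depth <= cfg$depth_band[2]
  if (!any(band)) return(mask)
  # background profile: median intensity per depth-pixel below the surface
  dpx <- round(depth / alpha_ax)
  dpx[!band] <- NA
  bins <- sort(unique(dpx[band]))
  bg <- vapply(bins, function(d) {
    stats::median(slice[which(dpx == d)])
  }, numeric(1))
  bg_px <- matrix(bg[match(dpx, bins)], H, W)
  dark <- band & !is.na(bg_px) & slice < cfg$rel_threshold * bg_px
  dark[is.na(dark)] <- FALSE
  lab <- label_components(dark, 8)
  if (max(lab) == 0) return(mask)
  idx <- which(lab > 0)
  comps <- split(idx, lab[idx])
  for (ci in comps) {
    a <- length(ci)
    if (a < cfg$min_area || a > cfg$max_area) next
    px <- cbind((ci - 1) %% H + 1, (ci - 1) %/% H + 1)
    if (isTRUE(cfg$exclude_border) && (any(px[, 2] == 1) ||
                                       any(px[, 2] == W))) next
    if (a >= 3) {
      cv <- stats::cov(px)
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 1e-12)
      ecc <- sqrt(1 - ev[2] / ev[1])
      if (ecc > cfg$max_eccentricity) next
    }
    mask[ci] <- TRUE
  }
  mask
}

#' Morphological cleanup of a lumen mask
#'
#' Area closing (fill small holes) followed by area opening (drop small
#' specks), exactly in that order.
#'
#' @param mask logical/0-1 matrix.
#' @param close_area hole-fill area threshold, px.
#' @param open_area speck-removal area threshold, px.
#' @return Logical matrix.
#' @export
clean_mask <- function(mask, close_area = 25, open_area = 9) {
  m <- mask != 0
  if (!any(m)) return(m)
  # both operations act inside the foreground bounding box (+1 pad);
  # background beyond it is border-connected and unaffected
  rr <- range(which(rowSums(m) > 0))
  cr <- range(which(colSums(m) > 0))
  r0 <- max(rr[1] - 1, 1); r1 <- min(rr[2] + 1, nrow(m))
  c0 <- max(cr[1] - 1, 1); c1 <- min(cr[2] + 1, ncol(m))
  sub <- m[r0:r1, c0:c1, drop = FALSE]
  m[r0:r1, c0:c1] <- area_opening(area_closing(sub, close_area), open_area)
  m
}

#' Measure lumen diameters in one mask slice
#'
#' Centerline-based: each 8-connected component is skeletonized and its
#' diameter taken as 2 x the mean Euclidean distance-transform value over
#' skeleton pixels; components whose skeleton is empty fall back to 2 x the
#' maximum distance-transform value. A single-pixel component measures
#' 2 x alpha by this convention.
#'
#' @param mask logical/0-1 matrix.
#' @param alpha mm per pixel (isotropic in-slice measurement scale).
#' @param slice_index bookkeeping index stored in the result.
#' @return data.frame, one row per component, ordered by component label:
#'   slice, component, diameter_mm, centerline_px, centroid_row,
#'   centroid_col (pixel units).
#' @export
measure_diameters <- function(mask, alpha = 1, slice_index = 1L) {
  lab <- label_components(mask, 8)
  n <- max(lab)
  empty <- data.frame(slice = integer(0), component = integer(0),
                      diameter_mm = numeric(0), centerline_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  if (n == 0) return(empty)
  H <- nrow(lab)
  idx <- which(lab > 0)
  comps <- split(idx, lab[idx])
  out <- vector("list", n)
  for (id in seq_len(n)) {
    ci <- comps[[id]]
    r <- (ci - 1) %% H + 1
    cc <- (ci - 1) %/% H + 1
    # work on the component's bounding box: EDT/thinning cost stays local
    r0 <- min(r); c0 <- min(cc)
    comp <- matrix(FALSE, max(r) - r0 + 1, max(cc) - c0 + 1)
    comp[cbind(r - r0 + 1, cc - c0 + 1)] <- TRUE
    dt <- distance_transform(comp)
    sk <- skeletonize(comp)
    if (any(sk)) {
      dia <- 2 * mean(dt[sk])
      ncl <- sum(sk)
    } else {
      dia <- 2 * max(dt)
      ncl <- 0L
    }
    out[[id]] <- data.frame(slice = slice_index, component = id,
                            diameter_mm = dia * alpha,
                            centerline_px = ncl,
                            centroid_row = mean(r),
                            centroid_col = mean(cc))
  }
  do.call(rbind, out)
}

#' Mask volume
#'
#' Binary voxel grid aligned with a \code{tissue_volume}.
#'
#' @param voxels 3D 0/1 array (NA allowed for never-touched voxels).
#' @param voxel_size,origin as in \code{\link{tissue_volume}}.
#' @param provenance "internal-segmenter" or "external-masks".
#' @return An object of class \code{mask_volume}.
#' @export
mask_volume <- function(voxels, voxel_size, origin,
                        provenance = "internal-segmenter") {
  vals <- voxels[!is.na(voxels)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop_roct("mask_volume: voxels must be binary", "roct_invalid_volume")
  }
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), provenance = provenance),
            class = "mask_volume")
}

#' Segment a whole acquisition into a lumen mask volume
#'
#' Applies enhance_contrast -> segment_lumens -> clean_mask per frame (or
#' takes externally supplied per-frame masks verbatim), voxelizes the masks
#' with the same poses as the intensity frames, and collects per-slice
#' centerline diameter measurements with base-frame centroids.
#'
#' @param log an \code{oct_log}.
#' @param cfg a \code{segmenter_config}.
#' @param external_masks optional list of logical matrices, one per frame,
#'   bypassing the internal segmenter.
#' @param threshold surface threshold passed to the surface detector.
#' @return list(mask_vol = \code{mask_volume}, measurements = data.frame
#'   with columns slice, component, diameter_mm, diameter_um,
#'   centroid_x_mm, centroid_y_mm, centroid_z_mm).
#' @export
build_mask_volume <- function(log, cfg = segmenter_config(),
                              external_masks = NULL, threshold = NULL) {
  n <- length(log$frames)
  if (!is.null(external_masks) && length(external_masks) != n) {
    stop_roct("build_mask_volume: external mask count mismatch",
              "roct_count_mismatch")
  }
  a_ax <- log$frames[[1]]$alpha_res[2]
  masks <- vector("list", n)
  meas <- vector("list", n)
  for (f in seq_len(n)) {
    b <- log$frames[[f]]
    if (is.null(external_masks)) {
      sd <- extract_surface_depth(b, threshold)
      enh <- enhance_contrast(b$pixels)
      m <- segment_lumens(enh, sd$row, a_ax, cfg)
      m <- clean_mask(m, cfg$close_area, cfg$open_area)
    } else {
      m <- external_masks[[f]] != 0
    }
    masks[[f]] <- m
    mm <- measure_diameters(m, alpha = a_ax, slice_index = f)
    if (nrow(mm) > 0) {
      p <- pixel_to_base(mm$centroid_col - 1, mm$centroid_row - 1, b)
      mm$centroid_x_mm <- p[, 1]
      mm$centroid_y_mm <- p[, 2]
      mm$centroid_z_mm <- p[, 3]
    }
    meas[[f]] <- mm
  }
  mask_scans <- lapply(seq_len(n), function(f) {
    bscan(masks[[f]] * 1, log$frames[[f]]$alpha_res, log$frames[[f]]$pose)
  })
  vol <- voxelize(mask_scans)
  vox <- vol$voxels
  vox[!is.na(vox)] <- as.numeric(vox[!is.na(vox)] >= 0.5)
  mv <- mask_volume(vox, vol$voxel_size, vol$origin,
                    if (is.null(external_masks)) "internal-segmenter"
                    else "external-masks")
  tab <- do.call(rbind, meas)
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- data.frame(slice = integer(0), component = integer(0),
                      diameter_mm = numeric(0), centerline_px = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      centroid_x_mm = numeric(0), centroid_y_mm = numeric(0),
                      centroid_z_mm = numeric(0))
  }
  tab$diameter_um <- tab$diameter_mm * 1000
  list(mask_vol = mv, measurements = tab)
}
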