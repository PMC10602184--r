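#' Virtual sample for the scanning simulator
#'
#' A virtual sample is a height field h(x, y) (surface altitude above the
#' base plane, mm), an extinction field mu_t(x, y, z) (mm^-1), an optional
#' set of tubular low-intensity lumens, a surface reflectance intensity I0
#' and a speckle/background noise model. All spatial arguments are base-frame
#' coordinates in mm.
#'
#' @param height_field vectorised function h(x, y) -> mm.
#' @param extinction_field vectorised function mu_t(x, y, z) -> mm^-1
#'   (z measured as depth below the local surface, >= 0).
#' @param lumens data.frame with one row per tubular lumen: columns
#'   \code{y} (lateral centre, mm), \code{depth} (centre depth below the
#'   surface, mm), \code{radius} (mm), \code{x0}, \code{x1} (elevational
#'   extent, mm), \code{factor} (backscatter intensity multiplier in
#'   [0, 1): fluid-filled lumens image dark) and \code{mu_scale}
#'   (multiplier on the local extinction inside the tube, < 1: lumens
#'   attenuate less than parenchyma). Tubes run along the base-frame x
#'   axis. May be NULL.
#' @param I0 surface reflectance intensity (default 1).
#' @param noise list: \code{speckle_shape} (gamma shape of the unit-mean
#'   multiplicative speckle; Inf disables speckle), \code{background}
#'   (additive background noise scale; 0 disables), \code{seed} (integer).
#' @param ground_truth free-form list of generator ground truth kept for
#'   parameter-recovery tests.
#' @return An object of class \code{virtual_sample}.
#' @export
virtual_sample <- function(height_field, extinction_field, lumens = NULL,
                           I0 = 1,
                           noise = list(speckle_shape = Inf, background = 0,
                                        seed = 0L),
                           ground_truth = list()) {
  stopifnot(is.function(height_field), is.function(extinction_field))
  if (!is.null(lumens)) {
    lumens <- as.data.frame(lumens)
    if (nrow(lumens) > 0 && any(lumens$radius <= 0)) {
      stop_roct("virtual_sample: lumen radius must be positive",
                "roct_invalid_sample")
    }
    if (nrow(lumens) > 0 && is.null(lumens$mu_scale)) {
      lumens$mu_scale <- 0.2
    }
  }
  noise <- utils::modifyList(
    list(speckle_shape = Inf, background = 0, seed = 0L), as.list(noise))
  structure(list(height_field = height_field,
                 extinction_field = extinction_field,
                 lumens = lumens, I0 = I0, noise = noise,
                 ground_truth = ground_truth),
            class = "virtual_sample")
}

#' @export
print.virtual_sample <- function(x, ...) {
  cat("<virtual_sample>",
      if (!is.null(x$lumens)) sprintf("%d lumens,", nrow(x$lumens)) else "",
      sprintf("I0 = %g, speckle shape = %g\n", x$I0, x$noise$speckle_shape))
  invisible(x)
}

#' Perfectly flat sample
#'
#' Uniform extinction, flat surface: the simplest fixture for controller and
#' fit tests.
#'
#' @param height surface altitude (mm).
#' @param mu_t uniform extinction coefficient (mm^-1).
#' @param ... passed to \code{virtual_sample}.
#' @return A \code{virtual_sample}.
#' @export
make_flat_sample <- function(height = 0, mu_t = 2, ...) {
  virtual_sample(
    height_field = function(x, y) rep_len(height, length(x)),
    extinction_field = function(x, y, z) rep_len(mu_t, length(x)),
    ground_truth = list(height = height, mu_t = mu_t), ...)
}

# 3x5 block font used to rasterize letter extrusions; enough glyphs for
# phantom labels.
.roct_font <- list(
  "#" = c("111", "111", "111", "111", "111"),  # solid block, calibration
  A = c("010", "101", "111", "101", "101"),
  C = c("111", "100", "100", "100", "111"),
  E = c("111", "100", "111", "100", "111"),
  H = c("101", "101", "111", "101", "101"),
  I = c("111", "010", "010", "010", "111"),
  K = c("101", "110", "100", "110", "101"),
  L = c("100", "100", "100", "100", "111"),
  N = c("101", "111", "111", "111", "101"),
  O = c("111", "101", "101", "101", "111"),
  R = c("110", "101", "110", "110", "101"),
  S = c("111", "100", "111", "001", "111"),
  T = c("111", "010", "010", "010", "010"),
  U = c("101", "101", "101", "101", "111"),
  X = c("101", "101", "010", "101", "101")
)

#' Letter-extrusion phantom
#'
#' Emulates a 3D-printed calibration phantom: a flat base plate carrying
#' letter-shaped extrusions of a fixed height. Glyphs are rasterized from a
#' 3x5 block font onto a regular grid; the height field is two-valued
#' (0 or \code{extrusion_height}).
#'
#' @param footprint c(width_x, width_y) of the plate in mm (the default
#'   mirrors a 48 mm by 20 mm plate).
#' @param letters character vector of glyphs (A C E H I K L N O R S T U X
#'   supported); eight by default.
#' @param extrusion_height extrusion height in mm (> 0).
#' @param glyph_size c(dx, dy) bounding box of one glyph in mm.
#' @param pitch raster grid pitch in mm.
#' @param margin border between plate edge and the glyph row, mm.
#' @param mu_t uniform extinction coefficient of the printed material
#'   (mm^-1).
#' @param ... passed to \code{virtual_sample} (noise, I0).
#' @return A \code{virtual_sample}; \code{$ground_truth} holds the raster
#'   mask, its grid axes, and per-glyph bounding boxes.
#' @export
make_letter_phantom <- function(footprint = c(48, 20),
                                letters = c("R", "O", "C", "T", "K", "I",
                                            "N", "E"),
                                extrusion_height = 1,
                                glyph_size = NULL, pitch = 0.1,
                                margin = NULL, mu_t = 2, ...) {
  if (length(letters) == 0) {
    stop_roct("make_letter_phantom: empty glyph set", "roct_invalid_sample")
  }
  if (extrusion_height <= 0) {
    stop_roct("make_letter_phantom: extrusion height must be > 0",
              "roct_invalid_sample")
  }
  bad <- setdiff(toupper(letters), names(.roct_font))
  if (length(bad)) {
    stop_roct(paste("make_letter_phantom: unsupported glyphs:",
                    paste(bad, collapse = " ")), "roct_invalid_sample")
  }
  n <- length(letters)
  if (is.null(margin)) margin <- 0.06 * min(footprint)
  if (is.null(glyph_size)) {
    dx <- (footprint[1] - 2 * margin) / n * 0.8
    glyph_size <- c(dx, min(footprint[2] - 2 * margin, dx * 5 / 3))
  }
  gx <- seq(0, footprint[1], by = pitch)
  gy <- seq(0, footprint[2], by = pitch)
  mask <- matrix(FALSE, length(gx), length(gy))
  boxes <- data.frame(letter = toupper(letters), x0 = NA_real_,
                      x1 = NA_real_, y0 = NA_real_, y1 = NA_real_)
  step_x <- (footprint[1] - 2 * margin) / n
  y0 <- (footprint[2] - glyph_size[2]) / 2
  for (g in seq_len(n)) {
    glyph <- .roct_font[[toupper(letters[g])]]
    x0 <- margin + (g - 1) * step_x + (step_x - glyph_size[1]) / 2
    cw <- glyph_size[1] / 3   # cell width, mm
    ch <- glyph_size[2] / 5
    for (r in 1:5) {
      bits <- strsplit(glyph[r], "")[[1]] == "1"
      for (cc in which(bits)) {
        xin <- gx >= x0 + (cc - 1) * cw & gx < x0 + cc * cw
        # font rows listed top-down; map row 1 to the high-y edge
        yin <- gy >= y0 + (5 - r) * ch & gy < y0 + (6 - r) * ch
        mask[xin, yin] <- TRUE
      }
    }
    boxes[g, 2:5] <- c(x0, x0 + glyph_size[1], y0, y0 + glyph_size[2])
  }
  hf <- function(x, y) {
    ix <- pmin(pmax(round(x / pitch) + 1, 1), length(gx))
    iy <- pmin(pmax(round(y / pitch) + 1, 1), length(gy))
    extrusion_height * as.numeric(mask[cbind(ix, iy)])
  }
  virtual_sample(
    height_field = hf,
    extinction_field = function(x, y, z) rep_len(mu_t, length(x)),
    ground_truth = list(mask = mask, grid_x = gx, grid_y = gy,
                        boxes = boxes, extrusion_height = extrusion_height,
                        pitch = pitch, mu_t = mu_t),
    ...)
}

#' Layered kidney-like sample with tubular lumens
#'
#' A synthetic stand-in for near-surface renal anatomy: a smooth surface
#' profile, depth-stratified extinction (e.g. capsule over cortex), and
#' straight tubular lumens of known diameter running along the elevational
#' (x) axis. Ground-truth lumen geometry is retained for parameter-recovery
#' tests.
#'
#' @param footprint c(Lx, Ly) extent in mm.
#' @param surface_profile vectorised function h(x, y) -> mm, default flat 0.
#' @param layer_depths increasing depth breakpoints below the surface (mm);
#'   layer i spans [d_i, d_{i+1}) with the last layer unbounded.
#' @param layer_extinctions extinction per layer, length =
#'   length(layer_depths); all >= 0.
#' @param n_lumens number of random tubes (0 for none).
#' @param lumen_diameter scalar or range (mm) of true tube diameters.
#' @param lumen_depth range of tube centre depths below the surface (mm).
#' @param lumen_factor backscatter multiplier inside a tube, in [0, 1).
#' @param lumen_mu_scale extinction multiplier inside a tube (< 1).
#' @param seed RNG seed for tube placement.
#' @param ... passed to \code{virtual_sample}.
#' @return A \code{virtual_sample}; \code{$lumens} is the ground-truth tube
#'   table (also in \code{$ground_truth$lumens}).
#' @export
make_layered_kidney <- function(footprint = c(10, 8),
                                surface_profile = NULL,
                                layer_depths = c(0, 0.3),
                                layer_extinctions = c(1.2, 2.5),
                                n_lumens = 0,
                                lumen_diameter = c(0.18, 0.3),
                                lumen_depth = c(0.35, 0.8),
                                lumen_factor = 0.05,
                                lumen_mu_scale = 0.2,
                                seed = 0L, ...) {
  if (any(layer_extinctions < 0)) {
    stop_roct("make_layered_kidney: negative extinction",
              "roct_invalid_sample")
  }
  if (length(layer_extinctions) != length(layer_depths)) {
    stop_roct("make_layered_kidney: one extinction per layer required",
              "roct_invalid_sample")
  }
  if (is.null(surface_profile)) {
    surface_profile <- function(x, y) rep_len(0, length(x))
  }
  lum <- NULL
  if (n_lumens > 0) {
    dia <- rep_len(as.numeric(lumen_diameter), 2)
    lum <- withr::with_seed(seed, {
      d <- stats::runif(n_lumens, dia[1], dia[2])
      data.frame(
        y = stats::runif(n_lumens, 0.08 * footprint[2], 0.92 * footprint[2]),
        depth = stats::runif(n_lumens, lumen_depth[1], lumen_depth[2]),
        radius = d / 2,
        x0 = 0, x1 = footprint[1],
        factor = lumen_factor, mu_scale = lumen_mu_scale)
    })
  }
  ef <- function(x, y, z) {
    idx <- findInterval(z, layer_depths, rightmost.closed = FALSE)
    layer_extinctions[pmax(idx, 1)]
  }
  virtual_sample(
    height_field = surface_profile, extinction_field = ef, lumens = lum,
    ground_truth = list(layer_depths = layer_depths,
                        layer_extinctions = layer_extinctions,
                        lumens = lum, footprint = footprint),
    ...)
}

#' Synthesize one B-scan of a virtual sample
#'
#' Forward single-scattering model: each lateral column is an ideal pencil
#' ray along -z of the base frame. Rows above the surface carry only
#' background noise; at and below the surface the intensity is
#' I0 * exp(-2 * integral of mu_t dz), discretized as a per-axial-pixel
#' cumulative sum, multiplied by the lumen intensity factor inside tubes and
#' by unit-mean gamma speckle when enabled. Columns whose surface lies
#' deeper than the axial FOV stay empty; a probe below the surface yields a
#' saturated image flagged with attribute \code{below_surface}.
#'
#' Only nadir-viewing poses (probe axial axis along -z of the base frame,
#' i.e. the entry-pose orientation) are supported by the synthesizer.
#'
#' @param sample a \code{virtual_sample}.
#' @param pose a \code{probe_pose}.
#' @param W_px,H_px image size in pixels (lateral, axial).
#' @param alpha_res length-3 pixel pitch (mm/px).
#' @param seed RNG seed for this frame's noise; default the sample's seed.
#'   Synthesis is deterministic given (sample, pose, seed).
#' @return A \code{bscan}.
#' @export
synthesize_bscan <- function(sample, pose, W_px = 180, H_px = 160,
                             alpha_res = c(0.03, 0.01, 0.03),
                             seed = NULL) {
  if (is.null(seed)) seed <- sample$noise$seed
  a <- alpha_res
  R <- pose$T[1:3, 1:3]
  if (max(abs(R - diag(c(1, -1, -1)))) > 1e-9) {
    stop_roct("synthesize_bscan: only the nadir entry-pose orientation is supported",
              "roct_unsupported_pose")
  }
  tr <- pose$T[1:3, 4]
  j <- seq_len(W_px) - 1
  # base-frame (x, y) of each column; lateral axis is -y under diag(1,-1,-1)
  cx <- rep_len(tr[1], W_px)
  cy <- tr[2] - (j - W_px / 2) * a[1]
  z0 <- tr[3]                        # altitude of the image's top row
  h <- sample$height_field(cx, cy)   # surface altitude per column
  d_surf <- z0 - h                   # optical distance probe -> surface, mm

  img <- matrix(0, H_px, W_px)
  if (all(d_surf < 0)) {
    img[] <- sample$I0
    attr(img, "below_surface") <- TRUE
    b <- bscan(img, a, pose)
    attr(b, "below_surface") <- TRUE
    return(b)
  }

  H_OCT <- H_px * a[2]
  krow <- seq_len(H_px) - 1
  noise <- sample$noise
  vis <- d_surf >= 0 & d_surf < H_OCT        # columns with surface in FOV
  k_surf <- floor(d_surf / a[2])             # 0-based surface row per col
  # depth below the surface for every pixel; < 0 above the surface
  depth <- outer(krow, k_surf, "-") * a[2]
  below <- sweep(depth >= 0, 2, vis, "&")
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    if (noise$background > 0) {
      img[] <- abs(stats::rnorm(H_px * W_px, 0, noise$background))
    }
    if (any(below)) {
      cxm <- matrix(cx, H_px, W_px, byrow = TRUE)
      cym <- matrix(cy, H_px, W_px, byrow = TRUE)
      mu <- matrix(0, H_px, W_px)
      mu[below] <- sample$extinction_field(cxm[below], cym[below],
                                           depth[below])
      lum_factor <- matrix(1, H_px, W_px)
      if (!is.null(sample$lumens) && nrow(sample$lumens) > 0) {
        for (li in seq_len(nrow(sample$lumens))) {
          L <- sample$lumens[li, ]
          dy <- cy - L$y
          hit <- vis & cx >= L$x0 & cx <= L$x1 & abs(dy) < L$radius
          if (!any(hit)) next
          half <- rep(0, W_px)
          half[hit] <- sqrt(L$radius^2 - dy[hit]^2)
          lo <- matrix(L$depth - half, H_px, W_px, byrow = TRUE)
          hi <- matrix(L$depth + half, H_px, W_px, byrow = TRUE)
          inside <- below & depth > lo & depth < hi &
            matrix(hit, H_px, W_px, byrow = TRUE)
          mu[inside] <- mu[inside] * L$mu_scale
          lum_factor[inside] <- pmin(lum_factor[inside], L$factor)
        }
      }
      # per-pixel cumulative attenuation; the surface pixel is unattenuated
      csum <- apply(mu, 2, cumsum)
      sig <- sample$I0 * exp(-2 * a[2] * (csum - mu)) * lum_factor
      if (is.finite(noise$speckle_shape)) {
        spk <- matrix(stats::rgamma(H_px * W_px,
                                    shape = noise$speckle_shape,
                                    rate = noise$speckle_shape),
                      H_px, W_px)
        sig <- sig * spk
      }
      img[below] <- img[below] + sig[below]
    }
  })
  bscan(img, a, pose)
}
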