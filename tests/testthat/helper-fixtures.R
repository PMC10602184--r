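# Shared fixtures and brute-force oracles. Everything is generated in code;
# no binary fixtures on disk.

# desk-scale acquisition defaults used across tests (H_OCT = 1.6 mm)
desk_cfg <- function(...) scan_config(...)

# a random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force voxelization oracle: per-bin means by an explicit loop
oracle_voxelize <- function(scans, voxel_size) {
  pts <- list(); val <- c()
  for (s in scans) {
    for (j in seq_len(s$W_px) - 1) {
      for (k in seq_len(s$H_px) - 1) {
        pts[[length(pts) + 1]] <- pixel_to_base(j, k, s)
        val <- c(val, s$pixels[k + 1, j + 1])
      }
    }
  }
  pts <- do.call(rbind, pts)
  mins <- apply(pts, 2, min)
  key <- apply(floor(sweep(sweep(pts, 2, mins), 2, voxel_size, "/") + 1e-9),
               1, paste, collapse = ",")
  vapply(split(val, key), mean, numeric(1))
}

# brute-force maximum-inscribed-circle oracle: for every foreground pixel,
# its distance to the nearest background pixel (image border counts as
# background); the radius is the maximum such distance
oracle_inscribed_diameter <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  bg <- which(!pad, arr.ind = TRUE)
  fg <- which(pad, arr.ind = TRUE)
  best <- 0
  for (t in seq_len(nrow(fg))) {
    d <- sqrt(min((bg[, 1] - fg[t, 1])^2 + (bg[, 2] - fg[t, 2])^2))
    if (d > best) best <- d
  }
  2 * best
}

# draw a filled disc in a matrix (1-based centre, radius in px)
draw_disc <- function(nr, nc, cr, cc, r) {
  m <- matrix(FALSE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  m[(rows - cr)^2 + (cols - cc)^2 <= r^2] <- TRUE
  m
}

# small letter phantom used for scan-level tests: one solid square glyph,
# 0.3 mm extrusion (fits inside the FOV margin above the regulated surface)
square_phantom <- function(extrusion = 0.3) {
  make_letter_phantom(footprint = c(8, 6), letters = "#",
                      extrusion_height = extrusion, pitch = 0.02,
                      glyph_size = c(3, 4))
}

# random smooth broadband sample for sweep tests: superposition of ten
# incommensurate sinusoid products (aliasing-free degradation), gamma
# speckle shape 16
sweep_fixture <- function(seed) {
  n <- 10
  withr::with_seed(seed, {
    ax <- stats::runif(n, -1, 1); ay <- stats::runif(n, -1, 1)
    fx <- stats::runif(n, 0.4, 4); fy <- stats::runif(n, 0.4, 4)
    phx <- stats::runif(n, 0, 2 * pi); phy <- stats::runif(n, 0, 2 * pi)
    lam <- stats::runif(1, 1, 3)
  })
  ef <- function(x, y, z) {
    v <- 0
    for (i in seq_len(n)) {
      v <- v + ax[i] * sin(2 * pi * x / fx[i] + phx[i]) *
        ay[i] * cos(2 * pi * y / fy[i] + phy[i])
    }
    pmax(1.5 + 0.5 * v, 0.2)
  }
  hf <- function(x, y) 0.08 * sin(2 * pi * x / lam)
  virtual_sample(hf, ef,
                 noise = list(speckle_shape = 16, background = 0.002,
                              seed = seed))
}

# lumen-field sample at isotropic pixel pitch for diameter-recovery tests
lumen_field <- function(n_lumens = 6, seed = 5) {
  make_layered_kidney(footprint = c(1, 5), layer_depths = 0,
                      layer_extinctions = 1.5, n_lumens = n_lumens,
                      lumen_diameter = c(0.16, 0.3),
                      lumen_depth = c(0.5, 0.9), seed = seed)
}

lumen_cfg <- function() {
  scan_config(W_px = 360, H_px = 150, alpha_lat = 0.01, alpha_ax = 0.01,
              v_x = 0.2)
}
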