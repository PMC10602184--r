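# Classical image-processing primitives used by the segmentation and map
# stages. The offline environment ships no raster image-processing package,
# so these are implemented here against brute-force oracles in the tests.

#' Label connected components of a binary image
#'
#' @param mask logical/0-1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape: 0 for background, 1..n for
#'   components, labelled in raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  nr <- nrow(mask)
  pos <- match(idx, idx)  # 1..m
  # edges between each foreground pixel and its right/down(/diagonal) mates
  nbr_off <- if (connectivity == 8) {
    list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))
  } else {
    list(c(1, 0), c(0, 1))
  }
  r <- (idx - 1) %% nr + 1
  cc <- (idx - 1) %/% nr + 1
  edges <- integer(0)
  for (o in nbr_off) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    idx2 <- (c2[ok] - 1) * nr + r2[ok]
    m <- match(idx2, idx)
    keep <- !is.na(m)
    edges <- c(edges, rbind(pos[ok][keep], m[keep]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel in raster order of first occurrence
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  lab[idx] <- relab[comp]
  lab
}

#' Euclidean distance transform of a binary mask
#'
#' For each foreground pixel, the Euclidean distance (in pixels) to the
#' nearest background pixel; pixels outside the image count as background.
#' Exact Felzenszwalb-Huttenlocher two-pass algorithm on squared distances.
#'
#' @param mask logical/0-1 matrix (foreground = TRUE/1).
#' @return Numeric matrix of distances; 0 on background.
#' @export
distance_transform <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  INF <- (nr + nc + 2)^2
  # pad with a background ring so the image border acts as background
  f <- matrix(INF, nr + 2, nc + 2)
  f[2:(nr + 1), 2:(nc + 1)][!mask] <- 0
  f[1, ] <- 0; f[nr + 2, ] <- 0; f[, 1] <- 0; f[, nc + 2] <- 0
  for (j in seq_len(nc + 2)) f[, j] <- .edt_1d(f[, j], INF)
  for (i in seq_len(nr + 2)) f[i, ] <- .edt_1d(f[i, ], INF)
  out <- sqrt(f[2:(nr + 1), 2:(nc + 1), drop = FALSE])
  out[!mask] <- 0
  out
}

# 1D squared-distance transform (lower envelope of parabolas)
.edt_1d <- function(f, INF) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' @param mask logical/0-1 matrix.
#' @return Logical matrix: the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  img <- (mask != 0) * 1L
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  sh <- function(m, dr, dc) {
    m[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc), drop = FALSE]
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- sh(pad, 0, 0)
      p2 <- sh(pad, -1, 0); p3 <- sh(pad, -1, 1); p4 <- sh(pad, 0, 1)
      p5 <- sh(pad, 1, 1);  p6 <- sh(pad, 1, 0);  p7 <- sh(pad, 1, -1)
      p8 <- sh(pad, 0, -1); p9 <- sh(pad, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ring <- cbind(as.vector(p2), as.vector(p3), as.vector(p4),
                    as.vector(p5), as.vector(p6), as.vector(p7),
                    as.vector(p8), as.vector(p9), as.vector(p2))
      A <- matrix(rowSums(ring[, 1:8, drop = FALSE] == 0 &
                            ring[, 2:9, drop = FALSE] == 1), nr, nc)
      if (phase == 1) {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- p == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        changed <- TRUE
        p[cond] <- 0L
        pad[2:(nr + 1), 2:(nc + 1)] <- p
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1), 2:(nc + 1), drop = FALSE] == 1L
}

#' Binary area opening
#'
#' Removes foreground components (8-connected) with fewer than
#' \code{min_area} pixels.
#'
#' @param mask logical/0-1 matrix.
#' @param min_area pixel-count threshold.
#' @return Logical matrix.
#' @export
area_opening <- function(mask, min_area) {
  lab <- label_components(mask, 8)
  if (max(lab) == 0) return(mask != 0)
  sizes <- tabulate(lab[lab > 0])
  keep <- sizes >= min_area
  out <- mask != 0
  out[lab > 0] <- keep[lab[lab > 0]]
  out
}

#' Binary area closing
#'
#' Fills background holes (4-connected background components not touching
#' the image border) with fewer than \code{min_area} pixels.
#'
#' @param mask logical/0-1 matrix.
#' @param min_area pixel-count threshold.
#' @return Logical matrix.
#' @export
area_closing <- function(mask, min_area) {
  m <- mask != 0
  lab <- label_components(!m, 4)
  if (max(lab) == 0) return(m)
  border <- unique(c(lab[1, ], lab[nrow(m), ], lab[, 1], lab[, ncol(m)]))
  border <- border[border > 0]
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes < min_area), border)
  m[lab %in% fill] <- TRUE
  m
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with histogram clipping and bilinear
#' blending of the per-tile mappings; output range-normalized to [0, 1].
#'
#' @param img numeric matrix.
#' @param n_tiles c(rows, cols) tile grid.
#' @param clip_limit clip fraction of the per-tile pixel count per histogram
#'   bin (e.g. 0.02); excess is redistributed uniformly.
#' @param n_bins histogram bins.
#' @return Matrix in [0, 1], same shape.
#' @export
clahe <- function(img, n_tiles = c(8, 8), clip_limit = 0.02,
                  n_bins = 128) {
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(0, nrow(img), ncol(img)))
  x <- (img - rng[1]) / diff(rng)
  bin <- pmin(floor(x * n_bins) + 1L, n_bins)
  nr <- nrow(img); nc <- ncol(img)
  tr <- pmin(n_tiles[1], nr); tc <- pmin(n_tiles[2], nc)
  # tile index and centre per pixel
  row_tile <- pmin(floor((seq_len(nr) - 0.5) / nr * tr) + 1L, tr)
  col_tile <- pmin(floor((seq_len(nc) - 0.5) / nc * tc) + 1L, tc)
  cdfs <- array(0, c(tr, tc, n_bins))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      b <- bin[row_tile == i, col_tile == j, drop = FALSE]
      h <- tabulate(b, n_bins)
      cl <- max(clip_limit * length(b), 1)
      excess <- sum(pmax(h - cl, 0))
      h <- pmin(h, cl) + excess / n_bins
      cdf <- cumsum(h) / sum(h)
      cdfs[i, j, ] <- cdf
    }
  }
  # bilinear interpolation between the four neighbouring tile mappings
  rc <- (row_tile - 0.5) / tr * nr  # tile centres in pixel units
  tile_center_r <- (seq_len(tr) - 0.5) * nr / tr
  tile_center_c <- (seq_len(tc) - 0.5) * nc / tc
  fr <- stats::approx(tile_center_r, seq_len(tr), xout = seq_len(nr),
                      rule = 2)$y
  fc <- stats::approx(tile_center_c, seq_len(tc), xout = seq_len(nc),
                      rule = 2)$y
  r0 <- pmin(pmax(floor(fr), 1), tr); r1 <- pmin(r0 + 1, tr)
  c0 <- pmin(pmax(floor(fc), 1), tc); c1 <- pmin(c0 + 1, tc)
  wr <- fr - r0; wc <- fc - c0
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    bj <- bin[, j]
    v00 <- cdfs[cbind(r0, c0[j], bj)]
    v10 <- cdfs[cbind(r1, c0[j], bj)]
    v01 <- cdfs[cbind(r0, c1[j], bj)]
    v11 <- cdfs[cbind(r1, c1[j], bj)]
    out[, j] <- (1 - wr) * ((1 - wc[j]) * v00 + wc[j] * v01) +
      wr * ((1 - wc[j]) * v10 + wc[j] * v11)
  }
  out <- out - min(out)
  if (max(out) > 0) out <- out / max(out)
  out
}

#' Resize a matrix by bicubic (Keys) interpolation
#'
#' Separable cubic-convolution resampling (a = -0.5) with clamped borders;
#' cell-centre alignment between input and output grids.
#'
#' @param m numeric matrix.
#' @param out_dim c(rows, cols) of the output.
#' @return Resized matrix.
#' @export
bicubic_resize <- function(m, out_dim) {
  ker <- function(x) {
    x <- abs(x); a <- -0.5
    ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  resample_1d <- function(mat, n_out) {   # along rows
    n_in <- nrow(mat)
    if (n_in == n_out) return(mat)
    # map output cell centres to input cell-centre coordinates
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    out <- matrix(0, n_out, ncol(mat))
    base <- floor(pos)
    for (o in -1:2) {
      idx <- pmin(pmax(base + o, 1), n_in)
      w <- ker(pos - (base + o))
      out <- out + mat[idx, , drop = FALSE] * w
    }
    # kernel weights sum to 1 only in the interior; renormalize
    wsum <- rowSums(vapply(-1:2, function(o) ker(pos - (floor(pos) + o)),
                           numeric(n_out)))
    out / wsum
  }
  t(resample_1d(t(resample_1d(m, out_dim[1])), out_dim[2]))
}

#' Mean local structural similarity between two images
#'
#' Standard SSIM with a uniform local window; constants
#' C1 = (0.01 L)^2, C2 = (0.03 L)^2 with L = \code{data_range}.
#'
#' @param a,b numeric matrices of identical shape.
#' @param window odd window side (default 7).
#' @param data_range dynamic range L; default from \code{a}.
#' @return Mean SSIM over the valid interior.
#' @export
ssim <- function(a, b, window = 7, data_range = NULL) {
  if (!all(dim(a) == dim(b))) {
    stop_roct("ssim: shape mismatch", "roct_invalid_input")
  }
  if (is.null(data_range)) data_range <- diff(range(a))
  if (data_range == 0) data_range <- 1
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_a <- .box_filter(a, window); mu_b <- .box_filter(b, window)
  s_aa <- .box_filter(a * a, window) - mu_a^2
  s_bb <- .box_filter(b * b, window) - mu_b^2
  s_ab <- .box_filter(a * b, window) - mu_a * mu_b
  s_aa <- pmax(s_aa, 0); s_bb <- pmax(s_bb, 0)
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

# uniform box filter, "valid"-free: same size with shrinking border windows
.box_filter <- function(m, w) {
  h <- (w - 1) / 2
  cs_rows <- function(x) {
    cs <- apply(x, 2, cumsum)
    n <- nrow(x)
    up <- pmin(seq_len(n) + h, n)
    lo <- seq_len(n) - h - 1
    top <- cs[up, , drop = FALSE]
    bot <- matrix(0, n, ncol(x))
    pos <- lo >= 1
    bot[pos, ] <- cs[lo[pos], , drop = FALSE]
    cnt <- up - pmax(lo, 0)
    (top - bot) / cnt
  }
  t(cs_rows(t(cs_rows(m))))
}
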