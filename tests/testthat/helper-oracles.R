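# Independent oracles used across the suite.  These deliberately avoid
# the package's traversal code paths: the dense system matrix is built by
# per-voxel slab clipping, TV quantities by direct formula transcription.

# Dense system matrix: intersection length of every ray with every voxel,
# computed by clipping the ray against each voxel's box independently.
# Rays are ordered angle-major (angle 1 pixels, angle 2 pixels, ...).
# Axis-parallel rays use the half-open convention [lo, hi) like the
# package kernel.
dense_system_matrix <- function(geom) {
  ns <- geom$volume_shape
  vs <- geom$voxel_size
  nd <- geom$detector_pixel_counts[1]
  pitch <- geom$detector_pixel_pitch[1]
  A <- matrix(0, length(geom$angles) * nd, prod(ns))
  for (ai in seq_along(geom$angles)) {
    th <- geom$angles[ai] * pi / 180
    ct <- cos(th); st <- sin(th)
    for (iu in seq_len(nd)) {
      tu <- (iu - 0.5 - nd / 2) * pitch
      if (geom$beam_mode == "parallel2d") {
        p0 <- c(-tu * st, tu * ct)
        d <- c(ct, st)
      } else {
        S <- geom$source_to_origin * c(ct, st)
        dc <- (geom$source_to_origin - geom$source_to_detector) * c(ct, st)
        pd <- dc + tu * c(-st, ct)
        d <- pd - S
        d <- d / sqrt(sum(d^2))
        p0 <- S
      }
      r <- (ai - 1) * nd + iu
      for (j in seq_len(ns[2])) for (i in seq_len(ns[1])) {
        lo <- c((i - 1 - ns[1] / 2) * vs[1], (j - 1 - ns[2] / 2) * vs[2])
        hi <- lo + vs
        tmin <- -Inf; tmax <- Inf; ok <- TRUE
        for (a in 1:2) {
          if (abs(d[a]) > 1e-12) {
            t1 <- (lo[a] - p0[a]) / d[a]; t2 <- (hi[a] - p0[a]) / d[a]
            tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
          } else if (p0[a] < lo[a] || p0[a] >= hi[a]) { ok <- FALSE; break }
        }
        if (ok && tmax > tmin) A[r, i + ns[1] * (j - 1)] <- tmax - tmin
      }
    }
  }
  A
}

# Projection matrix (angles x detector) -> dense-oracle ray vector.
proj_to_rayvec <- function(proj) as.numeric(t(proj))
rayvec_to_proj <- function(v, geom) {
  matrix(v, nrow = length(geom$angles),
         ncol = geom$detector_pixel_counts[1], byrow = TRUE)
}

# Small test geometry shared by the dense-oracle tests.
oracle_geom <- function(mode = "parallel2d", n = 8, n_angles = 6,
                        nd = 13, pitch = 1.1, start = 3) {
  scan_geometry(mode, angles = make_angles(360, n_angles, start),
                volume_shape = c(n, n), voxel_size = 1,
                detector_pixel_counts = nd, detector_pixel_pitch = pitch)
}

# Isotropic TV norm by direct transcription (backward differences, zero
# at the lower boundary), independent of the package helpers.
iso_tv_norm <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  d1 <- x - x[c(1, seq_len(nr - 1)), , drop = FALSE]
  d1[1, ] <- 0
  d2 <- x - x[, c(1, seq_len(nc - 1)), drop = FALSE]
  d2[, 1] <- 0
  sum(sqrt(d1^2 + d2^2))
}

# Smoothed, frozen-weight AwTV objective used to check the gradient by
# central finite differences.
frozen_awtv <- function(x, x0, delta, mu) {
  bd <- function(m, a) {
    d <- if (a == 1) m - m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
         else m - m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
    if (a == 1) d[1, ] <- 0 else d[, 1] <- 0
    d
  }
  w1 <- exp(-(bd(x0, 1) / delta)^2)
  w2 <- exp(-(bd(x0, 2) / delta)^2)
  sum(sqrt(w1 * bd(x, 1)^2 + w2 * bd(x, 2)^2 + mu^2))
}

# Plain (non-adaptive) unit-weight smoothed TV gradient descent,
# written independently of awtv_gradient/tv_descent.
plain_tv_descent <- function(x, ng, eta, mu) {
  bd <- function(m, a) {
    d <- if (a == 1) m - m[c(1, seq_len(nrow(m) - 1)), , drop = FALSE]
         else m - m[, c(1, seq_len(ncol(m) - 1)), drop = FALSE]
    if (a == 1) d[1, ] <- 0 else d[, 1] <- 0
    d
  }
  lead <- function(m, a) {
    if (a == 1) rbind(m[-1, , drop = FALSE], 0)
    else cbind(m[, -1, drop = FALSE], 0)
  }
  for (i in seq_len(ng)) {
    d1 <- bd(x, 1); d2 <- bd(x, 2)
    phi <- sqrt(d1^2 + d2^2 + mu^2)
    g <- d1 / phi - lead(d1 / phi, 1) + d2 / phi - lead(d2 / phi, 2)
    nrm <- sqrt(sum(g^2))
    if (nrm == 0) break
    x <- x - eta * g / nrm
  }
  x
}

# Small thorax-like test world reused by reconstruction tests.
tiny_world <- function(n = 32, n_views = 20, seed = NULL, voxel = 5,
                       noise = NULL) {
  truth <- render_phantom(thorax_phantom_spec(c(n, n)))
  geom <- scan_geometry("fan2d", angles = make_angles(360, n_views),
                        volume_shape = c(n, n), voxel_size = voxel,
                        detector_pixel_counts = n,
                        detector_pixel_pitch = voxel * 2)
  b <- forward_project(truth, geom)
  if (!is.null(noise)) b <- add_ct_noise(b, noise)
  list(truth = truth, geom = geom, b = b)
}
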