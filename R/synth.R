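## Synthetic fixtures: deterministic generators for every pipeline input.
## The prosthesis family is a 5-parameter lens-like shell (outline
## semi-axes, back depth, back bump, cornea height) sampled inside the
## size envelope of manufactured prostheses; OCT volumes render conformer
## window planes and the shape's back surface with the acquisition
## distortions the extraction stage corrects; eye photos composite
## sclera, stains, veins, iris ring, pupil, skin and highlights with
## full ground truth.

#' Synthetic prosthesis generator configuration
#' @param width_range,height_range bounding-box width/height ranges (mm)
#' @param back_depth_range back-surface depth range (mm)
#' @param cornea_range cornea apex height range (mm)
#' @param bump_range back-surface bump amplitude range (mm)
#' @param limbus_radius nominal limbus radius (mm)
#' @return list of family parameters
#' @export
synthetic_shape_config <- function(width_range = c(18.5, 28.6),
                                   height_range = c(15.9, 28),
                                   back_depth_range = c(7, 11.5),
                                   cornea_range = c(2.2, 3.4),
                                   bump_range = c(0, 1.2),
                                   limbus_radius = 5.9) {
  list(width_range = width_range, height_range = height_range,
       back_depth_range = back_depth_range, cornea_range = cornea_range,
       bump_range = bump_range, limbus_radius = limbus_radius)
}

# closed lens-shaped shell: top dome (cornea + flange) and bottom shell
# over an elliptical outline; returns mesh plus the canonical markers
.lens_mesh <- function(A, B, Cb, h, bump, rL, n_az = 48, n_rad = 20) {
  az <- (seq_len(n_az) - 1) / n_az * 2 * pi
  Rout <- 1 / sqrt((cos(az) / A)^2 + (sin(az) / B)^2)
  rho_hat <- seq_len(n_rad) / n_rad
  top_z <- function(rh) h * (1 - rh^2)^0.8
  bot_z <- function(rh, p) -Cb * sqrt(pmax(1 - rh^2, 0)) *
    (1 + 0.15 * bump * rh^2 * cos(2 * p))
  V <- c(0, 0, top_z(0))
  for (rh in rho_hat)
    V <- rbind(V, cbind(rh * Rout * cos(az), rh * Rout * sin(az),
                        top_z(rh)))
  for (rh in rev(rho_hat[-n_rad]))
    V <- rbind(V, cbind(rh * Rout * cos(az), rh * Rout * sin(az),
                        bot_z(rh, az)))
  V <- rbind(V, c(0, 0, bot_z(0, 0)))
  ring <- function(i) 1 + (i - 1) * n_az + seq_len(n_az)
  n_rings <- 2 * n_rad - 1
  F <- NULL
  r1 <- ring(1)
  F <- cbind(1, r1, r1[c(2:n_az, 1)])
  for (i in seq_len(n_rings - 1)) {
    a <- ring(i); b <- ring(i + 1)
    a2 <- a[c(2:n_az, 1)]; b2 <- b[c(2:n_az, 1)]
    F <- rbind(F, cbind(a, b, b2), cbind(a, b2, a2))
  }
  last <- nrow(V); bl <- ring(n_rings)
  F <- rbind(F, cbind(last, bl[c(2:n_az, 1)], bl))
  mesh <- op_mesh(V, F)
  # markers: exact mesh vertices on the cardinal azimuths, on the top
  # ring whose x radius is nearest the limbus radius
  i_star <- which.min(abs(rho_hat * A - rL))
  card <- c(1, n_az / 4 + 1, n_az / 2 + 1, 3 * n_az / 4 + 1) # 0,90,180,270
  vidx <- 1 + (i_star - 1) * n_az + card
  list(mesh = mesh,
       markers = list(p_N = V[vidx[1], ], p_S = V[vidx[2], ],
                      p_T = V[vidx[3], ], p_I = V[vidx[4], ]))
}

.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a set of marked prosthesis scans
#'
#' Samples the 5-parameter shell family inside the manufactured-size
#' envelope, marks the four limbus points analytically at exact mesh
#' vertices, and pushes each shape through a random rigid transform.
#'
#' @param n number of scans
#' @param seed RNG seed
#' @param config from \code{\link{synthetic_shape_config}}
#' @param rigid apply random rigid transforms (markers stay consistent)
#' @param sides eye sides to sample from
#' @return list of \code{marked_scan}
#' @export
gen_prosthesis_set <- function(n, seed = 1,
                               config = synthetic_shape_config(),
                               rigid = TRUE, sides = "right") {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      A <- runif(1, config$width_range[1], config$width_range[2]) / 2
      B <- runif(1, config$height_range[1], config$height_range[2]) / 2
      Cb <- runif(1, config$back_depth_range[1], config$back_depth_range[2])
      h <- runif(1, config$cornea_range[1], config$cornea_range[2])
      bump <- runif(1, config$bump_range[1], config$bump_range[2])
      lens <- .lens_mesh(A, B, Cb, h, bump, config$limbus_radius)
      side <- sample(sides, 1)
      if (rigid) {
        R <- .random_rotation()
        t <- runif(3, -20, 20)
        xf <- function(p) drop(p %*% R) + t
        V <- sweep(lens$mesh$vertices %*% R, 2, t, `+`)
        mk <- lapply(lens$markers, xf)
        marked_scan(op_mesh(V, lens$mesh$faces),
                    p_S = mk$p_S, p_N = mk$p_N, p_I = mk$p_I,
                    p_T = mk$p_T, eye_side = side)
      } else {
        marked_scan(lens$mesh, p_S = lens$markers$p_S,
                    p_N = lens$markers$p_N, p_I = lens$markers$p_I,
                    p_T = lens$markers$p_T, eye_side = side)
      }
    })
  })
}

#' Generate a linear landmark-space shape family
#'
#' A known k-mode linear generator in landmark space: base landmark mesh
#' plus k fixed orthonormal modes with decaying standard deviations and
#' optional isotropic noise. Used as ground truth for model-recovery
#' experiments.
#'
#' @param n number of shapes
#' @param k number of generator modes
#' @param seed RNG seed
#' @param base optional base \code{landmark_mesh} (a default shell
#'   is used when NULL)
#' @param sigmas mode standard deviations (mm per coordinate scale)
#' @param noise_sd isotropic coordinate noise (mm)
#' @return list with \code{shapes} (landmark meshes), \code{modes}
#'   (2514 x k), \code{sigmas}, \code{base}, \code{coords} (n x k true
#'   coordinates)
#' @export
gen_landmark_family <- function(n, k = 5, seed = 1, base = NULL,
                                sigmas = 1.2 * 0.8^(seq_len(k) - 1),
                                noise_sd = 1e-6) {
  if (is.null(base)) {
    cfg <- synthetic_shape_config()
    lens <- .lens_mesh(11.8, 10.5, 9.5, 2.8, 0.5, cfg$limbus_radius)
    base <- generate_correspondence(lens$mesh)
  }
  d <- length(base$points)
  with_seed(seed, {
    M <- qr.Q(qr(matrix(rnorm(d * k), d, k)))
    X <- matrix(rnorm(n * k), n, k)
    shapes <- lapply(seq_len(n), function(i) {
      v <- as.vector(base$points) + M %*% (X[i, ] * sigmas) +
        rnorm(d, sd = noise_sd)
      landmark_mesh(matrix(v, ncol = 3))
    })
    list(shapes = shapes, modes = M, sigmas = sigmas, base = base,
         coords = X)
  })
}

#' Synthesize an OCT socket volume with known ground truth
#'
#' Renders, at the downsampled voxel level, the two bright conformer
#' window planes (optionally tilted) and the shape's back surface with
#' the acquisition distortions the extraction stage corrects: refraction
#' shift at the tilted window, the +0.35 d depth bias, the window offset
#' below the iris plane, and the gaze rotation. Optional multiplicative
#' speckle. Desk-scale geometry by default.
#'
#' @param shape a \code{landmark_mesh} whose back surface is the socket
#' @param conformer a \code{conformer_spec}
#' @param geometry an \code{oct_geometry} (desk scale by default)
#' @param window_depth depth of the anterior window plane centre (mm)
#' @param tilt slopes (dz/dx, dz/dy) of the window plane
#' @param gaze_deg gaze angle emulated (degrees)
#' @param speckle fraction of columns with random bright noise voxels
#' @param seed RNG seed
#' @return list with \code{volumes} (a \code{filtered_volumes}),
#'   \code{truth} (256 x 256 ground-truth socket depth map, mm),
#'   \code{conformer}, \code{geometry}
#' @export
gen_oct_volume <- function(shape, conformer,
                           geometry = oct_geometry(slice_width_px = 536,
                                                   slice_depth_px = 469,
                                                   n_slices = 64),
                           window_depth = 1.5, tilt = c(0, 0),
                           gaze_deg = 6, speckle = 0, seed = 1) {
  g <- geometry
  psi <- gaze_deg * pi / 180
  mesh <- as_op_mesh(shape)
  # inverse gaze: the scanned socket is the truth rotated by -psi
  Vr <- mesh$vertices
  x <- Vr[, 1] * cos(psi) - Vr[, 3] * sin(psi)
  z <- Vr[, 1] * sin(psi) + Vr[, 3] * cos(psi)
  mesh_r <- op_mesh(cbind(x, Vr[, 2], z), mesh$faces)
  xs <- ((seq_len(g$nx) - 0.5) * g$x_pitch) - g$width_mm / 2
  ys <- ((seq_len(g$ny) - 0.5) * g$y_pitch) - g$height_mm / 2
  # back-surface depth of the rotated truth on the volume's lateral grid;
  # the rasterizer uses a square pitch, so y is index-scaled when the
  # lateral pitches differ
  sc <- g$y_pitch / g$x_pitch
  Vs <- mesh_r$vertices
  Vs[, 2] <- Vs[, 2] / sc
  zb <- .cpp_rasterize_depth(Vs, mesh_r$faces, g$nx, g$ny,
                             -g$width_mm / 2, -g$height_mm / 2 / sc,
                             g$x_pitch, FALSE)
  d_eff <- conformer$window_thickness
  dA <- window_depth + outer(xs * tilt[1], ys * tilt[2], `+`)
  gx <- tilt[1]; gy <- tilt[2]
  gnorm <- sqrt(gx^2 + gy^2)
  shift <- 0
  ux <- 0; uy <- 0
  if (gnorm > 1e-9) {
    theta_i <- atan(gnorm)
    theta_t <- asin(sin(theta_i) / conformer$refractive_index)
    shift <- d_eff * (tan(theta_i) - tan(theta_t))
    ux <- gx / gnorm; uy <- gy / gnorm
  }
  V_Median <- array(0, c(g$nx, g$ny, g$nz))
  zvox <- seq_len(g$nz) * g$z_pitch
  with_seed(seed, {
    for (j in seq_len(g$ny)) {
      # apparent socket depth for each column of this slice
      xq <- xs - shift * ux
      yq <- ys[j] - shift * uy
      iq <- clamp(round((xq + g$width_mm / 2) / g$x_pitch + 0.5), 1, g$nx)
      jq <- clamp(round((yq + g$height_mm / 2) / g$y_pitch + 0.5), 1, g$ny)
      depth_true <- -zb[cbind(iq, rep(jq, length(iq)))]
      app <- depth_true + 0.35 * d_eff - conformer$window_offset +
        window_depth
      slice <- matrix(0, g$nx, g$nz)
      a_band <- clamp(round(dA[, j] / g$z_pitch), 1, g$nz)
      p_band <- clamp(round((dA[, j] + d_eff) / g$z_pitch), 1, g$nz)
      # the flat window (and the socket visible through it) is a disc
      in_window <- sqrt(xs^2 + ys[j]^2) <= conformer$window_diameter / 2
      for (i in seq_len(g$nx)[in_window]) {
        slice[i, a_band[i]:min(a_band[i] + 1, g$nz)] <- 0.9
        slice[i, p_band[i]:min(p_band[i] + 1, g$nz)] <- 0.7
        if (is.finite(app[i]) && app[i] > 0) {
          z0 <- round(app[i] / g$z_pitch)
          if (z0 + 1 <= g$nz) {
            zi <- (z0 + 1):g$nz
            slice[i, zi] <- pmax(slice[i, zi],
                                 pmin(0.8, (zvox[zi] - app[i]) / 1.0 * 0.8))
          }
        }
      }
      if (speckle > 0) {
        ncols <- rbinom(1, g$nx, speckle)
        if (ncols > 0) {
          ci <- sample(g$nx, ncols)
          for (i in ci) {
            zpos <- sample(max(p_band[i] + 3, 2):g$nz, 1)
            slice[i, zpos] <- runif(1, 0.3, 1)
          }
        }
      }
      V_Median[, j, ] <- slice
    }
  })
  truth <- back_depth_map(shape, 256, 16)
  list(volumes = filtered_volumes(V_Median, NULL, g),
       truth = truth, conformer = conformer, geometry = g)
}

## --- synthetic eye photographs ---------------------------------------

#' Synthetic eye photo configuration
#' @param size image size (pixels, square)
#' @param iris_radius,pupil_radius pixels
#' @param iris_lab iris base colour (CIELAB)
#' @param sclera_lab sclera base colour (CIELAB)
#' @param stain_labs list of stain colours blended into the sclera
#' @param n_veins number of synthetic veins
#' @param n_highlights number of specular highlight dots
#' @return config list
#' @export
eye_photo_config <- function(size = 256, iris_radius = 60,
                             pupil_radius = 22,
                             iris_lab = c(45, 15, -30),
                             sclera_lab = c(78, 2, 6),
                             stain_labs = list(c(70, 6, 18),
                                               c(72, -2, 2)),
                             n_veins = 6, n_highlights = 0) {
  list(size = size, iris_radius = iris_radius, pupil_radius = pupil_radius,
       iris_lab = iris_lab, sclera_lab = sclera_lab,
       stain_labs = stain_labs, n_veins = n_veins,
       n_highlights = n_highlights)
}

#' Generate a synthetic eye photograph with ground truth
#'
#' Composites (in CIELAB) skin border, sclera with stain blotches and
#' reddish veins, a radially textured iris ring, a dark pupil and
#' optional specular highlights. Returns the image and all ground
#' truths.
#'
#' @param config from \code{\link{eye_photo_config}}
#' @param seed RNG seed
#' @return list: \code{lab} (H x W x 3 array), \code{regions} (matrix:
#'   1 pupil, 2 iris, 3 sclera, 4 skin), \code{centre}, radii,
#'   \code{vein_mask}, \code{highlight_mask}, \code{stain_labs}
#' @export
gen_eye_photo <- function(config = eye_photo_config(), seed = 1) {
  n <- config$size
  cx <- n / 2 + 0.5; cy <- n / 2 + 0.5
  X <- matrix(rep(seq_len(n), n), n, n)
  Y <- t(X)
  R <- sqrt((X - cx)^2 + (Y - cy)^2)
  PHI <- atan2(Y - cy, X - cx)
  ap_a <- n * 0.48; ap_b <- n * 0.33   # aperture ellipse (eyelids)
  in_ap <- ((X - cx) / ap_a)^2 + ((Y - cy) / ap_b)^2 <= 1
  regions <- matrix(4L, n, n)
  regions[in_ap] <- 3L
  regions[R <= config$iris_radius] <- 2L
  regions[R <= config$pupil_radius] <- 1L
  L <- matrix(35, n, n); A <- matrix(12, n, n); B <- matrix(18, n, n)
  sl <- config$sclera_lab
  L[regions == 3] <- sl[1]; A[regions == 3] <- sl[2]
  B[regions == 3] <- sl[3]
  with_seed(seed, {
    # stain blotches on the sclera
    for (g in config$stain_labs) {
      for (rep_ in 1:3) {
        bx <- runif(1, 0.1 * n, 0.9 * n); by <- runif(1, 0.25 * n, 0.75 * n)
        br <- runif(1, 0.06 * n, 0.12 * n)
        w <- exp(-((X - bx)^2 + (Y - by)^2) / (2 * br^2))
        sel <- regions == 3
        L[sel] <- L[sel] * (1 - w[sel]) + g[1] * w[sel]
        A[sel] <- A[sel] * (1 - w[sel]) + g[2] * w[sel]
        B[sel] <- B[sel] * (1 - w[sel]) + g[3] * w[sel]
      }
    }
    # veins: random walks from the aperture border toward the limbus
    vein_mask <- matrix(FALSE, n, n)
    for (v in seq_len(config$n_veins)) {
      ang <- runif(1, 0, 2 * pi)
      px <- cx + cos(ang) * ap_a * 0.95
      py <- cy + sin(ang) * ap_b * 0.95
      dir <- atan2(cy - py, cx - px)
      for (s in 1:120) {
        dir <- dir + rnorm(1, 0, 0.15)
        px <- px + cos(dir) * 1.2; py <- py + sin(dir) * 1.2
        if (sqrt((px - cx)^2 + (py - cy)^2) < config$iris_radius * 1.15)
          break
        ix <- round(px); iy <- round(py)
        if (ix < 2 || ix > n - 1 || iy < 2 || iy > n - 1) break
        vein_mask[(ix - 1):(ix + 1), iy] <- TRUE
        vein_mask[ix, (iy - 1):(iy + 1)] <- TRUE
      }
    }
    sel <- vein_mask & regions == 3
    L[sel] <- 55; A[sel] <- 30; B[sel] <- 14
    # iris: radial streak texture
    ir <- regions == 2
    streak <- 6 * sin(PHI * 24) + 3 * sin(PHI * 7 + 1)
    il <- config$iris_lab
    L[ir] <- il[1] + streak[ir] * (R[ir] / config$iris_radius)
    A[ir] <- il[2]; B[ir] <- il[3]
    L[regions == 1] <- 4; A[regions == 1] <- 0; B[regions == 1] <- 0
    highlight_mask <- matrix(FALSE, n, n)
    if (config$n_highlights > 0) {
      for (hgl in seq_len(config$n_highlights)) {
        hx <- round(cx + runif(1, -0.5, 0.5) * config$iris_radius)
        hy <- round(cy + runif(1, -0.5, 0.5) * config$iris_radius)
        hr <- 2
        selh <- (X - hx)^2 + (Y - hy)^2 <= hr^2
        L[selh] <- pmin(L[selh] + 40, 100)
        highlight_mask <- highlight_mask | selh
      }
    }
    lab <- array(c(L, A, B), c(n, n, 3))
    list(lab = lab, regions = regions, centre = c(cx, cy),
         iris_radius = config$iris_radius,
         pupil_radius = config$pupil_radius,
         vein_mask = vein_mask, highlight_mask = highlight_mask,
         stain_labs = config$stain_labs, config = config)
  })
}

#' Synthetic iris-disc mesh
#'
#' Disc in the x-y plane with a (optionally ragged) pupil hole, as the
#' OCT software would export for the iris surface.
#' @param iris_radius,pupil_radius mm
#' @param raggedness sd of radial jitter on the pupil boundary (mm)
#' @param n_az azimuthal resolution
#' @param n_rad radial rings
#' @param seed RNG seed
#' @return an \code{op_mesh} (open disc with a hole)
#' @export
gen_iris_mesh <- function(iris_radius = 5.9, pupil_radius = 1.7,
                          raggedness = 0, n_az = 48, n_rad = 8,
                          seed = 1) {
  with_seed(seed, {
    az <- (seq_len(n_az) - 1) / n_az * 2 * pi
    rp <- pupil_radius + rnorm(n_az, 0, raggedness)
    V <- NULL
    for (i in seq_len(n_rad)) {
      t <- (i - 1) / (n_rad - 1)
      r <- rp * (1 - t) + iris_radius * t
      V <- rbind(V, cbind(r * cos(az), r * sin(az), 0))
    }
    F <- NULL
    for (i in seq_len(n_rad - 1)) {
      a <- (i - 1) * n_az + seq_len(n_az)
      b <- i * n_az + seq_len(n_az)
      a2 <- a[c(2:n_az, 1)]; b2 <- b[c(2:n_az, 1)]
      F <- rbind(F, cbind(a, b, b2), cbind(a, b2, a2))
    }
    op_mesh(V, F)
  })
}
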