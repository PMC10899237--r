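## Iris segmentation (multi-scale Daugman operator + constant-area
## elliptical refinement), texture unwrapping and geometry preparation.

# circular line integral of img at (cx, cy, r), mean over n_angles
.circ_integral <- function(img, cx, cy, r, n_angles = 64) {
  ang <- (seq_len(n_angles) - 0.5) / n_angles * 2 * pi
  xs <- cx + r * cos(ang); ys <- cy + r * sin(ang)
  .bilinear_img(img, xs, ys)
}

.bilinear_img <- function(img, x, y) {
  x <- as.vector(x); y <- as.vector(y)
  n <- nrow(img); m <- ncol(img)
  x <- clamp(x, 1, n - 1e-6); y <- clamp(y, 1, m - 1e-6)
  i0 <- pmin(floor(x), n - 1); j0 <- pmin(floor(y), m - 1)
  fx <- x - i0; fy <- y - j0
  v00 <- img[cbind(i0, j0)]; v10 <- img[cbind(i0 + 1, j0)]
  v01 <- img[cbind(i0, j0 + 1)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

# Daugman integro-differential response: |d/dr of the smoothed circular
# mean| evaluated over a radius range at a fixed centre
.daugman_response <- function(img, cx, cy, radii) {
  means <- vapply(radii, function(r)
    mean(.circ_integral(img, cx, cy, r)), 0)
  d <- diff(means)
  # Gaussian smoothing over the radial derivative
  kr <- min(2, (length(d) - 1) %/% 2)
  if (kr > 0) {
    k <- dnorm(-kr:kr, sd = 1); k <- k / sum(k)
    ds <- stats::filter(d, k, sides = 2)
    ds[is.na(ds)] <- 0
  } else ds <- d
  i <- which.max(abs(ds))
  list(r = (radii[i] + radii[i + 1]) / 2, score = abs(ds[i]))
}

# grid search of centre and radius maximizing the Daugman response
.daugman_search <- function(img, cx_range, cy_range, r_range, step) {
  best <- list(score = -Inf)
  radii <- seq(r_range[1], r_range[2], by = step)
  if (length(radii) < 4) radii <- seq(r_range[1], r_range[2],
                                      length.out = 6)
  for (cx in seq(cx_range[1], cx_range[2], by = step)) {
    for (cy in seq(cy_range[1], cy_range[2], by = step)) {
      r <- .daugman_response(img, cx, cy, radii)
      if (r$score > best$score)
        best <- list(cx = cx, cy = cy, r = r$r, score = r$score)
    }
  }
  best
}

#' Detect iris and pupil boundaries
#'
#' Multi-scale Daugman operator on the chroma-minus-lightness image: a
#' coarse-to-fine pyramid (scales 8, 4, 2, 1) maximizes the
#' Gaussian-smoothed radial derivative of the circular line integral,
#' refining the previous estimate within +-4 px at each scale; the pupil
#' is searched inside the iris. The iris circle is then refined to an
#' ellipse of constant area over an eccentricity/angle grid, maximizing
#' the intensity difference between just outside and just inside the
#' boundary.
#'
#' @param I_clean H x W x 3 CIELAB image with the full iris visible
#' @param scales pyramid downscale factors, coarse to fine
#' @return object of class \code{iris_segmentation}: iris centre/radius,
#'   constant-area \code{ellipse} (a, b, angle), pupil centre/radius, and
#'   the iris+pupil mask \code{M_I}
#' @export
detect_iris <- function(I_clean, scales = c(8, 4, 2, 1)) {
  enh <- enhance_image(I_clean)
  n <- nrow(enh); m <- ncol(enh)
  est <- NULL
  for (s in scales) {
    img_s <- if (s > 1) .box_downscale(enh, s) else enh
    if (is.null(est)) {
      rr <- c(0.1, 0.45) * min(dim(img_s))
      sr <- .daugman_search(img_s, c(0.3, 0.7) * nrow(img_s),
                            c(0.3, 0.7) * ncol(img_s), rr, 2)
    } else {
      prev <- list(cx = est$cx * 2, cy = est$cy * 2, r = est$r * 2)
      sr <- .daugman_search(img_s, prev$cx + c(-4, 4),
                            prev$cy + c(-4, 4),
                            prev$r * c(0.85, 1.15), 1)
    }
    if (!is.finite(sr$score) || sr$score <= 0)
      abort_ocuprost("no iris boundary response above the noise floor",
                     "iris_detection_failure")
    est <- sr
  }
  iris <- est
  # pupil: dark centre on the enhanced image, radius below 0.8 r_iris
  pup <- .daugman_search(enh, iris$cx + c(-6, 6), iris$cy + c(-6, 6),
                         c(0.15, 0.8) * iris$r, 1)
  ell <- .refine_ellipse(enh, iris$cx, iris$cy, iris$r)
  iris$r <- ell$r_eff   # keep radius and ellipse area consistent
  X <- matrix(rep(seq_len(n), m), n, m); Y <- t(matrix(rep(seq_len(m), n), m, n))
  M_I <- ((X - iris$cx)^2 + (Y - iris$cy)^2) <= iris$r^2
  structure(list(iris = list(cx = iris$cx, cy = iris$cy, r = iris$r),
                 ellipse = ell,
                 pupil = list(cx = pup$cx, cy = pup$cy, r = pup$r),
                 M_I = M_I),
            class = "iris_segmentation")
}

.box_downscale <- function(img, s) {
  n <- nrow(img) %/% s; m <- ncol(img) %/% s
  img <- img[seq_len(n * s), seq_len(m * s)]
  acc <- matrix(0, n, m)
  for (di in seq_len(s)) for (dj in seq_len(s))
    acc <- acc + img[seq(di, by = s, length.out = n),
                     seq(dj, by = s, length.out = m)]
  acc / s^2
}

# constant-area elliptical refinement: axis ratios 1 -> 0.85 (step .01),
# angles 0 -> 175 deg (step 5), maximizing inner-minus-outer contrast.
# The effective radius is searched over a small range as well (the
# circular stage tends to lock onto the minor axis of an elliptical
# limbus); the area is held at pi * r_eff^2 within each candidate.
.refine_ellipse <- function(img, cx, cy, r, ratios = seq(1, 0.85, -0.01),
                            angles_deg = seq(0, 175, 5),
                            r_scales = c(1, 0.96, 1.04, 1.08)) {
  n_angles <- 96
  t <- (seq_len(n_angles) - 0.5) / n_angles * 2 * pi
  score_at <- function(ox, oy, re, q, phi) {
    a <- re / sqrt(q); b <- re * sqrt(q)
    ex <- a * cos(t) * cos(phi) - b * sin(t) * sin(phi)
    ey <- a * cos(t) * sin(phi) + b * sin(t) * cos(phi)
    mean(.bilinear_img(img, cx + ox + 0.97 * ex, cy + oy + 0.97 * ey)) -
      mean(.bilinear_img(img, cx + ox + 1.03 * ex, cy + oy + 1.03 * ey))
  }
  # pass 1: coarse grid including small centre offsets (the circular
  # stage can land off-centre for an elliptical boundary)
  b1 <- list(score = -Inf)
  for (ox in c(-4, -2, 0, 2, 4)) for (oy in c(-4, -2, 0, 2, 4)) {
    for (s in r_scales) for (q in seq(1, 0.85, -0.03)) {
      for (phi in seq(0, 165, 15) * pi / 180) {
        sc <- score_at(ox, oy, r * s, q, phi)
        if (sc > b1$score)
          b1 <- list(ox = ox, oy = oy, score = sc)
        if (q == 1) break
      }
    }
  }
  # pass 2: full grid at the refined centre
  best <- NULL
  for (s in r_scales) {
    re <- r * s
    for (q in ratios) {
      for (phi in angles_deg * pi / 180) {
        sc <- score_at(b1$ox, b1$oy, re, q, phi)
        if (is.null(best) || sc > best$score)
          best <- list(a = re / sqrt(q), b = re * sqrt(q), angle = phi,
                       r_eff = re, cx = cx + b1$ox, cy = cy + b1$oy,
                       score = sc)
        if (q == 1) break # angle is degenerate for a circle
      }
    }
  }
  best
}

#' Unwrap the iris to a cylindrical texture
#'
#' Samples the iris annulus (pupil boundary to limbus) bilinearly into
#' an angle-by-radius texture: columns are angle, rows run from the
#' limbus (top) to the pupil (bottom).
#'
#' @param I_clean CIELAB image
#' @param seg an \code{iris_segmentation}
#' @param width,height texture size (angle x radius); the reference
#'   texture is 4096 x 1024
#' @return object of class \code{iris_texture}: \code{lab} array
#'   (height x width x 3)
#' @export
unwrap_iris <- function(I_clean, seg, width = 4096, height = 1024) {
  ang <- (seq_len(width) - 0.5) / width * 2 * pi
  rad <- seg$pupil$r +
    (1 - (seq_len(height) - 0.5) / height) * (seg$iris$r - seg$pupil$r)
  xs <- outer(rad, cos(ang))
  ys <- outer(rad, sin(ang))
  out <- array(0, c(height, width, 3))
  for (k in 1:3)
    out[, , k] <- matrix(.bilinear_img(I_clean[, , k],
                                       seg$iris$cx + xs,
                                       seg$iris$cy + ys),
                         height, width)
  structure(list(lab = out), class = "iris_texture")
}

#' Contrast-enhance an iris texture
#'
#' Stretches per-row lightness deviations by \code{factor}, restores the
#' global mean lightness exactly, and sets the pupil-side bottom rows to
#' pure black.
#' @param tex an \code{iris_texture}
#' @param factor stretch factor
#' @param pupil_black_frac fraction of bottom rows blacked
#' @return an \code{iris_texture}
#' @export
enhance_contrast <- function(tex, factor = 1.5, pupil_black_frac = 0.02) {
  lab <- tex$lab
  L <- lab[, , 1]
  L0 <- mean(L)
  rowm <- rowMeans(L)
  L <- factor * (L - rowm) + rowm
  L1 <- mean(L)
  L <- L + (L0 - L1)
  lab[, , 1] <- L
  nb <- round(nrow(L) * pupil_black_frac)
  if (nb > 0) {
    rows <- nrow(L) - seq_len(nb) + 1
    lab[rows, , 1] <- 0
    lab[rows, , 2] <- 0
    lab[rows, , 3] <- 0
  }
  structure(list(lab = lab), class = "iris_texture")
}

#' Build iris geometry from the OCT iris mesh
#'
#' Normalizes the (possibly ragged) pupil boundary to a smooth circle of
#' the average radius, closes the pupil hole with a fan, assigns
#' angle/radius UVs matching the unwrapped texture, and places a black
#' cylinder behind the pupil to darken it against material light
#' transport.
#'
#' @param iris_mesh an \code{op_mesh} disc with a pupil hole (two
#'   boundary loops), iris plane = x-y plane
#' @param cylinder_depth mm the black cylinder extends behind the pupil
#' @return object of class \code{iris_geometry}: \code{disc} (closed at
#'   the pupil, with \code{uv}), \code{pupil_radius}, \code{cylinder}
#' @export
build_iris_geometry <- function(iris_mesh, cylinder_depth = 2) {
  loops <- .boundary_loops(iris_mesh)
  if (length(loops) != 2)
    stop("iris mesh must be a disc with a pupil hole (2 boundary loops)")
  rad <- function(idx) sqrt(rowSums(iris_mesh$vertices[idx, 1:2]^2))
  mr <- vapply(loops, function(l) mean(rad(l)), 0)
  pupil_loop <- loops[[which.min(mr)]]
  outer_r <- max(mr)
  V <- iris_mesh$vertices
  # circularize the pupil boundary at the mean radius
  pr <- mean(rad(pupil_loop))
  phi <- atan2(V[pupil_loop, 2], V[pupil_loop, 1])
  V[pupil_loop, 1] <- pr * cos(phi)
  V[pupil_loop, 2] <- pr * sin(phi)
  V[pupil_loop, 3] <- mean(V[pupil_loop, 3])
  # close the pupil with a fan around a centre vertex
  centre <- c(0, 0, mean(V[pupil_loop, 3]))
  V <- rbind(V, centre)
  ci <- nrow(V)
  ord <- pupil_loop[order(phi)]
  nl <- length(ord)
  fan <- cbind(ci, ord, ord[c(2:nl, 1)])
  F <- rbind(iris_mesh$faces, fan)
  disc <- op_mesh(V, F)
  ang <- atan2(V[, 2], V[, 1]) / (2 * pi)
  ang <- ifelse(ang < 0, ang + 1, ang)
  rho <- clamp(sqrt(V[, 1]^2 + V[, 2]^2) / outer_r, 0, 1)
  disc$uv <- cbind(ang, rho)
  cyl <- .cylinder_mesh(pr, cylinder_depth)
  structure(list(disc = disc, pupil_radius = pr,
                 outer_radius = outer_r, cylinder = cyl),
            class = "iris_geometry")
}

# boundary loops: edges referenced by exactly one face
.boundary_loops <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  single <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
  loops <- list()
  remaining <- single
  while (nrow(remaining) > 0) {
    loop <- remaining[1, 1]
    cur <- remaining[1, 2]
    remaining <- remaining[-1, , drop = FALSE]
    while (cur != loop[1]) {
      loop <- c(loop, cur)
      nxt <- which(remaining[, 1] == cur | remaining[, 2] == cur)[1]
      if (is.na(nxt)) break
      row <- remaining[nxt, ]
      cur <- if (row[1] == cur) row[2] else row[1]
      remaining <- remaining[-nxt, , drop = FALSE]
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

.cylinder_mesh <- function(r, depth, n_az = 24, z_top = 0) {
  az <- (seq_len(n_az) - 1) / n_az * 2 * pi
  top <- cbind(r * cos(az), r * sin(az), z_top)
  bot <- cbind(r * cos(az), r * sin(az), z_top - depth)
  V <- rbind(top, bot, c(0, 0, z_top), c(0, 0, z_top - depth))
  ti <- seq_len(n_az); bi <- n_az + ti
  ct <- 2 * n_az + 1; cb <- 2 * n_az + 2
  nxt <- c(2:n_az, 1)
  F <- rbind(cbind(ti, bi, bi[nxt]), cbind(ti, bi[nxt], ti[nxt]),
             cbind(ct, ti, ti[nxt]), cbind(cb, bi[nxt], bi))
  op_mesh(V, F)
}
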