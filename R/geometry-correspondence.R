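## Radial correspondence: landmarks are placed on 48 radial lines
## (7.5 degree steps) at fixed fractional distances between the origin and
## the silhouette of the aligned shape's depth projection. Points at the
## same fraction form a ring; rings with fewer than 48 points skip angles
## evenly so the density stays roughly homogeneous. The exact fractions and
## skip pattern below are this package's versioned scheme (v1); it is
## constrained to yield 189 front + 649 back = 838 landmarks, 1672 faces,
## and the limbus on the third front ring.

.N_ANGLES <- 48L
.ANGLE_STEP_DEG <- 7.5

#' Correspondence ring scheme (version 1)
#'
#' Fixed table of ring fractions and per-ring point counts for the front
#' and back depth projections. Counts divide 48, so each sparser ring
#' skips angles evenly.
#' @return list with \code{front}, \code{back} (data frames of
#'   \code{fraction}, \code{count}), \code{limbus_ring} (front ring index)
#'   and \code{version}
#' @export
correspondence_rings <- function() {
  list(
    front = data.frame(
      fraction = c(0, 0.16, 0.36, 0.56, 0.74, 0.90, 1.0),
      count    = c(1L, 4L, 16L, 48L, 48L, 48L, 24L)),
    back = data.frame(
      fraction = c(0, 0.18, seq(0.28, 0.97, length.out = 13)),
      count    = c(1L, 24L, rep(48L, 13))),
    limbus_ring = 3L,   # counting rings after the centre point
    version = "1")
}

# angle indices (1..48) used by a ring of `count` points
.ring_angle_idx <- function(count) {
  if (count == 1L) return(integer(0))
  as.integer(seq(1L, .N_ANGLES, by = .N_ANGLES / count))
}

# Merge-triangulate the band between two concentric vertex rings ordered
# by angle. Returns triangles oriented counter-clockwise seen from +z when
# ring A is inside ring B and both run counter-clockwise.
.ring_strip <- function(aV, aAng, bV, bAng) {
  n <- length(aV); m <- length(bV)
  tri <- matrix(0L, n + m, 3)
  ia <- 1L; ib <- 1L; t <- 0L
  nextA <- function() if (ia < n) aAng[ia + 1] else aAng[1] + 360
  nextB <- function() if (ib < m) bAng[ib + 1] else bAng[1] + 360
  advA <- 0L; advB <- 0L
  while (advA < n || advB < m) {
    a_next <- if (advA < n) nextA() else Inf
    b_next <- if (advB < m) nextB() else Inf
    t <- t + 1L
    if (b_next <= a_next) {
      ibn <- if (ib < m) ib + 1L else 1L
      tri[t, ] <- c(aV[ia], bV[ib], bV[ibn])
      ib <- ibn; advB <- advB + 1L
    } else {
      ian <- if (ia < n) ia + 1L else 1L
      tri[t, ] <- c(aV[ia], bV[ib], aV[ian])
      ia <- ian; advA <- advA + 1L
    }
  }
  tri
}

# fan around a centre vertex, counter-clockwise from +z
.ring_fan <- function(centre, ringV) {
  n <- length(ringV)
  cbind(centre, ringV, ringV[c(2:n, 1)])
}

.corr_cache <- new.env(parent = emptyenv())

# Vertex bookkeeping: front centre, front rings, back centre, back rings.
.corr_layout <- function() {
  if (!is.null(.corr_cache$layout)) return(.corr_cache$layout)
  rg <- correspondence_rings()
  layout <- list(rings = rg)
  id <- 0L
  take <- function(k) { v <- id + seq_len(k); id <<- id + k; v }
  fr <- rg$front; bk <- rg$back
  layout$front_centre <- take(1L)
  layout$front_ring_v <- lapply(fr$count[-1], take)
  layout$front_count <- id
  layout$back_centre <- take(1L)
  layout$back_ring_v <- lapply(bk$count[-1], take)
  layout$total <- id
  layout$back_count <- layout$total - layout$front_count
  .corr_cache$layout <- layout
  layout
}

#' Shared face list of the correspondence mesh
#'
#' The fixed triangulation connecting the landmark rings into a closed
#' orientable surface; identical for every landmark mesh.
#' @return integer m x 3 face matrix (1672 rows)
#' @export
landmark_faces <- function() {
  if (!is.null(.corr_cache$faces)) return(.corr_cache$faces)
  ly <- .corr_layout()
  fr <- ly$rings$front; bk <- ly$rings$back
  ang <- function(count) (.ring_angle_idx(count) - 1) * .ANGLE_STEP_DEG
  tris <- list()
  # front cap (CCW from +z, outward normal +z)
  tris[[length(tris) + 1]] <- .ring_fan(ly$front_centre, ly$front_ring_v[[1]])
  for (i in seq_len(length(ly$front_ring_v) - 1)) {
    tris[[length(tris) + 1]] <- .ring_strip(
      ly$front_ring_v[[i]], ang(fr$count[i + 1]),
      ly$front_ring_v[[i + 1]], ang(fr$count[i + 2]))
  }
  # back cap, built CCW then flipped so its outward normal points to -z
  back <- list(.ring_fan(ly$back_centre, ly$back_ring_v[[1]]))
  for (i in seq_len(length(ly$back_ring_v) - 1)) {
    back[[length(back) + 1]] <- .ring_strip(
      ly$back_ring_v[[i]], ang(bk$count[i + 1]),
      ly$back_ring_v[[i + 1]], ang(bk$count[i + 2]))
  }
  back <- do.call(rbind, back)[, c(1, 3, 2)]
  # junction band: front outline ring to outermost back ring
  nfr <- length(ly$front_ring_v)
  nbk <- length(ly$back_ring_v)
  junction <- .ring_strip(
    ly$front_ring_v[[nfr]], ang(fr$count[nfr + 1]),
    ly$back_ring_v[[nbk]], ang(bk$count[nbk + 1]))
  faces <- rbind(do.call(rbind, tris), junction, back)
  dimnames(faces) <- NULL
  storage.mode(faces) <- "integer"
  .corr_cache$faces <- faces
  faces
}

#' Landmark mesh constructor
#' @param points 838 x 3 matrix of landmark coordinates (mm)
#' @return object of class \code{landmark_mesh}
#' @export
landmark_mesh <- function(points) {
  ly <- .corr_layout()
  points <- as.matrix(points)
  stopifnot(nrow(points) == ly$total, ncol(points) == 3)
  structure(list(points = points, faces = landmark_faces(),
                 front_count = ly$front_count, back_count = ly$back_count,
                 scheme_version = ly$rings$version),
            class = "landmark_mesh")
}

#' @export
print.landmark_mesh <- function(x, ...) {
  cat(sprintf("<landmark_mesh: %d points (%d front / %d back), %d faces>\n",
              nrow(x$points), x$front_count, x$back_count, nrow(x$faces)))
  invisible(x)
}

#' Convert a landmark mesh to a plain mesh
#' @param lm a \code{landmark_mesh}
#' @return an \code{op_mesh}
#' @export
as_op_mesh <- function(lm) op_mesh(lm$points, lm$faces)

#' Vertex indices of a front ring
#' @param ring ring index counting outward from the centre point (the
#'   limbus is ring 3)
#' @return integer vertex indices
#' @export
limbus_ring_indices <- function(ring = correspondence_rings()$limbus_ring) {
  .corr_layout()$front_ring_v[[ring]]
}

# silhouette radius of the valid projection along one direction; errors on
# interior holes wider than `gap_px` pixels
.march_radius <- function(di, ct, st, rmax, gap_px = 2) {
  step <- di$pixel_pitch / 2
  r <- seq(0, rmax, by = step)
  px <- round((r * ct - di$origin[1]) / di$pixel_pitch + 0.5)
  py <- round((r * st - di$origin[2]) / di$pixel_pitch + 0.5)
  inside <- px >= 1 & px <= nrow(di$values) & py >= 1 & py <= ncol(di$values)
  ok <- logical(length(r))
  ok[inside] <- di$valid_mask[cbind(px[inside], py[inside])]
  last <- max(which(ok))
  if (any(!ok[seq_len(last)])) {
    runs <- rle(ok[seq_len(last)])
    gaps <- runs$lengths[!runs$values]
    if (any(gaps * step > gap_px * di$pixel_pitch))
      abort_ocuprost("hole in projection along a sampled radial line",
                     "correspondence_failure")
  }
  r[last]
}

#' Generate corresponding landmarks for an aligned shape
#'
#' Projects the shape to front and back depth maps, ray-marches 48 radial
#' lines from the origin to the silhouette, places ring points at the fixed
#' fractional distances of the versioned scheme (skipping angles on sparser
#' rings), and samples depths bilinearly. The fixed face list connects the
#' rings into a closed surface.
#'
#' @param shape an \code{aligned_shape} or \code{op_mesh} in the aligned
#'   frame
#' @param resolution depth-map resolution (pixels)
#' @param extent depth-map extent (mm)
#' @return a \code{landmark_mesh} (838 points, 1672 faces)
#' @export
generate_correspondence <- function(shape, resolution = 512, extent = 32) {
  front <- depth_project(shape, "front", resolution, extent)
  back <- depth_project(shape, "back", resolution, extent)
  cpix <- round(resolution / 2)
  if (!front$valid_mask[cpix, cpix])
    abort_ocuprost("projection does not cover the origin",
                   "correspondence_failure")
  ly <- .corr_layout()
  angles <- ((seq_len(.N_ANGLES) - 1) * .ANGLE_STEP_DEG) * pi / 180
  ct <- cos(angles); st <- sin(angles)
  rmax <- extent / 2 * 0.999
  R <- vapply(seq_len(.N_ANGLES),
              function(k) .march_radius(front, ct[k], st[k], rmax), 0)
  pts <- matrix(NA_real_, ly$total, 3)
  place <- function(vidx, fraction, count, di) {
    ai <- .ring_angle_idx(count)
    x <- fraction * R[ai] * ct[ai]
    y <- fraction * R[ai] * st[ai]
    pts[vidx, ] <<- cbind(x, y, depth_sample(di, x, y))
  }
  fr <- ly$rings$front; bk <- ly$rings$back
  pts[ly$front_centre, ] <- c(0, 0, depth_sample(front, 0, 0))
  for (i in seq_along(ly$front_ring_v))
    place(ly$front_ring_v[[i]], fr$fraction[i + 1], fr$count[i + 1], front)
  pts[ly$back_centre, ] <- c(0, 0, depth_sample(back, 0, 0))
  for (i in seq_along(ly$back_ring_v))
    place(ly$back_ring_v[[i]], bk$fraction[i + 1], bk$count[i + 1], back)
  landmark_mesh(pts)
}
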