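.cornea_indices <- function() {
  ly <- .corr_layout()
  c(ly$front_centre, unlist(ly$front_ring_v[1:3]))
}

#' Renormalize the cornea of a fitted or reconstructed shape
#'
#' Replaces the cornea region (front centre through the limbus ring) with
#' the mean shape's cornea, scaled so the apex lies 2.5 mm from the
#' origin and the limbus diameter matches the requested iris diameter.
#' The two front rings beyond the limbus blend smoothly into the original
#' surface; the posterior vertices are untouched.
#'
#' @param shape a \code{landmark_mesh}
#' @param iris_diameter mm, in (8, 14)
#' @param mean_shape the model mean \code{landmark_mesh}
#' @param apex_z target apex height (mm)
#' @return a \code{landmark_mesh}
#' @export
renormalize_cornea <- function(shape, iris_diameter, mean_shape,
                               apex_z = 2.5) {
  if (iris_diameter <= 8 || iris_diameter >= 14)
    stop("iris diameter must be in (8, 14) mm, got ", iris_diameter)
  ly <- .corr_layout()
  ci <- .cornea_indices()
  P <- shape$points
  Mc <- mean_shape$points[ci, , drop = FALSE]
  centre_z <- mean_shape$points[ly$front_centre, 3]
  s_z <- apex_z / centre_z
  r3 <- ly$front_ring_v[[3]]
  mean_limbus_d <- 2 * mean(sqrt(rowSums(mean_shape$points[r3, 1:2]^2)))
  s_xy <- iris_diameter / mean_limbus_d
  new_cornea <- cbind(Mc[, 1] * s_xy, Mc[, 2] * s_xy, Mc[, 3] * s_z)
  old_limbus <- P[r3, , drop = FALSE]
  P[ci, ] <- new_cornea
  # per-angle limbus displacement, blended outward with a cosine ramp
  delta <- P[r3, , drop = FALSE] - old_limbus
  blend <- c(0.75, 0.25)   # rings 4 and 5 (48 points each, same angles)
  for (b in seq_along(blend)) {
    ring <- ly$front_ring_v[[3 + b]]
    P[ring, ] <- P[ring, ] + blend[b] * delta
  }
  landmark_mesh(P)
}

#' Volume-increasing Loop-style subdivision
#'
#' Two rounds (by default) of Loop subdivision modified so that any
#' vertex the Loop stencil would pull inward (against the interpolated
#' vertex normal of the unrefined mesh) is reflected to the outside,
#' making the enclosed volume increase instead of shrink.
#'
#' @param mesh an \code{op_mesh} or \code{landmark_mesh} (closed manifold)
#' @param iterations number of subdivision rounds
#' @return an \code{op_mesh} with \code{4^iterations} times the faces
#' @export
subdivide_smooth <- function(mesh, iterations = 2) {
  if (inherits(mesh, "landmark_mesh")) mesh <- as_op_mesh(mesh)
  if (!mesh_is_closed(mesh))
    stop("subdivision requires a closed manifold mesh")
  for (i in seq_len(iterations)) mesh <- .loop_subdivide_outward(mesh)
  mesh
}

.loop_subdivide_outward <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  nV <- nrow(V); nF <- nrow(F)
  N <- mesh_vertex_normals(mesh)
  # undirected edges with the two opposite vertices
  he_from <- c(F[, 1], F[, 2], F[, 3])
  he_to <- c(F[, 2], F[, 3], F[, 1])
  he_opp <- c(F[, 3], F[, 1], F[, 2])
  lo <- pmin(he_from, he_to); hi <- pmax(he_from, he_to)
  key <- (lo - 1) * nV + hi
  ek <- unique(key)
  eid <- match(key, ek)
  nE <- length(ek)
  a <- (ek - 1) %/% nV + 1; b <- (ek - 1) %% nV + 1
  opp <- matrix(NA_integer_, nE, 2)
  slot <- integer(nE)
  for (h in seq_along(eid)) {
    e <- eid[h]
    slot[e] <- slot[e] + 1L
    opp[e, slot[e]] <- he_opp[h]
  }
  if (any(is.na(opp))) stop("non-manifold mesh")
  # odd vertices (Loop edge stencil), reflected outward when pulled in
  m_lin <- (V[a, , drop = FALSE] + V[b, , drop = FALSE]) / 2
  m_loop <- 0.375 * (V[a, , drop = FALSE] + V[b, , drop = FALSE]) +
    0.125 * (V[opp[, 1], , drop = FALSE] + V[opp[, 2], , drop = FALSE])
  n_e <- N[a, , drop = FALSE] + N[b, , drop = FALSE]
  n_e <- n_e / pmax(sqrt(rowSums(n_e^2)), 1e-12)
  d <- rowSums((m_loop - m_lin) * n_e)
  refl <- pmin(d, 0)
  m_new <- m_loop - 2 * refl * n_e
  # even vertices (Loop vertex stencil), likewise reflected
  deg <- tabulate(c(a, b), nV)
  nb_sum <- rowsum(rbind(V[b, , drop = FALSE], V[a, , drop = FALSE]),
                   c(a, b))
  nb_sum <- nb_sum[order(as.integer(rownames(nb_sum))), , drop = FALSE]
  beta <- (1 / deg) * (5 / 8 - (3 / 8 + 0.25 * cos(2 * pi / deg))^2)
  v_loop <- (1 - deg * beta) * V + beta * nb_sum
  dv <- rowSums((v_loop - V) * N)
  v_new <- v_loop - 2 * pmin(dv, 0) * N
  # faces: 4 children per parent
  e1 <- eid[seq_len(nF)]                 # edge (v1, v2)
  e2 <- eid[nF + seq_len(nF)]            # edge (v2, v3)
  e3 <- eid[2 * nF + seq_len(nF)]        # edge (v3, v1)
  m1 <- nV + e1; m2 <- nV + e2; m3 <- nV + e3
  newF <- rbind(cbind(F[, 1], m1, m3),
                cbind(F[, 2], m2, m1),
                cbind(F[, 3], m3, m2),
                cbind(m1, m2, m3))
  op_mesh(rbind(v_new, m_new), newF)
}

# smooth 0..1 ramp
.smoothstep <- function(t) {
  t <- clamp(t, 0, 1)
  t * t * (3 - 2 * t)
}

#' Clear-coat thickness map
#'
#' Per-vertex clear-coat displacement: predicted prostheses get a
#' locally varying coat, thicker in the lid-contact zones (large |y|
#' latitude) and toward the equatorial edge, between
#' \code{range_mm[1]} and \code{range_mm[2]}; reconstructed prostheses
#' get a uniform 0.2 mm coat.
#' @param mesh an \code{op_mesh}
#' @param mode "predicted" or "reconstructed"
#' @param range_mm coat thickness range for the predicted mode
#' @return numeric vector of per-vertex thickness (mm)
#' @export
clearcoat_map <- function(mesh, mode = c("predicted", "reconstructed"),
                          range_mm = c(0.1, 0.5)) {
  mode <- match.arg(mode)
  V <- mesh$vertices
  if (mode == "reconstructed") return(rep(0.2, nrow(V)))
  r <- sqrt(rowSums(V^2))
  rho <- sqrt(V[, 1]^2 + V[, 2]^2)
  w_lid <- .smoothstep((abs(V[, 2]) / pmax(r, 1e-9) - 0.3) / 0.5)
  w_edge <- .smoothstep((rho / max(rho) - 0.75) / 0.2)
  range_mm[1] + (range_mm[2] - range_mm[1]) * pmax(w_lid, w_edge)
}

#' Oversize a predicted shape and attach the clear coat
#'
#' Predicted mode: radial scaling about the origin enlarges the
#' prosthesis by 5 percent with a smooth cosine falloff to 1.0 inside
#' the limbus (over a 2 mm band just outside it) so the cornea size is
#' unchanged; the clear coat varies locally. Reconstructed mode: no
#' enlargement, uniform 0.2 mm coat.
#'
#' @param mesh an \code{op_mesh} or \code{landmark_mesh} (cornea already
#'   renormalized)
#' @param mode "predicted" or "reconstructed"
#' @param limbus_radius mm; radial scaling reaches 5 percent beyond
#'   \code{limbus_radius + blend_mm}
#' @param blend_mm width of the cosine blend band
#' @return object of class \code{processed_shape}: \code{mesh},
#'   \code{clearcoat} (per-vertex mm), \code{provenance}, \code{bbox}
#' @export
oversize_and_coat <- function(mesh, mode = c("predicted", "reconstructed"),
                              limbus_radius = 5.9, blend_mm = 2) {
  mode <- match.arg(mode)
  if (inherits(mesh, "landmark_mesh")) mesh <- as_op_mesh(mesh)
  V <- mesh$vertices
  if (mode == "predicted") {
    rho <- sqrt(V[, 1]^2 + V[, 2]^2)
    t <- clamp((rho - limbus_radius) / blend_mm, 0, 1)
    w <- (1 - cos(pi * t)) / 2
    V <- V * (1 + 0.05 * w)
  }
  out <- op_mesh(V, mesh$faces)
  structure(list(mesh = out, clearcoat = clearcoat_map(out, mode),
                 provenance = mode, bbox = mesh_bbox(out)),
            class = "processed_shape")
}

#' @export
print.processed_shape <- function(x, ...) {
  cat(sprintf("<processed_shape (%s): %d vertices, bbox %s mm>\n",
              x$provenance, nrow(x$mesh$vertices),
              paste(sprintf("%.1f", x$bbox$size), collapse = " x ")))
  invisible(x)
}

#' Regulatory size gate
#'
#' Shapes whose axis-aligned bounding box exceeds 30 x 29 x 20 mm
#' (width, height, depth) in any dimension are rejected; a box exactly at
#' the limit is accepted.
#' @param shape an \code{op_mesh}, \code{landmark_mesh} or
#'   \code{processed_shape}
#' @param limits mm (width, height, depth)
#' @return "accept" or "reject"
#' @export
safety_gate <- function(shape, limits = c(30, 29, 20)) {
  mesh <- if (inherits(shape, "processed_shape")) shape$mesh
          else if (inherits(shape, "landmark_mesh")) as_op_mesh(shape)
          else shape
  size <- mesh_bbox(mesh)$size
  if (any(size > limits + 1e-9)) "reject" else "accept"
}

#' Post-process a shape into printable geometry
#'
#' Cornea renormalization, two rounds of volume-increasing subdivision,
#' oversizing and clear coat, and the safety gate.
#' @param shape a \code{landmark_mesh} (fitted or reconstructed)
#' @param iris_diameter mm
#' @param mean_shape model mean \code{landmark_mesh}
#' @param mode "predicted" or "reconstructed"
#' @return a \code{processed_shape} with an \code{accepted} flag
#' @export
process_shape <- function(shape, iris_diameter, mean_shape,
                          mode = c("predicted", "reconstructed")) {
  mode <- match.arg(mode)
  lim_r <- iris_diameter / 2
  lm <- renormalize_cornea(shape, iris_diameter, mean_shape)
  refined <- subdivide_smooth(lm, 2)
  ps <- oversize_and_coat(refined, mode, limbus_radius = lim_r)
  ps$accepted <- safety_gate(ps) == "accept"
  ps
}

#' Reconstruct a prosthesis from a marked scan
#'
#' Alignment and correspondence give the shape directly; it bypasses the
#' shape model entirely (so shapes outside the model span replicate
#' faithfully) and is post-processed in reconstructed mode: no 5 percent
#' oversizing, uniform 0.2 mm clear coat.
#' @param scan a \code{marked_scan}
#' @param iris_diameter mm
#' @param mean_shape model mean \code{landmark_mesh} (for the cornea)
#' @return a \code{processed_shape}
#' @export
reconstruct_shape <- function(scan, iris_diameter, mean_shape) {
  aligned <- align_shape(scan)
  lm <- generate_correspondence(aligned)
  process_shape(lm, iris_diameter, mean_shape, "reconstructed")
}
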