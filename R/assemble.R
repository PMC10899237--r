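#' Assemble the printable prosthesis model
#'
#' Fuses the iris disc into the prosthesis body at the limbus plane
#' (the disc is scaled to the body's limbus ring so the seam closes),
#' places the black pupil cylinder, assigns UVs (spherical about the
#' origin for the body sclera texture, angle/radius for the iris) and
#' collects textures and metadata.
#'
#' @param processed a \code{processed_shape}
#' @param iris_geo an \code{iris_geometry}
#' @param sclera_texture a \code{sclera_texture}
#' @param iris_texture an \code{iris_texture}
#' @param metadata named list (conformer id, alpha, th, br, ...)
#' @return object of class \code{prosthesis_model}
#' @export
assemble_model <- function(processed, iris_geo, sclera_texture,
                           iris_texture, metadata = list()) {
  body <- processed$mesh
  # spherical UVs for the body
  V <- body$vertices
  r <- pmax(sqrt(rowSums(V^2)), 1e-9)
  u <- atan2(V[, 2], V[, 1]) / (2 * pi)
  u <- ifelse(u < 0, u + 1, u)
  theta <- acos(clamp(V[, 3] / r, -1, 1))
  body$uv <- cbind(u, 1 - theta / pi)
  # snap the iris disc to the body's limbus ring
  ring <- .limbus_ring_curve(body, iris_geo$outer_radius)
  disc <- iris_geo$disc
  scale_r <- ring$radius / iris_geo$outer_radius
  disc$vertices[, 1:2] <- disc$vertices[, 1:2] * scale_r
  disc$vertices[, 3] <- disc$vertices[, 3] + ring$z
  cyl <- iris_geo$cylinder
  cyl$vertices[, 3] <- cyl$vertices[, 3] + ring$z
  seam <- .seam_gap(disc, ring)
  structure(list(body = body, iris = disc, pupil_cylinder = cyl,
                 sclera_texture = sclera_texture,
                 iris_texture = iris_texture,
                 seam_gap = seam,
                 metadata = c(metadata,
                              list(scheme = "ocuprost-model",
                                   version = "1"))),
            class = "prosthesis_model")
}

# body limbus ring: mesh cross-section nearest the iris plane at the
# expected radius, fitted as a circle (radius + plane height)
.limbus_ring_curve <- function(body, expect_r) {
  V <- body$vertices
  rho <- sqrt(V[, 1]^2 + V[, 2]^2)
  sel <- abs(rho - expect_r) < 1.5 & abs(V[, 3]) < 2
  if (sum(sel) < 8) sel <- abs(rho - expect_r) < 3
  list(radius = mean(rho[sel]), z = mean(V[sel, 3]))
}

# max distance from the disc rim to the body limbus circle
.seam_gap <- function(disc, ring) {
  loops <- .boundary_loops(disc)
  if (length(loops) == 0) return(0)
  rad <- vapply(loops, function(l)
    mean(sqrt(rowSums(disc$vertices[l, 1:2, drop = FALSE]^2))), 0)
  rim <- loops[[which.max(rad)]]
  Vr <- disc$vertices[rim, , drop = FALSE]
  rho <- sqrt(Vr[, 1]^2 + Vr[, 2]^2)
  max(sqrt((rho - ring$radius)^2 + (Vr[, 3] - ring$z)^2))
}

#' @export
print.prosthesis_model <- function(x, ...) {
  cat(sprintf(
    "<prosthesis_model: body %d faces, iris %d faces, seam %.3g mm>\n",
    nrow(x$body$faces), nrow(x$iris$faces), x$seam_gap))
  invisible(x)
}

# write a lab texture as an sRGB PNG
.write_lab_png <- function(lab, path) {
  d <- dim(lab)
  rgb <- srgb_from_lab(matrix(lab, ncol = 3))
  png::writePNG(array(rgb, c(d[1], d[2], 3)), path)
  invisible(path)
}

#' Write an assembled model as OBJ + MTL + textures
#'
#' Writes \code{prosthesis.obj} (body, iris and pupil-cylinder groups),
#' \code{prosthesis.mtl}, sclera and iris textures (sRGB PNG), the
#' clear-coat displacement map (16-bit grey PNG, mm scaled by
#' \code{coat_scale}) and \code{metadata.json}.
#'
#' @param model a \code{prosthesis_model}
#' @param dir output directory (created when missing)
#' @param clearcoat per-vertex coat thickness of the body (mm), written
#'   as a displacement texture over the body UVs
#' @param coat_scale mm value mapped to full white
#' @return the directory, invisibly
#' @export
write_prosthesis_model <- function(model, dir, clearcoat = NULL,
                                   coat_scale = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- file.path(dir, "prosthesis.obj")
  con <- file(obj, "w")
  writeLines("mtllib prosthesis.mtl", con)
  off_v <- 0L; off_t <- 0L
  emit <- function(mesh, name, material) {
    V <- mesh$vertices
    writeLines(sprintf("o %s", name), con)
    writeLines(sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
    has_uv <- !is.null(mesh$uv)
    if (has_uv)
      writeLines(sprintf("vt %.6f %.6f", mesh$uv[, 1], mesh$uv[, 2]), con)
    writeLines(sprintf("usemtl %s", material), con)
    F <- mesh$faces + off_v
    if (has_uv) {
      Ft <- mesh$faces + off_t
      writeLines(sprintf("f %d/%d %d/%d %d/%d",
                         F[, 1], Ft[, 1], F[, 2], Ft[, 2],
                         F[, 3], Ft[, 3]), con)
      off_t <<- off_t + nrow(V)
    } else {
      writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
    }
    off_v <<- off_v + nrow(V)
  }
  emit(model$body, "body", "sclera")
  emit(model$iris, "iris", "iris")
  emit(model$pupil_cylinder, "pupil_cylinder", "black")
  close(con)
  writeLines(c("newmtl sclera", "map_Kd sclera.png",
               "newmtl iris", "map_Kd iris.png",
               "newmtl black", "Kd 0 0 0"),
             file.path(dir, "prosthesis.mtl"))
  .write_lab_png(model$sclera_texture$lab, file.path(dir, "sclera.png"))
  .write_lab_png(model$iris_texture$lab, file.path(dir, "iris.png"))
  if (!is.null(clearcoat)) {
    cc <- clamp(clearcoat / coat_scale, 0, 1)
    # bake per-vertex coat into a texture over the body UVs
    tex <- matrix(0, 256, 256)
    cnt <- matrix(0, 256, 256)
    uv <- model$body$uv
    px <- clamp(floor(uv[, 1] * 255) + 1, 1, 256)
    py <- clamp(floor(uv[, 2] * 255) + 1, 1, 256)
    for (i in seq_along(px)) {
      tex[py[i], px[i]] <- tex[py[i], px[i]] + cc[i]
      cnt[py[i], px[i]] <- cnt[py[i], px[i]] + 1
    }
    tex <- ifelse(cnt > 0, tex / pmax(cnt, 1), 0)
    png::writePNG(tex, file.path(dir, "clearcoat.png"))
  }
  jsonlite::write_json(c(model$metadata, list(seam_gap = model$seam_gap)),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
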