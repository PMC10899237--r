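#' Conformer specification
#'
#' Metadata for a transparent scanning conformer derived from an SSM base
#' shape: shape-space coordinates of the base shape, flat-window geometry
#' (offset below the iris plane, thickness, diameter), material refractive
#' index and eye side. The window offset increases the effective raster
#' depth; the extraction stage needs thickness, offset and index, not the
#' carved geometry itself.
#'
#' @param id identifier (e.g. "A05")
#' @param x_c shape-space coordinates of the base shape
#' @param window_offset mm below the iris plane of the anterior window
#'   plane
#' @param window_thickness mm
#' @param window_diameter mm, must be in (10, 16)
#' @param refractive_index of the window material
#' @param side "left" or "right"
#' @return object of class \code{conformer_spec}
#' @export
conformer_spec <- function(id, x_c, window_offset = 1.8,
                           window_thickness = 1.5, window_diameter = 15,
                           refractive_index = 1.5,
                           side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(window_diameter > 10, window_diameter < 16,
            window_thickness > 0, all(is.finite(x_c)))
  structure(list(id = id, x_c = as.numeric(x_c),
                 window_offset = window_offset,
                 window_thickness = window_thickness,
                 window_diameter = window_diameter,
                 refractive_index = refractive_index, side = side),
            class = "conformer_spec")
}

#' Visible window area of a conformer
#' @param spec a \code{conformer_spec}
#' @return area of the circular window in mm^2 (the upper bound on visible
#'   socket surface)
#' @export
conformer_window_area <- function(spec) pi * (spec$window_diameter / 2)^2

#' Derive a conformer from an SSM base shape
#'
#' Projects the base shape into shape space (x_c), then modifies the
#' synthesized base geometry: the anterior surface is cut by a plane
#' parallel to the iris plane at \code{window_offset} mm below it, with a
#' conical frustum wall (default 30 degree slope) running from the window
#' rim back to the uncut surface, forming a flat circular window.
#' Left-side conformers are mirrored across the y-z plane.
#'
#' @param model a \code{shape_model}
#' @param base a \code{landmark_mesh} base shape
#' @param id conformer identifier
#' @param wall_slope_deg frustum wall slope (degrees from the window plane)
#' @param ... window parameters passed to \code{\link{conformer_spec}}
#' @return list with \code{spec} (a \code{conformer_spec}) and \code{mesh}
#'   (the carved \code{op_mesh})
#' @export
make_conformer <- function(model, base, id, wall_slope_deg = 30, ...) {
  spec <- conformer_spec(id, x_c = project_shape(model, base), ...)
  base_mesh <- synthesize(model, spec$x_c)
  V <- base_mesh$points
  z_w <- -spec$window_offset
  if (min(V[, 3]) >= z_w)
    stop("base shape too shallow to cut a window at offset ",
         spec$window_offset, " mm")
  r_w <- spec$window_diameter / 2
  rho <- sqrt(V[, 1]^2 + V[, 2]^2)
  slope <- tan(wall_slope_deg * pi / 180)
  # flat window inside r_w, frustum wall outside
  cap <- ifelse(rho <= r_w, z_w, z_w + (rho - r_w) * slope)
  Vc <- V
  Vc[, 3] <- pmin(V[, 3], cap)
  faces <- base_mesh$faces
  if (spec$side == "left") {
    Vc[, 1] <- -Vc[, 1]
    faces <- faces[, c(1, 3, 2)]
  }
  list(spec = spec, mesh = op_mesh(Vc, faces))
}

#' Write a conformer registry
#'
#' JSON table keyed by conformer id; round-trips the shape vector and
#' window geometry used at scan time.
#' @param specs list of \code{conformer_spec}
#' @param path output JSON file
#' @export
write_conformer_registry <- function(specs, path) {
  entries <- lapply(specs, function(s) {
    list(x_c = s$x_c, window_offset = s$window_offset,
         window_thickness = s$window_thickness,
         window_diameter = s$window_diameter,
         refractive_index = s$refractive_index, side = s$side)
  })
  names(entries) <- vapply(specs, `[[`, "", "id")
  jsonlite::write_json(list(format = "ocuprost-conformers", version = "1",
                            conformers = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a conformer registry
#' @param path JSON file from \code{\link{write_conformer_registry}}
#' @return named list of \code{conformer_spec}
#' @export
read_conformer_registry <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(o$format, "ocuprost-conformers"))
  out <- lapply(names(o$conformers), function(id) {
    e <- o$conformers[[id]]
    conformer_spec(id, e$x_c, e$window_offset, e$window_thickness,
                   e$window_diameter, e$refractive_index, e$side)
  })
  setNames(out, names(o$conformers))
}
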