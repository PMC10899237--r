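#' Depth image
#'
#' Orthographic per-pixel surface depth along z over a regular x-y grid.
#' Pixel (i, j) is centred at \code{origin + (c(i, j) - 0.5) * pixel_pitch}.
#'
#' @param values numeric matrix of z values (mm); NA where invalid
#' @param valid_mask logical matrix; defaults to \code{!is.na(values)}
#' @param pixel_pitch mm per pixel
#' @param origin (x, y) of the grid corner in mm
#' @return object of class \code{depth_image}
#' @export
depth_image <- function(values, valid_mask = NULL, pixel_pitch, origin) {
  if (is.null(valid_mask)) valid_mask <- !is.na(values)
  stopifnot(all(dim(values) == dim(valid_mask)), pixel_pitch > 0)
  stopifnot(all(is.finite(values[valid_mask])))
  structure(list(values = values, valid_mask = valid_mask,
                 pixel_pitch = pixel_pitch, origin = as.numeric(origin)),
            class = "depth_image")
}

#' Orthographic depth projection of a mesh
#'
#' Projects the surface along the z axis onto a square grid centred on the
#' origin. The front view keeps, per pixel, the surface point nearest a
#' viewer at +z (maximum z); the back view the farthest (minimum z).
#'
#' @param mesh an \code{op_mesh} in the aligned iris-plane frame
#' @param side "front" or "back"
#' @param resolution grid size in pixels (square)
#' @param extent physical edge length in mm
#' @return a \code{depth_image}
#' @export
depth_project <- function(mesh, side = c("front", "back"),
                          resolution = 512, extent = 32) {
  side <- match.arg(side)
  if (inherits(mesh, "aligned_shape")) mesh <- mesh$mesh
  if (nrow(mesh$faces) == 0) stop("empty mesh")
  pitch <- extent / resolution
  x0 <- -extent / 2
  vals <- .cpp_rasterize_depth(mesh$vertices, mesh$faces,
                               resolution, resolution, x0, x0, pitch,
                               side == "front")
  depth_image(vals, pixel_pitch = pitch, origin = c(x0, x0))
}

#' Bilinear depth sampling with nearest-valid fallback
#'
#' Samples a depth image at arbitrary (x, y) positions in mm. At
#' invalid-pixel boundaries the sample falls back to the nearest valid
#' pixel; gaps wider than \code{max_gap_px} raise an error.
#'
#' @param di a \code{depth_image}
#' @param x,y coordinates in mm
#' @param max_gap_px maximum tolerated distance (pixels) to a valid pixel
#' @return numeric vector of depths
#' @export
depth_sample <- function(di, x, y, max_gap_px = 2) {
  px <- (x - di$origin[1]) / di$pixel_pitch + 0.5
  py <- (y - di$origin[2]) / di$pixel_pitch + 0.5
  nx <- nrow(di$values); ny <- ncol(di$values)
  i0 <- clamp(floor(px), 1, nx - 1); j0 <- clamp(floor(py), 1, ny - 1)
  fx <- clamp(px - i0, 0, 1); fy <- clamp(py - j0, 0, 1)
  idx <- function(i, j) di$values[cbind(i, j)]
  v00 <- idx(i0, j0);     v10 <- idx(i0 + 1, j0)
  v01 <- idx(i0, j0 + 1); v11 <- idx(i0 + 1, j0 + 1)
  out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
         (1 - fx) * fy * v01 + fx * fy * v11
  bad <- which(!is.finite(out))
  if (length(bad) > 0) {
    valid_idx <- which(di$valid_mask, arr.ind = TRUE)
    for (b in bad) {
      d2 <- (valid_idx[, 1] - px[b])^2 + (valid_idx[, 2] - py[b])^2
      m <- which.min(d2)
      if (sqrt(d2[m]) > max_gap_px)
        abort_ocuprost(
          sprintf("no valid depth within %g px of (%.2f, %.2f) mm",
                  max_gap_px, x[b], y[b]),
          "correspondence_failure")
      out[b] <- di$values[valid_idx[m, 1], valid_idx[m, 2]]
    }
  }
  out
}

#' @export
print.depth_image <- function(x, ...) {
  cat(sprintf("<depth_image: %d x %d px, pitch %.4g mm, %d valid>\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch,
              sum(x$valid_mask)))
  invisible(x)
}
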