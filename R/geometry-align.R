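#' Marked prosthesis scan
#'
#' A scanned prosthesis mesh together with the four limbus-crosshair
#' intersection points (superior, nasal, inferior, temporal) and the eye
#' side.
#'
#' @param mesh an \code{op_mesh} (vertices in mm, arbitrary frame)
#' @param p_S,p_N,p_I,p_T marker 3-vectors (mm)
#' @param eye_side "left" or "right"
#' @return object of class \code{marked_scan}
#' @export
marked_scan <- function(mesh, p_S, p_N, p_I, p_T, eye_side = "right") {
  eye_side <- match.arg(eye_side, c("left", "right"))
  structure(list(mesh = mesh,
                 p_S = as.numeric(p_S), p_N = as.numeric(p_N),
                 p_I = as.numeric(p_I), p_T = as.numeric(p_T),
                 eye_side = eye_side),
            class = "marked_scan")
}

#' Align a marked scan into the canonical iris-plane frame
#'
#' Translates by minus the marker centroid and rotates with the orthogonal
#' Procrustes solution that sends the nasal/superior/inferior/temporal
#' markers onto the +x/+y/-y/-x directions, so the limbus lies in the x-y
#' plane with its centre at the origin and +z points toward the cornea.
#' Left-eye scans are mirrored across the y-z plane afterwards (with face
#' winding flipped) so every shape fits a right socket.
#'
#' @param scan a \code{marked_scan}
#' @return object of class \code{aligned_shape}: the transformed
#'   \code{mesh}, transformed \code{markers}, the rigid transform
#'   (\code{rotation}, \code{translation}) and the marker residual (mm)
#' @export
align_shape <- function(scan) {
  stopifnot(inherits(scan, "marked_scan"))
  P0 <- rbind(scan$p_N, scan$p_S, scan$p_I, scan$p_T)
  ctr <- colMeans(P0)
  P <- sweep(P0, 2, ctr)
  if (qr(P)$rank < 2 ||
      min(svd(P)$d[1:2]) < 1e-9 * max(1, svd(P)$d[1]))
    abort_ocuprost("marker points are collinear or degenerate",
                   "alignment_degenerate")
  # target directions for (N, S, I, T); scale is irrelevant after the
  # orthogonal Procrustes projection
  Tm <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(-1, 0, 0))
  s <- svd(crossprod(P, Tm))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u; u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  xf <- function(X) sweep(as.matrix(X), 2, ctr) %*% R
  V <- xf(scan$mesh$vertices)
  F <- scan$mesh$faces
  markers <- xf(P0)
  # residual against the target directions, before any mirroring
  dirs <- markers / sqrt(rowSums(markers^2))
  resid <- sqrt(mean((dirs - Tm)^2))
  mirrored <- scan$eye_side == "left"
  if (mirrored) {
    V[, 1] <- -V[, 1]
    markers[, 1] <- -markers[, 1]
    F <- F[, c(1, 3, 2)]
  }
  structure(list(mesh = op_mesh(V, F),
                 markers = markers,
                 rotation = R, translation = -ctr,
                 mirrored = mirrored,
                 marker_residual = resid),
            class = "aligned_shape")
}

#' @export
print.aligned_shape <- function(x, ...) {
  cat(sprintf("<aligned_shape: %d vertices, residual %.2e mm%s>\n",
              nrow(x$mesh$vertices), x$marker_residual,
              if (x$mirrored) ", mirrored" else ""))
  invisible(x)
}
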