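# flatten an (nx, ny, nz) array to columns x depth
.cols_by_depth <- function(V) {
  d <- dim(V)
  matrix(V, d[1] * d[2], d[3])
}

# least-squares plane depth = c + a*ix + b*iy over masked columns
.fit_plane <- function(D, mask, nx, ny) {
  idx <- which(mask)
  if (length(idx) < 3) stop("degenerate window mask during plane fit")
  ix <- (idx - 1) %% nx + 1
  iy <- (idx - 1) %/% nx + 1
  cf <- lsfit(cbind(ix, iy), D[idx])$coefficients
  unname(cf) # (intercept, a, b)
}

.plane_values <- function(cf, nx, ny) {
  outer(seq_len(nx) * cf[2], seq_len(ny) * cf[3], `+`) + cf[1]
}

#' Trace the conformer window surfaces in the edge volume
#'
#' Pixel-wise column tracing along depth: the anterior surface is the
#' first edge hit per column, masked to depths below
#' \code{median + 0.75 tau} and refined 8 times by fitting a plane and
#' keeping columns within \code{0.5 tau} of it. The posterior surface
#' starts \code{0.5 tau} deeper, is refined 4 times, and its mask is
#' cleaned with a median filter and morphological opening. \code{tau} is
#' the window thickness in voxels.
#'
#' @param fv a \code{filtered_volumes}
#' @param conformer a \code{conformer_spec}
#' @param min_columns minimum number of columns with edge hits
#' @return object of class \code{window_surfaces}: depth maps \code{D_A},
#'   \code{D_B} (voxels), masks \code{M_A}, \code{M_B}, plane coefficients
#'   \code{P_A}, \code{P_B} (intercept, x, y in voxel units), \code{tau}
#' @export
trace_window <- function(fv, conformer, min_columns = 500) {
  g <- fv$geometry
  tau <- max(1, round(conformer$window_thickness / g$z_pitch))
  E <- .cols_by_depth(fv$V_Edge) * 1L
  hit <- rowSums(E) > 0
  if (sum(hit) < min_columns)
    abort_ocuprost(sprintf(
      "no conformer window found: only %d columns with edge hits",
      sum(hit)), "no_window_found")
  first_hit <- rep(NA_real_, length(hit))
  first_hit[hit] <- max.col(E[hit, , drop = FALSE], ties.method = "first")
  D_A <- matrix(first_hit, g$nx, g$ny)
  M_A <- !is.na(D_A) & D_A < (median(D_A, na.rm = TRUE) + 0.75 * tau)
  for (it in seq_len(8)) {
    P_A <- .fit_plane(D_A, M_A, g$nx, g$ny)
    M_A <- !is.na(D_A) & abs(D_A - .plane_values(P_A, g$nx, g$ny)) < 0.5 * tau
  }
  # posterior: search from D_A + 0.5 tau downward
  D_B <- matrix(NA_real_, g$nx, g$ny)
  M_B <- M_A
  cols <- which(M_B)
  Emat <- E
  for (ci in cols) {
    z0 <- floor(D_A[ci] + 0.5 * tau)
    prof <- Emat[ci, ]
    zi <- which(prof[seq.int(min(z0 + 1, g$nz), g$nz)] > 0)
    if (length(zi) == 0) { M_B[ci] <- FALSE; next }
    D_B[ci] <- min(z0 + 1, g$nz) + zi[1] - 1
  }
  for (it in seq_len(4)) {
    P_B <- .fit_plane(D_B, M_B, g$nx, g$ny)
    M_B <- !is.na(D_B) & abs(D_B - .plane_values(P_B, g$nx, g$ny)) < 0.5 * tau
  }
  # close gaps: median filter then morphological opening on the mask
  Mb <- EBImage::medianFilter(M_B * 1, size = 1) > 0.5
  Mb <- EBImage::opening(Mb, EBImage::makeBrush(3, "box")) > 0.5
  M_B <- as.matrix(Mb) & !is.na(D_B)
  structure(list(D_A = D_A, M_A = M_A, P_A = P_A,
                 D_B = D_B, M_B = M_B, P_B = P_B,
                 tau = tau, geometry = g),
            class = "window_surfaces")
}

#' Trace the socket surface below the conformer window
#'
#' For each column in the posterior window mask, starts
#' \code{z0_offset} voxels below the posterior window surface; finds the
#' global intensity maximum z1 beyond z0, the position z2 of steepest
#' rise from z0, and takes the socket surface z3 as the last zero-valued
#' voxel before z2. A 5x5 median filter rejects outliers deviating more
#' than \code{outlier_mm}. Aborts when the surviving mask covers less
#' than \code{min_area_mm2}.
#'
#' @param fv a \code{filtered_volumes}
#' @param windows a \code{window_surfaces}
#' @param z0_offset voxels below D_B at which tracing starts; default
#'   scales the full-resolution value of 10 voxels with the depth
#'   resolution
#' @param outlier_mm median-deviation rejection threshold (mm)
#' @param min_area_mm2 abort threshold on the extracted area
#' @return list with \code{D_raw} (depth in voxels), \code{mask},
#'   \code{area_mm2}
#' @export
trace_socket <- function(fv, windows, z0_offset = NULL, outlier_mm = 0.5,
                         min_area_mm2 = 32) {
  g <- fv$geometry
  if (is.null(z0_offset)) z0_offset <- max(1, round(10 * g$nz / 469))
  Vm <- .cols_by_depth(fv$V_Median)
  D <- matrix(NA_real_, g$nx, g$ny)
  for (ci in which(windows$M_B)) {
    z0 <- round(windows$D_B[ci] + z0_offset)
    if (!is.finite(z0) || z0 >= g$nz - 2) next
    v <- Vm[ci, ]
    zs <- (z0 + 1):g$nz
    z1 <- zs[which.max(v[zs])]
    zr <- (z0 + 1):z1
    slopes <- (v[zr] - v[z0]) / (zr - z0)
    z2 <- zr[which.max(slopes)]
    zeros <- which(v[seq_len(z2 - 1)] == 0)
    zeros <- zeros[zeros > z0]
    if (length(zeros) == 0) next
    D[ci] <- max(zeros)
  }
  mask <- !is.na(D)
  # 5x5 neighbourhood median for outlier rejection
  med <- .neighbourhood_median(D, 2)
  keep <- mask & abs(D - med) <= outlier_mm / g$z_pitch
  keep[is.na(keep)] <- FALSE
  area <- sum(keep) * g$x_pitch * g$y_pitch
  if (area < min_area_mm2)
    abort_ocuprost(sprintf(
      "extracted socket mask covers %.1f mm^2 (< %g mm^2): aborting",
      area, min_area_mm2), "socket_area_abort")
  list(D_raw = D, mask = keep, area_mm2 = area)
}

.neighbourhood_median <- function(D, r) {
  nx <- nrow(D); ny <- ncol(D)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  stack <- array(NA_real_, c(nx, ny, nrow(offs)))
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    si <- seq_len(nx) + di; sj <- seq_len(ny) + dj
    ok_i <- si >= 1 & si <= nx; ok_j <- sj >= 1 & sj <= ny
    stack[ok_i, ok_j, k] <- D[si[ok_i], sj[ok_j]]
  }
  apply(stack, c(1, 2), median, na.rm = TRUE)
}

#' Correct the raw socket trace and resample to the iris-plane grid
#'
#' Applies the three corrections to the traced point cloud: (1) Snell
#' refraction at the tilted conformer window (refractive index from the
#' conformer spec) as an in-plane displacement, plus the empiric depth
#' bias of \code{-0.35 d} for effective window thickness d in mm; (2) a z
#' shift placing the anterior window plane through the origin, plus the
#' window offset below the iris plane; (3) a rotation of the gaze angle
#' (default 6 degrees) about the y axis. The corrected cloud is resampled
#' to a square mm grid.
#'
#' @param raw output of \code{\link{trace_socket}}
#' @param windows a \code{window_surfaces}
#' @param conformer a \code{conformer_spec}
#' @param gaze_deg gaze-angle correction (degrees, about y)
#' @param out_res output grid resolution (pixels)
#' @param out_extent output grid extent (mm)
#' @return object of class \code{socket_depth_map}: \code{values} (depth
#'   in mm, positive into the socket, measured from the iris plane),
#'   \code{mask}, \code{pitch}, \code{origin}, \code{area_mm2}, and the
#'   corrected point cloud \code{points}
#' @export
correct_and_grid <- function(raw, windows, conformer, gaze_deg = 6,
                             out_res = 256, out_extent = 16) {
  g <- windows$geometry
  idx <- which(raw$mask)
  ix <- (idx - 1) %% g$nx + 1
  iy <- (idx - 1) %/% g$nx + 1
  x <- (ix - 0.5) * g$x_pitch - g$width_mm / 2
  y <- (iy - 0.5) * g$y_pitch - g$height_mm / 2
  depth <- raw$D_raw[idx] * g$z_pitch
  # anterior plane in mm: depth_mm(x, y) and its lateral gradient
  cf <- windows$P_A
  if (!all(is.finite(cf))) stop("degenerate anterior plane")
  gx <- cf[2] * g$z_pitch / g$x_pitch
  gy <- cf[3] * g$z_pitch / g$y_pitch
  gnorm <- sqrt(gx^2 + gy^2)
  d_eff <- conformer$window_thickness
  if (gnorm > 1e-9) {
    theta_i <- atan(gnorm)
    theta_t <- asin(sin(theta_i) / conformer$refractive_index)
    shift <- d_eff * (tan(theta_i) - tan(theta_t))
    x <- x - shift * gx / gnorm
    y <- y - shift * gy / gnorm
  }
  depth <- depth - 0.35 * d_eff
  # plane depth at the lateral origin, in mm
  c0 <- (g$nx / 2 + 0.5) * cf[2] + (g$ny / 2 + 0.5) * cf[3] + cf[1]
  depth <- depth - c0 * g$z_pitch + conformer$window_offset
  # gaze correction: rotate about y by gaze_deg (frame z = -depth)
  psi <- gaze_deg * pi / 180
  z <- -depth
  xr <- x * cos(psi) + z * sin(psi)
  zr <- -x * sin(psi) + z * cos(psi)
  pts <- cbind(x = xr, y = y, z = zr)
  # resample to the output grid
  pitch <- out_extent / out_res
  pi_ <- floor((xr + out_extent / 2) / pitch) + 1
  pj <- floor((y + out_extent / 2) / pitch) + 1
  ok <- pi_ >= 1 & pi_ <= out_res & pj >= 1 & pj <= out_res
  key <- (pj[ok] - 1) * out_res + pi_[ok]
  dsum <- rowsum(-zr[ok], key)
  dcount <- rowsum(rep(1, sum(ok)), key)
  vals <- matrix(NA_real_, out_res, out_res)
  kk <- as.integer(rownames(dsum))
  vals[kk] <- dsum / dcount
  mask <- !is.na(vals)
  # pixel-based area equals the traced-column area at full scale; at
  # desk scale the grid undersamples, so the traced area is kept too
  structure(list(values = vals, mask = mask, pitch = pitch,
                 origin = c(-out_extent / 2, -out_extent / 2),
                 area_mm2 = sum(mask) * pitch^2,
                 area_traced_mm2 = raw$area_mm2, points = pts),
            class = "socket_depth_map")
}

#' @export
print.socket_depth_map <- function(x, ...) {
  cat(sprintf("<socket_depth_map: %d x %d px, area %.1f mm^2>\n",
              nrow(x$values), ncol(x$values), x$area_mm2))
  invisible(x)
}

#' Run the full socket-extraction pipeline
#'
#' Filtered volume to corrected socket depth map: window tracing, socket
#' column tracing and correction/regridding.
#' @param fv a \code{filtered_volumes}
#' @param conformer a \code{conformer_spec}
#' @param ... passed to \code{\link{correct_and_grid}}
#' @return a \code{socket_depth_map}
#' @export
extract_socket <- function(fv, conformer, ...) {
  w <- trace_window(fv, conformer)
  raw <- trace_socket(fv, w)
  correct_and_grid(raw, w, conformer, ...)
}

#' Write a socket depth map (TIFF + mask PNG + JSON)
#' @param sdm a \code{socket_depth_map}
#' @param prefix output path prefix
#' @export
write_socket_depth_map <- function(sdm, prefix) {
  v <- sdm$values
  v[!sdm$mask] <- 0
  tiff::writeTIFF(t(v) / 50, paste0(prefix, "_depth.tiff"),
                  bits.per.sample = 32L)
  png::writePNG(t(sdm$mask * 1), paste0(prefix, "_mask.png"))
  jsonlite::write_json(list(area_mm2 = sdm$area_mm2, pitch = sdm$pitch,
                            origin = sdm$origin, depth_scale = 50),
                       paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a socket depth map written by \code{write_socket_depth_map}
#' @param prefix path prefix
#' @return a \code{socket_depth_map}
#' @export
read_socket_depth_map <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  v <- t(tiff::readTIFF(paste0(prefix, "_depth.tiff"))) * meta$depth_scale
  m <- t(png::readPNG(paste0(prefix, "_mask.png"))) > 0.5
  v[!m] <- NA
  structure(list(values = v, mask = m, pitch = meta$pitch,
                 origin = meta$origin, area_mm2 = meta$area_mm2,
                 points = NULL),
            class = "socket_depth_map")
}
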