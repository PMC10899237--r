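#' OCT raster-scan geometry
#'
#' Physical and pixel geometry of the raster volume. The full-scale device
#' exports 256 slices of 2145 x 1877 pixels (width x depth) covering
#' 16 x 14 mm, stacked over 16 mm; the median cascade downsamples each
#' slice by 4 to 536 x 469, giving a 536 x 256 x 469 voxel volume. Smaller
#' geometries (same proportions) are used for desk-scale synthetic
#' volumes.
#'
#' @param slice_width_px,slice_depth_px full-resolution slice size
#' @param n_slices number of slices (y direction)
#' @param width_mm,height_mm,depth_mm physical extents (x, y, z)
#' @param down downsampling factor of the median cascade
#' @return object of class \code{oct_geometry} with voxel counts
#'   (\code{nx}, \code{ny}, \code{nz}) and mm-per-voxel pitches
#' @export
oct_geometry <- function(slice_width_px = 2145, slice_depth_px = 1877,
                         n_slices = 256, width_mm = 16, height_mm = 16,
                         depth_mm = 14, down = 4) {
  nx <- slice_width_px %/% down
  nz <- slice_depth_px %/% down
  structure(list(slice_width_px = slice_width_px,
                 slice_depth_px = slice_depth_px,
                 n_slices = as.integer(n_slices),
                 width_mm = width_mm, height_mm = height_mm,
                 depth_mm = depth_mm, down = down,
                 nx = as.integer(nx), ny = as.integer(n_slices),
                 nz = as.integer(nz),
                 x_pitch = width_mm / nx, y_pitch = height_mm / n_slices,
                 z_pitch = depth_mm / nz),
            class = "oct_geometry")
}

#' Threshold a raw OCT slice
#'
#' Maps 8-bit values through \code{(max(B, 25) - 25) / 230}, suppressing
#' the noise floor and rescaling to [0, 1].
#' @param B numeric matrix of 8-bit pixel values (0-255)
#' @param b_th noise-floor threshold
#' @return matrix in [0, 1]
#' @export
threshold_slice <- function(B, b_th = 25) {
  (pmax(B, b_th) - b_th) / (255 - b_th)
}

# 2x2 median pooling: the median of 4 values is the mean of the middle
# two, i.e. (sum - min - max) / 2. Trailing odd rows/cols are dropped.
.median_pool2 <- function(M) {
  nr <- nrow(M) %/% 2 * 2; nc <- ncol(M) %/% 2 * 2
  M <- M[seq_len(nr), seq_len(nc), drop = FALSE]
  i1 <- seq(1, nr, 2); i2 <- i1 + 1; j1 <- seq(1, nc, 2); j2 <- j1 + 1
  a <- M[i1, j1]; b <- M[i2, j1]; c <- M[i1, j2]; d <- M[i2, j2]
  (a + b + c + d - pmin(a, b, c, d) - pmax(a, b, c, d)) / 2
}

# k x k max pooling with trailing remainder dropped
.max_pool <- function(M, k) {
  nr <- nrow(M) %/% k; nc <- ncol(M) %/% k
  M <- M[seq_len(nr * k), seq_len(nc * k), drop = FALSE]
  out <- matrix(-Inf, nr, nc)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    out <- pmax(out, M[seq(di, by = k, length.out = nr),
                       seq(dj, by = k, length.out = nc)])
  }
  out
}

.median_filter <- function(M, k) {
  # EBImage medianFilter takes a radius and values in [0, 1]
  r <- (k - 1) / 2
  lo <- min(M); hi <- max(M)
  if (hi - lo < 1e-12) return(M)
  Mn <- (M - lo) / (hi - lo)
  out <- EBImage::medianFilter(Mn, size = r)
  as.matrix(out) * (hi - lo) + lo
}

#' Median-cascade downsampling of a thresholded slice
#'
#' Denoises and downscales a slice by 4 in each direction:
#' median(5) -> 2x2 median pool -> median(3) -> 2x2 median pool yields
#' \code{B_Median}; plain 4x4 max pooling yields \code{B_Max}. At full
#' scale 2145 x 1877 becomes 536 x 469 (remainder pixels truncated).
#'
#' @param Bp thresholded slice from \code{\link{threshold_slice}}
#' @param geometry an \code{oct_geometry}; input size must match
#' @return list with \code{B_Median} and \code{B_Max}
#' @export
downsample_slice <- function(Bp, geometry = oct_geometry()) {
  if (nrow(Bp) != geometry$slice_width_px ||
      ncol(Bp) != geometry$slice_depth_px)
    stop(sprintf("slice must be %d x %d pixels, got %d x %d",
                 geometry$slice_width_px, geometry$slice_depth_px,
                 nrow(Bp), ncol(Bp)))
  B_Median <- .median_pool2(.median_filter(
    .median_pool2(.median_filter(Bp, 5)), 3))
  B_Max <- .max_pool(Bp, geometry$down)
  list(B_Median = B_Median, B_Max = B_Max)
}

# separable 5x5 Sobel second-derivative kernel along the depth axis
# (columns): derivative taps [1 0 -2 0 1], smoothing [1 4 6 4 1] / 16.
.sobel5_kernel <- function() {
  outer(c(1, 4, 6, 4, 1) / 16, c(1, 0, -2, 0, 1))
}

#' Gradient edge map of a downsampled slice
#'
#' Masks \code{B_Max} to pixels where \code{B_Median} is nonzero, applies
#' the size-5 Sobel second derivative along the depth axis and thresholds
#' at -0.05: strong dark-side curvature marks the trailing edges of bright
#' window-surface bands.
#'
#' @param B_Median,B_Max equally sized matrices (width x depth)
#' @param threshold edge threshold on the second derivative
#' @return logical matrix \code{B_Edge}
#' @export
edge_map <- function(B_Median, B_Max, threshold = -0.05) {
  stopifnot(all(dim(B_Median) == dim(B_Max)))
  masked <- B_Max * (B_Median > 0)
  G <- as.matrix(EBImage::filter2(masked, .sobel5_kernel()))
  G < threshold
}

#' Process raw slices into the filtered socket volume
#'
#' Applies threshold, median cascade and edge map per slice and stacks the
#' results into the \code{V_Median} and \code{V_Edge} voxel tensors
#' (width x slices x depth).
#'
#' @param slices list of raw 8-bit slice matrices, or a function
#'   \code{function(i)} returning slice i (so full-scale volumes need not
#'   be held in memory at once)
#' @param geometry an \code{oct_geometry}
#' @return object of class \code{filtered_volumes}: arrays
#'   \code{V_Median} (numeric) and \code{V_Edge} (logical) of dim
#'   (nx, ny, nz), plus the geometry
#' @export
build_filtered_volumes <- function(slices, geometry = oct_geometry()) {
  get <- if (is.function(slices)) slices else function(i) slices[[i]]
  ny <- geometry$n_slices
  V_Median <- array(0, c(geometry$nx, ny, geometry$nz))
  V_Edge <- array(FALSE, c(geometry$nx, ny, geometry$nz))
  for (i in seq_len(ny)) {
    ds <- downsample_slice(threshold_slice(get(i)), geometry)
    V_Median[, i, ] <- ds$B_Median
    V_Edge[, i, ] <- edge_map(ds$B_Median, ds$B_Max)
  }
  structure(list(V_Median = V_Median, V_Edge = V_Edge,
                 geometry = geometry),
            class = "filtered_volumes")
}

#' Wrap precomputed voxel tensors as a filtered volume
#'
#' Used by the synthetic generator, which emits desk-scale tensors
#' directly at the downsampled level.
#' @param V_Median numeric array (nx, ny, nz) in [0, 1]
#' @param V_Edge logical array of the same dim (computed from
#'   \code{V_Median} via \code{\link{edge_map}} when omitted, using
#'   V_Median for both inputs)
#' @param geometry an \code{oct_geometry} whose (nx, ny, nz) match
#' @return a \code{filtered_volumes}
#' @export
filtered_volumes <- function(V_Median, V_Edge = NULL, geometry) {
  stopifnot(all(dim(V_Median) == c(geometry$nx, geometry$ny, geometry$nz)))
  if (is.null(V_Edge)) {
    V_Edge <- array(FALSE, dim(V_Median))
    for (i in seq_len(geometry$ny))
      V_Edge[, i, ] <- edge_map(V_Median[, i, ], V_Median[, i, ])
  }
  structure(list(V_Median = V_Median, V_Edge = V_Edge,
                 geometry = geometry),
            class = "filtered_volumes")
}

#' Read a directory of OCT slice bitmaps
#'
#' Slices are PNG (greyscale) files ordered by name; a manifest JSON with
#' the conformer id may sit alongside.
#' @param dir directory of slice images
#' @return list with \code{slices} (a function of slice index returning an
#'   8-bit matrix) , \code{n}, and \code{conformer_id} (from
#'   \code{manifest.json} when present)
#' @export
read_oct_slices <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG slices in ", dir)
  manifest <- file.path(dir, "manifest.json")
  cid <- if (file.exists(manifest))
    jsonlite::read_json(manifest)$conformer_id else NULL
  list(slices = function(i) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    # png stores row-major images; transpose to (width, depth)
    t(img) * 255
  }, n = length(files), conformer_id = cid)
}
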