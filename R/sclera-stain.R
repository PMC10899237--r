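#' Seamless cylindrical 3D Perlin noise field
#'
#' Samples 3D Perlin gradient noise on a cylinder so the field is
#' continuous across the left/right texture borders (the u direction
#' wraps). Three octaves with persistence 0.5.
#'
#' @param width,height texture size (u x v)
#' @param seed noise-table seed
#' @param freq_u,freq_v feature frequencies across the texture
#' @param octaves number of octaves
#' @return height x width matrix (rows = v)
#' @export
perlin_cylinder <- function(width, height, seed = 1, freq_u = 8,
                            freq_v = 4, octaves = 3) {
  u <- (seq_len(width) - 0.5) / width
  v <- (seq_len(height) - 0.5) / height
  U <- matrix(rep(u, each = height), height, width)
  V <- matrix(rep(v, width), height, width)
  R <- freq_u / (2 * pi)
  out <- matrix(0, height, width)
  amp <- 1; f <- 1; norm <- 0
  for (o in seq_len(octaves)) {
    x <- R * f * cos(2 * pi * U)
    y <- R * f * sin(2 * pi * U)
    z <- V * freq_v * f
    out <- out + amp * matrix(
      .cpp_perlin3(as.vector(x), as.vector(y), as.vector(z),
                   as.integer(seed + 131 * o)),
      height, width)
    norm <- norm + amp
    amp <- amp / 2; f <- f * 2
  }
  out / norm
}

#' Render the sclera staining texture
#'
#' Fills the texture with the palette base colour and overlays one
#' Perlin-noise stain layer per palette colour. Each noise field is
#' standardized; the pixelwise maximum is thresholded at the
#' \code{1 - coverage} quantile so the stains cover the requested
#' fraction of the image exactly, and each stained pixel takes the
#' colour whose field is largest there, giving roughly equal areas per
#' colour. Cylindrical noise sampling makes the u borders seamless.
#'
#' @param palette a \code{sclera_palette}
#' @param seed RNG/noise seed
#' @param width,height texture size (reference 4096 x 2048)
#' @param coverage stained fraction of the image
#' @return object of class \code{sclera_texture}: \code{lab}
#'   (height x width x 3), \code{stain_index} (0 = base colour),
#'   \code{coverage}
#' @export
render_staining <- function(palette, seed = 1, width = 4096,
                            height = 2048, coverage = 0.9) {
  k <- nrow(palette$colours)
  fields <- array(0, c(height, width, k))
  for (i in seq_len(k)) {
    f <- perlin_cylinder(width, height, seed = seed * 1000 + i)
    fields[, , i] <- (f - mean(f)) / sd(f)
  }
  M <- apply(fields, c(1, 2), max)
  widx <- apply(fields, c(1, 2), which.max)
  thr <- quantile(M, 1 - coverage, names = FALSE)
  stained <- M > thr
  stain_index <- matrix(0L, height, width)
  stain_index[stained] <- widx[stained]
  lab <- array(0, c(height, width, 3))
  cols <- as.matrix(palette$colours[, c("L", "a", "b")])
  for (ch in 1:3) {
    plane <- matrix(palette$g_B[ch], height, width)
    for (i in seq_len(k)) {
      sel <- stain_index == i
      # soft blend near the threshold for a painterly edge
      wblend <- clamp((fields[, , i][sel] - thr) / 0.6, 0, 1) * 0.85
      plane[sel] <- (1 - wblend) * plane[sel] + wblend * cols[i, ch]
    }
    lab[, , ch] <- plane
  }
  structure(list(lab = lab, stain_index = stain_index,
                 coverage = mean(stained), seed = seed),
            class = "sclera_texture")
}

#' @export
print.sclera_texture <- function(x, ...) {
  cat(sprintf("<sclera_texture: %d x %d, staining coverage %.3f>\n",
              ncol(x$lab[, , 1]), nrow(x$lab[, , 1]), x$coverage))
  invisible(x)
}
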