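## Raw-photo processing chain: demosaic (optional), strong non-local
## means denoise, dark-frame subtraction, flat fielding, colour
## characterization, light denoise, then specular-highlight removal.

# bilinear demosaic of a GR Bayer single-plane raw
.demosaic_bilinear <- function(raw) {
  h <- nrow(raw); w <- ncol(raw)
  # GR pattern: row 1: G R G R ..., row 2: B G B G ...
  gr <- outer(seq_len(h), seq_len(w), function(i, j) (i + j) %% 2 == 0)
  rmask <- outer(seq_len(h), seq_len(w),
                 function(i, j) i %% 2 == 1 & j %% 2 == 0)
  bmask <- outer(seq_len(h), seq_len(w),
                 function(i, j) i %% 2 == 0 & j %% 2 == 1)
  fill <- function(mask) {
    img <- raw * mask
    wts <- mask * 1
    k <- matrix(c(0.25, 0.5, 0.25, 0.5, 1, 0.5, 0.25, 0.5, 0.25), 3, 3)
    num <- as.matrix(EBImage::filter2(img, k))
    den <- as.matrix(EBImage::filter2(wts, k))
    num / pmax(den, 1e-9)
  }
  array(c(fill(rmask), fill(gr), fill(bmask)), c(h, w, 3))
}

.nlm_channels <- function(img, h, search_radius = 5) {
  if (length(dim(img)) == 2) return(.cpp_nlm(img, h, search_radius))
  out <- img
  for (k in seq_len(dim(img)[3]))
    out[, , k] <- .cpp_nlm(img[, , k], h, search_radius)
  out
}

#' Process a raw eye photograph into characterized CIELAB
#'
#' Stage chain: demosaic (when the input is a single-plane Bayer raw),
#' non-local-means denoise with a high filtering parameter (15 on the
#' 8-bit scale), dark-frame subtraction \code{I' = I - mean(dark)}, flat
#' fielding \code{I'' = mean(W) (I' / W)}, colour characterization to
#' CIELAB, and a light non-local-means pass (parameter 1.5). All
#' intermediate stages are returned for inspection.
#'
#' @param I_raw H x W x 3 RGB array in [0, 1], or H x W Bayer plane
#' @param calib list with \code{dark_mean} (scalar or per-channel),
#'   \code{flat} (H x W x 3 or H x W flat-field image) and
#'   \code{characterization} (a \code{colour_characterization})
#' @param denoise logical; disable to skip the non-local-means passes
#' @return object of class \code{eye_image}: stages \code{I},
#'   \code{I_prime}, \code{I_pp}, \code{I_col} (CIELAB)
#' @export
process_raw <- function(I_raw, calib, denoise = TRUE) {
  if (is.null(calib$characterization))
    stop("missing colour characterization in calib")
  if (is.null(calib$dark_mean) || is.null(calib$flat))
    stop("missing dark/flat calibration")
  I <- if (length(dim(I_raw)) == 2) .demosaic_bilinear(I_raw) else I_raw
  if (denoise) I <- .nlm_channels(I, 15 / 255)
  Ip <- I - calib$dark_mean
  W <- calib$flat
  if (length(dim(W)) == 2) W <- array(W, c(dim(W), 3))
  wbar <- mean(W)
  Ipp <- wbar * (Ip / pmax(W, 1e-6))
  I_col <- apply_characterization(calib$characterization,
                                  clamp(Ipp, 0, 1))
  if (denoise) I_col <- .nlm_channels(I_col, 1.5)
  structure(list(I_raw = I_raw, I = I, I_prime = Ip, I_pp = Ipp,
                 I_col = I_col),
            class = "eye_image")
}

# neighbourhood median of a single channel (square window)
.median_box <- function(M, r) {
  lo <- min(M); hi <- max(M)
  if (hi - lo < 1e-12) return(M)
  as.matrix(EBImage::medianFilter((M - lo) / (hi - lo), size = r)) *
    (hi - lo) + lo
}

#' Detect and remove specular highlights
#'
#' Masks pixels that are oversaturated in the raw capture or whose
#' lightness deviates more than \code{delta_L} from the 15 x 15
#' neighbourhood median; the mask is dilated (3 x 3, 2 iterations) and
#' filled by diffusion inpainting on each CIELAB channel.
#'
#' @param I_col H x W x 3 CIELAB image
#' @param I_raw raw image aligned with \code{I_col} (values in [0, 1])
#' @param delta_L lightness deviation threshold
#' @param saturation_limit raw values at or above this count as
#'   oversaturated (default 4095/4096 of full scale)
#' @return list with \code{I_clean} (inpainted CIELAB) and the mask
#'   \code{M_H}
#' @export
remove_highlights <- function(I_col, I_raw, delta_L = 10,
                              saturation_limit = 4095 / 4096) {
  L <- I_col[, , 1]
  med <- .median_box(L, 7)
  sat <- if (length(dim(I_raw)) == 3) {
    apply(I_raw, c(1, 2), max) >= saturation_limit
  } else I_raw >= saturation_limit
  M_H <- sat | abs(L - med) > delta_L
  kern <- EBImage::makeBrush(3, "box")
  for (i in 1:2) M_H <- as.matrix(EBImage::dilate(M_H * 1, kern)) > 0.5
  if (mean(M_H) > 0.3)
    warning(sprintf("highlight mask covers %.0f%% of the image",
                    100 * mean(M_H)))
  I_clean <- I_col
  for (k in 1:3)
    I_clean[, , k] <- .diffusion_inpaint(I_col[, , k], M_H)
  list(I_clean = I_clean, M_H = M_H)
}

# iterative Laplacian diffusion over masked pixels
.diffusion_inpaint <- function(M, mask, max_iter = 400, tol = 1e-4) {
  if (!any(mask)) return(M)
  X <- M
  X[mask] <- mean(M[!mask])
  n <- nrow(X); m <- ncol(X)
  idx <- which(mask)
  for (it in seq_len(max_iter)) {
    up <- X[pmax(row(X) - 1, 1) + (col(X) - 1) * n]
    dn <- X[pmin(row(X) + 1, n) + (col(X) - 1) * n]
    lf <- X[row(X) + (pmax(col(X) - 2, 0)) * n]
    rt <- X[row(X) + (pmin(col(X), m - 1)) * n]
    new <- (up + dn + lf + rt) / 4
    delta <- max(abs(new[idx] - X[idx]))
    X[idx] <- new[idx]
    if (delta < tol) break
  }
  X
}

#' Contrast-enhanced greyscale image for boundary detection
#'
#' Converts a CIELAB image to CIELCh and returns chroma minus lightness;
#' the iris (chromatic, darker) stands out against the sclera (light,
#' achromatic).
#' @param lab H x W x 3 CIELAB array
#' @return matrix
#' @export
enhance_image <- function(lab) {
  lch <- lch_from_lab(matrix(lab, ncol = 3))
  matrix(lch[, 2] - lch[, 1], dim(lab)[1], dim(lab)[2])
}
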