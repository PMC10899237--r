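#' Fit the two-stage camera colour characterization
#'
#' Stage one is a linear map \code{f_A(c) = A c} from camera RGB to
#' CIEXYZ (least squares on the patch set); stage two converts to CIELAB
#' under D50/2 and applies a root-polynomial correction
#' \code{g_B(L, a, b) = B (L, a, b, r(L a), r(L b), r(a b), 1)'} with a
#' 3 x 7 matrix B, where \code{r} is the signed square root
#' \code{sign(x) sqrt(|x|)} (CIELAB components can be negative, which
#' the usual non-negative root-polynomial convention does not cover).
#' The reference patch set is 24 colour-checker + 24 iris + 15 sclera
#' colours.
#'
#' @param patches data frame with columns R, G, B (camera, in [0, 1])
#'   and L, a, b (measured CIELAB)
#' @return object of class \code{colour_characterization}: matrices
#'   \code{A} (3 x 3) and \code{B} (3 x 7), white point metadata and
#'   CIEDE2000 residual statistics on the training patches
#' @export
fit_characterization <- function(patches) {
  need <- c("R", "G", "B", "L", "a", "b")
  stopifnot(all(need %in% names(patches)))
  if (nrow(patches) < 10)
    stop("at least 10 patch pairs are required, got ", nrow(patches))
  rgb <- as.matrix(patches[, c("R", "G", "B")])
  lab <- as.matrix(patches[, c("L", "a", "b")])
  if (qr(rgb)$rank < 3)
    stop("rank-deficient patch set: camera RGB values do not span 3D")
  xyz <- xyz_from_lab(lab)
  A <- t(lsfit(rgb, xyz, intercept = FALSE)$coefficients)
  lab0 <- lab_from_xyz(rgb %*% t(A))
  Phi <- .root_poly_features(lab0)
  B <- t(lsfit(Phi, lab, intercept = FALSE)$coefficients)
  fitted <- Phi %*% t(B)
  res <- delta_e2000(fitted, lab)
  structure(list(A = A, B = B, white_point = "D50", observer = "2deg",
                 residual_mean = mean(res), residual_max = max(res),
                 n_patches = nrow(patches)),
            class = "colour_characterization")
}

.signed_sqrt <- function(x) sign(x) * sqrt(abs(x))

.root_poly_features <- function(lab) {
  lab <- matrix(lab, ncol = 3)
  cbind(lab[, 1], lab[, 2], lab[, 3],
        .signed_sqrt(lab[, 1] * lab[, 2]),
        .signed_sqrt(lab[, 1] * lab[, 3]),
        .signed_sqrt(lab[, 2] * lab[, 3]),
        1)
}

#' Apply a colour characterization to camera RGB values
#' @param chr a \code{colour_characterization}
#' @param rgb n x 3 matrix (camera RGB in [0, 1]) or H x W x 3 array
#' @return CIELAB values in the same layout
#' @export
apply_characterization <- function(chr, rgb) {
  dims <- dim(rgb)
  is_img <- length(dims) == 3
  m <- if (is_img) matrix(rgb, ncol = 3) else matrix(rgb, ncol = 3)
  lab0 <- lab_from_xyz(m %*% t(chr$A))
  lab <- .root_poly_features(lab0) %*% t(chr$B)
  if (is_img) array(lab, dims) else lab
}

#' @export
print.colour_characterization <- function(x, ...) {
  cat(sprintf(
    "<colour_characterization: %d patches, DE00 mean %.3g max %.3g>\n",
    x$n_patches, x$residual_mean, x$residual_max))
  invisible(x)
}

#' Write a characterization to JSON
#' @param chr a \code{colour_characterization}
#' @param path output path
#' @export
write_characterization <- function(chr, path) {
  jsonlite::write_json(list(format = "ocuprost-characterization",
                            version = "1",
                            A = chr$A, B = chr$B,
                            white_point = chr$white_point,
                            observer = chr$observer,
                            residual_mean = chr$residual_mean,
                            residual_max = chr$residual_max,
                            n_patches = chr$n_patches),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a characterization from JSON
#' @param path file from \code{\link{write_characterization}}
#' @return a \code{colour_characterization}
#' @export
read_characterization <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(o$format, "ocuprost-characterization"))
  structure(list(A = matrix(unlist(o$A), 3, 3, byrow = TRUE),
                 B = matrix(unlist(o$B), 3, 7, byrow = TRUE),
                 white_point = o$white_point, observer = o$observer,
                 residual_mean = o$residual_mean,
                 residual_max = o$residual_max,
                 n_patches = o$n_patches),
            class = "colour_characterization")
}

#' Read a patch set from CSV
#' @param path CSV with columns R,G,B,L,a,b
#' @return data frame
#' @export
read_patches <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate a synthetic characterization patch set
#'
#' Emulates a camera with a known linear RGB response: camera RGB =
#' \code{M xyz} for a known mixing matrix M, evaluated on a reference
#' set of 24 colour-checker-like, 24 iris and 15 sclera CIELAB colours.
#' \code{fit_characterization} should recover \code{A = M^-1} on this
#' noiseless set.
#'
#' @param M camera mixing matrix (3 x 3, XYZ -> camera RGB); a default
#'   well-conditioned matrix is used when NULL
#' @param noise_sd Gaussian noise on camera RGB
#' @param seed RNG seed
#' @return list with \code{patches} (data frame), \code{M}, and
#'   \code{A_true = solve(M)}
#' @export
gen_characterization_patches <- function(M = NULL, noise_sd = 0, seed = 1) {
  if (is.null(M))
    M <- matrix(c(0.9, 0.15, -0.05,
                  -0.1, 1.05, 0.05,
                  0.02, -0.08, 1.1), 3, 3, byrow = TRUE) / 100
  checker <- rbind(
    c(37, 13, 14), c(65, 15, 17), c(50, -4, -21), c(43, -13, 22),
    c(55, 9, -24), c(70, -32, 0), c(62, 33, 56), c(40, 11, -45),
    c(51, 48, 16), c(30, 21, -20), c(72, -23, 57), c(72, 19, 67),
    c(29, 14, -50), c(55, -38, 31), c(41, 53, 26), c(81, 2, 79),
    c(51, 49, -14), c(51, -28, -28), c(96, 0, 1), c(81, 0, 0),
    c(66, 0, 0), c(51, 0, 0), c(35, 0, 0), c(20, 0, 0))
  with_seed(seed, {
    iris <- cbind(runif(24, 25, 60), runif(24, -10, 30),
                  runif(24, -35, 35))
    sclera <- cbind(runif(15, 60, 85), runif(15, -4, 8),
                    runif(15, 0, 18))
    lab <- rbind(checker, iris, sclera)
    rgb <- xyz_from_lab(lab) %*% t(M)
    if (noise_sd > 0) rgb <- rgb + rnorm(length(rgb), sd = noise_sd)
    list(patches = data.frame(R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                              L = lab[, 1], a = lab[, 2], b = lab[, 3]),
         M = M, A_true = solve(M))
  })
}
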