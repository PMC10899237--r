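## CIE colour math under D50 / 2 degree observer. The characterization
## chain is Gamma: CIEXYZ -> CIELAB under D50/2, plus sRGB encoding (with
## Bradford adaptation to D65) for texture export only.

# D50 white point (2 degree observer), Y = 100
.WP_D50 <- c(X = 96.422, Y = 100.000, Z = 82.521)

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
.lab_finv <- function(t) {
  d <- 6 / 29
  ifelse(t > d, t^3, 3 * d^2 * (t - 4 / 29))
}

#' CIEXYZ to CIELAB (D50, 2 degree observer)
#' @param xyz n x 3 matrix (Y of white = 100)
#' @return n x 3 matrix of (L*, a*, b*)
#' @export
lab_from_xyz <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  fx <- .lab_f(xyz[, 1] / .WP_D50[1])
  fy <- .lab_f(xyz[, 2] / .WP_D50[2])
  fz <- .lab_f(xyz[, 3] / .WP_D50[3])
  cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' CIELAB to CIEXYZ (D50, 2 degree observer)
#' @param lab n x 3 matrix
#' @return n x 3 matrix (Y of white = 100)
#' @export
xyz_from_lab <- function(lab) {
  lab <- matrix(lab, ncol = 3)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  cbind(X = .WP_D50[1] * .lab_finv(fx),
        Y = .WP_D50[2] * .lab_finv(fy),
        Z = .WP_D50[3] * .lab_finv(fz))
}

#' CIELAB to CIELCh
#' @param lab n x 3 matrix
#' @return n x 3 matrix of (L*, C*, h in degrees 0-360)
#' @export
lch_from_lab <- function(lab) {
  lab <- matrix(lab, ncol = 3)
  h <- atan2(lab[, 3], lab[, 2]) * 180 / pi
  h <- ifelse(h < 0, h + 360, h)
  cbind(L = lab[, 1], C = sqrt(lab[, 2]^2 + lab[, 3]^2), h = h)
}

#' CIEDE2000 colour difference
#'
#' Standard implementation of the CIEDE2000 formula between paired rows.
#' @param lab1,lab2 n x 3 CIELAB matrices
#' @return numeric vector of differences
#' @export
delta_e2000 <- function(lab1, lab2) {
  lab1 <- matrix(lab1, ncol = 3); lab2 <- matrix(lab2, ncol = 3)
  L1 <- lab1[, 1]; a1 <- lab1[, 2]; b1 <- lab1[, 3]
  L2 <- lab2[, 1]; a2 <- lab2[, 2]; b2 <- lab2[, 3]
  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cb <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cb^7 / (Cb^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  h1p <- ifelse(C1p == 0, 0, atan2(b1, a1p) * 180 / pi %% 360)
  h1p <- ifelse(h1p < 0, h1p + 360, h1p)
  h2p <- ifelse(C2p == 0, 0, atan2(b2, a2p) * 180 / pi %% 360)
  h2p <- ifelse(h2p < 0, h2p + 360, h2p)
  dLp <- L2 - L1
  dCp <- C2p - C1p
  dhp <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
                ifelse(dhp > 180, dhp - 360,
                       ifelse(dhp < -180, dhp + 360, dhp)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)
  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
                ifelse(abs(h1p - h2p) <= 180, hsum / 2,
                       ifelse(hsum < 360, hsum / 2 + 180, hsum / 2 - 180)))
  T_ <- 1 - 0.17 * cos((hbp - 30) * pi / 180) +
    0.24 * cos(2 * hbp * pi / 180) +
    0.32 * cos((3 * hbp + 6) * pi / 180) -
    0.20 * cos((4 * hbp - 63) * pi / 180)
  dTheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * T_
  RT <- -sin(2 * dTheta * pi / 180) * RC
  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}

# Bradford-adapted D50 -> sRGB (D65) conversion for texture export
.BRADFORD_D50_D65 <- matrix(c(
  0.9555766, -0.0230393, 0.0631636,
  -0.0282895, 1.0099416, 0.0210077,
  0.0122982, -0.0204830, 1.3299098), 3, 3, byrow = TRUE)

.XYZ_TO_SRGB <- matrix(c(
  3.2404542, -1.5371385, -0.4985314,
  -0.9692660, 1.8760108, 0.0415560,
  0.0556434, -0.2040259, 1.0572252), 3, 3, byrow = TRUE)

#' CIELAB (D50) to sRGB
#'
#' Bradford-adapts to D65 and applies the sRGB matrix and transfer
#' curve; out-of-gamut values are clipped.
#' @param lab n x 3 matrix
#' @return n x 3 matrix of sRGB in [0, 1]
#' @export
srgb_from_lab <- function(lab) {
  xyz <- xyz_from_lab(lab) / 100
  xyz65 <- xyz %*% t(.BRADFORD_D50_D65)
  lin <- clamp(xyz65 %*% t(.XYZ_TO_SRGB), 0, 1)
  ifelse(lin <= 0.0031308, 12.92 * lin,
         1.055 * lin^(1 / 2.4) - 0.055)
}
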