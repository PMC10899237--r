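#' Segment the eye photograph into pupil, iris, sclera and skin
#'
#' Median-blurs the image (alternating kernel sizes 5 and 3 over 20
#' passes), extracts seed points from the central horizontal
#' cross-section (darkest pixel = pupil; brightest pixels left and right
#' = sclera; derivative extrema between them = iris), seeds the image
#' border as skin/aperture, and grows a seeded watershed. The sclera
#' label is then refined: pixels darker than L* 50 (eyelashes), a
#' dilated iris mask (limbus) and reddish chromatic pixels (veins:
#' C* > 8 and hue in [345, 60] degrees) are removed.
#'
#' @param I_col H x W x 3 CIELAB image
#' @param M_I iris+pupil mask from \code{\link{detect_iris}}
#' @param blur_passes median-blur iterations (each pass: kernel 5 then 3)
#' @return object of class \code{sclera_segmentation}: label matrix
#'   \code{M_E} (1 pupil, 2 iris, 3 sclera, 4 skin/aperture), refined
#'   mask \code{M_W}, masked CIELAB pixels \code{I_S} (n x 3), and
#'   \code{I_median}
#' @export
segment_sclera <- function(I_col, M_I, blur_passes = 10) {
  L <- I_col[, , 1]
  Lm <- L
  for (i in seq_len(blur_passes)) {
    Lm <- .median_box(Lm, 2)
    Lm <- .median_box(Lm, 1)
  }
  n <- nrow(L); m <- ncol(L)
  mid <- round(m / 2)
  cross <- Lm[, mid]
  ip <- which.min(cross)
  if (cross[ip] > 40)
    abort_ocuprost("no dark pupil minimum on the central cross-section",
                   "seed_extraction_failure")
  left <- seq_len(max(ip - 5, 1))
  right <- seq.int(min(ip + 5, n), n)
  is_l <- left[which.max(cross[left])]
  is_r <- right[which.max(cross[right])]
  # iris seeds: between sclera and pupil seeds the two derivative
  # extrema mark the limbus and the pupil boundary; the iris lies
  # between them
  d <- c(0, diff(cross))
  iris_seed <- function(a, b) {
    seg <- seq.int(min(a, b) + 2, max(a, b) - 2)
    bnd <- seg[order(abs(d[seg]), decreasing = TRUE)]
    first <- bnd[1]
    second <- bnd[abs(bnd - first) >= 5][1]
    if (is.na(second)) second <- first
    round((first + second) / 2)
  }
  ii_l <- iris_seed(is_l, ip)
  ii_r <- iris_seed(ip, is_r)
  seeds <- matrix(0L, n, m)
  seeds[ip, mid] <- 1L
  seeds[ii_l, mid] <- 2L; seeds[ii_r, mid] <- 2L
  seeds[is_l, mid] <- 3L; seeds[is_r, mid] <- 3L
  seeds[c(1, n), ] <- 4L; seeds[, c(1, m)] <- 4L
  M_E <- .seeded_watershed(Lm, seeds)
  lch <- lch_from_lab(matrix(I_col, ncol = 3))
  Lv <- lch[, 1]; Cv <- lch[, 2]; hv <- lch[, 3]
  reddish <- Cv > 8 & (hv >= 345 | hv <= 60)
  keep <- matrix(Lv >= 50 & !reddish, n, m)
  M_I_d <- as.matrix(EBImage::dilate(M_I * 1,
                                     EBImage::makeBrush(7, "disc"))) > 0.5
  M_W <- (M_E == 3L) & keep & !M_I_d
  structure(list(M_E = M_E, M_W = M_W,
                 I_S = matrix(I_col, ncol = 3)[as.vector(M_W), ,
                                               drop = FALSE],
                 I_median = Lm),
            class = "sclera_segmentation")
}

# marker-based watershed by immersion: labels flood outward from the
# seeds over the gradient magnitude, lowest gradient levels first, so
# region boundaries settle on gradient ridges
.seeded_watershed <- function(img, seeds, levels = 256) {
  gx <- as.matrix(EBImage::filter2(img, .sobel5_kernel()))
  gy <- as.matrix(EBImage::filter2(img, t(.sobel5_kernel())))
  g <- sqrt(gx^2 + gy^2)
  q <- floor((levels - 1) * (g - min(g)) / max(diff(range(g)), 1e-9))
  lab <- seeds
  n <- nrow(img); m <- ncol(img)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  shift_mat <- function(M, s, fill = 0L) {
    out <- matrix(fill, n, m)
    si <- max(1, 1 + s[1]):min(n, n + s[1])
    sj <- max(1, 1 + s[2]):min(m, m + s[2])
    out[si, sj] <- M[si - s[1], sj - s[2], drop = FALSE]
    out
  }
  for (lev in sort(unique(as.vector(q)))) {
    open <- q <= lev
    repeat {
      cand <- matrix(0L, n, m)
      for (s in shifts) {
        nb <- shift_mat(lab, s)
        cand[cand == 0L] <- nb[cand == 0L]
      }
      new <- lab == 0L & open & cand > 0L
      if (!any(new)) break
      lab[new] <- cand[new]
    }
  }
  # any pixels never reached (plateaus above all seeds) join nearest label
  if (any(lab == 0L)) {
    repeat {
      cand <- matrix(0L, n, m)
      for (s in shifts) {
        nb <- shift_mat(lab, s)
        cand[cand == 0L] <- nb[cand == 0L]
      }
      new <- lab == 0L & cand > 0L
      if (!any(new)) break
      lab[new] <- cand[new]
    }
  }
  lab
}

#' Extract the 9-colour sclera palette
#'
#' k-means with 9 clusters and k-means++ initialization on the masked
#' sclera CIELAB pixels. Cluster colours are weighted by normalized
#' lightness \code{w_i = (L_i - L_min) / (L_max - L_min)} and the base
#' colour is their weighted average (staining darkens, so lighter
#' colours dominate the base). When all cluster lightnesses coincide the
#' weights are undefined; uniform weights are used and the base colour
#' is the plain mean.
#'
#' @param I_S n x 3 CIELAB pixel matrix (or a
#'   \code{sclera_segmentation})
#' @param k number of clusters
#' @param seed RNG seed for the k-means++ initialization
#' @return object of class \code{sclera_palette}: data frame
#'   \code{colours} (L, a, b, weight), base colour \code{g_B},
#'   \code{degenerate} flag
#' @export
extract_palette <- function(I_S, k = 9, seed = 1) {
  if (inherits(I_S, "sclera_segmentation")) I_S <- I_S$I_S
  I_S <- matrix(I_S, ncol = 3)
  if (nrow(I_S) < 1000)
    stop("need at least 1000 sclera pixels, got ", nrow(I_S))
  centres <- with_seed(seed, {
    init <- .kmeanspp_init(I_S, k)
    if (nrow(unique(round(I_S, 9))) < k) {
      matrix(I_S[1, ], k, 3, byrow = TRUE)
    } else {
      km <- kmeans(I_S, centers = init, iter.max = 50)
      km$centers
    }
  })
  g <- palette_base_colour(centres)
  structure(list(colours = data.frame(L = centres[, 1], a = centres[, 2],
                                      b = centres[, 3],
                                      weight = g$weights),
                 g_B = g$g_B, degenerate = g$degenerate),
            class = "sclera_palette")
}

#' Lightness-weighted base colour of a palette
#'
#' Direct evaluation of the weighted-average base colour: weights are
#' the min-max-normalized cluster lightnesses.
#' @param centres k x 3 CIELAB matrix
#' @return list with \code{g_B}, \code{weights}, \code{degenerate}
#' @export
palette_base_colour <- function(centres) {
  Lv <- centres[, 1]
  rng <- max(Lv) - min(Lv)
  if (rng < 1e-9) {
    return(list(g_B = colMeans(centres), weights = rep(1, nrow(centres)),
                degenerate = TRUE))
  }
  w <- (Lv - min(Lv)) / rng
  list(g_B = colSums(centres * w) / sum(w), weights = w,
       degenerate = FALSE)
}

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centres <- X[sample.int(n, 1), , drop = FALSE]
  while (nrow(centres) < k) {
    d2 <- apply(centres, 1, function(c_)
      rowSums(sweep(X, 2, c_)^2))
    dmin <- if (is.matrix(d2)) apply(d2, 1, min) else d2
    p <- dmin / sum(dmin)
    if (!all(is.finite(p)) || sum(dmin) <= 0) {
      centres <- rbind(centres, X[sample.int(n, 1), ])
    } else {
      centres <- rbind(centres, X[sample.int(n, 1, prob = p), ])
    }
  }
  centres
}

#' @export
print.sclera_palette <- function(x, ...) {
  cat(sprintf(
    "<sclera_palette: %d colours, base Lab (%.1f, %.1f, %.1f)%s>\n",
    nrow(x$colours), x$g_B[1], x$g_B[2], x$g_B[3],
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
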