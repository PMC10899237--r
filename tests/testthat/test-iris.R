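test_that("iris and pupil are detected within pixel tolerance", {
  photo <- fx_photo(seed = 2)
  seg <- fx_iris_seg(seed = 2)
  expect_lt(abs(seg$iris$cx - photo$centre[1]), 1)
  expect_lt(abs(seg$iris$cy - photo$centre[2]), 1)
  expect_lt(abs(seg$iris$r - photo$iris_radius), 2)
  expect_lt(abs(seg$pupil$r - photo$pupil_radius), 2)
  expect_lt(abs(seg$pupil$cx - photo$centre[1]), 2)
  # a circular limbus refines to a near-circle at constant area
  expect_lt(1 - seg$ellipse$b / seg$ellipse$a, 0.05)
  expect_equal(seg$ellipse$a * seg$ellipse$b, seg$iris$r^2,
               tolerance = 0.005)
  # pupil inside iris
  expect_lt(seg$pupil$r, seg$iris$r)
})

test_that("detection is invariant to a global lightness offset", {
  photo <- fx_photo(seed = 2)
  shifted <- photo$lab
  shifted[, , 1] <- shifted[, , 1] + 10
  seg0 <- fx_iris_seg(seed = 2)
  seg1 <- detect_iris(shifted)
  expect_lt(abs(seg1$iris$r - seg0$iris$r), 2)
  expect_lt(abs(seg1$iris$cx - seg0$iris$cx), 2)
})

test_that("an elliptical limbus is recovered at constant area", {
  cfg <- eye_photo_config(size = 256, iris_radius = 60)
  photo <- gen_eye_photo(cfg, seed = 8)
  # squash the image columns to make the limbus elliptical (b/a = 0.9)
  lab <- photo$lab
  n <- dim(lab)[1]
  sq <- lab
  cy <- (n + 1) / 2
  src <- cy + (seq_len(n) - cy) / 0.9
  ok <- src >= 1 & src <= n
  for (k in 1:3) {
    plane <- matrix(35, n, n)
    plane[, ok] <- lab[, round(src[ok]), k]
    if (k == 2) plane[, !ok] <- 12
    if (k == 3) plane[, !ok] <- 18
    sq[, , k] <- plane
  }
  seg <- detect_iris(sq)
  q <- seg$ellipse$b / seg$ellipse$a
  expect_equal(min(q, 1 / q), 0.9, tolerance = 0.03)
  expect_equal(seg$ellipse$a * seg$ellipse$b, seg$iris$r^2,
               tolerance = 0.005 * seg$iris$r^2)
  # matches a brute-force search over the same grid
  enh <- enhance_image(sq)
  brute <- ocuprost:::.refine_ellipse(enh, seg$iris$cx, seg$iris$cy,
                                      seg$iris$r)
  expect_equal(seg$ellipse$a, brute$a)
  expect_equal(seg$ellipse$angle, brute$angle)
})

test_that("unwrapping maps rings to rows and spokes to columns", {
  # concentric-ring synthetic iris: rows become constant
  n <- 192
  X <- matrix(rep(1:n, n), n, n); Y <- t(X)
  R <- sqrt((X - 96.5)^2 + (Y - 96.5)^2)
  lab <- array(0, c(n, n, 3))
  lab[, , 1] <- 40 + 10 * sin(R / 4)
  seg <- structure(list(iris = list(cx = 96.5, cy = 96.5, r = 60),
                        pupil = list(cx = 96.5, cy = 96.5, r = 20),
                        M_I = R <= 60),
                   class = "iris_segmentation")
  tex <- unwrap_iris(lab, seg, width = 256, height = 64)
  expect_equal(dim(tex$lab), c(64, 256, 3))
  row_sd <- apply(tex$lab[, , 1], 1, sd)
  expect_lt(max(row_sd), 0.2)
  # a radial spoke becomes a vertical stripe at the matching column
  phi0 <- 1.1
  spoke <- abs(((atan2(Y - 96.5, X - 96.5) - phi0 + pi) %% (2 * pi)) -
                 pi) < 0.04
  lab2 <- lab
  lab2[, , 1][spoke] <- 90
  tex2 <- unwrap_iris(lab2, seg, width = 256, height = 64)
  bright_cols <- which(colMeans(tex2$lab[, , 1]) >
                         mean(tex2$lab[, , 1]) + 5)
  expect_lt(min(abs(bright_cols - phi0 / (2 * pi) * 256)), 3)
  # reference texture dimensions
  tex_ref <- unwrap_iris(lab, seg, width = 4096, height = 1024)
  expect_equal(dim(tex_ref$lab), c(1024, 4096, 3))
})

test_that("contrast enhancement stretches rows and preserves the mean", {
  # constant texture is unchanged
  const <- structure(list(lab = array(50, c(32, 64, 3))),
                     class = "iris_texture")
  out <- enhance_contrast(const, pupil_black_frac = 0)
  expect_equal(out$lab, const$lab)
  # sinusoidal rows stretch by exactly 1.5 about the row mean
  tex <- const
  amp <- 8
  tex$lab[, , 1] <- 50 + amp *
    sin(matrix(rep(1:64, each = 32), 32, 64) / 5)
  out2 <- enhance_contrast(tex, pupil_black_frac = 0)
  resid0 <- tex$lab[, , 1] - rowMeans(tex$lab[, , 1])
  resid1 <- out2$lab[, , 1] - rowMeans(out2$lab[, , 1])
  expect_equal(resid1, 1.5 * resid0, tolerance = 1e-9)
  expect_equal(mean(out2$lab[, , 1]), mean(tex$lab[, , 1]),
               tolerance = 1e-6)
  # pupil-side rows are blacked
  out3 <- enhance_contrast(tex, pupil_black_frac = 0.1)
  nb <- round(32 * 0.1)
  expect_true(all(out3$lab[(32 - nb + 1):32, , ] == 0))
})

test_that("iris geometry normalizes the pupil and assigns UVs", {
  ragged <- gen_iris_mesh(raggedness = 0.3, seed = 3)
  geo <- build_iris_geometry(ragged)
  # the pupil hole is closed: only the outer rim boundary remains
  loops <- ocuprost:::.boundary_loops(geo$disc)
  expect_length(loops, 1)
  # the circularized pupil ring sits at the mean of the ragged radii
  in_rad <- vapply(ocuprost:::.boundary_loops(ragged), function(l)
    mean(sqrt(rowSums(ragged$vertices[l, 1:2, drop = FALSE]^2))), 0)
  expect_equal(geo$pupil_radius, min(in_rad), tolerance = 1e-9)
  # all vertices at the pupil radius lie on an exact circle
  V <- geo$disc$vertices
  rr_all <- sqrt(V[, 1]^2 + V[, 2]^2)
  ring <- abs(rr_all - geo$pupil_radius) < 1e-6
  expect_gt(sum(ring), 10)
  expect_lt(diff(range(rr_all[ring])), 1e-9)
  # UV of a vertex at angle phi and fractional radius rho
  V <- geo$disc$vertices
  i <- which.max(V[, 1])    # on the outer rim, angle ~ 0
  expect_equal(geo$disc$uv[i, 2], 1, tolerance = 0.01)
  expect_lt(min(abs(geo$disc$uv[i, 1] - c(0, 1))), 0.01)
  expect_true(all(geo$disc$uv >= 0 & geo$disc$uv <= 1))
  # black cylinder: axis through the pupil centre, correct radius
  cyl_rho <- sqrt(rowSums(geo$cylinder$vertices[, 1:2]^2))
  expect_equal(max(cyl_rho), geo$pupil_radius, tolerance = 1e-9)
  expect_true(mesh_is_closed(geo$cylinder))
  # non-disc input is rejected
  expect_error(build_iris_geometry(fx_sphere(r = 3, nth = 6, nph = 8)),
               "disc")
})

test_that("unwrap and inverse mapping reproduce the iris pixels", {
  photo <- fx_photo(seed = 2)
  seg <- fx_iris_seg(seed = 2)
  tex <- unwrap_iris(photo$lab, seg, width = 1024, height = 256)
  # map each unwrapped texel back into the image and compare
  ang <- (seq_len(1024) - 0.5) / 1024 * 2 * pi
  rad <- seg$pupil$r + (1 - (seq_len(256) - 0.5) / 256) *
    (seg$iris$r - seg$pupil$r)
  xs <- outer(rad, cos(ang)) + seg$iris$cx
  ys <- outer(rad, sin(ang)) + seg$iris$cy
  orig <- matrix(ocuprost:::.bilinear_img(photo$lab[, , 1], xs, ys),
                 256, 1024)
  err <- tex$lab[, , 1] - orig
  psnr <- -10 * log10(mean(err^2) / 100^2)
  expect_gt(psnr, 35)
})
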