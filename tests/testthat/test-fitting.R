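test_that("the distance energy matches its definition", {
  m <- fx_model()
  x <- rep(0, m$k)
  sdm <- fx_sdm_from(m, x)
  # exact equality gives (numerically) zero energy
  expect_lt(energy_dist(x, sdm, m), 1e-6)
  # single-pixel mask with a 0.1 mm difference: 10000 * 0.01 = 100
  one <- sdm
  px <- which(sdm$mask, arr.ind = TRUE)[100, ]
  one$mask[, ] <- FALSE; one$mask[px[1], px[2]] <- TRUE
  one$values[px[1], px[2]] <- one$values[px[1], px[2]] + 0.1
  expect_equal(energy_dist(x, one, m), 100, tolerance = 1e-6)
  # brute-force per-pixel loop oracle on a random configuration
  x2 <- c(0.5, -0.3, rep(0.2, m$k - 2))
  Z <- back_depth_map(synthesize(m, x2))
  acc <- 0; nmask <- 0
  for (i in seq_len(nrow(sdm$values))) for (j in seq_len(ncol(sdm$values))) {
    if (!sdm$mask[i, j]) next
    nmask <- nmask + 1
    zij <- if (is.na(Z[i, j])) 0 else Z[i, j]
    acc <- acc + (zij - sdm$values[i, j])^2
  }
  expect_equal(energy_dist(x2, sdm, m), 10000 / nmask * acc,
               tolerance = 1e-9)
})

test_that("the reference energy is the weighted L2 norm", {
  x0 <- rep(0, 12)
  expect_equal(energy_ref(x0, x0), 0)
  e1 <- replace(x0, 1, 1)
  expect_equal(energy_ref(e1, x0), 2048)
  e12 <- replace(x0, 1:2, 1)
  expect_equal(energy_ref(e12, x0), sqrt(2048^2 + 1024^2))
  # weights continue with 16 beyond the tenth mode
  w <- ref_weights(14)
  expect_equal(w[1:7], c(2048, 1024, 512, 256, 128, 64, 32))
  expect_true(all(w[8:14] == 16))
  # analytic gradient of the reference energy matches finite differences
  set.seed(8)
  x <- rnorm(6); xt <- rnorm(6); w6 <- ref_weights(6)
  g_ana <- w6^2 * (x - xt) / energy_ref(x, xt, w6)
  g_num <- vapply(1:6, function(i) {
    h <- 1e-6; e <- replace(rep(0, 6), i, h)
    (energy_ref(x + e, xt, w6) - energy_ref(x - e, xt, w6)) / (2 * h)
  }, 0)
  expect_equal(g_ana, g_num, tolerance = 1e-4)
})

test_that("target interpolation is alpha times the conformer shape", {
  x_c <- c(2, -1, 0.5)
  expect_equal(make_target(x_c, 0), c(0, 0, 0))
  expect_equal(make_target(x_c, 1), x_c)
  expect_equal(make_target(x_c, 0.5), c(1, -0.5, 0.25))
  expect_error(make_target(x_c, 1.2))
})

test_that("fitting recovers the generating coordinates", {
  m <- fx_model()
  set.seed(5)
  x_true <- clip(rnorm(m$k) * 0.8, -2, 2)
  sdm <- fx_sdm_from(m, x_true)
  fit <- fit_shape(sdm, m, NULL, alphas = 0)[[1]]
  err <- mean(sqrt(rowSums((synthesize(m, fit$x_f)$points -
                              synthesize(m, x_true)$points)^2)))
  expect_lt(err, 0.3)
  expect_false(fit$fallback_used)
  # optimizer never worsens the start
  e_start <- energy_dist(rep(0, m$k), sdm, m) +
    energy_ref(rep(0, m$k), rep(0, m$k))
  expect_lte(fit$energy, e_start)
  # back-surface agreement on the synthetic suite
  Zf <- back_depth_map(synthesize(m, fit$x_f))
  expect_lt(mean(abs(Zf - sdm$values)[sdm$mask], na.rm = TRUE), 0.25)
})

test_that("saturated fits trigger the rigid-DOF fallback", {
  m <- fx_model()
  x_edge <- clip(c(2.9, 0.5, -0.5, rep(0, m$k - 3))[seq_len(m$k)], -3, 3)
  sdm <- fx_sdm_from(m, x_edge, shift_z = 2)
  fit <- fit_shape(sdm, m, NULL, alphas = 0)[[1]]
  expect_true(fit$fallback_used)
  expect_lte(max(abs(fit$x_f)), 3)
  expect_lte(abs(fit$theta), 30 * pi / 180)
  expect_lte(abs(fit$z), 2.5)
  # with equal distance and penalty weights, the rigid-z subproblem's
  # optimum for a residual shift dz is at most dz/2 (and mode
  # absorption can only lower it); check the recovered z obeys that
  # bound while remaining positive
  expect_gt(fit$z, 0)
  expect_lte(fit$z, 1.2)
})

test_that("a stronger target bias pulls the fit toward the conformer", {
  m <- fx_model()
  conf <- make_conformer(m, fx_landmarks()[[3]], id = "A07")
  set.seed(9)
  sdm <- fx_sdm_from(m, clip(rnorm(m$k) * 0.6, -2, 2))
  fits <- fit_shape(sdm, m, conf$spec, alphas = c(0, 0.9))
  w <- ref_weights(m$k)
  x_c <- conf$spec$x_c[seq_len(m$k)]
  d0 <- sqrt(sum((w * (fits[[1]]$x_f - x_c))^2))
  d9 <- sqrt(sum((w * (fits[[2]]$x_f - x_c))^2))
  expect_lt(d9, d0)
})
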