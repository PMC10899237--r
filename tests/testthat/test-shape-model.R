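test_that("a known 5-mode linear family is recovered at the 98% target", {
  fam <- gen_landmark_family(40, k = 5, seed = 7)
  m <- build_model(fam$shapes)
  expect_equal(m$k, 5)
  # principal angles between true and estimated subspaces
  cosines <- svd(crossprod(fam$modes, m$modes[, 1:5]))$d
  angles <- acos(pmin(cosines, 1))
  expect_lt(max(angles), 1e-3)
  # explained fractions sum to one over all modes
  expect_equal(sum(m$explained), 1, tolerance = 1e-9)
  # mode orthonormality
  G <- crossprod(m$modes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # sigmas non-increasing
  expect_true(all(diff(m$sigmas) <= 1e-12))
})

test_that("identical training shapes degenerate to a zero-variance model", {
  base <- fx_landmarks()[[1]]
  m <- build_model(list(base, base, base, base))
  expect_true(m$zero_variance)
  expect_equal(m$k, 1)
  expect_equal(m$sigmas, 0)
  # S(0) is still the mean (= the shape itself)
  expect_equal(synthesize(m, 0)$points, base$points)
  expect_error(synthesize(m, 1), "zero-variance")
})

test_that("synthesize and project are exact inverses on shape space", {
  m <- fx_model()
  expect_equal(synthesize(m, rep(0, m$k))$points, m$mean_shape$points)
  e1 <- c(1, rep(0, m$k - 1))
  s1 <- synthesize(m, e1)
  expect_equal(as.vector(s1$points),
               as.vector(m$mean_shape$points) +
                 m$sigmas[1] * m$modes[, 1],
               tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:5) {
    x <- rnorm(m$k)
    expect_lt(max(abs(project_shape(m, synthesize(m, x)) - x)), 1e-9)
  }
})

test_that("shapes outside the span lose their orthogonal component", {
  m <- fx_model()
  x <- rnorm(m$k)
  s <- synthesize(m, x)
  # add a perturbation orthogonal to the modes
  d <- rnorm(length(s$points))
  d <- d - m$modes %*% crossprod(m$modes, d)
  s_out <- landmark_mesh(s$points + matrix(0.1 * d, ncol = 3))
  rec <- synthesize(m, project_shape(m, s_out))
  resid <- as.vector(s_out$points) - as.vector(rec$points)
  expect_equal(sqrt(sum(resid^2)), 0.1 * sqrt(sum(d^2)),
               tolerance = 1e-6)
})

test_that("model evaluation metrics behave as expected", {
  lms <- fx_landmarks(12, seed = 19)
  ev <- evaluate_model(lms, n_specificity = 100, seed = 5)
  expect_setequal(ev$metric,
                  c("replication", "generalization", "specificity"))
  expect_true(all(ev$mean >= 0))
  # leave-one-out error cannot beat in-sample error
  expect_lte(ev$mean[ev$metric == "replication"],
             ev$mean[ev$metric == "generalization"])
  # shapes exactly in a k-dim subspace replicate exactly
  fam <- gen_landmark_family(10, k = 3, seed = 2, noise_sd = 0)
  ev0 <- evaluate_model(fam$shapes, n_specificity = 20, seed = 1)
  expect_lt(ev0$mean[ev0$metric == "replication"], 1e-8)
  # tightly clustered training shapes are more specific than dispersed
  tight <- gen_landmark_family(8, k = 3, seed = 4,
                               sigmas = c(0.1, 0.08, 0.06))$shapes
  wide <- gen_landmark_family(8, k = 3, seed = 4,
                              sigmas = c(3, 2.4, 1.8))$shapes
  sp_t <- evaluate_model(tight, n_specificity = 50, seed = 9)
  sp_w <- evaluate_model(wide, n_specificity = 50, seed = 9)
  expect_lt(sp_t$mean[sp_t$metric == "specificity"],
            sp_w$mean[sp_w$metric == "specificity"])
})

test_that("fewer than 3 shapes is an insufficient-data error", {
  lms <- fx_landmarks()
  expect_error(build_model(lms[1:2]), class = "insufficient_data")
})

test_that("the model archive round-trips through JSON", {
  m <- fx_model()
  f <- tempfile(fileext = ".json")
  write_shape_model(m, f)
  m2 <- read_shape_model(f)
  expect_equal(m2$k, m$k)
  expect_equal(m2$sigmas, m$sigmas)
  expect_equal(m2$mean_shape$points, m$mean_shape$points)
  expect_equal(m2$modes, m$modes)
  x <- rnorm(m$k)
  expect_equal(synthesize(m2, x)$points, synthesize(m, x)$points)
})
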