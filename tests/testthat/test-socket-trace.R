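desk_geometry <- function(n_slices = 64)
  oct_geometry(slice_width_px = 536, slice_depth_px = 469,
               n_slices = n_slices)

test_that("window tracing recovers two parallel tilted planes", {
  oct <- fx_oct(tilt = c(tan(5 * pi / 180), 0))
  g <- oct$geometry
  w <- trace_window(oct$volumes, oct$spec)
  ang <- atan(w$P_A[2] * g$z_pitch / g$x_pitch) * 180 / pi
  expect_equal(ang, 5, tolerance = 0.5)
  # posterior below anterior everywhere on the shared mask
  both <- w$M_A & w$M_B
  expect_true(all(w$D_B[both] > w$D_A[both]))
  # plane separation close to the window thickness
  sep <- median((w$D_B - w$D_A)[both]) * g$z_pitch
  expect_equal(sep, oct$spec$window_thickness, tolerance = 0.4)
  # RMS distance of traced anterior depths to the fitted plane < 1 voxel
  pa <- outer(seq_len(g$nx) * w$P_A[2], seq_len(g$ny) * w$P_A[3], `+`) +
    w$P_A[1]
  expect_lt(sqrt(mean((w$D_A - pa)[w$M_A]^2)), 1)
})

test_that("an exact untilted plane is recovered with zero residual", {
  oct <- fx_oct()
  g <- oct$geometry
  w <- trace_window(oct$volumes, oct$spec)
  pa <- outer(seq_len(g$nx) * w$P_A[2], seq_len(g$ny) * w$P_A[3], `+`) +
    w$P_A[1]
  expect_lt(max(abs((w$D_A - pa)[w$M_A])), 1)
  expect_lt(abs(w$P_A[2]), 1e-2)
})

test_that("speckle columns are excluded by the plane-refinement rule", {
  oct <- fx_oct(seed = 9, speckle = 0.2)
  w <- trace_window(oct$volumes, oct$spec)
  g <- oct$geometry
  pa <- outer(seq_len(g$nx) * w$P_A[2], seq_len(g$ny) * w$P_A[3], `+`) +
    w$P_A[1]
  # all surviving mask entries lie within half a thickness of the plane
  expect_true(all(abs((w$D_A - pa)[w$M_A]) < 0.5 * w$tau))
})

test_that("column tracing rules match their brute-force definitions", {
  set.seed(12)
  nz <- 120
  z0 <- 10
  for (rep in 1:200) {
    v <- numeric(nz)
    # random socket profile: zeros, then a noisy ramp, plus optional blob
    zs <- sample(30:90, 1)
    v[zs:nz] <- pmin(1, (seq_len(nz - zs + 1)) * runif(1, 0.02, 0.2))
    if (runif(1) < 0.5) {
      b <- sample((z0 + 2):(zs - 5), 1)
      v[b:(b + 1)] <- runif(1, 0.05, 0.4)   # detached noise blob
    }
    # implementation (same arithmetic as trace_socket's inner loop)
    zr_all <- (z0 + 1):nz
    z1 <- zr_all[which.max(v[zr_all])]
    zr <- (z0 + 1):z1
    z2 <- zr[which.max((v[zr] - v[z0]) / (zr - z0))]
    zeros <- which(v[seq_len(z2 - 1)] == 0)
    zeros <- zeros[zeros > z0]
    z3 <- max(zeros)
    # exhaustive evaluation of the definitions
    best <- -Inf; z2_ref <- NA
    for (z in (z0 + 1):z1) {
      s <- (v[z] - v[z0]) / (z - z0)
      if (s > best) { best <- s; z2_ref <- z }
    }
    z3_ref <- max(setdiff(which(v == 0), seq_len(z0)))
    z3_ref <- max(Filter(function(z) z < z2_ref && v[z] == 0,
                         (z0 + 1):nz))
    expect_equal(z2, z2_ref)
    expect_equal(z3, z3_ref)
    # clean ramp: z3 is the last zero before the rise
    if (all(v[(z0 + 1):(zs - 1)] == 0)) expect_equal(z3, zs - 1)
  }
})

test_that("a synthetic socket surface is recovered within tolerance", {
  oct <- fx_oct()
  w <- trace_window(oct$volumes, oct$spec)
  raw <- trace_socket(oct$volumes, w)
  expect_gt(raw$area_mm2, 100)
  sdm <- correct_and_grid(raw, w, oct$spec)
  both <- sdm$mask & !is.na(oct$truth)
  err <- abs(sdm$values - oct$truth)[both]
  expect_lt(mean(err), 0.15)
  # voxel-level agreement of the raw trace: < 2 voxels on average
  expect_lt(mean(err) / oct$geometry$z_pitch, 2)
})

test_that("the process aborts when the masked area is too small", {
  oct <- fx_oct()
  w <- trace_window(oct$volumes, oct$spec)
  # shrink the posterior mask to a sliver
  w$M_B[, ] <- FALSE
  w$M_B[65:70, 30:34] <- TRUE
  expect_error(trace_socket(oct$volumes, w), class = "socket_area_abort")
})

test_that("corrections follow the stated conventions", {
  # d = 1.5 mm gives a depth shift of -0.525 mm
  expect_equal(-0.35 * 1.5, -0.525)
  oct <- fx_oct()
  w <- trace_window(oct$volumes, oct$spec)
  raw <- trace_socket(oct$volumes, w)
  base <- correct_and_grid(raw, w, oct$spec, gaze_deg = 0)
  spec2 <- oct$spec
  spec2$window_thickness <- spec2$window_thickness + 1
  shifted <- correct_and_grid(raw, w, spec2, gaze_deg = 0)
  both <- base$mask & shifted$mask
  # one extra mm of effective thickness pulls depths 0.35 mm shallower
  expect_equal(mean((shifted$values - base$values)[both]), -0.35,
               tolerance = 1e-6)
  # full-window capture never exceeds the 177 mm^2 visible bound
  expect_lte(base$area_traced_mm2, conformer_window_area(oct$spec) * 1.01)
})
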