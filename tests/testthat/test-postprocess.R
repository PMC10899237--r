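test_that("cornea renormalization hits the apex and limbus targets", {
  m <- fx_model()
  lm <- fx_landmarks()[[2]]
  rn <- renormalize_cornea(lm, 11.8, m$mean_shape)
  expect_equal(rn$points[1, 3], 2.5, tolerance = 0.05)
  r3 <- limbus_ring_indices()
  expect_equal(2 * mean(sqrt(rowSums(rn$points[r3, 1:2]^2))), 11.8,
               tolerance = 0.1)
  # only the anterior surface changes
  back_idx <- 190:838
  expect_identical(rn$points[back_idx, ], lm$points[back_idx, ])
  expect_error(renormalize_cornea(lm, 7, m$mean_shape), "iris diameter")
})

test_that("volume-increasing subdivision quadruples faces and grows volume", {
  lm <- fx_landmarks()[[1]]
  m0 <- as_op_mesh(lm)
  m1 <- subdivide_smooth(lm, 1)
  m2 <- subdivide_smooth(lm, 2)
  expect_equal(nrow(m0$faces), 1672)
  expect_equal(nrow(m1$faces), 6688)
  expect_equal(nrow(m2$faces), 26752)
  v0 <- mesh_volume(m0); v1 <- mesh_volume(m1); v2 <- mesh_volume(m2)
  expect_gt(v1, v0)
  expect_gt(v2, v1)
  expect_true(mesh_is_closed(m2))
})

test_that("subdividing a sphere stays spherical", {
  s <- fx_sphere(r = 5)
  s2 <- subdivide_smooth(s, 2)
  r <- sqrt(rowSums(s2$vertices^2))
  # Hausdorff distance to the circumscribing sphere below 1% of radius
  expect_lt(max(abs(r - 5)) / 5, 0.01)
})

test_that("oversizing enlarges outside the cornea only", {
  lm <- fx_landmarks()[[2]]
  m <- fx_model()
  rn <- renormalize_cornea(lm, 11.8, m$mean_shape)
  ps <- oversize_and_coat(rn, "predicted", limbus_radius = 5.9)
  V0 <- as_op_mesh(rn)$vertices
  V1 <- ps$mesh$vertices
  ratio <- sqrt(rowSums(V1^2)) / pmax(sqrt(rowSums(V0^2)), 1e-9)
  rho <- sqrt(V0[, 1]^2 + V0[, 2]^2)
  expect_equal(max(ratio), 1.05, tolerance = 1e-6)
  expect_true(all(abs(ratio[rho < 5.9] - 1) < 1e-9))
  expect_gt(mesh_volume(ps$mesh), mesh_volume(as_op_mesh(rn)))
  expect_true(all(ps$clearcoat >= 0.1 & ps$clearcoat <= 0.5))
})

test_that("reconstructed shapes get a uniform 0.2 mm coat, no oversizing", {
  lm <- fx_landmarks()[[2]]
  ps <- oversize_and_coat(lm, "reconstructed")
  expect_identical(ps$mesh$vertices, as_op_mesh(lm)$vertices)
  expect_true(all(ps$clearcoat == 0.2))
})

test_that("the safety gate rejects strictly oversized boxes only", {
  box_mesh <- function(w, h, d) {
    v <- as.matrix(expand.grid(c(0, w), c(0, h), c(0, d)))
    f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
               c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
               c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
    op_mesh(v, f)
  }
  expect_equal(safety_gate(box_mesh(29, 28, 19)), "accept")
  expect_equal(safety_gate(box_mesh(30.1, 28, 19)), "reject")
  expect_equal(safety_gate(box_mesh(30, 29, 20)), "accept")
})

test_that("reconstruction replicates shapes outside the model span", {
  m <- fx_model()
  # a scan with a localized posterior bump no linear model of this
  # family can express
  scan <- gen_prosthesis_set(1, seed = 55, rigid = FALSE)[[1]]
  V <- scan$mesh$vertices
  sel <- V[, 3] < -2 & sqrt((V[, 1] - 3)^2 + V[, 2]^2) < 4
  V[sel, 3] <- V[sel, 3] - 1.5 * exp(-((V[sel, 1] - 3)^2 +
                                         V[sel, 2]^2) / 8)
  bumped <- marked_scan(op_mesh(V, scan$mesh$faces), scan$p_S, scan$p_N,
                        scan$p_I, scan$p_T)
  lm_rec <- generate_correspondence(align_shape(bumped))
  # the SSM projection cannot reproduce the bump
  ssm_route <- synthesize(m, project_shape(m, lm_rec))
  back_idx <- 190:838
  err_ssm <- max(sqrt(rowSums((ssm_route$points[back_idx, ] -
                                 lm_rec$points[back_idx, ])^2)))
  ps <- reconstruct_shape(bumped, 11.8, m$mean_shape)
  expect_s3_class(ps, "processed_shape")
  expect_true(all(ps$clearcoat == 0.2))
  # reconstructed back surface stays close to the scanned landmarks
  lm_back <- lm_rec$points[back_idx, ]
  d <- vapply(seq_len(nrow(lm_back)), function(i)
    min(sqrt(rowSums(sweep(ps$mesh$vertices, 2, lm_back[i, ])^2))), 0)
  expect_lt(max(d), 0.3)
  expect_gt(err_ssm, max(d))
})

test_that("the full predicted pipeline output is watertight", {
  m <- fx_model()
  ps <- process_shape(synthesize(m, rep(0.5, m$k)), 11.8, m$mean_shape,
                      "predicted")
  expect_true(mesh_is_closed(ps$mesh))
  expect_gt(mesh_volume(ps$mesh), 0)
  expect_true(ps$accepted)
})
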