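test_that("correspondence emits exactly 838 landmarks (189 front, 649 back)", {
  lm <- generate_correspondence(fx_sphere(r = 6))
  expect_equal(nrow(lm$points), 838)
  expect_equal(lm$front_count, 189)
  expect_equal(lm$back_count, 649)
})

test_that("the shared face list is a closed genus-0 surface", {
  F <- landmark_faces()
  expect_equal(nrow(F), 1672)
  lm <- generate_correspondence(fx_sphere(r = 6))
  m <- as_op_mesh(lm)
  expect_true(mesh_is_closed(m))
  E <- nrow(mesh_edges(m))
  expect_equal(E, 2508)
  expect_equal(nrow(m$vertices) - E + nrow(m$faces), 2)
  # identical across instances
  lm2 <- generate_correspondence(fx_sphere(r = 4))
  expect_identical(lm$faces, lm2$faces)
  # outward orientation
  expect_gt(mesh_volume(m), 0)
})

test_that("rings on an axisymmetric shape share z within sampling tolerance", {
  lm <- generate_correspondence(fx_sphere(r = 6))
  front <- depth_project(fx_sphere(r = 6), "front")
  tol <- 2 * front$pixel_pitch
  r3 <- limbus_ring_indices()
  expect_lt(diff(range(lm$points[r3, 3])), tol)
  # radius of each ring point is also near-constant
  expect_lt(diff(range(sqrt(rowSums(lm$points[r3, 1:2]^2)))), tol)
})

test_that("correspondence commutes with rotations by multiples of 7.5 deg", {
  scan <- gen_prosthesis_set(1, seed = 31, rigid = FALSE)[[1]]
  lm0 <- generate_correspondence(scan$mesh)
  ang <- 4 * 7.5 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rot <- op_mesh(scan$mesh$vertices %*% t(R), scan$mesh$faces)
  lmr <- generate_correspondence(rot)
  # rotating the rotated landmarks back must reproduce the originals up
  # to a permutation within each ring; compare sorted ring geometry
  back <- lmr$points %*% R
  r3 <- limbus_ring_indices()
  d0 <- sort(round(lm0$points[r3, 3], 2))
  d1 <- sort(round(back[r3, 3], 2))
  expect_equal(d1, d0, tolerance = 0.05)
  expect_equal(sort(sqrt(rowSums(back[r3, 1:2]^2))),
               sort(sqrt(rowSums(lm0$points[r3, 1:2]^2))),
               tolerance = 0.05)
})

test_that("projections with interior holes are rejected", {
  # sphere with an annular band of faces removed: the projection has a
  # ring-shaped hole crossing every radial line
  m <- fx_sphere(r = 6)
  ctr <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
            m$vertices[m$faces[, 3], ]) / 3
  rho <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
  keep <- rho < 2 | rho > 3.2
  m2 <- op_mesh(m$vertices, m$faces[keep, , drop = FALSE])
  expect_error(generate_correspondence(m2),
               class = "correspondence_failure")
})

test_that("landmark mesh of a convex shape has no self-intersections", {
  lm <- generate_correspondence(fx_sphere(r = 6))
  m <- as_op_mesh(lm)
  # for a convex closed mesh every vertex must see the centroid without
  # crossing the surface; cheap proxy: all faces keep outward normals
  V <- m$vertices; F <- m$faces
  ctr <- colMeans(V)
  e1 <- V[F[, 2], ] - V[F[, 1], ]
  e2 <- V[F[, 3], ] - V[F[, 1], ]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  mid <- (V[F[, 1], ] + V[F[, 2], ] + V[F[, 3], ]) / 3
  out <- rowSums(n * sweep(mid, 2, ctr))
  expect_true(all(out > 0))
})
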