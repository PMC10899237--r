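test_that("sclera segmentation matches the generator ground truth", {
  photo <- fx_photo(seed = 2)
  scl <- fx_sclera_seg(seed = 2)
  expect_gte(mean(scl$M_E == photo$regions), 0.95)
  # refined mask is contained in the sclera label
  expect_true(all(scl$M_E[scl$M_W] == 3))
  expect_gt(nrow(scl$I_S), 1000)
})

test_that("the refinement filters follow their threshold semantics", {
  # achromatic pixels never trip the vein filter; lightness threshold
  # is strict at 50
  lab <- matrix(c(49.9, 0, 0,
                  50.1, 5 * cos(0.3), 5 * sin(0.3),
                  60, 20 * cos(0.1), 20 * sin(0.1),    # reddish, C > 8
                  60, 20 * cos(2.5), 20 * sin(2.5)),   # greenish hue
                ncol = 3, byrow = TRUE)
  lch <- lch_from_lab(lab)
  reddish <- lch[, 2] > 8 & (lch[, 3] >= 345 | lch[, 3] <= 60)
  keep <- lab[, 1] >= 50 & !reddish
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("k-means recovers a two-colour mixture", {
  set.seed(3)
  A <- c(75, 2, 8); B <- c(60, 6, 18)
  px <- rbind(matrix(rep(A, 600), ncol = 3, byrow = TRUE),
              matrix(rep(B, 400), ncol = 3, byrow = TRUE)) +
    rnorm(3000, sd = 0.05)
  centres <- with(list(), {
    init <- ocuprost:::.kmeanspp_init(px, 2)
    kmeans(px, centers = init)$centers
  })
  d <- delta_e2000(centres, rbind(A, B))
  d_swap <- delta_e2000(centres, rbind(B, A))
  expect_lt(min(max(d), max(d_swap)), 0.5)
})

test_that("the base colour matches a direct arithmetic evaluation", {
  set.seed(9)
  G <- cbind(runif(9, 55, 85), runif(9, -3, 6), runif(9, 2, 20))
  res <- palette_base_colour(G)
  # independent spreadsheet-style evaluation
  L <- G[, 1]
  w <- (L - min(L)) / (max(L) - min(L))
  gB <- c(sum(w * G[, 1]), sum(w * G[, 2]), sum(w * G[, 3])) / sum(w)
  expect_equal(unname(res$g_B), gB, tolerance = 1e-12)
  expect_equal(res$weights, w)
  # degenerate limit: equal lightness -> uniform weights, plain mean
  Geq <- G; Geq[, 1] <- 70
  deg <- palette_base_colour(Geq)
  expect_true(deg$degenerate)
  expect_equal(unname(deg$g_B), unname(colMeans(Geq)))
})

test_that("palette extraction runs on segmented pixels", {
  pal <- extract_palette(fx_sclera_seg(seed = 2), seed = 1)
  expect_equal(nrow(pal$colours), 9)
  expect_true(all(pal$colours$weight >= 0 & pal$colours$weight <= 1))
  expect_true(all(is.finite(pal$g_B)))
  # the two injected stain colours appear among the clusters
  photo <- fx_photo(seed = 2)
  for (g in photo$stain_labs) {
    d <- delta_e2000(as.matrix(pal$colours[, c("L", "a", "b")]),
                     matrix(rep(g, 9), ncol = 3, byrow = TRUE))
    expect_lt(min(d), 6)
  }
  expect_error(extract_palette(matrix(1, 10, 3)), "1000")
})

test_that("staining covers 90% with seamless borders, deterministically", {
  pal <- extract_palette(fx_sclera_seg(seed = 2), seed = 1)
  for (s in c(1, 7, 13)) {
    st <- render_staining(pal, seed = s, width = 256, height = 128)
    expect_gte(st$coverage, 0.88)
    expect_lte(st$coverage, 0.92)
  }
  st <- render_staining(pal, seed = 1, width = 256, height = 128)
  st2 <- render_staining(pal, seed = 1, width = 256, height = 128)
  expect_identical(st$lab, st2$lab)   # bit-identical under a fixed seed
  # seam: first and last columns differ no more than interior neighbours
  L <- st$lab[, , 1]
  seam <- mean(abs(L[, 1] - L[, ncol(L)]))
  interior <- mean(abs(L[, -1] - L[, -ncol(L)]))
  expect_lt(seam, 3 * interior + 0.5)
  # per-colour stained areas roughly equal (within 40% relative)
  tab <- table(st$stain_index[st$stain_index > 0])
  expect_lt(max(tab) / min(tab), 2)
})

test_that("vein growth obeys seeds, layers and the global parameters", {
  net <- grow_veins(th = 1, br = 1.2, seed = 5)
  seeds <- vein_seed_points()
  roots <- net$nodes[net$nodes$layer == 1 & net$nodes$node == 1, ]
  expect_equal(nrow(roots), 10)
  for (i in seq_len(nrow(roots))) {
    d <- sqrt((seeds[, 1] - roots$u[i])^2 + (seeds[, 2] - roots$v[i])^2)
    expect_lt(min(d), 1e-9)
  }
  # no node beyond the limbus
  expect_true(all(net$nodes$v < net$params$limbus_v))
  # thickness positive and non-increasing along each vein
  for (vid in unique(net$nodes$vein)) {
    tv <- net$nodes$thickness[net$nodes$vein == vid]
    expect_true(all(tv > 0))
    expect_true(all(diff(tv) <= 1e-12))
  }
  # br = 0: only layer-1 veins
  net0 <- grow_veins(th = 1, br = 0, seed = 5)
  expect_equal(unique(net0$nodes$layer), 1L)
  # doubling th doubles initial thicknesses exactly (same seed)
  net_a <- grow_veins(th = 0.8, br = 1, seed = 7)
  net_b <- grow_veins(th = 1.6, br = 1, seed = 7)
  r_a <- net_a$nodes[net_a$nodes$node == 1 & net_a$nodes$layer == 1, ]
  r_b <- net_b$nodes[net_b$nodes$node == 1 & net_b$nodes$layer == 1, ]
  expect_equal(r_b$thickness, 2 * r_a$thickness, tolerance = 1e-12)
})

test_that("vein pixel coverage rises with thickness and branching", {
  pal <- extract_palette(fx_sclera_seg(seed = 2), seed = 1)
  st <- render_staining(pal, seed = 2, width = 256, height = 128)
  cover <- function(th, br) {
    f <- vapply(1:3, function(s) {
      rv <- render_veins(grow_veins(th, br, seed = s), st)
      mean(is.finite(rv$depth_map))
    }, 0)
    mean(f)
  }
  c_th <- cover(1.6, 1); c_base <- cover(0.8, 1)
  expect_gt(c_th, c_base)
  expect_gt(cover(1, 2.4), cover(1, 0.4))
})

test_that("profile selection matches the exhaustive weighted argmin", {
  profiles <- vein_profiles()
  expect_length(profiles, 15)
  for (p in profiles) {
    expect_equal(nrow(p$lab), 21)
    expect_length(p$alpha, 21)
  }
  set.seed(10)
  for (rep in 1:50) {
    t <- runif(1, 0.002, 0.02); d <- runif(1, 0.1, 1)
    sel <- select_profile(t, d, profiles)
    costs <- vapply(profiles, function(p)
      5 * (p$thickness - t)^2 + (p$depth - d)^2, 0)
    expect_equal(sel, which.min(costs))
  }
})

test_that("rendering follows the centreline and depth ordering", {
  pal <- list(g_B = c(75, 2, 8),
              colours = data.frame(L = rep(75, 9), a = 2, b = 8,
                                   weight = 1))
  class(pal) <- "sclera_palette"
  st <- render_staining(pal, seed = 1, width = 200, height = 100)
  # straight two-node vein, zero jitter: painted pixels hug the line
  net <- structure(list(
    nodes = data.frame(vein = 1, node = 1:2, u = c(0.5, 1.5),
                       v = c(0.5, 0.5), thickness = 0.03, depth = 0.5,
                       layer = 1, recipe = 1),
    params = list(th = 1, br = 1, seed = 1, limbus_v = 0.95)),
    class = "vein_network")
  rv <- render_veins(net, st, jitter_amp = 0)
  hit <- which(is.finite(rv$depth_map), arr.ind = TRUE)
  expect_gt(nrow(hit), 10)
  expect_lt(max(abs(hit[, 1] - 0.5 * 100)), 0.03 * 100 / 2 + 1.5)
  # crossing veins: the shallower depth wins the depth buffer
  net2 <- structure(list(
    nodes = data.frame(vein = c(1, 1, 2, 2), node = c(1, 2, 1, 2),
                       u = c(0.5, 1.5, 1, 1), v = c(0.5, 0.5, 0.1, 0.9),
                       thickness = 0.04, depth = c(0.8, 0.8, 0.2, 0.2),
                       layer = c(1, 1, 3, 3), recipe = c(1, 1, 11, 11)),
    params = list(th = 1, br = 1, seed = 1, limbus_v = 0.95)),
    class = "vein_network")
  rv2 <- render_veins(net2, st, jitter_amp = 0)
  expect_equal(rv2$depth_map[50, 100], 0.2)
})
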