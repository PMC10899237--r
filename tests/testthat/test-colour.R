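test_that("a known linear camera is recovered to numerical precision", {
  gp <- gen_characterization_patches()
  expect_equal(nrow(gp$patches), 63) # 24 checker + 24 iris + 15 sclera
  chr <- fit_characterization(gp$patches)
  expect_equal(chr$A, gp$A_true, tolerance = 1e-9, ignore_attr = TRUE)
  lab_out <- apply_characterization(
    chr, as.matrix(gp$patches[, c("R", "G", "B")]))
  lab_in <- as.matrix(gp$patches[, c("L", "a", "b")])
  expect_lt(max(delta_e2000(lab_out, lab_in)), 1e-6)
  expect_lt(chr$residual_max, 1e-6)
})

test_that("the root-polynomial stage is the identity on correct pairs", {
  gp <- gen_characterization_patches()
  chr <- fit_characterization(gp$patches)
  # B applied to already-correct Lab values changes nothing
  lab <- as.matrix(gp$patches[, c("L", "a", "b")])
  feats <- cbind(lab[, 1], lab[, 2], lab[, 3],
                 sign(lab[, 1] * lab[, 2]) * sqrt(abs(lab[, 1] * lab[, 2])),
                 sign(lab[, 1] * lab[, 3]) * sqrt(abs(lab[, 1] * lab[, 3])),
                 sign(lab[, 2] * lab[, 3]) * sqrt(abs(lab[, 2] * lab[, 3])),
                 1)
  expect_lt(max(abs(feats %*% t(chr$B) - lab)), 1e-6)
})

test_that("degenerate patch sets are rejected", {
  gp <- gen_characterization_patches()
  p <- gp$patches
  p$G <- p$R; p$B <- p$R
  expect_error(fit_characterization(p), "rank")
  expect_error(fit_characterization(gp$patches[1:5, ]), "at least 10")
})

test_that("XYZ/Lab conversions round-trip and match the reference", {
  set.seed(6)
  lab <- cbind(runif(100, 0, 100), runif(100, -80, 80),
               runif(100, -80, 80))
  expect_lt(max(abs(lab_from_xyz(xyz_from_lab(lab)) - lab)), 1e-10)
  # CIEDE2000 against the farver implementation
  skip_if_not_installed("farver")
  a <- lab[1:20, ]; b <- lab[21:40, ]
  ours <- delta_e2000(a, b)
  ref <- diag(farver::compare_colour(a, b, from_space = "lab",
                                     method = "cie2000",
                                     white_from = "D50"))
  expect_equal(ours, ref, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("the raw processing chain reproduces known scenes", {
  gp <- gen_characterization_patches()
  chr <- fit_characterization(gp$patches)
  photo <- fx_photo(seed = 3, size = 96)
  xyz <- xyz_from_lab(matrix(photo$lab, ncol = 3))
  img <- array(xyz %*% t(gp$M), c(96, 96, 3))
  flat <- array(rep(0.9 + 0.1 * cos(outer((1:96) / 96, (1:96) / 96)), 3),
                c(96, 96, 3))
  flat <- flat / mean(flat)
  dark <- 0.02
  raw <- img * flat + dark
  calib <- list(dark_mean = dark, flat = flat, characterization = chr)
  ei <- process_raw(raw, calib, denoise = FALSE)
  expect_lt(max(abs(ei$I_col - photo$lab)), 1e-9)
  # flat-fielding the flat itself gives a constant image
  eiW <- process_raw(flat + dark, calib, denoise = FALSE)
  expect_gt(sd(ei$I_pp), 0) # the scene image is not constant
  expect_lt(sd(eiW$I_pp), 1e-12)
  # a dark frame processes to (near) zero before characterization
  ei0 <- process_raw(array(dark, c(96, 96, 3)), calib, denoise = FALSE)
  expect_lt(max(abs(ei0$I_prime)), 1e-12)
  expect_error(process_raw(raw, list(flat = flat,
                                     characterization = chr)), "dark")
})

test_that("non-local means raises PSNR on noisy images", {
  gp <- gen_characterization_patches()
  chr <- fit_characterization(gp$patches)
  set.seed(4)
  clean <- matrix(0.5 + 0.3 * sin(outer(1:64, 1:64, `+`) / 10), 64, 64)
  noisy <- clean + rnorm(64^2, sd = 0.05)
  den <- ocuprost:::.cpp_nlm(noisy, 15 / 255, 5L)
  psnr <- function(x) -10 * log10(mean((x - clean)^2))
  expect_gt(psnr(den), psnr(noisy))
})

test_that("highlight masking follows the saturation and lightness rules", {
  # smooth image, no saturation: empty mask, output untouched
  smooth <- array(rep(60 + outer(1:64, 1:64, `+`) / 40, 3), c(64, 64, 3))
  smooth[, , 2] <- 5; smooth[, , 3] <- 5
  raw <- array(0.5, c(64, 64, 3))
  hl <- remove_highlights(smooth, raw)
  expect_false(any(hl$M_H))
  expect_equal(hl$I_clean, smooth)
  # an injected bright dot is masked and inpainted close to the clean
  # value
  spiked <- smooth
  spiked[30:34, 30:34, 1] <- spiked[30:34, 30:34, 1] + 40
  hl2 <- remove_highlights(spiked, raw)
  expect_true(all(hl2$M_H[31:33, 31:33]))
  expect_lt(max(abs(hl2$I_clean[30:34, 30:34, 1] -
                      smooth[30:34, 30:34, 1])), 5)
  # raw saturation masks regardless of lightness
  raw_sat <- raw
  raw_sat[10, 10, 1] <- 1
  hl3 <- remove_highlights(smooth, raw_sat)
  expect_true(hl3$M_H[10, 10])
})
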