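# Shared fixtures, built once per test run and cached. Everything is
# generated in code at a desk scale that keeps the suite fast.

.fx <- new.env(parent = emptyenv())

fixture_cached <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# UV sphere mesh (closed, outward-oriented)
fx_sphere <- function(r = 5, nth = 24, nph = 48) {
  th <- seq(0, pi, length.out = nth + 1)
  v <- rbind(c(0, 0, r))
  for (t in th[2:nth]) for (p in (0:(nph - 1)) / nph * 2 * pi)
    v <- rbind(v, c(r * sin(t) * cos(p), r * sin(t) * sin(p), r * cos(t)))
  v <- rbind(v, c(0, 0, -r))
  f <- NULL
  ring <- function(i) 1 + (i - 1) * nph + 1:nph
  r1 <- ring(1)
  for (k in 1:nph) f <- rbind(f, c(1, r1[k], r1[k %% nph + 1]))
  for (i in 1:(nth - 2)) {
    a <- ring(i); b <- ring(i + 1)
    for (k in 1:nph) {
      k2 <- k %% nph + 1
      f <- rbind(f, c(a[k], b[k], b[k2]), c(a[k], b[k2], a[k2]))
    }
  }
  last <- nrow(v); bl <- ring(nth - 1)
  for (k in 1:nph) f <- rbind(f, c(last, bl[k %% nph + 1], bl[k]))
  op_mesh(v, f)
}

# landmark meshes of the parametric shell family (canonical frame)
fx_landmarks <- function(n = 20, seed = 11) {
  fixture_cached(sprintf("lms_%d_%d", n, seed), function() {
    scans <- gen_prosthesis_set(n, seed = seed, rigid = FALSE)
    lapply(scans, function(s) generate_correspondence(s$mesh))
  })
}

# shape model over the parametric family
fx_model <- function(n = 20, seed = 11) {
  fixture_cached(sprintf("model_%d_%d", n, seed), function()
    build_model(fx_landmarks(n, seed)))
}

# socket depth map synthesized from known coordinates (full projection)
fx_sdm_from <- function(model, x, mask_fn = NULL, shift_z = 0) {
  lm <- synthesize(model, x)
  pts <- lm$points
  pts[, 3] <- pts[, 3] + shift_z
  Z <- back_depth_map(landmark_mesh(pts))
  mask <- !is.na(Z) & Z > 0.5
  if (!is.null(mask_fn)) mask <- mask & mask_fn(Z)
  structure(list(values = ifelse(mask, Z, NA), mask = mask,
                 pitch = 16 / 256, origin = c(-8, -8),
                 area_mm2 = sum(mask) * (16 / 256)^2,
                 area_traced_mm2 = sum(mask) * (16 / 256)^2,
                 points = NULL),
            class = "socket_depth_map")
}

fx_photo <- function(seed = 2, ...) {
  fixture_cached(sprintf("photo_%d_%s", seed,
                         paste(unlist(list(...)), collapse = "_")),
                 function() gen_eye_photo(eye_photo_config(...),
                                          seed = seed))
}

fx_iris_seg <- function(seed = 2) {
  fixture_cached(sprintf("seg_%d", seed), function()
    detect_iris(fx_photo(seed)$lab))
}

fx_sclera_seg <- function(seed = 2) {
  fixture_cached(sprintf("sclseg_%d", seed), function()
    segment_sclera(fx_photo(seed)$lab, fx_iris_seg(seed)$M_I))
}

fx_oct <- function(seed = 4, ...) {
  fixture_cached(sprintf("oct_%d_%s", seed,
                         paste(unlist(list(...)), collapse = "_")),
                 function() {
    m <- fx_model()
    conf <- make_conformer(m, fx_landmarks()[[1]], id = "A05")
    target <- gen_prosthesis_set(1, seed = 77, rigid = FALSE)[[1]]
    lm_t <- generate_correspondence(target$mesh)
    c(gen_oct_volume(lm_t, conf$spec, seed = seed, ...),
      list(spec = conf$spec))
  })
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
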