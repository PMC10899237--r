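## Procedural vein network: stochastic growth of node chains in a
## dimensionless 2:1 (u x v) domain, three layers deep, steered by 15
## growth recipes (5 per layer), rendered with quadratic B-splines and
## 1-D colour/alpha cross-section profiles.
##
## The 15 recipe parameter sets, the 10 seed positions and the 15
## profiles are this package's versioned stand-in defaults (in clinical
## practice such tables are hand-authored): seeds ring the fornix border of the texture,
## recipes produce visually layered networks (thick straight trunks,
## mid branches, fine capillaries).

#' Vein growth recipes (version 1)
#'
#' 15 parameter sets, 5 per layer: base thickness and depth (texture
#' units), step length, maximum steps, per-node branching rate,
#' straightness (inverse heading noise), and thickness decay per step.
#' @return data frame with one row per recipe
#' @export
vein_recipes <- function() {
  data.frame(
    recipe = 1:15,
    layer = rep(1:3, each = 5),
    thickness = c(0.016, 0.014, 0.018, 0.013, 0.015,
                  0.009, 0.008, 0.010, 0.007, 0.009,
                  0.004, 0.005, 0.004, 0.003, 0.005),
    depth = c(0.9, 0.85, 0.95, 0.8, 0.9,
              0.55, 0.5, 0.6, 0.45, 0.55,
              0.2, 0.25, 0.15, 0.2, 0.25),
    step_len = c(rep(0.020, 5), rep(0.014, 5), rep(0.009, 5)),
    max_steps = c(rep(60L, 5), rep(40L, 5), rep(28L, 5)),
    branching = c(0.05, 0.06, 0.04, 0.07, 0.05,
                  0.08, 0.09, 0.07, 0.10, 0.08,
                  0, 0, 0, 0, 0),
    straightness = c(0.92, 0.9, 0.94, 0.88, 0.91,
                     0.8, 0.78, 0.82, 0.75, 0.8,
                     0.65, 0.6, 0.68, 0.62, 0.66),
    decay = c(rep(0.995, 5), rep(0.99, 5), rep(0.985, 5)))
}

#' First-layer vein seed positions (version 1)
#'
#' Ten positions around the fornix border of the 2:1 texture domain
#' (u in [0, 2), v = 0 is the fornix, v = 1 the limbus edge).
#' @return 10 x 2 matrix (u, v)
#' @export
vein_seed_points <- function() {
  cbind(u = c(0.1, 0.35, 0.6, 0.85, 1.05, 1.25, 1.5, 1.7, 1.9, 0.95),
        v = c(0.05, 0.03, 0.06, 0.04, 0.05, 0.04, 0.06, 0.03, 0.05, 0.02))
}

#' Grow the procedural vein network
#'
#' Layer-1 veins start at the 10 seed positions and grow toward the
#' limbus with heading noise set by their recipe; a vein stops after its
#' recipe's maximum number of steps, when its thickness falls below a
#' quarter of its initial value, or when it reaches the limbus
#' (v >= \code{limbus_v}). Grown veins branch into next-layer veins at
#' randomly selected nodes (branch thickness 0.6 of the node, same
#' depth, random recipe of the next layer). The global parameters
#' \code{th} and \code{br} directly scale all recipe thickness and
#' branching values; neither changes the random stream, so two runs with
#' the same seed differ only in scale.
#'
#' @param th thickness multiplier in (0, 3]
#' @param br branching multiplier in [0, 3]
#' @param seed RNG seed
#' @param limbus_v limbus boundary in the v coordinate
#' @return object of class \code{vein_network}: data frame \code{nodes}
#'   (vein, node, u, v, thickness, depth, layer, recipe), and
#'   \code{params}
#' @export
grow_veins <- function(th = 1, br = 1, seed = 1, limbus_v = 0.95) {
  stopifnot(th > 0, th <= 3, br >= 0, br <= 3)
  recipes <- vein_recipes()
  seeds <- vein_seed_points()
  nodes <- list()
  vein_id <- 0L
  with_seed(seed, {
    grow_one <- function(u, v, thickness, depth, layer, recipe_id, dir0) {
      rc <- recipes[recipe_id, ]
      vein_id <<- vein_id + 1L
      id <- vein_id
      pts <- matrix(0, rc$max_steps + 1, 3)
      pts[1, ] <- c(u, v, thickness)
      dir <- dir0
      cnt <- 1L
      for (s in seq_len(rc$max_steps)) {
        dir <- dir * rc$straightness +
          (1 - rc$straightness) * rnorm(1, 0, 1.2)
        # heading measured from the +v axis; veins drift limbus-ward
        u <- (u + sin(dir) * rc$step_len) %% 2
        v <- v + cos(dir) * rc$step_len
        thickness <- thickness * rc$decay
        if (v >= limbus_v || v < 0) break
        if (thickness < 0.25 * pts[1, 3]) break
        cnt <- cnt + 1L
        pts[cnt, ] <- c(u, v, thickness)
      }
      pts <- pts[seq_len(cnt), , drop = FALSE]
      nodes[[length(nodes) + 1]] <<- data.frame(
        vein = id, node = seq_len(cnt), u = pts[, 1], v = pts[, 2],
        thickness = pts[, 3], depth = depth, layer = rc$layer,
        recipe = recipe_id)
      # branching into the next layer
      if (rc$layer < 3 && cnt > 3) {
        rate <- rc$branching * br
        nb <- rbinom(1, cnt - 2, min(rate, 1))
        if (nb > 0) {
          at <- sample(2:(cnt - 1), nb)
          for (aidx in at) {
            nxt <- which(recipes$layer == rc$layer + 1)
            rid <- sample(nxt, 1)
            grow_one(pts[aidx, 1], pts[aidx, 2],
                     0.6 * pts[aidx, 3], rc$depth,
                     rc$layer + 1, rid, rnorm(1, 0, 1.5))
          }
        }
      }
    }
    l1 <- which(recipes$layer == 1)
    for (i in seq_len(nrow(seeds))) {
      rid <- sample(l1, 1)
      grow_one(seeds[i, 1], seeds[i, 2],
               recipes$thickness[rid] * th, recipes$depth[rid],
               1L, rid, rnorm(1, 0, 0.3))
    }
  })
  structure(list(nodes = do.call(rbind, nodes),
                 params = list(th = th, br = br, seed = seed,
                               limbus_v = limbus_v)),
            class = "vein_network")
}

#' @export
print.vein_network <- function(x, ...) {
  cat(sprintf("<vein_network: %d veins, %d nodes, layers %s>\n",
              length(unique(x$nodes$vein)), nrow(x$nodes),
              paste(sort(unique(x$nodes$layer)), collapse = "/")))
  invisible(x)
}

#' Vein rendering profiles (version 1)
#'
#' 15 synthetic 1-D cross-sections of 21 samples each: CIELAB colour
#' and alpha across the vein width (reddish core, transparent flanks),
#' labelled with the width and depth they represent.
#' @return list of profiles: \code{lab} (21 x 3), \code{alpha} (21),
#'   \code{thickness}, \code{depth}
#' @export
vein_profiles <- function() {
  rc <- vein_recipes()
  lapply(seq_len(15), function(i) {
    t <- seq(-1, 1, length.out = 21)
    core <- exp(-(t / 0.45)^2)
    # deeper veins are bluer and fainter
    d <- rc$depth[i]
    lab <- cbind(L = 62 - 20 * core * d,
                 a = 12 + 26 * core * (0.4 + 0.6 * d),
                 b = 8 + 6 * core * d - 6 * (1 - d))
    alpha <- core * (0.35 + 0.55 * d)
    list(lab = lab, alpha = alpha,
         thickness = rc$thickness[i], depth = rc$depth[i])
  })
}

#' Select the rendering profile for a vein
#'
#' Minimal weighted squared distance to the profile's labelled depth
#' and thickness, with a five times greater weight on the thickness.
#' @param thickness,depth the vein recipe's values
#' @param profiles from \code{\link{vein_profiles}}
#' @return profile index
#' @export
select_profile <- function(thickness, depth, profiles = vein_profiles()) {
  cost <- vapply(profiles, function(p)
    5 * (p$thickness - thickness)^2 + (p$depth - depth)^2, 0)
  which.min(cost)
}

# quadratic B-spline through a sliding window of control points,
# sampled densely; four knots per local segment
.spline_samples <- function(P, step) {
  if (nrow(P) == 2) {
    n <- max(2, ceiling(sqrt(sum((P[2, ] - P[1, ])^2)) / step))
    t <- seq(0, 1, length.out = n)
    return(cbind(P[1, 1] + t * (P[2, 1] - P[1, 1]),
                 P[1, 2] + t * (P[2, 2] - P[1, 2])))
  }
  out <- list()
  for (i in seq_len(nrow(P) - 2)) {
    p0 <- P[i, ]; p1 <- P[i + 1, ]; p2 <- P[i + 2, ]
    a <- (p0 + p1) / 2; b <- (p1 + p2) / 2
    len <- sqrt(sum((b - a)^2)) + 1e-9
    n <- max(2, ceiling(len / step))
    t <- seq(0, 1, length.out = n)
    # quadratic Bezier equivalent of the uniform B-spline segment
    out[[i]] <- cbind(
      (1 - t)^2 * a[1] + 2 * t * (1 - t) * p1[1] + t^2 * b[1],
      (1 - t)^2 * a[2] + 2 * t * (1 - t) * p1[2] + t^2 * b[2])
  }
  do.call(rbind, out)
}

#' Render the vein network onto a sclera texture
#'
#' Rasterizes each vein as a quadratic B-spline swept with its selected
#' 1-D profile: the perpendicular distance to the curve (modulated by a
#' sinusoidal offset along the path) indexes colour and alpha in the
#' profile. A depth buffer composites overlapping veins so shallower
#' veins win; the buffer doubles as an optional displacement map.
#'
#' @param network a \code{vein_network}
#' @param texture a \code{sclera_texture} (staining layer)
#' @param jitter_amp amplitude of the sinusoidal path offset (fraction
#'   of the vein half-width); 0 disables
#' @return a \code{sclera_texture} with the veins composited and a
#'   \code{depth_map} layer
#' @export
render_veins <- function(network, texture, jitter_amp = 0.35) {
  lab <- texture$lab
  H <- dim(lab)[1]; W <- dim(lab)[2]
  profiles <- vein_profiles()
  depth_buf <- matrix(Inf, H, W)
  nd <- network$nodes
  for (vid in unique(nd$vein)) {
    vn <- nd[nd$vein == vid, ]
    if (nrow(vn) < 2) next
    rc_th <- vn$thickness[1]
    pidx <- select_profile(rc_th, vn$depth[1], profiles)
    prof <- profiles[[pidx]]
    # domain (u in [0,2], v in [0,1]) to pixels
    P <- cbind(vn$u / 2 * W, vn$v * H)
    hw <- max(1, vn$thickness[1] / 2 * H)
    S <- .spline_samples(P, step = 0.5)
    if (is.null(S) || nrow(S) < 2) next
    dxy <- diff(S)
    nrm <- cbind(-dxy[, 2], dxy[, 1])
    nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-9)
    arc <- c(0, cumsum(sqrt(rowSums(dxy^2))))
    phase <- vid * 1.7
    offs <- seq(-ceiling(hw), ceiling(hw), by = 1)
    for (s in seq_len(nrow(S) - 1)) {
      jit <- jitter_amp * hw * sin(arc[s] / (6 * hw) * 2 * pi + phase)
      px <- round(S[s, 1] + nrm[s, 1] * (offs + jit))
      py <- round(S[s, 2] + nrm[s, 2] * (offs + jit))
      px <- ((px - 1) %% W) + 1     # u wraps
      ok <- py >= 1 & py <= H
      if (!any(ok)) next
      prof_pos <- clamp(round((offs / hw) * 10) + 11, 1, 21)
      d <- vn$depth[1]
      for (ii in which(ok)) {
        if (d < depth_buf[py[ii], px[ii]] ||
            is.infinite(depth_buf[py[ii], px[ii]])) {
          a <- prof$alpha[prof_pos[ii]]
          if (a <= 0) next
          lab[py[ii], px[ii], ] <-
            (1 - a) * lab[py[ii], px[ii], ] + a * prof$lab[prof_pos[ii], ]
          if (a > 0.2) depth_buf[py[ii], px[ii]] <- d
        }
      }
    }
  }
  out <- texture
  out$lab <- lab
  out$depth_map <- depth_buf
  out$network <- network
  out
}

#' Serialize a vein network to JSON
#' @param network a \code{vein_network}
#' @param path output path
#' @export
write_vein_network <- function(network, path) {
  jsonlite::write_json(list(format = "ocuprost-veins", version = "1",
                            params = network$params,
                            nodes = network$nodes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
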