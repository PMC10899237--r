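#' Fitting configuration
#'
#' Energy weights and bounds for the shape fit. The reference weights
#' decay like the expected mode variances; all modes beyond the tenth use
#' weight 16.
#' @param k number of model modes
#' @param w_dist distance-term weight
#' @param w_ext penalty weight on the extended degrees of freedom
#' @param box coordinate bound (standard deviations per mode)
#' @param theta_limit_deg rotation bound for the fallback (degrees)
#' @param z_limit translation bound for the fallback (mm)
#' @param alphas target-shape interpolation factors
#' @param mode_step modes unlocked per coarse-to-fine stage
#' @return object of class \code{fit_config}
#' @export
fit_config <- function(k, w_dist = 10000, w_ext = 10000, box = 3,
                       theta_limit_deg = 30, z_limit = 2.5,
                       alphas = c(0, 0.5, 0.9), mode_step = 3) {
  structure(list(k = k, w_dist = w_dist, w_ref = ref_weights(k),
                 w_ext = w_ext, box = box,
                 theta_limit = theta_limit_deg * pi / 180,
                 z_limit = z_limit, alphas = alphas,
                 mode_step = mode_step),
            class = "fit_config")
}

#' Reference weights per mode
#' @param k number of modes
#' @return numeric vector (2048, 1024, 512, 256, 128, 64, 32, 16, 16, ...)
#' @export
ref_weights <- function(k) {
  base <- c(2048, 1024, 512, 256, 128, 64, 32)
  c(base, rep(16, max(0, k - 7)))[seq_len(k)]
}

#' Orthographic back-surface depth map of a landmark mesh
#'
#' \code{Z_z}: rasterizes the mesh on the socket grid and keeps, per
#' pixel, the deepest surface (minimum z), reported as depth in mm
#' positive into the socket, matching \code{socket_depth_map} values.
#' @param lm a \code{landmark_mesh} (or \code{op_mesh})
#' @param resolution,extent grid (pixels, mm)
#' @return matrix of depths (NA where the projection misses the mesh)
#' @export
back_depth_map <- function(lm, resolution = 256, extent = 16) {
  m <- if (inherits(lm, "landmark_mesh")) as_op_mesh(lm) else lm
  z <- .cpp_rasterize_depth(m$vertices, m$faces, resolution, resolution,
                            -extent / 2, -extent / 2, extent / resolution,
                            FALSE)
  -z
}

# rigid perturbation used by the extended fit
.rigid_yz <- function(points, theta, z) {
  if (theta != 0) {
    ct <- cos(theta); st <- sin(theta)
    x <- points[, 1] * ct + points[, 3] * st
    zz <- -points[, 1] * st + points[, 3] * ct
    points[, 1] <- x; points[, 3] <- zz
  }
  points[, 3] <- points[, 3] + z
  points
}

#' Distance energy between a shape and the socket surface
#'
#' Mean squared masked difference between the orthographic back-surface
#' depth of S(x) (optionally rigidly perturbed by a rotation about y and
#' a z translation) and the socket depth map, weighted by \code{w_dist}.
#' Socket pixels missed by the projection contribute with depth 0 (the
#' iris plane).
#'
#' @param x shape coordinates
#' @param sdm a \code{socket_depth_map}
#' @param model a \code{shape_model}
#' @param theta rotation about y (radians)
#' @param z translation along z (mm)
#' @param w_dist weight
#' @return scalar energy
#' @export
energy_dist <- function(x, sdm, model, theta = 0, z = 0, w_dist = 10000) {
  n_mask <- sum(sdm$mask)
  if (n_mask == 0) stop("empty socket mask")
  lm <- synthesize(model, x)
  pts <- .rigid_yz(lm$points, theta, z)
  res <- nrow(sdm$values)
  Z <- back_depth_map(op_mesh(pts, lm$faces), res,
                      res * sdm$pitch)
  diff <- Z - sdm$values
  diff[is.na(Z) & sdm$mask] <- -sdm$values[is.na(Z) & sdm$mask]
  w_dist / n_mask * sum(diff[sdm$mask]^2, na.rm = TRUE)
}

#' Reference energy
#'
#' Weighted L2 norm of the difference to the target shape:
#' \code{||w_ref (x - x_t)||_2}.
#' @param x,x_t shape coordinates of equal length
#' @param w_ref per-mode weights (defaults to \code{ref_weights})
#' @return scalar
#' @export
energy_ref <- function(x, x_t, w_ref = ref_weights(length(x))) {
  stopifnot(length(x) == length(x_t))
  sqrt(sum((w_ref * (x - x_t))^2))
}

#' Target shape coordinates
#'
#' Interpolates between the mean shape (x = 0) and the conformer base
#' shape: \code{x_t = alpha * x_c}.
#' @param x_c conformer base-shape coordinates
#' @param alpha bias in [0, 1]
#' @return coordinate vector
#' @export
make_target <- function(x_c, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  alpha * x_c
}

#' Fit the shape model to a socket depth map
#'
#' Minimizes \code{E(x) = E_dist(x) + E_ref(x)} with bounded L-BFGS-B,
#' starting from the target shape and unlocking modes coarse-to-fine in
#' steps of \code{mode_step} (locked modes stay pinned at their target
#' values; previously unlocked coordinates remain free). If any
#' coordinate of the solution saturates the \code{±box} bound, the fit is
#' rerun with two extra rigid degrees of freedom (rotation theta about y,
#' translation z along z) penalized by \code{w_ext (theta^2 + z^2)}.
#'
#' @param sdm a \code{socket_depth_map}
#' @param model a \code{shape_model}
#' @param conformer optional \code{conformer_spec} providing x_c (mean
#'   shape used when NULL)
#' @param alphas target biases to fit (one result per value)
#' @param config a \code{fit_config}
#' @return list of \code{fit_result} objects, one per alpha: fitted
#'   coordinates \code{x_f}, rigid \code{theta}, \code{z},
#'   \code{energy}, \code{fallback_used}, \code{alpha}, \code{x_t}
#' @export
fit_shape <- function(sdm, model, conformer = NULL,
                      alphas = c(0, 0.5, 0.9),
                      config = fit_config(model$k)) {
  stopifnot(model$k >= 3)
  x_c <- if (is.null(conformer)) rep(0, model$k) else {
    xc <- conformer$x_c
    length(xc) <- model$k
    xc[is.na(xc)] <- 0
    xc
  }
  lapply(alphas, function(alpha) {
    x_t <- make_target(x_c, alpha)
    fit1 <- .fit_one(sdm, model, x_t, config)
    sat <- any(abs(fit1$x_f) >= config$box - 1e-6)
    if (sat) {
      fit2 <- .fit_one(sdm, model, x_t, config, extended = TRUE)
      fit2$fallback_used <- TRUE
      fit2$alpha <- alpha; fit2$x_t <- x_t
      structure(fit2, class = "fit_result")
    } else {
      fit1$fallback_used <- FALSE
      fit1$alpha <- alpha; fit1$x_t <- x_t
      structure(fit1, class = "fit_result")
    }
  })
}

.fit_one <- function(sdm, model, x_t, config, extended = FALSE) {
  k <- model$k
  x <- x_t
  theta <- 0; z <- 0
  trace <- numeric(0)
  stages <- seq(config$mode_step, k, by = config$mode_step)
  if (tail(stages, 1) != k) stages <- c(stages, k)
  for (m in stages) {
    act <- seq_len(m)
    npar <- length(act) + if (extended) 2 else 0
    par0 <- c(x[act], if (extended) c(theta, z))
    lower <- c(rep(-config$box, length(act)),
               if (extended) c(-config$theta_limit, -config$z_limit))
    upper <- -lower
    fn <- function(p) {
      xx <- x
      xx[act] <- p[seq_along(act)]
      th <- if (extended) p[length(act) + 1] else 0
      zz <- if (extended) p[length(act) + 2] else 0
      e <- energy_dist(xx, sdm, model, th, zz, config$w_dist) +
        energy_ref(xx, x_t, config$w_ref) +
        if (extended) config$w_ext * (th^2 + zz^2) else 0
      e
    }
    res <- tryCatch(
      optim(par0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 60, ndeps = rep(1e-3, npar))),
      error = function(e) list(par = par0, value = fn(par0),
                               convergence = 52))
    if (res$value <= fn(par0) + 1e-12) {
      x[act] <- res$par[seq_along(act)]
      if (extended) {
        theta <- res$par[length(act) + 1]
        z <- res$par[length(act) + 2]
      }
    }
    if (!is.null(res$convergence) && res$convergence == 1)
      warning("optimizer reached max iterations; using best iterate")
    trace <- c(trace, res$value)
  }
  list(x_f = x, theta = theta, z = z, energy = tail(trace, 1),
       energy_trace = trace)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result: alpha %.1f, energy %.3f, |x|max %.2f%s>\n",
    x$alpha, x$energy, max(abs(x$x_f)),
    if (x$fallback_used)
      sprintf(", fallback theta %.2f deg z %.2f mm",
              x$theta * 180 / pi, x$z) else ""))
  invisible(x)
}
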