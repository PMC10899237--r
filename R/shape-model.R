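#' Build a PCA statistical shape model
#'
#' Standard PCA by singular value decomposition on the matrix of flattened
#' landmark coordinates (one row per training shape, 838 x 3 = 2514
#' columns). No Procrustes size normalization is applied: rotation is
#' already canonical after alignment, and prosthesis size correlates with
#' shape, which the model should capture. The number of retained modes k is
#' the smallest count whose cumulative explained variance reaches
#' \code{variance_target}. Modes are unit vectors scaled at synthesis time
#' by their standard deviations, so shape coordinates are in units of
#' per-mode standard deviations.
#'
#' @param shapes list of \code{landmark_mesh} objects sharing the fixed
#'   face list
#' @param variance_target fraction of shape variance to explain (on the
#'   variances, not the standard deviations)
#' @return object of class \code{shape_model}: \code{mean_shape} (838 x 3),
#'   \code{modes} (2514 x k, orthonormal columns), \code{sigmas},
#'   \code{k}, \code{explained} (all-mode variance fractions),
#'   \code{n_samples}, \code{zero_variance} flag
#' @export
build_model <- function(shapes, variance_target = 0.98) {
  if (length(shapes) < 3)
    abort_ocuprost("at least 3 training shapes are required",
                   "insufficient_data")
  X <- do.call(rbind, lapply(shapes, function(s) as.vector(s$points)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  n <- nrow(X)
  sv <- svd(Xc)
  sig <- sv$d / sqrt(n - 1)          # per-mode standard deviations
  var_ <- sig^2
  tot <- sum(var_)
  zero_variance <- tot < 1e-24
  if (zero_variance) {
    k <- 1L
    explained <- c(1, rep(0, length(var_) - 1))
    sig <- rep(0, length(sig))
  } else {
    explained <- var_ / tot
    k <- which(cumsum(explained) >= variance_target - 1e-12)[1]
  }
  modes <- sv$v[, seq_len(max(k, 1L)), drop = FALSE]
  # deterministic sign: largest-magnitude component of each mode positive
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  structure(list(mean_shape = landmark_mesh(matrix(mu, ncol = 3)),
                 modes = modes, sigmas = sig[seq_len(k)], k = as.integer(k),
                 explained = explained, n_samples = n,
                 zero_variance = zero_variance),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "<shape_model: k = %d modes from %d shapes, %.1f%% variance%s>\n",
    x$k, x$n_samples, 100 * sum(x$explained[seq_len(x$k)]),
    if (x$zero_variance) ", zero-variance" else ""))
  invisible(x)
}

#' Synthesize a shape from shape-space coordinates
#'
#' \code{S(x) = mean + sum_i x_i sigma_i C_i}; \code{x = 0} gives the mean
#' shape exactly.
#' @param model a \code{shape_model}
#' @param x numeric vector of length \code{model$k} (standard deviations
#'   per mode)
#' @return a \code{landmark_mesh}
#' @export
synthesize <- function(model, x) {
  stopifnot(length(x) == model$k, all(is.finite(x)))
  zero_sig <- model$sigmas == 0
  if (any(zero_sig & x != 0))
    stop("nonzero coordinate requested on a zero-variance mode")
  v <- as.vector(model$mean_shape$points) +
    model$modes %*% (x * model$sigmas)
  landmark_mesh(matrix(v, ncol = 3))
}

#' Project a landmark mesh into shape space
#'
#' Least-squares coordinates of (shape - mean) on the scaled modes. The
#' round trip \code{project(synthesize(x)) = x} is exact; the reverse
#' generally is not: components outside the mode span are lost.
#' @param model a \code{shape_model}
#' @param shape a \code{landmark_mesh}
#' @return numeric coordinate vector of length \code{model$k}
#' @export
project_shape <- function(model, shape) {
  d <- as.vector(shape$points) - as.vector(model$mean_shape$points)
  raw <- drop(crossprod(model$modes, d))   # modes are orthonormal
  ifelse(model$sigmas > 0, raw / model$sigmas, 0)
}

# mean per-vertex Euclidean distance between two landmark meshes
vertex_distance <- function(a, b) {
  mean(sqrt(rowSums((a$points - b$points)^2)))
}

#' Evaluate a shape model (replication, generalization, specificity)
#'
#' Replication: mean per-vertex distance of each training shape to its own
#' model projection. Generalization: the same with the shape excluded from
#' training (leave-one-out). Specificity: mean distance from randomly
#' sampled shapes (standard-normal coordinates) to the nearest training
#' shape.
#'
#' @param shapes list of \code{landmark_mesh}
#' @param variance_target passed to \code{\link{build_model}}
#' @param n_specificity number of sampled shapes
#' @param seed RNG seed for the specificity sample
#' @return data frame with one row per metric: \code{mean} and \code{sd}
#'   of the per-shape (or per-sample) vertex distances, in mm
#' @export
evaluate_model <- function(shapes, variance_target = 0.98,
                           n_specificity = 10000, seed = 1) {
  if (length(shapes) < 4)
    abort_ocuprost("at least 4 shapes required for evaluation",
                   "insufficient_data")
  model <- build_model(shapes, variance_target)
  rep_d <- vapply(shapes, function(s)
    vertex_distance(s, synthesize(model, project_shape(model, s))), 0)
  gen_d <- vapply(seq_along(shapes), function(i) {
    m <- build_model(shapes[-i], variance_target)
    vertex_distance(shapes[[i]],
                    synthesize(m, project_shape(m, shapes[[i]])))
  }, 0)
  P <- lapply(shapes, `[[`, "points")
  spec_d <- with_seed(seed, {
    vapply(seq_len(n_specificity), function(i) {
      s <- synthesize(model, rnorm(model$k))
      min(vapply(P, function(p)
        mean(sqrt(rowSums((p - s$points)^2))), 0))
    }, 0)
  })
  data.frame(metric = c("replication", "generalization", "specificity"),
             mean = c(mean(rep_d), mean(gen_d), mean(spec_d)),
             sd = c(sd(rep_d), sd(gen_d), sd(spec_d)))
}

#' Serialize a shape model to a JSON archive
#' @param model a \code{shape_model}
#' @param path output file (.json)
#' @export
write_shape_model <- function(model, path) {
  obj <- list(format = "ocuprost-ssm", version = "1",
              scheme_version = model$mean_shape$scheme_version,
              k = model$k, n_samples = model$n_samples,
              zero_variance = model$zero_variance,
              sigmas = model$sigmas, explained = model$explained,
              mean_shape = as.vector(model$mean_shape$points),
              modes = as.vector(model$modes))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a shape model archive
#' @param path file written by \code{\link{write_shape_model}}
#' @return a \code{shape_model}
#' @export
read_shape_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(o$format, "ocuprost-ssm"))
  structure(list(
    mean_shape = landmark_mesh(matrix(o$mean_shape, ncol = 3)),
    modes = matrix(o$modes, ncol = o$k),
    sigmas = o$sigmas[seq_len(o$k)], k = as.integer(o$k),
    explained = o$explained, n_samples = o$n_samples,
    zero_variance = isTRUE(o$zero_variance)),
    class = "shape_model")
}
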