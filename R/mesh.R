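#' Triangle mesh container
#'
#' Minimal triangle-mesh representation used throughout the package:
#' vertex coordinates in millimetres and a 1-based face index matrix.
#'
#' @param vertices numeric n x 3 matrix (mm)
#' @param faces integer m x 3 matrix of 1-based vertex indices
#' @return an object of class \code{op_mesh}
#' @export
op_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            all(faces >= 1), all(faces <= nrow(vertices)))
  structure(list(vertices = vertices, faces = faces), class = "op_mesh")
}

#' @export
print.op_mesh <- function(x, ...) {
  cat(sprintf("<op_mesh: %d vertices, %d faces, bbox %s mm>\n",
              nrow(x$vertices), nrow(x$faces),
              paste(sprintf("%.1f", mesh_bbox(x)$size), collapse = " x ")))
  invisible(x)
}

#' Axis-aligned bounding box of a mesh
#' @param mesh an \code{op_mesh}
#' @return list with \code{min}, \code{max} and \code{size} (width, height,
#'   depth in mm)
#' @export
mesh_bbox <- function(mesh) {
  mn <- apply(mesh$vertices, 2, min)
  mx <- apply(mesh$vertices, 2, max)
  list(min = mn, max = mx, size = mx - mn)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed surfaces.
#' @param mesh an \code{op_mesh}
#' @return volume in mm^3
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Area-weighted vertex normals
#' @param mesh an \code{op_mesh}
#' @return n x 3 matrix of unit normals
#' @export
mesh_vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], F[, k])
      n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Undirected edge list of a mesh
#' @param mesh an \code{op_mesh}
#' @return 2-column matrix of unique undirected edges
#' @export
mesh_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Check that a mesh is a closed orientable surface
#'
#' Every undirected edge must be shared by exactly two faces with opposite
#' directed orientation.
#' @param mesh an \code{op_mesh}
#' @return logical
#' @export
mesh_is_closed <- function(mesh) {
  F <- mesh$faces
  de <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(de[, 1], de[, 2])
  rkey <- paste(de[, 2], de[, 1])
  if (any(duplicated(key))) return(FALSE)
  all(key %in% rkey)
}

## --- file formats -----------------------------------------------------

#' Read an ASCII STL file
#' @param path file path
#' @param merge_tol vertices closer than this (mm) are merged
#' @return an \code{op_mesh}
#' @export
read_stl <- function(path, merge_tol = 1e-6) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("not a valid ASCII STL file: ", path)
  vv <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(round(vv / merge_tol), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- vv[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  op_mesh(verts, faces)
}

#' Write an ASCII STL file
#' @param mesh an \code{op_mesh}
#' @param path output path
#' @param name solid name
#' @export
write_stl <- function(mesh, path, name = "ocuprost") {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  tri <- sprintf(
    "facet normal 0 0 0\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    V[F[, 1], 1], V[F[, 1], 2], V[F[, 1], 3],
    V[F[, 2], 1], V[F[, 2], 2], V[F[, 2], 3],
    V[F[, 3], 1], V[F[, 3], 2], V[F[, 3], 3])
  writeLines(tri, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read a Wavefront OBJ file
#'
#' Supports v / vt / f records; texture indices are dropped when absent.
#' @param path file path
#' @return an \code{op_mesh}; texture coordinates (if any) attached as the
#'   \code{uv} element
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sp <- strsplit(trimws(lines), "\\s+")
  tag <- vapply(sp, function(p) p[1] %||% "", "")
  v <- do.call(rbind, lapply(sp[tag == "v"], function(p) as.numeric(p[2:4])))
  vt <- sp[tag == "vt"]
  f <- sp[tag == "f"]
  if (is.null(v) || length(f) == 0) stop("not a valid OBJ file: ", path)
  fidx <- do.call(rbind, lapply(f, function(p) {
    as.integer(vapply(strsplit(p[2:4], "/"), `[[`, "", 1))
  }))
  m <- op_mesh(v, fidx)
  if (length(vt) > 0)
    m$uv <- do.call(rbind, lapply(vt, function(p) as.numeric(p[2:3])))
  m
}

#' Write a Wavefront OBJ file
#' @param mesh an \code{op_mesh}, optionally with a \code{uv} element
#' @param path output path
#' @param mtl optional MTL file name to reference
#' @param material optional material name (usemtl)
#' @export
write_obj <- function(mesh, path, mtl = NULL, material = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(mtl)) writeLines(sprintf("mtllib %s", mtl), con)
  V <- mesh$vertices
  writeLines(sprintf("v %g %g %g", V[, 1], V[, 2], V[, 3]), con)
  has_uv <- !is.null(mesh$uv)
  if (has_uv)
    writeLines(sprintf("vt %g %g", mesh$uv[, 1], mesh$uv[, 2]), con)
  if (!is.null(material)) writeLines(sprintf("usemtl %s", material), con)
  F <- mesh$faces
  if (has_uv) {
    writeLines(sprintf("f %d/%d %d/%d %d/%d",
                       F[, 1], F[, 1], F[, 2], F[, 2], F[, 3], F[, 3]), con)
  } else {
    writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
  }
  invisible(path)
}

#' Read marker points from a sidecar text file
#'
#' Four labelled rows (S, N, I, T) with x y z coordinates in mm, e.g.
#' \code{S 0.1 5.9 0.0}.
#' @param path file path
#' @return named list of 3-vectors \code{p_S}, \code{p_N}, \code{p_I},
#'   \code{p_T}
#' @export
read_markers <- function(path) {
  tab <- utils::read.table(path, col.names = c("label", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  need <- c("S", "N", "I", "T")
  if (!all(need %in% tab$label)) stop("marker file must label rows S N I T")
  out <- lapply(need, function(l) unlist(tab[tab$label == l, 2:4],
                                         use.names = FALSE))
  setNames(out, paste0("p_", need))
}

#' Write marker points to a sidecar text file
#' @param markers named list with \code{p_S}, \code{p_N}, \code{p_I},
#'   \code{p_T}
#' @param path output path
#' @export
write_markers <- function(markers, path) {
  lab <- c("S", "N", "I", "T")
  lines <- vapply(lab, function(l) {
    p <- markers[[paste0("p_", l)]]
    sprintf("%s %.9g %.9g %.9g", l, p[1], p[2], p[3])
  }, "")
  writeLines(lines, path)
  invisible(path)
}
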