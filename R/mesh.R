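# Triangle surface meshes in millimetre coordinates: construction, OBJ I/O,
# and the elementary measures (area, enclosed volume) everything else uses.

#' Triangle mesh in millimetre coordinates
#'
#' Constructs an indexed triangle mesh. Coordinates are interpreted as
#' millimetres throughout the package; derived volumes are reported in
#' millilitres (1 ml = 1000 mm^3) and areas in square centimetres
#' (1 cm^2 = 100 mm^2). Faces are vertex-index triples; the winding order
#' defines the face orientation.
#'
#' @param vertices numeric matrix (or coercible) with 3 columns, one row per
#'   vertex, in mm.
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param clean if \code{TRUE} (default), faces with area below
#'   \code{1e-10} mm^2 are dropped so downstream invariants (no degenerate
#'   faces) hold.
#' @return an object of class \code{triangle_mesh}: a list with elements
#'   \code{vertices} and \code{faces}.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1, 2, 3)))
#' surface_area(m)
#' @export
triangle_mesh <- function(vertices, faces, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("vertices must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (length(faces) == 0L)
    stop("mesh has no faces")
  if (ncol(faces) != 3L)
    stop("faces must have 3 columns (triangles)")
  if (nrow(vertices) == 0L)
    stop("mesh has no vertices")
  if (!all(is.finite(vertices)))
    stop("non-finite vertex coordinates")
  if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face references a nonexistent vertex (indices must be in 1..",
         nrow(vertices), ")")
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "triangle_mesh")
  if (clean) {
    a <- face_areas(mesh)
    keep <- a > 1e-10
    if (!all(keep)) {
      mesh$faces <- mesh$faces[keep, , drop = FALSE]
      if (nrow(mesh$faces) == 0L)
        stop("mesh has no non-degenerate faces")
    }
  }
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [mm]: x %.1f..%.1f  y %.1f..%.1f  z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# row-wise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' @rdname mesh_measures
#' @export
face_areas <- function(mesh) {
  n <- cross3(face_corner(mesh, 2) - face_corner(mesh, 1),
              face_corner(mesh, 3) - face_corner(mesh, 1))
  0.5 * sqrt(rowSums(n * n))
}

face_normals <- function(mesh, unit = TRUE) {
  n <- cross3(face_corner(mesh, 2) - face_corner(mesh, 1),
              face_corner(mesh, 3) - face_corner(mesh, 1))
  if (unit) {
    len <- sqrt(rowSums(n * n))
    len[len < 1e-300] <- 1
    n <- n / len
  }
  n
}

face_centroids <- function(mesh) {
  (face_corner(mesh, 1) + face_corner(mesh, 2) + face_corner(mesh, 3)) / 3
}

# Undirected edge bookkeeping. Returns counts per undirected edge and whether
# the winding is consistent (each shared edge traversed once in each direction).
mesh_edge_audit <- function(mesh) {
  f <- mesh$faces
  ea <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ea[, 1], ea[, 2]), pmax(ea[, 1], ea[, 2]))
  cnt <- table(key)
  dir_key <- paste(ea[, 1], ea[, 2])
  dup_directed <- any(duplicated(dir_key))
  list(boundary_edges = sum(cnt == 1L),
       overshared_edges = sum(cnt > 2L),
       consistent_winding = !dup_directed)
}

#' Watertightness test
#'
#' A mesh is watertight when every edge is shared by exactly two faces and the
#' winding order is globally consistent (each shared edge is traversed once in
#' each direction).
#'
#' @param mesh a \code{triangle_mesh}.
#' @return logical scalar with attributes \code{boundary_edges} and
#'   \code{consistent_winding}.
#' @export
is_watertight <- function(mesh) {
  a <- mesh_edge_audit(mesh)
  ok <- a$boundary_edges == 0L && a$overshared_edges == 0L &&
    a$consistent_winding
  structure(ok, boundary_edges = a$boundary_edges,
            consistent_winding = a$consistent_winding)
}

#' Surface area and enclosed volume of a triangle mesh
#'
#' \code{surface_area} sums the triangle areas (mm^2) and reports cm^2.
#' \code{enclosed_volume} applies the divergence theorem,
#' \eqn{V = \frac{1}{6}\sum v_0\cdot(v_1\times v_2)}, to a watertight,
#' consistently wound mesh and reports ml. If the global orientation turns out
#' to be inward (negative signed volume) the absolute value is returned with a
#' warning.
#'
#' @param mesh a \code{triangle_mesh}; for \code{enclosed_volume} it must be
#'   watertight (an informative error names the number of open edges
#'   otherwise).
#' @return \code{surface_area}: area in cm^2. \code{enclosed_volume}: volume
#'   in ml.
#' @name mesh_measures
#' @export
surface_area <- function(mesh) {
  sum(face_areas(mesh)) / 100
}

#' @rdname mesh_measures
#' @export
enclosed_volume <- function(mesh) {
  a <- mesh_edge_audit(mesh)
  if (a$boundary_edges > 0L || a$overshared_edges > 0L)
    stop("mesh is not watertight: ", a$boundary_edges, " open edge(s), ",
         a$overshared_edges, " edge(s) shared by more than two faces")
  if (!a$consistent_winding)
    stop("mesh winding is inconsistent; enclosed volume is undefined")
  # signed tetra volumes det(v0, v1, v2) / 6; origin-independent on a closed
  # surface
  v <- sum(rowSums(face_corner(mesh, 1) *
                     cross3(face_corner(mesh, 2), face_corner(mesh, 3)))) / 6
  vol_ml <- v / 1000
  if (vol_ml < 0) {
    warning("mesh is oriented inward; returning |volume|")
    vol_ml <- -vol_ml
  }
  vol_ml
}

#' Read a Wavefront OBJ mesh
#'
#' Parses \code{v} and \code{f} records; normals, texture coordinates,
#' materials and grouping are ignored. Polygonal faces are fan-triangulated
#' from their first vertex; negative (relative) indices are accepted.
#' Coordinates are taken as millimetres.
#'
#' @param path path to an OBJ file.
#' @param clean drop degenerate (zero-area) faces after load (default TRUE).
#' @return a \code{triangle_mesh}.
#' @export
read_obj <- function(path, clean = TRUE) {
  if (!file.exists(path))
    stop("OBJ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("empty or face-less OBJ: ", path)
  vtok <- strsplit(sub("^v\\s+", "", vlines), "\\s+")
  verts <- t(vapply(vtok, function(s) as.numeric(s[1:3]), numeric(3)))
  if (!all(is.finite(verts)))
    stop("non-numeric vertex record in ", path)
  nv <- nrow(verts)
  ftok <- strsplit(sub("^f\\s+", "", flines), "\\s+")
  tri_list <- lapply(ftok, function(s) {
    idx <- as.integer(sub("/.*$", "", s))
    idx <- ifelse(idx < 0L, nv + idx + 1L, idx)
    if (anyNA(idx) || length(idx) < 3L)
      stop("malformed face record in OBJ")
    if (min(idx) < 1L || max(idx) > nv)
      stop("face references a nonexistent vertex (", max(idx),
           " of ", nv, ")")
    k <- length(idx)
    cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  })
  faces <- do.call(rbind, tri_list)
  triangle_mesh(verts, faces, clean = clean)
}

#' Write a Wavefront OBJ mesh
#'
#' Emits plain \code{v}/\code{f} records. Optional per-vertex colors are
#' written as the common \code{v x y z r g b} extension (used for
#' distance-map visualisation).
#'
#' @param mesh a \code{triangle_mesh}.
#' @param path output path.
#' @param vertex_colors optional n x 3 matrix of RGB values in \code{[0, 1]}.
#' @return invisibly, \code{path}.
#' @export
write_obj <- function(mesh, path, vertex_colors = NULL) {
  if (!inherits(mesh, "triangle_mesh"))
    stop("mesh must be a triangle_mesh")
  if (nrow(mesh$faces) == 0L || nrow(mesh$vertices) == 0L)
    stop("refusing to write an empty mesh")
  v <- mesh$vertices
  if (is.null(vertex_colors)) {
    vrec <- sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  } else {
    stopifnot(nrow(vertex_colors) == nrow(v))
    vrec <- sprintf("v %.9g %.9g %.9g %.4f %.4f %.4f",
                    v[, 1], v[, 2], v[, 3],
                    vertex_colors[, 1], vertex_colors[, 2],
                    vertex_colors[, 3])
  }
  frec <- sprintf("f %d %d %d",
                  mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# breastvol OBJ export", vrec, frec), con)
  invisible(path)
}

#' Merge two meshes into one
#'
#' Concatenates vertex and face lists (no welding). Used e.g. to check volume
#' additivity of disjoint solids.
#'
#' @param a,b \code{triangle_mesh} objects.
#' @return a \code{triangle_mesh}.
#' @export
merge_meshes <- function(a, b) {
  triangle_mesh(rbind(a$vertices, b$vertices),
                rbind(a$faces, b$faces + nrow(a$vertices)),
                clean = FALSE)
}

# Apply a rigid (or affine) motion x -> R x + t to a point matrix.
transform_points <- function(p, R = diag(3), t = c(0, 0, 0)) {
  sweep(p %*% t(R), 2, t, "+")
}

#' Rigidly transform a mesh
#'
#' @param mesh a \code{triangle_mesh}.
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation (mm).
#' @return the transformed \code{triangle_mesh}.
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  mesh$vertices <- transform_points(mesh$vertices, R, t)
  mesh
}

#' Icosphere mesh
#'
#' Unit icosahedron subdivided \code{subdivisions} times with vertices
#' projected to the sphere. Used as an analytic fixture (inscribed polyhedron:
#' volume and area are below the sphere values and converge with refinement).
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions.
#' @param center sphere center.
#' @return a watertight \code{triangle_mesh}.
#' @export
icosphere <- function(radius = 1, subdivisions = 2, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v * v))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      m <- edge_mid[[key]]
      if (!is.null(m)) return(m)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / vnorm(p)
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- matrix(p, 1)
      edge_mid[[key]] <- nv
      nv
    }
    nf <- nrow(f)
    newf <- matrix(0L, 4L * nf, 3L)
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(4 * k - 3):(4 * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  triangle_mesh(sweep(v * radius, 2, center, "+"), f, clean = FALSE)
}
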