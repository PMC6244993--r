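# Independent geometric oracles: voxel-counting volume (column parity) and a
# small incremental 3-D convex hull. These exist so the divergence-theorem
# volume can be cross-checked against an unrelated construction.

#' Voxel-counting volume of a watertight mesh
#'
#' Counts voxel centers inside the mesh by vertical-column parity: for each
#' (x, y) column of voxel centers, all intersections of the column with the
#' surface are collected, sorted, paired into inside intervals, and the voxel
#' centers within them counted. Independent of the divergence-theorem path in
#' \code{\link{enclosed_volume}}, so the two serve as mutual checks.
#'
#' @param mesh a watertight \code{triangle_mesh}.
#' @param voxel voxel edge length (mm).
#' @param xy_window optional \code{c(xmin, xmax, ymin, ymax)} restricting the
#'   counted columns (used to voxelize a sub-region, e.g. a breast bump as the
#'   difference of two meshes over its footprint).
#' @return volume in ml.
#' @export
voxelized_volume <- function(mesh, voxel = 0.5, xy_window = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  if (is.null(xy_window)) {
    xy_window <- c(min(v[, 1]) - voxel, max(v[, 1]) + voxel,
                   min(v[, 2]) - voxel, max(v[, 2]) + voxel)
  }
  # slight irrational-ish offset so columns avoid edges/vertices generically
  x0 <- xy_window[1] - voxel * 0.0012345
  y0 <- xy_window[3] - voxel * 0.0023456
  z0 <- min(v[, 3]) - voxel
  nx <- max(1L, ceiling((xy_window[2] - x0) / voxel))
  col_of <- function(ix, iy) (iy - 1) * nx + ix
  x1 <- v[f[, 1], 1]; y1 <- v[f[, 1], 2]; z1 <- v[f[, 1], 3]
  x2 <- v[f[, 2], 1]; y2 <- v[f[, 2], 2]; z2 <- v[f[, 2], 3]
  x3 <- v[f[, 3], 1]; y3 <- v[f[, 3], 2]; z3 <- v[f[, 3], 3]
  denom <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  cols <- vector("list", nrow(f))
  zs <- vector("list", nrow(f))
  for (k in seq_len(nrow(f))) {
    if (abs(denom[k]) < 1e-12) next
    fx <- c(x1[k], x2[k], x3[k]); fy <- c(y1[k], y2[k], y3[k])
    if (max(fx) < xy_window[1] || min(fx) > xy_window[2] ||
        max(fy) < xy_window[3] || min(fy) > xy_window[4]) next
    ix <- seq(ceiling((max(min(fx), xy_window[1]) - x0) / voxel - 0.5 + 1e-12),
              floor((min(max(fx), xy_window[2]) - x0) / voxel - 0.5 + 1 - 1e-12))
    iy <- seq(ceiling((max(min(fy), xy_window[3]) - y0) / voxel - 0.5 + 1e-12),
              floor((min(max(fy), xy_window[4]) - y0) / voxel - 0.5 + 1 - 1e-12))
    if (!length(ix) || !length(iy)) next
    cx <- x0 + (ix - 0.5) * voxel
    cy <- y0 + (iy - 0.5) * voxel
    gx <- rep(cx, times = length(cy))
    gy <- rep(cy, each = length(cx))
    gix <- rep(ix, times = length(iy))
    giy <- rep(iy, each = length(ix))
    l1 <- ((y2[k] - y3[k]) * (gx - x3[k]) +
             (x3[k] - x2[k]) * (gy - y3[k])) / denom[k]
    l2 <- ((y3[k] - y1[k]) * (gx - x3[k]) +
             (x1[k] - x3[k]) * (gy - y3[k])) / denom[k]
    l3 <- 1 - l1 - l2
    hit <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(hit)) next
    cols[[k]] <- col_of(gix[hit], giy[hit])
    zs[[k]] <- l1[hit] * z1[k] + l2[hit] * z2[k] + l3[hit] * z3[k]
  }
  col <- unlist(cols)
  z <- unlist(zs)
  if (!length(col)) return(0)
  o <- order(col, z)
  col <- col[o]; z <- z[o]
  # drop duplicate crossings (column through a shared edge hits both faces)
  dup <- c(FALSE, diff(col) == 0 & abs(diff(z)) < 1e-9)
  col <- col[!dup]; z <- z[!dup]
  cnt <- rle(col)$lengths
  odd_cols <- sum(cnt %% 2L == 1L)
  if (odd_cols > 0) {
    # degenerate grazing columns: discard them (measure-zero contribution)
    keep <- rep(cnt %% 2L == 0L, times = cnt)
    col <- col[keep]; z <- z[keep]
    if (odd_cols > 0.01 * length(cnt))
      warning(odd_cols, " columns with odd crossing parity discarded")
  }
  if (!length(z)) return(0)
  lo <- z[seq(1, length(z), by = 2)]
  hi <- z[seq(2, length(z), by = 2)]
  n_in <- floor((hi - z0) / voxel + 0.5) - floor((lo - z0) / voxel + 0.5)
  sum(n_in) * voxel^3 / 1000
}

#' Convex hull of 3-D points
#'
#' Incremental convex hull (visible-face deletion over the horizon), returning
#' an outward-oriented watertight \code{triangle_mesh}. Intended for fixture
#' construction (random convex solids with exactly computable volume), not as
#' a general-purpose computational-geometry routine.
#'
#' @param points n x 3 matrix, n >= 4, in general position.
#' @return a \code{triangle_mesh} whose faces triangulate the hull.
#' @export
convex_hull3 <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points")
  scale <- max(abs(pts), 1)
  eps <- 1e-9 * scale
  tri_normal <- function(a, b, c)
    c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
      (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  # initial simplex
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) stop("degenerate point set")
  ab <- pts[i2, ] - pts[i1, ]
  d2 <- sweep(pts, 2, pts[i1, ])
  crossn <- cbind(ab[2] * d2[, 3] - ab[3] * d2[, 2],
                  ab[3] * d2[, 1] - ab[1] * d2[, 3],
                  ab[1] * d2[, 2] - ab[2] * d2[, 1])
  i3 <- which.max(rowSums(crossn^2))
  nrm <- tri_normal(pts[i1, ], pts[i2, ], pts[i3, ])
  hdist <- d2 %*% nrm
  i4 <- which.max(abs(hdist))
  if (abs(hdist[i4]) < eps) stop("points are (near) coplanar")
  base <- c(i1, i2, i3)
  if (hdist[i4] > 0) base <- base[c(1, 3, 2)]  # put i4 behind (i1,i2,i3)
  # side faces traverse each base edge in the reverse direction so the closed
  # winding is consistent (normals outward)
  faces <- rbind(base,
                 c(base[2], base[1], i4),
                 c(base[3], base[2], i4),
                 c(base[1], base[3], i4))
  # outward by construction: each face sees no simplex vertex in front
  for (pi in setdiff(seq_len(n), c(base, i4))) {
    p <- pts[pi, ]
    nf <- nrow(faces)
    excess <- numeric(nf)
    for (k in seq_len(nf)) {
      a <- pts[faces[k, 1], ]
      nrm <- tri_normal(a, pts[faces[k, 2], ], pts[faces[k, 3], ])
      excess[k] <- sum(nrm * (p - a) / sqrt(sum(nrm^2)))
    }
    if (max(excess) <= eps) next
    # visible set restricted to the faces edge-connected to the most visible
    # one, so near-coplanar jitter cannot produce a pinched horizon
    cand <- which(excess > eps)
    ekey <- function(f) paste(pmin(f[c(1, 2, 3)], f[c(2, 3, 1)]),
                              pmax(f[c(1, 2, 3)], f[c(2, 3, 1)]))
    keys_by_face <- lapply(seq_len(nf), function(k) ekey(faces[k, ]))
    vis <- logical(nf)
    queue <- which.max(excess)
    vis[queue] <- TRUE
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      nb <- cand[!vis[cand]]
      nb <- nb[vapply(nb, function(j)
        any(keys_by_face[[j]] %in% keys_by_face[[k]]), logical(1))]
      vis[nb] <- TRUE
      queue <- c(queue, nb)
    }
    vis_faces <- faces[vis, , drop = FALSE]
    dir_edges <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)],
                       vis_faces[, c(3, 1)])
    keys <- paste(dir_edges[, 1], dir_edges[, 2])
    rev_keys <- paste(dir_edges[, 2], dir_edges[, 1])
    # horizon: directed edges of visible faces whose reverse is not visible
    horizon <- dir_edges[!(rev_keys %in% keys), , drop = FALSE]
    faces <- rbind(faces[!vis, , drop = FALSE],
                   cbind(horizon, pi))
  }
  triangle_mesh(pts, faces, clean = FALSE)
}
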