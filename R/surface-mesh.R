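# SurfaceMesh container: triangulated crown / antagonist surfaces, plus the
# exact point-triangle distance primitives used by contact detection.

#' Construct a triangulated surface mesh
#'
#' @param vertices v x 3 numeric matrix (mm).
#' @param triangles t x 3 integer matrix of vertex indices; triangles are
#'   expected counter-clockwise seen from outside (outward normals).
#' @param facet_labels optional per-triangle tag.
#' @param validate reject degenerate (zero-area) triangles.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, facet_labels = NULL,
                         validate = TRUE) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL; dimnames(triangles) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop("triangle indices out of range")
  }
  m <- structure(list(vertices = vertices, triangles = triangles,
                      facet_labels = facet_labels),
                 class = "surface_mesh")
  if (validate && nrow(triangles) > 0 && any(triangle_areas(m) <= 0)) {
    stop("degenerate (zero-area) triangles present")
  }
  m
}

#' Triangle areas of a surface mesh
#' @param mesh a `surface_mesh`.
#' @return numeric vector (mm^2).
#' @export
triangle_areas <- function(mesh) {
  sqrt(rowSums(triangle_cross(mesh)^2)) / 2
}

#' Outward unit normals of all triangles
#' @param mesh a `surface_mesh`.
#' @return t x 3 matrix of unit normals.
#' @export
triangle_normals <- function(mesh) {
  cr <- triangle_cross(mesh)
  cr / sqrt(rowSums(cr * cr))
}

triangle_cross <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

triangle_centroids <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

#' Exact distance from points to a triangle
#'
#' Classic region-based closest-point projection (Eberly), vectorized over
#' query points.
#'
#' @param p q x 3 matrix of query points.
#' @param a,b,c triangle corners (length-3 vectors).
#' @return numeric vector of Euclidean distances.
#' @keywords internal
point_triangle_distance <- function(p, a, b, c) {
  p <- matrix(p, ncol = 3)
  ab <- b - a; ac <- c - a
  ap <- sweep(p, 2, a)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  aa <- sum(ab * ab); bb <- sum(ac * ac); abab <- sum(ab * ac)
  det <- aa * bb - abab * abab
  # barycentric coordinates of the unconstrained projection
  s <- (bb * d1 - abab * d2) / det
  t <- (aa * d2 - abab * d1) / det
  # clamp into the triangle region by region
  s2 <- s; t2 <- t
  inside <- s >= 0 & t >= 0 & (s + t) <= 1
  if (!all(inside)) {
    out <- which(!inside)
    for (i in out) {
      r <- closest_bary(d1[i], d2[i], aa, bb, abab)
      s2[i] <- r[1]; t2[i] <- r[2]
    }
  }
  q <- outer(as.vector(s2), ab) + outer(as.vector(t2), ac)
  q <- sweep(q, 2, a, "+")
  sqrt(rowSums((p - q)^2))
}

# closest point on the triangle boundary in barycentric (s,t) for a point
# whose projection falls outside; d1 = ap.ab, d2 = ap.ac
closest_bary <- function(d1, d2, aa, bb, abab) {
  # edge ab (t = 0)
  s_ab <- min(max(d1 / aa, 0), 1)
  cand <- list(c(s_ab, 0))
  # edge ac (s = 0)
  t_ac <- min(max(d2 / bb, 0), 1)
  cand[[2]] <- c(0, t_ac)
  # edge bc: param u from b to c
  # point = b + u (c - b); minimize |ap - (ab + u(ac-ab))|^2
  num <- (d2 - d1) + (aa - abab)
  den <- aa + bb - 2 * abab
  u <- if (den > 0) min(max(num / den, 0), 1) else 0
  cand[[3]] <- c(1 - u, u)
  # pick candidate minimizing squared distance (up to constant |ap|^2):
  # f(s,t) = s^2 aa + t^2 bb + 2 s t abab - 2 s d1 - 2 t d2
  f <- vapply(cand, function(st) {
    s <- st[1]; t <- st[2]
    s * s * aa + t * t * bb + 2 * s * t * abab - 2 * s * d1 - 2 * t * d2
  }, numeric(1))
  cand[[which.min(f)]]
}

#' Distance from points to a surface mesh
#'
#' Exact min-over-triangles distance, with a uniform-grid spatial index to
#' prune candidate triangles. Set `index = NULL` to force the brute-force
#' all-triangles path (the test oracle).
#'
#' @param p q x 3 matrix of query points.
#' @param mesh a `surface_mesh`.
#' @param index optional index from [surface_index()].
#' @return numeric vector of unsigned distances (mm).
#' @export
point_surface_distance <- function(p, mesh, index = NULL) {
  p <- matrix(p, ncol = 3)
  v <- mesh$vertices; tr <- mesh$triangles
  d <- rep(Inf, nrow(p))
  if (is.null(index)) {
    for (k in seq_len(nrow(tr))) {
      d <- pmin(d, point_triangle_distance(p, v[tr[k, 1], ], v[tr[k, 2], ],
                                           v[tr[k, 3], ]))
    }
    return(d)
  }
  for (i in seq_len(nrow(p))) {
    d[i] <- index_point_distance(p[i, ], mesh, index)
  }
  d
}

#' Build a uniform-grid spatial index over a surface mesh
#'
#' @param mesh a `surface_mesh`.
#' @param cell grid cell edge (mm); defaults to twice the median triangle edge.
#' @return an opaque index object for [point_surface_distance()].
#' @export
surface_index <- function(mesh, cell = NULL) {
  v <- mesh$vertices; tr <- mesh$triangles
  if (is.null(cell)) {
    e <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
    cell <- 2 * stats::median(sqrt(rowSums(e * e)))
    if (!is.finite(cell) || cell <= 0) cell <- 1
  }
  lo <- apply(v, 2, min) - 1e-9
  # cell range per triangle AABB
  tmin <- pmin(v[tr[, 1], ], v[tr[, 2], ], v[tr[, 3], ])
  tmax <- pmax(v[tr[, 1], ], v[tr[, 2], ], v[tr[, 3], ])
  cmin <- floor(sweep(tmin, 2, lo) / cell)
  cmax <- floor(sweep(tmax, 2, lo) / cell)
  buckets <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(tr))) {
    for (ix in cmin[k, 1]:cmax[k, 1]) for (iy in cmin[k, 2]:cmax[k, 2])
      for (iz in cmin[k, 3]:cmax[k, 3]) {
        key <- paste(ix, iy, iz, sep = ",")
        buckets[[key]] <- c(buckets[[key]], k)
      }
  }
  list(cell = cell, lo = lo, buckets = buckets)
}

# distance from one point via the grid index: search expanding shells of cells
index_point_distance <- function(p, mesh, index) {
  v <- mesh$vertices; tr <- mesh$triangles
  ci <- floor((p - index$lo) / index$cell)
  best <- Inf
  for (ring in 0:64) {
    # cells in the shell at Chebyshev radius `ring`
    cand <- integer(0)
    rng <- (-ring):ring
    for (ix in rng) for (iy in rng) for (iz in rng) {
      if (max(abs(c(ix, iy, iz))) != ring) next
      key <- paste(ci[1] + ix, ci[2] + iy, ci[3] + iz, sep = ",")
      cand <- c(cand, index$buckets[[key]])
    }
    if (length(cand)) {
      cand <- unique(cand)
      for (k in cand) {
        best <- min(best, point_triangle_distance(rbind(p), v[tr[k, 1], ],
                                                  v[tr[k, 2], ], v[tr[k, 3], ]))
      }
    }
    # a hit in shell r guarantees no closer triangle beyond shell r+1
    if (is.finite(best) && best <= (ring) * index$cell) break
  }
  best
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}
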