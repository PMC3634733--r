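# Occlusal contact detection at maximum intercuspation: approach translation,
# epsilon-proximity contact triangles, edge-connected patch clustering.

#' Translate the antagonist into contact along an approach direction
#'
#' Finds the largest translation of `upper` along `direction` that leaves the
#' surfaces separated by at least `gap_tol`, by casting rays from each vertex
#' of one surface onto the other (vertex-versus-facet closure; edge-edge first
#' contact between two well-resolved surfaces is bounded by the facet size).
#'
#' @param lower,upper `surface_mesh` objects; `upper` moves, `lower` is fixed.
#' @param direction approach direction (need not be unit length); the default
#'   is straight down the tooth axis.
#' @param gap_tol residual gap retained at contact, mm.
#' @param max_travel bound on the search (mm).
#' @return the translation magnitude (mm); move `upper` by
#'   `offset * direction / |direction|`.
#' @export
approach_to_contact <- function(lower, upper, direction = c(0, -1, 0),
                                gap_tol = 0.01, max_travel = 100) {
  d <- as.numeric(direction)
  nd <- sqrt(sum(d^2))
  if (!is.finite(nd) || nd == 0) stop("approach_to_contact: zero direction")
  d <- d / nd
  t1 <- ray_hits(upper$vertices, d, lower)       # upper vertices onto lower
  t2 <- ray_hits(lower$vertices, -d, upper)      # lower vertices onto upper
  t_all <- c(t1, t2)
  t_all <- t_all[is.finite(t_all) & t_all >= -gap_tol & t_all <= max_travel]
  if (!length(t_all)) {
    stop("approach_to_contact: no contact achievable along the given direction")
  }
  max(min(t_all) - gap_tol, 0)
}

# smallest positive ray parameter from each origin along dir to the mesh
# (Moller-Trumbore, vectorized over triangles per origin)
ray_hits <- function(origins, dir, mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - p1
  e2 <- v[tr[, 3], , drop = FALSE] - p1
  # h = dir x e2 (constant dir)
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  out <- rep(Inf, nrow(origins))
  for (i in seq_len(nrow(origins))) {
    s <- sweep(p1, 2, origins[i, ], "-") * -1    # origin - p1
    u <- rowSums(s * h) / a
    q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
               s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
               s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
    vv <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / a
    t <- rowSums(e2 * q) / a
    hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & t > 0
    if (any(hit)) out[i] <- min(t[hit])
  }
  out
}

#' Detect occlusal contact patches
#'
#' A lower-surface triangle is in contact when its distance to the upper
#' surface (minimum over its three vertices and centroid of the exact
#' point-to-surface distance) is at most `epsilon`. Contact triangles are
#' clustered into edge-connected patches; each patch reports its area,
#' area-weighted outward unit normal and centroid.
#'
#' @param lower,upper `surface_mesh` objects positioned at maximum
#'   intercuspation (after [approach_to_contact()]).
#' @param epsilon proximity tolerance, mm (default 0.05, on the order of the
#'   55 micron resolution of typical intraoral/micro-CT surface models).
#' @param brute_force skip the spatial prefilter and compute every
#'   point-triangle distance (the oracle path for testing).
#' @return object of class `contact_result`: list with `patches` (list of
#'   patch records), `total_area`, `epsilon`, `n_triangles`.
#' @export
detect_contact_patches <- function(lower, upper, epsilon = 0.05,
                                   brute_force = FALSE) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("detect_contact_patches: epsilon must be > 0")
  }
  tr <- lower$triangles
  cen <- triangle_centroids(lower)
  q <- rbind(lower$vertices, cen)    # query points: vertices then centroids
  dmin <- query_distances(q, upper, cutoff = 3 * epsilon,
                          brute_force = brute_force)
  nv <- nrow(lower$vertices)
  tri_d <- pmin(dmin[tr[, 1]], dmin[tr[, 2]], dmin[tr[, 3]],
                dmin[nv + seq_len(nrow(tr))])
  contact <- which(tri_d <= epsilon)
  patches <- cluster_patches(lower, contact)
  patches <- order_patches(patches)
  structure(list(patches = patches,
                 total_area = sum(vapply(patches, `[[`, numeric(1), "area")),
                 epsilon = epsilon,
                 n_triangles = length(contact)),
            class = "contact_result")
}

# distance from query points to `mesh`, exact below `cutoff` (Inf-censored
# above); prefilter = expanded AABB per triangle
query_distances <- function(q, mesh, cutoff, brute_force = FALSE) {
  if (brute_force) return(point_surface_distance(q, mesh, index = NULL))
  v <- mesh$vertices; tr <- mesh$triangles
  d <- rep(Inf, nrow(q))
  tmin <- pmin(v[tr[, 1], ], v[tr[, 2], ], v[tr[, 3], ]) - cutoff
  tmax <- pmax(v[tr[, 1], ], v[tr[, 2], ], v[tr[, 3], ]) + cutoff
  qx <- q[, 1]; qy <- q[, 2]; qz <- q[, 3]
  for (k in seq_len(nrow(tr))) {
    sel <- which(qx >= tmin[k, 1] & qx <= tmax[k, 1] &
                 qy >= tmin[k, 2] & qy <= tmax[k, 2] &
                 qz >= tmin[k, 3] & qz <= tmax[k, 3])
    if (!length(sel)) next
    dk <- point_triangle_distance(q[sel, , drop = FALSE],
                                  v[tr[k, 1], ], v[tr[k, 2], ], v[tr[k, 3], ])
    d[sel] <- pmin(d[sel], dk)
  }
  d
}

# cluster contact triangles into edge-connected components
cluster_patches <- function(mesh, contact_ids) {
  if (!length(contact_ids)) return(list())
  tr <- mesh$triangles[contact_ids, , drop = FALSE]
  n <- length(contact_ids)
  # shared-edge adjacency among contact triangles
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  ek <- pmin(edges[, 1], edges[, 2]) * (nrow(mesh$vertices) + 1) +
    pmax(edges[, 1], edges[, 2])
  owner <- rep(seq_len(n), 3)
  ord <- order(ek)
  eo <- ek[ord]; oo <- owner[ord]
  same <- which(eo[-1] == eo[-length(eo)])
  a <- oo[same]; b <- oo[same + 1L]
  # union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (m in seq_along(a)) {
    ra <- find(a[m]); rb <- find(b[m])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_len(n), find, integer(1))
  areas <- triangle_areas(mesh)
  normals <- triangle_normals(mesh)
  cens <- triangle_centroids(mesh)
  lapply(split(seq_len(n), comp), function(ix) {
    ids <- contact_ids[ix]
    w <- areas[ids]
    nrm <- colSums(normals[ids, , drop = FALSE] * w)
    nn <- sqrt(sum(nrm^2))
    list(triangle_ids = ids,
         area = sum(w),
         normal = if (nn > 0) nrm / nn else c(0, 1, 0),
         centroid = colSums(cens[ids, , drop = FALSE] * w) / sum(w))
  })
}

# deterministic ordering: descending area, ties by centroid lexicographic
order_patches <- function(patches) {
  if (!length(patches)) return(list())
  area <- vapply(patches, `[[`, numeric(1), "area")
  cen <- t(vapply(patches, `[[`, numeric(3), "centroid"))
  ord <- order(-area, cen[, 1], cen[, 2], cen[, 3])
  unname(patches[ord])
}

#' Tabulate a contact result
#'
#' @param result a `contact_result`.
#' @return data.frame with one row per patch (area, unit normal, centroid,
#'   triangle count), sorted by descending area (ties by centroid); the total
#'   contact area is attached as attribute `total_area`.
#' @export
contact_summary <- function(result) {
  stopifnot(inherits(result, "contact_result"))
  ps <- result$patches
  df <- data.frame(
    patch = seq_along(ps),
    area_mm2 = vapply(ps, `[[`, numeric(1), "area"),
    nx = vapply(ps, function(p) p$normal[1], numeric(1)),
    ny = vapply(ps, function(p) p$normal[2], numeric(1)),
    nz = vapply(ps, function(p) p$normal[3], numeric(1)),
    cx = vapply(ps, function(p) p$centroid[1], numeric(1)),
    cy = vapply(ps, function(p) p$centroid[2], numeric(1)),
    cz = vapply(ps, function(p) p$centroid[3], numeric(1)),
    n_triangles = vapply(ps, function(p) length(p$triangle_ids), integer(1)))
  attr(df, "total_area") <- result$total_area
  df
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("contact result: %d patch(es), total area %.3f mm^2 (epsilon %g mm)\n",
              length(x$patches), x$total_area, x$epsilon))
  invisible(x)
}

#' Translate a surface mesh
#'
#' @param mesh a `surface_mesh`.
#' @param offset length-3 translation (mm).
#' @return the translated mesh.
#' @export
translate_surface <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), "+")
  mesh
}
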