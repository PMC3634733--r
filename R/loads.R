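# Load construction: consistent nodal loads on quadratic boundary faces and
# the facet-perpendicular, resultant-normalized occlusal load case.

# 6-node triangle shape functions at area coordinates (L1, L2, L3)
tri6_shape <- function(L1, L2, L3) {
  c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
    4 * L1 * L2, 4 * L2 * L3, 4 * L1 * L3)
}

#' Consistent nodal forces for a uniform traction on a quadratic face
#'
#' Integrates the quadratic shape functions against a constant traction over
#' a 6-node boundary triangle with a degree-2 (mid-edge) rule, exact for
#' straight-sided faces. For a straight face of area A under pressure p the
#' corner forces vanish and each midside node carries pA/3.
#'
#' @param face_coords 6 x 3 node coordinates (corners 1:3, midsides of edges
#'   1-2, 2-3, 1-3).
#' @param traction length-3 traction vector (N/mm^2).
#' @return 6 x 3 matrix of nodal force vectors (N); rows sum to
#'   `traction * area`.
#' @export
consistent_face_loads <- function(face_coords, traction) {
  stopifnot(is.matrix(face_coords), nrow(face_coords) == 6,
            ncol(face_coords) == 3, length(traction) == 3,
            all(is.finite(traction)))
  e1 <- face_coords[2, ] - face_coords[1, ]
  e2 <- face_coords[3, ] - face_coords[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  detJ <- sqrt(sum(cr^2))          # = 2 * area, constant on straight faces
  f <- matrix(0, 6, 3)
  for (g in seq_len(3)) {
    pt <- TRI_GAUSS3$points[g, ]
    N <- tri6_shape(1 - pt[1] - pt[2], pt[1], pt[2])
    f <- f + (TRI_GAUSS3$weights[g] * detJ) * outer(N, traction)
  }
  f
}

#' Build the occlusal load case from contact patches
#'
#' Each patch loads the tooth along the negative of its outward facet normal
#' (compressive tooth-to-tooth contact, perpendicular to the wear facet), with
#' magnitude proportional to patch area; a single global scale then sets the
#' magnitude of the resultant force vector to `total` (100 N by default).
#' Patch pressures are applied as consistent nodal loads on the occlusal
#' boundary faces of the volume mesh nearest to each patch.
#'
#' @param mesh a `volume_mesh` carrying `occlusal_faces` (see
#'   [generate_tooth()]).
#' @param contacts a `contact_result` with at least one patch.
#' @param crown the crown `surface_mesh` the patches live on.
#' @param total prescribed resultant magnitude (N).
#' @param tol patch-to-face matching distance (mm); defaults to 1.5 times the
#'   mesh edge length, bridging the analytic surface and the voxel boundary.
#' @return object of class `load_case`: `forces` (n x 3 N), `total_magnitude`,
#'   `resultant`, `patch_forces` (p x 3).
#' @export
build_load_case <- function(mesh, contacts, crown, total = 100, tol = NULL) {
  stopifnot(inherits(contacts, "contact_result"))
  if (!length(contacts$patches)) stop("build_load_case: no occlusal contacts")
  of <- mesh$occlusal_faces
  if (is.null(of) || !nrow(of$faces)) {
    stop("build_load_case: mesh has no occlusal boundary faces")
  }
  if (is.null(tol)) tol <- 1.5 * (if (!is.null(mesh$h)) mesh$h else 1)

  ps <- contacts$patches
  areas <- vapply(ps, `[[`, numeric(1), "area")
  normals <- t(vapply(ps, `[[`, numeric(3), "normal"))
  dirsum <- colSums(-normals * areas)
  if (sqrt(sum(dirsum^2)) < 1e-6 * sum(areas)) {
    stop("build_load_case: indeterminate normalization ",
         "(patch normals cancel to a near-zero resultant)")
  }
  scale <- total / sqrt(sum(dirsum^2))
  patch_forces <- -normals * areas * scale        # p x 3, sums to |.| = total

  # assign each occlusal boundary face to the nearest patch within tol
  fc <- of$centroid
  dmat <- matrix(Inf, nrow(fc), length(ps))
  v <- crown$vertices; tr <- crown$triangles
  for (ip in seq_along(ps)) {
    for (k in ps[[ip]]$triangle_ids) {
      dmat[, ip] <- pmin(dmat[, ip],
                         point_triangle_distance(fc, v[tr[k, 1], ],
                                                 v[tr[k, 2], ], v[tr[k, 3], ]))
    }
  }
  best <- max.col(-dmat, ties.method = "first")
  bestd <- dmat[cbind(seq_len(nrow(fc)), best)]
  assigned <- ifelse(bestd <= tol, best, NA_integer_)

  forces <- matrix(0, nrow(mesh$nodes), 3)
  for (ip in seq_along(ps)) {
    fsel <- which(assigned == ip)
    if (!length(fsel)) {
      stop("build_load_case: contact patch ", ip,
           " has no occlusal boundary faces within ", signif(tol, 3), " mm")
    }
    a_faces <- sum(of$area[fsel])
    traction <- patch_forces[ip, ] / a_faces
    for (fi in fsel) {
      ids <- of$faces[fi, ]
      fl <- consistent_face_loads(mesh$nodes[ids, , drop = FALSE], traction)
      forces[ids, ] <- forces[ids, ] + fl
    }
  }
  structure(list(forces = forces,
                 total_magnitude = total,
                 resultant = colSums(forces),
                 patch_forces = patch_forces),
            class = "load_case")
}

#' Uniform traction on a named face set (verification loads)
#'
#' Applies a constant traction over all boundary faces whose nodes all belong
#' to the named node set, as consistent nodal loads.
#'
#' @param mesh a `volume_mesh` with node sets.
#' @param set_name node-set name (e.g. "Z1" on a validation solid).
#' @param traction length-3 traction (N/mm^2), or `total_force` to divide a
#'   force evenly over the face area.
#' @param total_force optional length-3 total force (N) overriding `traction`.
#' @return a `load_case`.
#' @export
apply_face_traction <- function(mesh, set_name, traction = NULL,
                                total_force = NULL) {
  set <- mesh$node_sets[[set_name]]
  if (is.null(set)) stop("apply_face_traction: unknown node set ", set_name)
  bf <- boundary_faces(mesh)
  inset <- matrix(bf$faces %in% set, nrow(bf$faces), 6)
  sel <- which(rowSums(inset) == 6L)
  if (!length(sel)) stop("apply_face_traction: no boundary faces in set ", set_name)
  area <- sum(bf$area[sel])
  if (!is.null(total_force)) traction <- as.numeric(total_force) / area
  forces <- matrix(0, nrow(mesh$nodes), 3)
  for (fi in sel) {
    ids <- bf$faces[fi, ]
    forces[ids, ] <- forces[ids, ] +
      consistent_face_loads(mesh$nodes[ids, , drop = FALSE], traction)
  }
  structure(list(forces = forces,
                 total_magnitude = sqrt(sum(colSums(forces)^2)),
                 resultant = colSums(forces),
                 patch_forces = NULL),
            class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  r <- x$resultant
  cat(sprintf("load case: resultant (%.3f, %.3f, %.3f) N, |R| = %.6f N, %d loaded nodes\n",
              r[1], r[2], r[3], sqrt(sum(r^2)), sum(rowSums(x$forces != 0) > 0)))
  invisible(x)
}
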