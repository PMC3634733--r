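# VolumeMesh container: 10-node tetrahedra with per-element tissue regions
# and named node sets.

REGIONS <- c("ENAMEL", "DENTINE", "PULP", "PDL", "BONE")

#' Construct a 10-node tetrahedral volume mesh
#'
#' @param nodes n x 3 numeric matrix of coordinates (mm).
#' @param elements e x 10 integer matrix, local ordering as in the element
#'   library (corners 1:4, then midsides of edges 1-2, 2-3, 1-3, 1-4, 2-4, 3-4).
#' @param region character vector of length e; tissue tag per element.
#' @param node_sets named list of integer node-index vectors (e.g. MESIAL_CUT,
#'   DISTAL_CUT, OCCLUSAL_SURFACE, BUCCAL_CERVIX).
#' @param validate check Jacobians, midside placement and node-set indices.
#' @return an object of class `volume_mesh`.
#' @export
volume_mesh <- function(nodes, elements, region, node_sets = list(),
                        validate = TRUE) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elements <- as.matrix(elements); storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elements) == 10,
            length(region) == nrow(elements))
  region <- as.character(region)
  m <- structure(list(nodes = nodes, elements = elements, region = region,
                      node_sets = node_sets),
                 class = "volume_mesh")
  if (validate) validate_volume_mesh(m)
  m
}

validate_volume_mesh <- function(mesh, tol = 1e-8) {
  if (any(mesh$elements < 1L) || any(mesh$elements > nrow(mesh$nodes))) {
    stop("element connectivity references non-existent nodes")
  }
  v <- element_volumes(mesh)
  if (any(v <= 0)) {
    stop("non-positive Jacobian in element(s) ",
         paste(utils::head(which(v <= 0), 5), collapse = ", "))
  }
  # midside nodes must sit at edge midpoints (straight-sided elements)
  dev <- midside_deviation(mesh)
  if (dev > tol * max(1, max(abs(mesh$nodes)))) {
    stop("midside nodes deviate from edge midpoints (max ", signif(dev, 3), " mm)")
  }
  for (nm in names(mesh$node_sets)) {
    s <- mesh$node_sets[[nm]]
    if (length(s) && (any(s < 1L) || any(s > nrow(mesh$nodes)))) {
      stop("node set ", nm, " references non-existent nodes")
    }
  }
  invisible(TRUE)
}

# orientation-independent numeric key for corner triples (exact below 2^53)
face_sort_key <- function(tri, n_nodes) {
  a <- tri[, 1]; b <- tri[, 2]; c3 <- tri[, 3]
  hi <- pmax(a, b, c3); lo <- pmin(a, b, c3); mid <- a + b + c3 - hi - lo
  nn <- as.numeric(n_nodes) + 1
  (lo * nn + mid) * nn + hi
}

# max distance of any midside node from its edge midpoint
midside_deviation <- function(mesh) {
  el <- mesh$elements; nd <- mesh$nodes
  dev <- 0
  for (k in seq_len(6)) {
    a <- TET10_EDGES[k, 1]; b <- TET10_EDGES[k, 2]
    mid <- (nd[el[, a], , drop = FALSE] + nd[el[, b], , drop = FALSE]) / 2
    d <- mid - nd[el[, 4 + k], , drop = FALSE]
    dev <- max(dev, sqrt(max(rowSums(d * d), 0)))
  }
  dev
}

#' Signed volumes of all elements (corner geometry; straight-sided)
#'
#' @param mesh a `volume_mesh`.
#' @return numeric vector of element volumes in mm^3.
#' @export
element_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elements
  p1 <- nd[el[, 1], , drop = FALSE]
  a <- nd[el[, 2], , drop = FALSE] - p1
  b <- nd[el[, 3], , drop = FALSE] - p1
  c3 <- nd[el[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
   a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
   a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Per-region volumes
#'
#' @param mesh a `volume_mesh`.
#' @return named numeric vector, mm^3 per tissue tag.
#' @export
region_volumes <- function(mesh) {
  v <- element_volumes(mesh)
  vapply(split(v, mesh$region), sum, numeric(1))
}

#' Boundary faces of a volume mesh (or an element subset)
#'
#' A face shared by two elements is interior; faces owned by exactly one
#' element form the boundary. Returned faces are outward-oriented 6-node
#' triangles (3 corners + 3 midsides). With `elements` given, the boundary of
#' that sub-mesh is returned (e.g. the surface of one tissue), with `element`
#' indices into the full mesh.
#'
#' @param mesh a `volume_mesh`.
#' @param elements optional integer vector of element indices to restrict to.
#' @return list with `faces` (f x 6 node indices), `element` (owning element
#'   index), `centroid` (f x 3, corner centroid), `normal` (f x 3 outward unit
#'   normals), `area` (mm^2, corner triangle area).
#' @export
boundary_faces <- function(mesh, elements = NULL) {
  el <- mesh$elements
  eix <- if (is.null(elements)) seq_len(nrow(el)) else as.integer(elements)
  el <- el[eix, , drop = FALSE]
  ne <- nrow(el)
  # 4 faces per element, as global node triples
  f_all <- matrix(0L, 4 * ne, 6)
  owner <- rep(eix, each = 4)
  for (f in seq_len(4)) {
    f_all[seq(f, by = 4, length.out = ne), ] <- el[, TET10_FACES[f, ], drop = FALSE]
  }
  key <- face_sort_key(f_all[, 1:3, drop = FALSE], nrow(mesh$nodes))
  keep <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  faces <- f_all[keep, , drop = FALSE]
  owner <- owner[keep]
  nd <- mesh$nodes
  p1 <- nd[faces[, 1], , drop = FALSE]
  e1 <- nd[faces[, 2], , drop = FALSE] - p1
  e2 <- nd[faces[, 3], , drop = FALSE] - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(nrm * nrm))
  list(faces = faces,
       element = owner,
       centroid = (p1 + nd[faces[, 2], , drop = FALSE] +
                     nd[faces[, 3], , drop = FALSE]) / 3,
       normal = nrm / area2,
       area = area2 / 2)
}

#' Promote a 4-node tetrahedral mesh to 10-node (quadratic) elements
#'
#' Inserts one midside node per unique edge, shared across all elements that
#' use the edge; element geometry (straight edges) is unchanged.
#'
#' @param nodes n x 3 corner coordinates.
#' @param elements e x 4 corner connectivity.
#' @param region optional per-element tissue tags (defaults to "DENTINE").
#' @param node_sets optional node sets (corner indices are preserved).
#' @return a `volume_mesh` with 10-node elements.
#' @export
linear_to_quadratic <- function(nodes, elements, region = NULL,
                                node_sets = list()) {
  nodes <- as.matrix(nodes); elements <- as.matrix(elements)
  stopifnot(ncol(elements) == 4)
  if (anyDuplicated(apply(elements, 1, function(r) paste(sort(r), collapse = "_")))) {
    stop("duplicate elements in tet4 mesh")
  }
  if (any(apply(elements, 1, anyDuplicated) > 0)) {
    stop("degenerate element: repeated corner node")
  }
  ne <- nrow(elements)
  # unique edges across the mesh
  ea <- elements[, TET10_EDGES[, 1], drop = FALSE]  # ne x 6
  eb <- elements[, TET10_EDGES[, 2], drop = FALSE]
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- lo * (nrow(nodes) + 1) + hi  # unique numeric key
  ukey <- sort(unique(as.vector(key)))
  mid_id <- match(key, ukey)          # ne x 6 index into new midside nodes
  ulo <- ukey %/% (nrow(nodes) + 1); uhi <- ukey %% (nrow(nodes) + 1)
  mids <- (nodes[ulo, , drop = FALSE] + nodes[uhi, , drop = FALSE]) / 2
  el10 <- cbind(elements, matrix(nrow(nodes) + as.vector(mid_id), ne, 6))
  if (is.null(region)) region <- rep("DENTINE", ne)
  volume_mesh(rbind(nodes, mids), el10, region, node_sets)
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat("10-node tetrahedral mesh:", nrow(x$nodes), "nodes,",
      nrow(x$elements), "elements\n")
  cat("  regions:", paste(sprintf("%s=%d", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  if (length(x$node_sets)) {
    cat("  node sets:", paste(sprintf("%s(%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "), "\n")
  }
  invisible(x)
}
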