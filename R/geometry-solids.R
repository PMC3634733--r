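# Canonical verification solids for the elastic solver (bar, cantilever, cube).

#' Generate a single-region box mesh for solver verification
#'
#' Structured subdivision of an axis-aligned box `[0, dims]` into 10-node
#' tetrahedra, with the six face node sets named X0, X1, Y0, Y1, Z0, Z1
#' (min/max faces per axis). `kind` selects conventional default dimensions
#' only; the mesh is a box either way.
#'
#' @param kind one of "bar", "cantilever", "cube".
#' @param dims length-3 positive dimensions (mm); defaults depend on `kind`.
#' @param mesh_size target edge length (mm); must not exceed `min(dims)`.
#' @param region tissue tag for all elements (default DENTINE).
#' @return a `volume_mesh`.
#' @export
generate_validation_solid <- function(kind = c("bar", "cantilever", "cube"),
                                      dims = NULL, mesh_size = 1,
                                      region = "DENTINE") {
  kind <- match.arg(kind)
  if (is.null(dims)) {
    dims <- switch(kind,
                   bar = c(10, 10, 40),
                   cantilever = c(4, 4, 40),
                   cube = c(1, 1, 1))
  }
  if (length(dims) != 3 || any(!is.finite(dims)) || any(dims <= 0)) {
    stop("generate_validation_solid: dims must be three positive lengths")
  }
  if (mesh_size > min(dims)) {
    stop("generate_validation_solid: mesh_size exceeds the smallest dimension")
  }
  grid <- box_tet4_grid(c(0, 0, 0), dims, mesh_size)
  mesh <- linear_to_quadratic(grid$nodes, grid$elements,
                              region = rep(region, nrow(grid$elements)))
  mesh$h <- mesh_size
  tol <- 1e-9 * max(dims)
  nd <- mesh$nodes
  mesh$node_sets <- list(
    X0 = which(abs(nd[, 1]) < tol),        X1 = which(abs(nd[, 1] - dims[1]) < tol),
    Y0 = which(abs(nd[, 2]) < tol),        Y1 = which(abs(nd[, 2] - dims[2]) < tol),
    Z0 = which(abs(nd[, 3]) < tol),        Z1 = which(abs(nd[, 3] - dims[3]) < tol))
  validate_volume_mesh(mesh)
  mesh
}
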