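# 10-node tetrahedral element: shape functions, quadrature, stiffness.
#
# Local node ordering (VTK_QUADRATIC_TETRA / Abaqus C3D10):
#   1..4   corner nodes
#   5  midside of edge (1,2)
#   6  midside of edge (2,3)
#   7  midside of edge (1,3)
#   8  midside of edge (1,4)
#   9  midside of edge (2,4)
#   10 midside of edge (3,4)
# Natural coordinates (xi, eta, zeta) with barycentric
#   L1 = 1 - xi - eta - zeta, L2 = xi, L3 = eta, L4 = zeta.

# edges as (corner, corner) for midside nodes 5..10, in local ordering
TET10_EDGES <- matrix(c(
  1L, 2L,
  2L, 3L,
  1L, 3L,
  1L, 4L,
  2L, 4L,
  3L, 4L), ncol = 2, byrow = TRUE)

# faces of a tetrahedron (corner triples, outward when tet is positively
# oriented), with their midside nodes appended -> 6-node boundary triangles
TET10_FACES <- matrix(c(
  1L, 3L, 2L, 7L, 6L, 5L,
  1L, 2L, 4L, 5L, 9L, 8L,
  2L, 3L, 4L, 6L, 10L, 9L,
  1L, 4L, 3L, 8L, 10L, 7L), ncol = 6, byrow = TRUE)

#' Shape functions of the 10-node tetrahedron
#'
#' @param xi,eta,zeta natural coordinates inside the reference tetrahedron.
#' @return numeric vector of length 10.
#' @keywords internal
tet10_shape <- function(xi, eta, zeta) {
  L1 <- 1 - xi - eta - zeta; L2 <- xi; L3 <- eta; L4 <- zeta
  c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1), L4 * (2 * L4 - 1),
    4 * L1 * L2, 4 * L2 * L3, 4 * L1 * L3,
    4 * L1 * L4, 4 * L2 * L4, 4 * L3 * L4)
}

#' Shape-function derivatives w.r.t. natural coordinates
#'
#' @inheritParams tet10_shape
#' @return 10 x 3 matrix, column j = dN/d(xi_j).
#' @keywords internal
tet10_dshape <- function(xi, eta, zeta) {
  L1 <- 1 - xi - eta - zeta; L2 <- xi; L3 <- eta; L4 <- zeta
  # dLi/d(xi,eta,zeta): L1 -> (-1,-1,-1), L2 -> (1,0,0), L3 -> (0,1,0), L4 -> (0,0,1)
  d <- matrix(0, 10, 3)
  g1 <- 4 * L1 - 1; g2 <- 4 * L2 - 1; g3 <- 4 * L3 - 1; g4 <- 4 * L4 - 1
  d[1, ] <- -g1
  d[2, ] <- c(g2, 0, 0)
  d[3, ] <- c(0, g3, 0)
  d[4, ] <- c(0, 0, g4)
  d[5, ] <- c(4 * (L1 - L2), -4 * L2, -4 * L2)
  d[6, ] <- c(4 * L3, 4 * L2, 0)
  d[7, ] <- c(-4 * L3, 4 * (L1 - L3), -4 * L3)
  d[8, ] <- c(-4 * L4, -4 * L4, 4 * (L1 - L4))
  d[9, ] <- c(4 * L4, 0, 4 * L2)
  d[10, ] <- c(0, 4 * L4, 4 * L3)
  d
}

# 4-point degree-2 Gauss rule on the reference tetrahedron (exact for the
# stiffness integrand of straight-sided quadratic tets). Barycentric
# (a,b,b,b) permutations; weights sum to the reference volume 1/6.
TET_GAUSS4 <- local({
  a <- 0.585410196624968515
  b <- 0.138196601125010515
  bary <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
  list(points = bary[, 2:4, drop = FALSE],  # (xi,eta,zeta) = (L2,L3,L4)
       weights = rep(1 / 24, 4),
       bary = bary)
})

# degree-2 rule on the reference triangle (midpoints of edges), exact for
# quadratic integrands; weights sum to reference area 1/2
TRI_GAUSS3 <- list(
  points = rbind(c(0.5, 0), c(0.5, 0.5), c(0, 0.5)),
  weights = rep(1 / 6, 3))

#' Isotropic elasticity matrix (engineering strain convention)
#'
#' @param E elastic modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 6 x 6 matrix mapping (exx, eyy, ezz, gxy, gyz, gxz) to
#'   (sxx, syy, szz, sxy, syz, sxz).
#' @keywords internal
elastic_matrix <- function(E, nu) {
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- c1 * nu
  diag(D)[1:3] <- c1 * (1 - nu)
  diag(D)[4:6] <- c1 * (1 - 2 * nu) / 2
  D
}

#' Element stiffness matrix of a 10-node tetrahedron
#'
#' Integrates \eqn{B^T D B} with the 4-point degree-2 Gauss rule, exact for
#' straight-sided elements.
#'
#' @param coords 10 x 3 matrix of node coordinates (mm), local ordering as
#'   documented in this file.
#' @param material a [material()] (E in GPa; converted to MPa internally).
#' @return symmetric 30 x 30 stiffness matrix (N/mm); DOFs ordered
#'   (x1, y1, z1, x2, ...).
#' @export
element_stiffness <- function(coords, material) {
  stopifnot(is.matrix(coords), nrow(coords) == 10, ncol(coords) == 3)
  D <- elastic_matrix(material$E * 1000, material$nu)  # GPa -> MPa
  ke <- matrix(0, 30, 30)
  for (g in seq_len(4)) {
    p <- TET_GAUSS4$points[g, ]
    dN <- tet10_dshape(p[1], p[2], p[3])          # 10 x 3
    J <- crossprod(dN, coords)                    # 3 x 3, dx/dxi
    detJ <- det(J)
    if (!is.finite(detJ) || detJ <= 0) {
      stop("inverted element: non-positive Jacobian at quadrature point ", g)
    }
    dNx <- dN %*% t(solve(J))                     # 10 x 3 derivatives wrt x,y,z
    B <- tet10_bmatrix(dNx)
    ke <- ke + (TET_GAUSS4$weights[g] * detJ) * crossprod(B, D %*% B)
  }
  (ke + t(ke)) / 2
}

# strain-displacement matrix from cartesian shape gradients (10 x 3)
tet10_bmatrix <- function(dNx) {
  B <- matrix(0, 6, 30)
  ix <- 3 * (0:9) + 1
  B[1, ix]     <- dNx[, 1]
  B[2, ix + 1] <- dNx[, 2]
  B[3, ix + 2] <- dNx[, 3]
  B[4, ix]     <- dNx[, 2]; B[4, ix + 1] <- dNx[, 1]
  B[5, ix + 1] <- dNx[, 3]; B[5, ix + 2] <- dNx[, 2]
  B[6, ix]     <- dNx[, 3]; B[6, ix + 2] <- dNx[, 1]
  B
}

# volume of a straight-sided tet from its 4 corners
tet_volume <- function(p1, p2, p3, p4) {
  det(cbind(p2 - p1, p3 - p1, p4 - p1)) / 6
}
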