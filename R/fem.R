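# Global assembly, boundary constraints and the sparse linear-elastic solve.

#' Constraint set: fixed (zero) displacement axes per node
#'
#' @param node integer node indices.
#' @param axis axis per entry: 1 = x, 2 = y, 3 = z (recycled against `node`).
#' @return object of class `constraint_set` (data.frame node/axis).
#' @export
constraint_set <- function(node = integer(0), axis = integer(0)) {
  df <- data.frame(node = as.integer(node), axis = as.integer(axis))
  if (nrow(df) && (any(df$axis < 1) || any(df$axis > 3))) {
    stop("constraint_set: axis must be 1, 2 or 3")
  }
  df <- unique(df[order(df$node, df$axis), , drop = FALSE])
  rownames(df) <- NULL
  class(df) <- c("constraint_set", "data.frame")
  df
}

#' Fix axes of every node in a set
#'
#' @param constraints an existing `constraint_set` (or NULL).
#' @param nodes integer node indices.
#' @param axes axes to fix for each of these nodes (any of 1:3).
#' @return the extended `constraint_set`.
#' @export
fix_nodes <- function(constraints = NULL, nodes, axes) {
  add <- expand.grid(node = as.integer(nodes), axis = as.integer(axes))
  if (is.null(constraints)) return(constraint_set(add$node, add$axis))
  constraint_set(c(constraints$node, add$node), c(constraints$axis, add$axis))
}

#' Default tooth-model constraints
#'
#' The mesial cut face of the bone block is restrained in x translation only
#' (linguo-buccally); the distal cut face is restrained in y and z
#' (supero-inferiorly and mesio-distally). Together these remove all six
#' rigid-body modes of the block.
#'
#' @param mesh a `volume_mesh` with MESIAL_CUT and DISTAL_CUT node sets.
#' @return a `constraint_set`.
#' @export
default_tooth_constraints <- function(mesh) {
  ns <- mesh$node_sets
  if (is.null(ns$MESIAL_CUT) || is.null(ns$DISTAL_CUT)) {
    stop("default_tooth_constraints: mesh lacks MESIAL_CUT/DISTAL_CUT node sets")
  }
  fix_nodes(fix_nodes(NULL, ns$MESIAL_CUT, 1L), ns$DISTAL_CUT, c(2L, 3L))
}

#' Assemble the global stiffness matrix
#'
#' @param mesh a `volume_mesh`.
#' @param materials named list of [material()] covering every region present.
#' @return sparse symmetric stiffness matrix (dgCMatrix), dimension
#'   `3 * n_nodes`; DOFs interleaved (x1, y1, z1, x2, ...).
#' @export
assemble_stiffness <- function(mesh, materials) {
  regs <- unique(mesh$region)
  missing <- setdiff(regs, names(materials))
  if (length(missing)) {
    stop("assemble_stiffness: no material for region(s) ",
         paste(missing, collapse = ", "))
  }
  geo <- element_geometry(mesh)
  lam_mu <- lame_parameters(mesh, materials)
  lam <- lam_mu$lambda; mu <- lam_mu$mu
  dN <- lapply(seq_len(4), function(g) {
    p <- TET_GAUSS4$points[g, ]; tet10_dshape(p[1], p[2], p[3])
  })
  w <- TET_GAUSS4$weights
  ne <- nrow(mesh$elements)
  ke_all <- matrix(0, ne, 900)
  # K^{ab}_{ij} = lam Ga_i Gb_j + mu Ga_j Gb_i + delta_ij mu (Ga . Gb),
  # vectorized over elements (isotropic Hooke in Lame form)
  for (g in seq_len(4)) {
    wdet <- w[g] * geo$detJ
    G <- shape_gradients(dN[[g]], geo)      # list of 10 (ne x 3) matrices
    wl <- wdet * lam; wm <- wdet * mu
    for (a in seq_len(10)) {
      Ga <- G[[a]]
      for (b in a:10) {
        Gb <- G[[b]]
        dots <- wm * (Ga[, 1] * Gb[, 1] + Ga[, 2] * Gb[, 2] + Ga[, 3] * Gb[, 3])
        for (i in 1:3) for (j in 1:3) {
          v <- wl * Ga[, i] * Gb[, j] + wm * Ga[, j] * Gb[, i]
          if (i == j) v <- v + dots
          p <- 3L * (a - 1L) + i; q <- 3L * (b - 1L) + j
          ke_all[, (q - 1L) * 30L + p] <- ke_all[, (q - 1L) * 30L + p] + v
          if (b > a) {
            # symmetry: K^{ba}_{ji} = K^{ab}_{ij}
            p2 <- 3L * (b - 1L) + j; q2 <- 3L * (a - 1L) + i
            ke_all[, (q2 - 1L) * 30L + p2] <- ke_all[, (q2 - 1L) * 30L + p2] + v
          }
        }
      }
    }
  }
  el <- mesh$elements
  dofmat <- matrix(0L, ne, 30)
  for (a in seq_len(10)) for (i in 1:3) {
    dofmat[, 3L * (a - 1L) + i] <- 3L * (el[, a] - 1L) + i
  }
  jrep <- rep(seq_len(30), each = 30)
  irep <- rep(seq_len(30), times = 30)
  Matrix::sparseMatrix(i = as.vector(dofmat[, irep]),
                       j = as.vector(dofmat[, jrep]),
                       x = as.vector(ke_all),
                       dims = c(3L, 3L) * nrow(mesh$nodes))
}

# per-element affine geometry of straight-sided tets: Jacobian determinant
# and the rows of t(J^-1) (gradients of the natural coordinates)
element_geometry <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elements
  p1 <- nd[el[, 1], , drop = FALSE]
  a <- nd[el[, 2], , drop = FALSE] - p1
  b <- nd[el[, 3], , drop = FALSE] - p1
  c3 <- nd[el[, 4], , drop = FALSE] - p1
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cr(b, c3)
  detJ <- rowSums(a * bxc)
  bad <- which(!is.finite(detJ) | detJ <= 0)
  if (length(bad)) {
    stop("inverted element(s): non-positive Jacobian in element ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  list(detJ = detJ,
       g1 = bxc / detJ, g2 = cr(c3, a) / detJ, g3 = cr(a, b) / detJ)
}

# cartesian shape-function gradients for all elements at one gauss point:
# G[[a]][e, j] = dN_a/dx_j in element e
shape_gradients <- function(dNg, geo) {
  lapply(seq_len(10), function(a) {
    dNg[a, 1] * geo$g1 + dNg[a, 2] * geo$g2 + dNg[a, 3] * geo$g3
  })
}

# Lame parameters per element in MPa (E stored in GPa)
lame_parameters <- function(mesh, materials) {
  E <- vapply(materials, `[[`, numeric(1), "E")[mesh$region] * 1000
  nu <- vapply(materials, `[[`, numeric(1), "nu")[mesh$region]
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

# rigid-body mode basis (3n x 6) for given node coordinates
rigid_modes <- function(nodes) {
  n <- nrow(nodes)
  x <- nodes[, 1]; y <- nodes[, 2]; z <- nodes[, 3]
  zero <- numeric(n)
  tx <- cbind(1, 0, 0); ty <- cbind(0, 1, 0); tz <- cbind(0, 0, 1)
  interleave <- function(a, b, c3) as.vector(rbind(a, b, c3))
  cbind(interleave(rep(1, n), zero, zero),
        interleave(zero, rep(1, n), zero),
        interleave(zero, zero, rep(1, n)),
        interleave(zero, -z, y),
        interleave(z, zero, -x),
        interleave(-y, x, zero))
}

#' Reduce a system by eliminating constrained DOFs
#'
#' Verifies first that the constraints remove all six rigid-body modes (a
#' rigid motion with zero displacement at every constrained DOF would leave
#' the reduced system singular), then removes the fixed rows/columns.
#'
#' @param K global stiffness (sparse, 3n x 3n).
#' @param f global load vector (length 3n).
#' @param constraints a `constraint_set`.
#' @param nodes node coordinates (needed for the rigid-mode check).
#' @return list: `Kff`, `ff`, `free` (free DOF indices), `fixed`.
#' @export
apply_constraints <- function(K, f, constraints, nodes) {
  n_dof <- nrow(K)
  fixed <- sort(unique(3L * (constraints$node - 1L) + constraints$axis))
  if (length(fixed) && (min(fixed) < 1 || max(fixed) > n_dof)) {
    stop("apply_constraints: constraint references non-existent DOF")
  }
  R <- rigid_modes(nodes)
  Rc <- R[fixed, , drop = FALSE]
  sv <- svd(crossprod(Rc))$d
  scale_r <- max(sv, 1)
  if (length(fixed) == 0 || sum(sv > 1e-10 * scale_r) < 6L) {
    # identify a rigid combination unseen by the constraints
    null_ix <- which(sv <= 1e-10 * scale_r)
    mode_names <- c("x-translation", "y-translation", "z-translation",
                    "rotation about x", "rotation about y", "rotation about z")
    v <- if (length(fixed)) svd(crossprod(Rc))$u[, utils::tail(null_ix, 1)] else c(1, 0, 0, 0, 0, 0)
    dom <- mode_names[which.max(abs(v))]
    stop("apply_constraints: insufficient constraints; free rigid-body mode ",
         "detected (dominant component: ", dom, ")")
  }
  free <- setdiff(seq_len(n_dof), fixed)
  list(Kff = K[free, free, drop = FALSE], ff = f[free],
       free = free, fixed = fixed)
}

#' Solve the linear-elastic problem
#'
#' Assembles, reduces and solves `K u = f` with a sparse Cholesky
#' factorization, returning nodal displacements, reactions at constrained
#' DOFs, strain energy and the global equilibrium residual.
#'
#' @param mesh a `volume_mesh`.
#' @param materials named list of [material()] per region.
#' @param load_case a `load_case`.
#' @param constraints a `constraint_set`.
#' @return object of class `displacement_field`: `u` (n x 3, mm),
#'   `reactions` (n x 3, N, nonzero only on constrained DOFs), `energy`
#'   (N mm), `equilibrium_residual` (relative), `K` (the assembled matrix,
#'   kept for reuse), `free`, `fixed`.
#' @export
solve_elastic <- function(mesh, materials, load_case, constraints) {
  stopifnot(inherits(load_case, "load_case"))
  K <- assemble_stiffness(mesh, materials)
  f <- as.vector(t(load_case$forces))
  red <- apply_constraints(K, f, constraints, mesh$nodes)
  Kff <- Matrix::forceSymmetric(red$Kff)
  uf <- tryCatch({
    ch <- Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
    as.vector(Matrix::solve(ch, red$ff))
  }, error = function(e) {
    stop("solve_elastic: sparse solve failed (", conditionMessage(e),
         "); the constrained system may be singular")
  })
  u <- numeric(length(f))
  u[red$free] <- uf
  r <- as.vector(K %*% u) - f
  reactions <- numeric(length(f))
  reactions[red$fixed] <- r[red$fixed]
  applied <- colSums(load_case$forces)
  res_vec <- applied + colSums(matrix(reactions, ncol = 3, byrow = TRUE))
  denom <- sqrt(sum(applied^2))
  structure(list(u = matrix(u, ncol = 3, byrow = TRUE),
                 reactions = matrix(reactions, ncol = 3, byrow = TRUE),
                 energy = 0.5 * sum(u * f),
                 equilibrium_residual = if (denom > 0) sqrt(sum(res_vec^2)) / denom else 0,
                 free = red$free, fixed = red$fixed),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement field: %d nodes, max |u| = %.4g mm, energy %.4g N mm, equilibrium residual %.2e\n",
              nrow(x$u), sqrt(max(rowSums(x$u^2))), x$energy,
              x$equilibrium_residual))
  invisible(x)
}
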