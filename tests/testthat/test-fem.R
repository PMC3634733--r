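# Assembly, constraints, and the elastic solve against closed-form solutions.

test_that("global assembly of a single element equals the element matrix", {
  n1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- linear_to_quadratic(n1, matrix(1:4, 1), region = "DENTINE")
  mats <- list(DENTINE = material(18.6, 0.31))
  K <- as.matrix(assemble_stiffness(m, mats))
  ke <- element_stiffness(m$nodes[m$elements[1, ], ], mats$DENTINE)
  # global DOFs follow global node ids; permute to the element-local order
  ids <- m$elements[1, ]
  dofs <- as.vector(rbind(3L * ids - 2L, 3L * ids - 1L, 3L * ids))
  expect_equal(K[dofs, dofs], unname(ke), tolerance = 1e-12)
  expect_error(assemble_stiffness(m, list(BONE = material(1, 0.3))),
               "no material for region")
})

test_that("assembled stiffness is symmetric with block rigid modes", {
  cube <- generate_validation_solid("cube", c(1, 1, 1), mesh_size = 0.5)
  mats <- list(DENTINE = material(10, 0.25))
  K <- assemble_stiffness(cube, mats)
  asym <- max(abs(K - Matrix::t(K))) / max(abs(K))
  expect_lt(asym, 1e-12)
  # two disconnected elements: 12 rigid modes (dense eigensolve, tiny mesh)
  n2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
              c(5, 5, 5), c(6, 5, 5), c(5, 6, 5), c(5, 5, 6))
  m2 <- linear_to_quadratic(n2, rbind(1:4, 5:8), region = c("DENTINE", "DENTINE"))
  K2 <- as.matrix(assemble_stiffness(m2, mats))
  ev <- eigen((K2 + t(K2)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < 1e-8 * max(ev)), 12L)
})

test_that("constraint reduction detects free rigid-body modes", {
  bar <- generate_validation_solid("bar", c(2, 2, 4), mesh_size = 1)
  mats <- list(DENTINE = material(10, 0.3))
  K <- assemble_stiffness(bar, mats)
  f <- numeric(nrow(K))
  expect_error(apply_constraints(K, f, constraint_set(), bar$nodes),
               "insufficient constraints")
  # fixing one axis of one node still leaves rigid modes
  weak <- constraint_set(1L, 1L)
  expect_error(apply_constraints(K, f, weak, bar$nodes),
               "insufficient constraints")
  # a fully clamped face is sufficient
  cons <- fix_nodes(NULL, bar$node_sets$Z0, 1:3)
  red <- apply_constraints(K, f, cons, bar$nodes)
  expect_identical(length(red$free) + length(red$fixed), nrow(K))
})

test_that("axial bar matches sigma = F/A and elongation FL/EA", {
  fx <- solved_axial_bar()
  A <- 100; L <- 40; E <- 18600
  w_end <- mean(fx$solution$u[fx$mesh$node_sets$Z1, 3])
  expect_equal(w_end, 100 * L / (E * A), tolerance = 0.005)
  # uniform axial stress 1 MPa
  expect_equal(unname(range(fx$stress$sigma[, 3])), c(1, 1), tolerance = 0.01)
  # zero displacement on constrained axes, equilibrium, positive energy
  expect_true(all(fx$solution$u[fx$mesh$node_sets$Z0, 3] == 0))
  expect_lt(fx$solution$equilibrium_residual, 1e-8)
  expect_gt(fx$solution$energy, 0)
})

test_that("zero load gives zero displacement; doubling load doubles it", {
  fx <- solved_axial_bar()
  lc0 <- fx$load_case; lc0$forces <- lc0$forces * 0
  sol0 <- solve_elastic(fx$mesh, fx$materials, lc0, fx$constraints)
  expect_identical(max(abs(sol0$u)), 0)
  lc2 <- fx$load_case; lc2$forces <- lc2$forces * 2
  sol2 <- solve_elastic(fx$mesh, fx$materials, lc2, fx$constraints)
  expect_equal(sol2$u, 2 * fx$solution$u, tolerance = 1e-12)
})

test_that("cantilever tip deflection approaches slender-beam theory", {
  mats <- list(DENTINE = material(18.6, 0.31))
  E <- 18600; nu <- 0.31
  P <- 10; L <- 40; b <- 4
  I <- b^4 / 12
  euler <- P * L^3 / (3 * E * I)
  defl <- function(h) {
    m <- generate_validation_solid("cantilever", c(b, b, L), mesh_size = h)
    lc <- apply_face_traction(m, "Z1", total_force = c(P, 0, 0))
    sol <- solve_elastic(m, mats, lc, fix_nodes(NULL, m$node_sets$Z0, 1:3))
    mean(sol$u[m$node_sets$Z1, 1])
  }
  d2 <- defl(2); d1 <- defl(1)
  expect_equal(d1, euler, tolerance = 0.05)
  # convergence: the finer mesh is closer to the converged 3D answer, which
  # for this slenderness sits within a few percent of Euler theory
  expect_lt(abs(d1 - euler), abs(d2 - euler))
})

test_that("dense and sparse solution paths agree on a small system", {
  m <- generate_validation_solid("bar", c(2, 2, 6), mesh_size = 2)
  expect_lte(3 * nrow(m$nodes), 400)
  mats <- list(DENTINE = material(5, 0.2))
  lc <- apply_face_traction(m, "Z1", total_force = c(1, 2, 5))
  cons <- fix_nodes(NULL, m$node_sets$Z0, 1:3)
  sol <- solve_elastic(m, mats, lc, cons)
  K <- assemble_stiffness(m, mats)
  f <- as.vector(t(lc$forces))
  red <- apply_constraints(K, f, cons, m$nodes)
  u_dense <- solve(as.matrix(red$Kff), red$ff)
  u_sparse <- as.vector(t(sol$u))[red$free]
  expect_equal(u_sparse, u_dense, tolerance = 1e-9)
})

test_that("tooth constraint pattern is well-posed and balances the load", {
  st <- tooth_state(0.24)
  expect_lt(st$solution$equilibrium_residual, 1e-8)
  # restrained axes: x on the mesial cut, y and z on the distal cut
  m <- st$model$volume
  expect_true(all(st$solution$u[m$node_sets$MESIAL_CUT, 1] == 0))
  expect_true(all(st$solution$u[m$node_sets$DISTAL_CUT, 2] == 0))
  expect_true(all(st$solution$u[m$node_sets$DISTAL_CUT, 3] == 0))
  expect_gt(st$solution$energy, 0)
})
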