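# Shared fixtures and independent oracles for the test suite.
# Expensive solves are memoised so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- fn()
  .fixture_cache[[name]]
}

# flat square grid surface in the xz-plane at height y, n x n quads
square_grid_surface <- function(n = 8, side = 1, y = 0, flip = FALSE,
                                origin = c(0, 0)) {
  xs <- seq(0, side, length.out = n + 1) + origin[1]
  zs <- seq(0, side, length.out = n + 1) + origin[2]
  g <- expand.grid(x = xs, z = zs)
  verts <- cbind(g$x, y, g$z)
  vid <- function(i, j) (j - 1L) * (n + 1L) + i
  tris <- list()
  for (j in seq_len(n)) {
    i <- seq_len(n)
    a <- vid(i, j); b <- vid(i + 1L, j); c2 <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    tris[[j]] <- rbind(cbind(a, c2, b), cbind(a, d, c2))  # normals +y
  }
  tri <- do.call(rbind, tris)
  if (flip) tri <- tri[, c(1, 3, 2)]
  surface_mesh(verts, tri)
}

# UV-sphere surface (<= ~500 triangles for the brute-force contact oracle)
uv_sphere_surface <- function(radius = 1, center = c(0, 0, 0),
                              n_theta = 24, n_phi = 10) {
  phi <- seq(0, pi, length.out = n_phi + 1)[-c(1, n_phi + 1)]
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ring <- as.matrix(expand.grid(p = phi, t = th))
  pts <- cbind(sin(ring[, 1]) * cos(ring[, 2]),
               cos(ring[, 1]),
               sin(ring[, 1]) * sin(ring[, 2]))
  top <- c(0, 1, 0); bot <- c(0, -1, 0)
  verts <- sweep(radius * rbind(top, bot, pts), 2, center, "+")
  np <- length(phi)
  vid <- function(ip, it) 2L + ((it - 1L) %% n_theta) * np + ip
  it <- seq_len(n_theta)
  tris <- list(cbind(1L, vid(1L, it + 1L), vid(1L, it)),       # top cap
               cbind(2L, vid(np, it), vid(np, it + 1L)))       # bottom cap
  for (ip in seq_len(np - 1)) {
    a <- vid(ip, it); b <- vid(ip + 1L, it)
    a2 <- vid(ip, it + 1L); b2 <- vid(ip + 1L, it + 1L)
    tris[[ip + 2]] <- rbind(cbind(a, a2, b2), cbind(a, b2, b))
  }
  surface_mesh(verts, do.call(rbind, tris))
}

# independent element-stiffness oracle: Duffy (collapsed-cube) transform of
# the reference tetrahedron with a tensor Gauss-Legendre rule, exact for the
# polynomial stiffness integrand of straight-sided quadratic tets
element_stiffness_oracle <- function(coords, material, n_gl = 6) {
  D <- toothfem:::elastic_matrix(material$E * 1000, material$nu)
  gl <- statmod_gauss_legendre01(n_gl)
  ke <- matrix(0, 30, 30)
  for (iu in seq_len(n_gl)) for (iv in seq_len(n_gl)) for (iw in seq_len(n_gl)) {
    u <- gl$nodes[iu]; v <- gl$nodes[iv]; w <- gl$nodes[iw]
    xi <- u; eta <- v * (1 - u); zeta <- w * (1 - u) * (1 - v)
    jac_duffy <- (1 - u)^2 * (1 - v)
    dN <- toothfem:::tet10_dshape(xi, eta, zeta)
    J <- crossprod(dN, coords)
    B <- toothfem:::tet10_bmatrix(dN %*% t(solve(J)))
    wt <- gl$weights[iu] * gl$weights[iv] * gl$weights[iw] * jac_duffy * det(J)
    ke <- ke + wt * crossprod(B, D %*% B)
  }
  ke
}

# Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigenproblem
statmod_gauss_legendre01 <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b; A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (x[ord] + 1) / 2, weights = w[ord] / 2)
}

# principal-stress oracle: real roots of the characteristic polynomial
principal_oracle <- function(v) {
  s <- matrix(c(v[1], v[4], v[6],
                v[4], v[2], v[5],
                v[6], v[5], v[3]), 3, 3)
  i1 <- sum(diag(s))
  i2 <- (i1^2 - sum(s * s)) / 2
  i3 <- det(s)
  r <- polyroot(c(-i3, i2, -i1, 1))
  sort(Re(r), decreasing = TRUE)
}

# memoised coarse solved bar (shared by fem / stress / acceptance tests)
solved_axial_bar <- function() {
  fixture("axial_bar", function() {
    bar <- generate_validation_solid("bar", c(10, 10, 40), mesh_size = 2.5)
    mats <- list(DENTINE = material(18.6, 0.31))
    lc <- apply_face_traction(bar, "Z1", total_force = c(0, 0, 100))
    cons <- fix_nodes(NULL, bar$node_sets$Z0, 3L)
    n1 <- which(rowSums(abs(bar$nodes)) < 1e-9)
    n2 <- which(abs(bar$nodes[, 1] - 10) < 1e-9 & abs(bar$nodes[, 2]) < 1e-9 &
                  abs(bar$nodes[, 3]) < 1e-9)
    cons <- fix_nodes(cons, n1, c(1L, 2L))
    cons <- fix_nodes(cons, n2, 2L)
    sol <- solve_elastic(bar, mats, lc, cons)
    list(mesh = bar, materials = mats, load_case = lc, constraints = cons,
         solution = sol, stress = recover_stress(bar, mats, sol))
  })
}

# memoised tooth pipeline state at a given wear depth (coarse test mesh)
tooth_state <- function(wear_depth, mesh_size = 1.2, total = 100) {
  key <- sprintf("tooth_%g_%g_%g", wear_depth, mesh_size, total)
  fixture(key, function() {
    p <- tooth_params(mesh_size = mesh_size, wear_depth = wear_depth)
    tm <- generate_tooth(p)
    off <- approach_to_contact(tm$crown, tm$antagonist)
    an <- translate_surface(tm$antagonist, c(0, -off, 0))
    ct <- detect_contact_patches(tm$crown, an)
    lc <- build_load_case(tm$volume, ct, tm$crown, total = total)
    mats <- default_materials()
    sol <- solve_elastic(tm$volume, mats, lc,
                         default_tooth_constraints(tm$volume))
    st <- recover_stress(tm$volume, mats, sol)
    sample <- cervical_sigma1(sample_cervical_nodes(tm$volume), st,
                              mesh = tm$volume)
    list(params = p, model = tm, offset = off, contacts = ct, load_case = lc,
         materials = mats, solution = sol, stress = st, sample = sample,
         zones = pattern_report(st, tm$volume, root_length = p$root_length))
  })
}

stage_states <- function(mesh_size = 1.2) {
  p <- tooth_params(mesh_size = mesh_size)
  lapply(1:3, function(s) tooth_state(stage_wear_depth(s, p), mesh_size))
}
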