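# Stress recovery (integration points -> nodes, region-aware averaging) and
# principal stresses.

# corner-extrapolation constants of the 4-point rule: gauss values define a
# linear field; corner value = (sigma_g - b * sum(sigma)) / (a - b)
GAUSS_EXTRAP <- local({
  a <- 0.585410196624968515
  b <- 0.138196601125010515
  list(a = a, b = b)
})

#' Recover the nodal stress field from a displacement solution
#'
#' Stress is evaluated at the 4 integration points of every element
#' (B-matrix strain, isotropic Hooke's law), extrapolated linearly to the
#' element nodes, then volume-weight averaged over the elements sharing each
#' node -- separately per tissue region, so bimaterial interfaces (e.g. the
#' enamel-dentine junction) are never averaged across tissues. The combined
#' per-node field takes each node's value from its dominant region (largest
#' accumulated element volume).
#'
#' @param mesh a `volume_mesh`.
#' @param materials named list of [material()] per region.
#' @param displacement a `displacement_field` (or an n x 3 matrix).
#' @return object of class `stress_field`: `sigma` (n x 6 MPa, columns
#'   sxx, syy, szz, sxy, syz, sxz), `principal` (n x 3, sigma1 >= sigma2 >=
#'   sigma3), `node_region` (dominant region per node), `by_region` (named
#'   list with per-region nodal values).
#' @export
recover_stress <- function(mesh, materials, displacement) {
  u <- if (inherits(displacement, "displacement_field")) displacement$u else displacement
  stopifnot(nrow(u) == nrow(mesh$nodes), ncol(u) == 3)
  geo <- element_geometry(mesh)
  lm <- lame_parameters(mesh, materials)
  dN <- lapply(seq_len(4), function(g) {
    p <- TET_GAUSS4$points[g, ]; tet10_dshape(p[1], p[2], p[3])
  })
  a <- GAUSS_EXTRAP$a; b <- GAUSS_EXTRAP$b
  el <- mesh$elements
  ne <- nrow(el)
  U <- lapply(seq_len(10), function(k) u[el[, k], , drop = FALSE])
  sg <- vector("list", 4)                       # gauss-point stress, ne x 6
  for (g in seq_len(4)) {
    G <- shape_gradients(dN[[g]], geo)
    eps <- matrix(0, ne, 6)                     # exx eyy ezz gxy gyz gxz
    for (k in seq_len(10)) {
      Gk <- G[[k]]; Uk <- U[[k]]
      eps[, 1] <- eps[, 1] + Gk[, 1] * Uk[, 1]
      eps[, 2] <- eps[, 2] + Gk[, 2] * Uk[, 2]
      eps[, 3] <- eps[, 3] + Gk[, 3] * Uk[, 3]
      eps[, 4] <- eps[, 4] + Gk[, 2] * Uk[, 1] + Gk[, 1] * Uk[, 2]
      eps[, 5] <- eps[, 5] + Gk[, 3] * Uk[, 2] + Gk[, 2] * Uk[, 3]
      eps[, 6] <- eps[, 6] + Gk[, 3] * Uk[, 1] + Gk[, 1] * Uk[, 3]
    }
    tr <- lm$lambda * (eps[, 1] + eps[, 2] + eps[, 3])
    sg[[g]] <- cbind(tr + 2 * lm$mu * eps[, 1],
                     tr + 2 * lm$mu * eps[, 2],
                     tr + 2 * lm$mu * eps[, 3],
                     lm$mu * eps[, 4], lm$mu * eps[, 5], lm$mu * eps[, 6])
  }
  tot <- sg[[1]] + sg[[2]] + sg[[3]] + sg[[4]]
  corner <- lapply(seq_len(4), function(g) (sg[[g]] - b * tot) / (a - b))
  nodal <- c(corner,
             lapply(seq_len(6), function(k) {
               (corner[[TET10_EDGES[k, 1]]] + corner[[TET10_EDGES[k, 2]]]) / 2
             }))
  vol <- geo$detJ / 6
  regs <- sort(unique(mesh$region))
  n <- nrow(mesh$nodes)
  # volume-weighted accumulation per (node, region), vectorized with rowsum
  idx_long <- as.vector(el)                     # ne*10, grouped by local node
  w_long <- rep(vol, 10)
  s_long <- do.call(rbind, nodal)
  reg_long <- rep(mesh$region, 10)
  acc <- lapply(regs, function(r) {
    sel <- which(reg_long == r)
    wsum <- rowsum(w_long[sel], idx_long[sel])
    ssum <- rowsum(s_long[sel, , drop = FALSE] * w_long[sel], idx_long[sel])
    nodes <- as.integer(rownames(wsum))
    w <- numeric(n); s <- matrix(0, n, 6)
    w[nodes] <- wsum
    s[nodes, ] <- ssum
    list(w = w, s = s)
  })
  names(acc) <- regs
  by_region <- lapply(acc, function(z) {
    sel <- which(z$w > 0)
    s <- z$s[sel, , drop = FALSE] / z$w[sel]
    list(nodes = sel, sigma = s, principal = principal_stresses(s))
  })
  wmat <- vapply(acc, function(z) z$w, numeric(n))
  dom <- max.col(wmat, ties.method = "first")
  node_region <- regs[dom]
  sigma <- matrix(0, n, 6)
  for (k in seq_along(regs)) {
    sel <- which(dom == k & wmat[, k] > 0)
    sigma[sel, ] <- acc[[k]]$s[sel, , drop = FALSE] / wmat[sel, k]
  }
  colnames(sigma) <- c("sxx", "syy", "szz", "sxy", "syz", "sxz")
  structure(list(sigma = sigma,
                 principal = principal_stresses(sigma),
                 node_region = node_region,
                 by_region = by_region),
            class = "stress_field")
}

#' Principal stresses of symmetric stress tensors
#'
#' @param tensor one of: a symmetric 3 x 3 matrix; a length-6 vector
#'   (sxx, syy, szz, sxy, syz, sxz); or an n x 6 matrix of such rows.
#' @param tol asymmetry tolerance for 3 x 3 input (relative).
#' @return sorted eigenvalues sigma1 >= sigma2 >= sigma3 (vector for single
#'   input, n x 3 matrix otherwise). Positive sigma1 indicates tension.
#' @export
principal_stresses <- function(tensor, tol = 1e-9) {
  if (is.matrix(tensor) && nrow(tensor) == 3 && ncol(tensor) == 3) {
    asym <- max(abs(tensor - t(tensor)))
    if (asym > tol * max(1, max(abs(tensor)))) {
      stop("principal_stresses: tensor is not symmetric")
    }
    s <- (tensor + t(tensor)) / 2
    return(sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE))
  }
  m <- if (is.matrix(tensor)) tensor else matrix(tensor, nrow = 1)
  stopifnot(ncol(m) == 6)
  out <- matrix(0, nrow(m), 3)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    s <- matrix(c(v[1], v[4], v[6],
                  v[4], v[2], v[5],
                  v[6], v[5], v[3]), 3, 3)
    out[i, ] <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  }
  colnames(out) <- c("sigma1", "sigma2", "sigma3")
  if (!is.matrix(tensor)) out[1, ] else out
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("stress field: %d nodes, sigma1 in [%.3f, %.3f] MPa\n",
              nrow(x$sigma), min(x$principal[, 1]), max(x$principal[, 1])))
  invisible(x)
}
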