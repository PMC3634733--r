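# Occlusal contact: approach translation, proximity detection, patch
# clustering, and the brute-force oracle equivalence.

test_that("exact point-triangle distance handles all projection regions", {
  a <- c(0, 0, 0); b <- c(2, 0, 0); c3 <- c(0, 2, 0)
  pts <- rbind(
    c(0.5, 0.5, 1),    # face region: distance = 1
    c(-1, -1, 0),      # vertex a region: sqrt(2)
    c(1, -2, 0),       # edge ab region: 2
    c(3, 3, 0),        # edge bc region
    c(0.2, 0.3, 0))    # inside, distance 0
  d <- point_triangle_distance(pts, a, b, c3)
  expect_equal(d[1], 1)
  expect_equal(d[2], sqrt(2))
  expect_equal(d[3], 2)
  expect_equal(d[4], 2 * sqrt(2), tolerance = 1e-12)  # to bc midpoint (1,1,0)
  expect_equal(d[5], 0)
})

test_that("approach closes parallel planes and degenerate cases error", {
  lower <- square_grid_surface(4, side = 1, y = 0)
  upper <- square_grid_surface(4, side = 1, y = 1, flip = TRUE)
  off <- approach_to_contact(lower, upper, c(0, -1, 0), gap_tol = 0.01)
  expect_equal(off, 0.99, tolerance = 1e-9)
  # already touching: zero offset
  touching <- square_grid_surface(4, side = 1, y = 0.005, flip = TRUE)
  expect_equal(approach_to_contact(lower, touching, c(0, -1, 0), gap_tol = 0.01), 0)
  # approach parallel to both planes: no contact achievable
  expect_error(approach_to_contact(lower, upper, c(1, 0, 0)), "no contact")
  expect_error(approach_to_contact(lower, upper, c(0, 0, 0)), "direction")
})

test_that("coincident squares form one full-area patch; gaps give none", {
  lower <- square_grid_surface(6, side = 1, y = 0)
  upper <- square_grid_surface(6, side = 1, y = 0.01, flip = TRUE)
  res <- detect_contact_patches(lower, upper, epsilon = 0.05)
  expect_length(res$patches, 1)
  expect_equal(res$total_area, 1, tolerance = 1e-9)
  expect_equal(res$patches[[1]]$normal, c(0, 1, 0), tolerance = 1e-9)
  far <- square_grid_surface(6, side = 1, y = 0.5, flip = TRUE)
  expect_length(detect_contact_patches(lower, far, epsilon = 0.05)$patches, 0)
  expect_error(detect_contact_patches(lower, far, epsilon = -1), "epsilon")
})

test_that("spatially filtered detection equals the brute-force oracle", {
  # sphere resting on a plane: same triangle set as exhaustive all-pairs
  plane <- square_grid_surface(10, side = 4, y = 0, origin = c(-2, -2))
  sphere <- uv_sphere_surface(radius = 1, center = c(0, 1.02, 0))
  expect_lte(nrow(plane$triangles), 500)
  fast <- detect_contact_patches(plane, sphere, epsilon = 0.1)
  slow <- detect_contact_patches(plane, sphere, epsilon = 0.1,
                                 brute_force = TRUE)
  ids_fast <- sort(unlist(lapply(fast$patches, `[[`, "triangle_ids")))
  ids_slow <- sort(unlist(lapply(slow$patches, `[[`, "triangle_ids")))
  expect_identical(ids_fast, ids_slow)
  expect_length(fast$patches, 1)
  expect_equal(fast$total_area, slow$total_area, tolerance = 1e-12)
})

test_that("contact is symmetric under role swap within discretization", {
  p <- tooth_params(mesh_size = 1.3)
  tm <- generate_tooth(p)
  off <- approach_to_contact(tm$crown, tm$antagonist, c(0, -1, 0))
  an <- translate_surface(tm$antagonist, c(0, -off, 0))
  a <- detect_contact_patches(tm$crown, an, epsilon = 0.05)
  b <- detect_contact_patches(an, tm$crown, epsilon = 0.05)
  # both surfaces discretize the same facet windows on matched polar grids
  expect_equal(a$total_area, b$total_area, tolerance = 0.05)
  expect_gt(a$total_area, 0)
})

test_that("contact summary is canonically ordered and total is conserved", {
  lower <- square_grid_surface(6, side = 1, y = 0)
  # two separated half-size upper plates -> two patches of different area
  u1 <- square_grid_surface(3, side = 0.45, y = 0.01, flip = TRUE)
  u2 <- square_grid_surface(2, side = 0.3, y = 0.01, flip = TRUE,
                            origin = c(0.65, 0.65))
  upper <- surface_mesh(rbind(u1$vertices, u2$vertices),
                        rbind(u1$triangles, u2$triangles + nrow(u1$vertices)))
  res <- detect_contact_patches(lower, upper, epsilon = 0.02)
  df <- contact_summary(res)
  expect_gte(nrow(df), 2)
  expect_true(all(diff(df$area_mm2) <= 1e-12))          # descending area
  expect_equal(sum(df$area_mm2), attr(df, "total_area"), tolerance = 1e-12)
  expect_equal(sum(df$area_mm2), res$total_area, tolerance = 1e-12)
  # empty result: headers only
  far <- square_grid_surface(2, side = 1, y = 3, flip = TRUE)
  empty <- contact_summary(detect_contact_patches(lower, far, epsilon = 0.01))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("patch", "area_mm2", "nx", "cx") %in% names(empty)))
})
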