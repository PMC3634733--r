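# Synthetic geometry: validation solids, tet4->tet10 promotion, the
# parametric premolar and its wear operator.

test_that("unit cube subdivision partitions the volume exactly", {
  m <- generate_validation_solid("cube", c(1, 1, 1), mesh_size = 0.34)
  expect_equal(sum(element_volumes(m)), 1, tolerance = 1e-9)
  expect_true(all(element_volumes(m) > 0))
  expect_equal(midside_deviation(m), 0, tolerance = 1e-12)
  # no orphan nodes
  expect_identical(sort(unique(as.vector(m$elements))),
                   seq_len(nrow(m$nodes)))
  expect_error(generate_validation_solid("cube", c(1, 1, 1), mesh_size = 2),
               "mesh_size")
  expect_error(generate_validation_solid("bar", c(-1, 1, 1)), "dims")
})

test_that("linear_to_quadratic shares midside nodes across elements", {
  # single tetrahedron: 4 corners + 6 edges
  n1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m1 <- linear_to_quadratic(n1, matrix(1:4, 1))
  expect_identical(nrow(m1$nodes), 10L)
  # two tets sharing a face: unique-edge count by brute force enumeration
  n2 <- rbind(n1, c(1, 1, 1))
  el2 <- rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))
  edges <- unique(t(apply(rbind(
    el2[1, c(1, 2)], el2[1, c(2, 3)], el2[1, c(1, 3)], el2[1, c(1, 4)],
    el2[1, c(2, 4)], el2[1, c(3, 4)],
    el2[2, c(1, 2)], el2[2, c(2, 3)], el2[2, c(1, 3)], el2[2, c(1, 4)],
    el2[2, c(2, 4)], el2[2, c(3, 4)]), 1, sort)))
  m2 <- linear_to_quadratic(n2, el2)
  expect_identical(nrow(m2$nodes), 5L + nrow(edges))   # 5 + 9 unique edges
  expect_identical(nrow(m2$nodes), 14L)
  # volumes unchanged by promotion (straight edges)
  v4 <- abs(det(cbind(n2[2, ] - n2[1, ], n2[3, ] - n2[1, ], n2[4, ] - n2[1, ]))) / 6
  expect_equal(element_volumes(m2)[1], v4, tolerance = 1e-12)
  expect_error(linear_to_quadratic(n2, rbind(el2, el2[1, ])), "duplicate")
  expect_error(linear_to_quadratic(n2, rbind(c(1L, 1L, 2L, 3L))), "degenerate")
})

test_that("tooth parameter validation names the offending field", {
  expect_error(tooth_params(wear_depth = 9), "wear_depth")
  expect_error(tooth_params(enamel_thickness = 5), "enamel_thickness")
  expect_error(tooth_params(buccal_cusp_slope = 90), "buccal_cusp_slope")
  expect_error(tooth_params(root_length = -1), "root_length")
  expect_error(tooth_params(bone_block = c(1, 2)), "bone_block")
})

test_that("wear operator updates depth and the Smith stage consistently", {
  p <- tooth_params()
  expect_identical(smith_stage(p)$stage, 1L)
  expect_false(smith_stage(p)$dentine_exposed)
  p2 <- apply_wear(p, 1.3)                 # beyond the 1.2 mm enamel cap
  expect_identical(smith_stage(p2)$stage, 3L)
  expect_true(smith_stage(p2)$dentine_exposed)
  expect_identical(smith_stage(apply_wear(p, 1.0))$stage, 2L)
  expect_error(apply_wear(p, p$crown_height), "crown_height")
  # stage monotone in depth
  stages <- vapply(c(0, 0.2, 0.5, 1.0, 1.3, 2),
                   function(d) smith_stage(apply_wear(p, d))$stage, integer(1))
  expect_true(all(diff(stages) >= 0))
})

test_that("generated premolar honours its input parameters", {
  p <- tooth_params(mesh_size = 1.3)
  tm <- generate_tooth(p)
  m <- tm$volume
  # all five tissues present while enamel is intact
  expect_setequal(unique(m$region),
                  c("ENAMEL", "DENTINE", "PULP", "PDL", "BONE"))
  # unworn crown height matches the buccal cusp height within mesh resolution
  tooth_nodes <- unique(as.vector(
    m$elements[m$region %in% c("ENAMEL", "DENTINE"), ]))
  expect_equal(max(m$nodes[tooth_nodes, 2]), p$buccal_cusp_height,
               tolerance = p$mesh_size / p$buccal_cusp_height)
  # mesh validity: positive Jacobians, straight midsides, no orphans
  expect_true(all(element_volumes(m) > 0))
  expect_lt(midside_deviation(m), 1e-9)
  expect_identical(sort(unique(as.vector(m$elements))), seq_len(nrow(m$nodes)))
  # region partition: per-region volumes sum to the total
  expect_equal(sum(region_volumes(m)), sum(element_volumes(m)),
               tolerance = 1e-9)
  # required node sets populated
  for (s in c("MESIAL_CUT", "DISTAL_CUT", "OCCLUSAL_SURFACE", "BUCCAL_CERVIX")) {
    expect_gt(length(m$node_sets[[s]]), 0)
  }
  # cut faces are planar at the bone-block z extremes
  expect_true(all(abs(m$nodes[m$node_sets$MESIAL_CUT, 3] + p$bone_block[3] / 2) < 1e-9))
  expect_true(all(abs(m$nodes[m$node_sets$DISTAL_CUT, 3] - p$bone_block[3] / 2) < 1e-9))
})

test_that("deep truncation removes all material above the wear plane", {
  p <- tooth_params(mesh_size = 1.3, wear_depth = 5)
  tm <- generate_tooth(p)
  m <- tm$volume
  plane <- p$buccal_cusp_height - p$wear_depth
  # element centroids (the classification points) never sit above the plane
  cen_y <- (m$nodes[m$elements[, 1], 2] + m$nodes[m$elements[, 2], 2] +
              m$nodes[m$elements[, 3], 2] + m$nodes[m$elements[, 4], 2]) / 4
  expect_true(all(cen_y[m$region == "ENAMEL"] <= plane + 1e-9))
  expect_true(all(cen_y <= plane + 1e-9))
  # and no node pokes more than one cell above it
  expect_lt(max(m$nodes[, 2]), plane + p$mesh_size)
})

test_that("generation is deterministic for fixed parameters and seed", {
  p <- tooth_params(mesh_size = 1.4, seed = 7L)
  a <- generate_tooth(p); b <- generate_tooth(p)
  expect_identical(a$volume$nodes, b$volume$nodes)
  expect_identical(a$volume$elements, b$volume$elements)
  expect_identical(a$volume$region, b$volume$region)
  expect_identical(a$crown$vertices, b$crown$vertices)
  expect_identical(a$antagonist$vertices, b$antagonist$vertices)
})

test_that("enamel volume and crown height decrease monotonically with wear", {
  p <- tooth_params(mesh_size = 1.3)
  # depth steps exceed the element size so each step removes material even
  # on this coarse centroid-classified grid
  depths <- c(0, 1.4, 2.8, 4.2, 5.6)
  vols <- numeric(length(depths)); tops <- numeric(length(depths))
  for (i in seq_along(depths)) {
    m <- generate_tooth(apply_wear(p, depths[i]))$volume
    vols[i] <- region_volumes(m)[["ENAMEL"]]
    tops[i] <- max(m$nodes[, 2])
  }
  expect_true(all(diff(vols) < 0))          # strictly shrinking enamel
  expect_true(all(diff(tops) <= 1e-12))     # non-increasing height
})
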