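# Consistent surface loads and the resultant-normalized occlusal load case.

test_that("uniform pressure on a straight quadratic face loads only midsides", {
  # right triangle legs 2, area 2, pressure 3 N/mm^2 along -y
  corners <- rbind(c(0, 5, 0), c(2, 5, 0), c(0, 5, 2))
  face <- rbind(corners, (corners[c(1, 2, 1), ] + corners[c(2, 3, 3), ]) / 2)
  traction <- c(0, -3, 0)
  f <- consistent_face_loads(face, traction)
  A <- 2
  expect_equal(f[1:3, ], matrix(0, 3, 3), tolerance = 1e-12)      # corners 0
  for (k in 4:6) expect_equal(f[k, ], traction * A / 3, tolerance = 1e-12)
  expect_equal(colSums(f), traction * A, tolerance = 1e-12)
  # zero traction and linearity
  expect_identical(consistent_face_loads(face, c(0, 0, 0)),
                   matrix(0, 6, 3))
  expect_equal(consistent_face_loads(face, 2 * traction), 2 * f,
               tolerance = 1e-14)
})

# small slab mesh whose top face acts as the occlusal surface, plus a
# coincident "crown" surface carrying synthetic contact patches
slab_with_patches <- function(normals, split_x = 2) {
  mesh <- generate_validation_solid("cube", dims = c(4, 1, 2), mesh_size = 0.5)
  bf <- boundary_faces(mesh)
  top <- which(bf$normal[, 2] > 0.99)
  mesh$occlusal_faces <- lapply(
    list(faces = bf$faces, element = bf$element, centroid = bf$centroid,
         normal = bf$normal, area = bf$area),
    function(v) if (is.matrix(v)) v[top, , drop = FALSE] else v[top])
  mesh$h <- 0.5
  crown <- square_grid_surface(8, side = 4, y = 1)
  crown$vertices[, 3] <- crown$vertices[, 3] / 2   # 4 x 2 footprint
  cen <- triangle_centroids(crown)
  areas <- triangle_areas(crown)
  halves <- list(which(cen[, 1] < split_x), which(cen[, 1] >= split_x))
  patches <- lapply(seq_along(normals), function(i) {
    ids <- halves[[i]]
    list(triangle_ids = ids, area = sum(areas[ids]),
         normal = normals[[i]],
         centroid = colSums(cen[ids, , drop = FALSE] * areas[ids]) / sum(areas[ids]))
  })
  contacts <- structure(list(patches = patches,
                             total_area = sum(areas),
                             epsilon = 0.05, n_triangles = nrow(cen)),
                        class = "contact_result")
  list(mesh = mesh, crown = crown, contacts = contacts)
}

test_that("single-patch load case gives the prescribed axial resultant", {
  s <- slab_with_patches(list(c(0, 1, 0)), split_x = 99)  # one patch, all tris
  s$contacts$patches <- s$contacts$patches[1]
  lc <- build_load_case(s$mesh, s$contacts, s$crown, total = 100)
  expect_equal(lc$resultant, c(0, -100, 0), tolerance = 1e-8)
  expect_equal(sqrt(sum(colSums(lc$forces)^2)), 100, tolerance = 1e-8)
  # forces confined to occlusal-face nodes
  loaded <- which(rowSums(abs(lc$forces)) > 0)
  expect_true(all(loaded %in% as.vector(s$mesh$occlusal_faces$faces)))
})

test_that("two equal patches at right angles normalize to 100 N resultant", {
  s <- slab_with_patches(list(c(-1, 0, 0), c(0, -1, 0)))
  areas <- vapply(s$contacts$patches, `[[`, numeric(1), "area")
  expect_equal(areas[1], areas[2], tolerance = 1e-12)
  lc <- build_load_case(s$mesh, s$contacts, s$crown, total = 100)
  # closed form: each patch magnitude 100/sqrt(2), resultant magnitude 100
  mags <- sqrt(rowSums(lc$patch_forces^2))
  expect_equal(mags, rep(100 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(sqrt(sum(lc$resultant^2)), 100, tolerance = 1e-8)
  # patch force magnitudes proportional to areas
  expect_equal(mags[1] / mags[2], areas[1] / areas[2], tolerance = 1e-9)
})

test_that("degenerate patch configurations are rejected", {
  s <- slab_with_patches(list(c(1, 0, 0), c(-1, 0, 0)))
  expect_error(build_load_case(s$mesh, s$contacts, s$crown),
               "indeterminate normalization")
  empty <- structure(list(patches = list(), total_area = 0, epsilon = 0.05,
                          n_triangles = 0L), class = "contact_result")
  expect_error(build_load_case(s$mesh, empty, s$crown), "no occlusal contacts")
})

test_that("resultant conservation holds for random patch configurations", {
  set.seed(99)
  for (rep in 1:5) {
    nrm <- matrix(rnorm(6), 2, 3)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    nrm[, 2] <- abs(nrm[, 2]) + 0.5            # roughly upward normals
    nrm <- nrm / sqrt(rowSums(nrm^2))
    s <- slab_with_patches(list(nrm[1, ], nrm[2, ]), split_x = 1.5)
    lc <- build_load_case(s$mesh, s$contacts, s$crown, total = 37.5)
    expect_equal(sqrt(sum(lc$resultant^2)), 37.5, tolerance = 1e-8 * 37.5)
    areas <- vapply(s$contacts$patches, `[[`, numeric(1), "area")
    mags <- sqrt(rowSums(lc$patch_forces^2))
    expect_equal(mags[1] / mags[2], areas[1] / areas[2], tolerance = 1e-9)
  }
})

test_that("face-set tractions integrate to the requested total force", {
  bar <- generate_validation_solid("bar", c(10, 10, 40), mesh_size = 5)
  lc <- apply_face_traction(bar, "Z1", total_force = c(0, 0, 100))
  expect_equal(lc$resultant, c(0, 0, 100), tolerance = 1e-10)
  expect_error(apply_face_traction(bar, "NOPE", total_force = c(1, 0, 0)),
               "unknown node set")
})
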