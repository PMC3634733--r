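# Cervical sampling, homology across wear states, zone summaries.

test_that("cervical sampling returns distinct ordered homologous nodes", {
  st <- tooth_state(0.24)
  m <- st$model$volume
  s <- sample_cervical_nodes(m, n = 10)
  expect_identical(nrow(s), 10L)
  expect_identical(anyDuplicated(s$node), 0L)
  expect_true(all(diff(s$arc_position) > 0))
  # nodes lie on the buccal half, in the cervical band
  expect_true(all(s$x > 0))
  expect_true(all(abs(s$y) <= 0.5))
  # n = 1 picks the node nearest the arc midpoint
  s1 <- sample_cervical_nodes(m, n = 1)
  pool <- m$node_sets$BUCCAL_CERVIX
  arc <- (atan2(m$nodes[pool, 3], m$nodes[pool, 1]) + pi / 2) / pi
  expect_equal(s1$arc_position, arc[which.min(abs(arc - 0.5))],
               tolerance = 1e-12)
  expect_error(sample_cervical_nodes(m, n = length(pool) + 1), "cervix nodes")
})

test_that("arc positions are identical across wear states (homology)", {
  a <- tooth_state(0.24)
  b <- tooth_state(1.68)
  expect_identical(a$sample$arc_position, b$sample$arc_position)
  expect_identical(a$sample$x, b$sample$x)  # same physical points
})

test_that("wear comparison computes aligned deltas and obliquity", {
  a <- tooth_state(0.24)
  b <- tooth_state(1.68)
  cmp <- compare_wear_states(list(sample = a$sample, load_case = a$load_case),
                             list(sample = b$sample, load_case = b$load_case))
  expect_identical(nrow(cmp$table), 10L)
  expect_equal(cmp$table$delta, a$sample$sigma1 - b$sample$sigma1)
  expect_equal(cmp$mean_delta, mean(cmp$table$delta))
  # identical inputs: all deltas zero
  same <- compare_wear_states(list(sample = a$sample, load_case = a$load_case),
                              list(sample = a$sample, load_case = a$load_case))
  expect_identical(unique(same$table$delta), 0)
  # linearity: doubling both stress states doubles every delta
  a2 <- a$sample; a2$sigma1 <- 2 * a2$sigma1
  b2 <- b$sample; b2$sigma1 <- 2 * b2$sigma1
  cmp2 <- compare_wear_states(list(sample = a2, load_case = a$load_case),
                              list(sample = b2, load_case = b$load_case))
  expect_equal(cmp2$table$delta, 2 * cmp$table$delta, tolerance = 1e-12)
  # mismatched positions are rejected
  bad <- b$sample; bad$arc_position <- bad$arc_position + 0.01
  expect_error(compare_wear_states(list(sample = a$sample, load_case = a$load_case),
                                   list(sample = bad, load_case = b$load_case)),
               "homologous")
})

test_that("load obliquity measures the angle to the tooth axis", {
  mk <- function(r) structure(list(forces = matrix(0, 1, 3), resultant = r,
                                   total_magnitude = sqrt(sum(r^2))),
                              class = "load_case")
  expect_equal(load_obliquity(mk(c(0, -100, 0))), 0)
  expect_equal(load_obliquity(mk(c(100, -100, 0) / sqrt(2))), 45)
  expect_equal(load_obliquity(mk(c(0, 0, 0))), 0)
})

test_that("zone report covers the anatomy and respects zero load", {
  st <- tooth_state(0.24)
  zn <- st$zones
  expect_setequal(zn$zone, c("buccal_cervix", "lingual_cervix", "mesial_side",
                             "distal_side", "root_apex"))
  expect_true(all(zn$n_nodes > 0))
  expect_identical(sum(zn$global_max_sigma1), 1L)
  # zero displacement: all zone statistics vanish
  m <- st$model$volume
  st0 <- recover_stress(m, st$materials, matrix(0, nrow(m$nodes), 3))
  zn0 <- pattern_report(st0, m, root_length = st$params$root_length)
  expect_equal(max(abs(zn0$mean_sigma1)), 0)
  expect_equal(max(abs(zn0$mean_trace)), 0)
})

test_that("lesion prevalence reports percentages at one decimal", {
  expect_identical(nccl_prevalence(10, 225), 4.4)
  expect_identical(nccl_prevalence(0, 100), 0)
  expect_identical(nccl_prevalence(5, 85), 5.9)
  expect_error(nccl_prevalence(10, 5))
})
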