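# Pubococcygeal-line measurement geometry.

fake_geometry <- function(pubis = c(0, 60, 0), coccyx = c(0, -40, -10)) {
  structure(list(landmarks = list(pubic_symphysis_inferior = pubis,
                                  coccyx_last_joint = coccyx)),
            class = "pelvic_geometry")
}

test_that("the PCL runs pubis to coccyx in the midsagittal plane", {
  g <- fake_geometry()
  line <- pcl_line(g)
  expect_equal(line$point, c(0, 60, 0))
  expect_equal(line$direction,
               (c(0, -40, -10) - c(0, 60, 0)) / sqrt(100^2 + 10^2))
  expect_equal(sum(line$normal^2), 1)
  expect_lt(line$normal[3], 0)  # caudal side
  # off-plane landmarks are projected to x = 0 first
  g2 <- fake_geometry(pubis = c(12, 60, 0), coccyx = c(-3, -40, -10))
  expect_equal(pcl_line(g2)$point, c(0, 60, 0))
  expect_equal(pcl_line(g2)$direction, line$direction)
  # swapped landmarks: same line, reversed direction
  g3 <- fake_geometry(pubis = c(0, -40, -10), coccyx = c(0, 60, 0))
  expect_equal(pcl_line(g3)$direction, -line$direction)
  expect_error(pcl_line(fake_geometry(coccyx = c(0, 60, 0))),
               class = "pelvifem_geometry_error")
})

test_that("perpendicular distance is planar, signed caudal-positive", {
  g <- fake_geometry(pubis = c(0, 0, 0), coccyx = c(0, 100, 0))
  line <- pcl_line(g)
  expect_equal(perpendicular_distance(c(0, 50, 0), line), 0)
  expect_equal(perpendicular_distance(c(0, 50, -30), line), 30)
  # out-of-plane x is discarded by the midsagittal projection
  expect_equal(perpendicular_distance(c(12, 50, -30), line), 30)
  expect_equal(perpendicular_distance(c(0, 50, 30), line), -30)
})

test_that("descent is zero at rest, tracks rigid caudal translation, flags lateral Ba", {
  geom <- build_pelvic_geometry(geometry_params(support_condition = "pathological"))
  mesh <- mesh_geometry(geom)
  model <- fe_model(mesh)
  n <- nrow(mesh$nodes)
  zero <- structure(list(displacement = matrix(0, n, 3)),
                    class = "simulation_result")
  d0 <- measure_descent(model, geom, zero)
  expect_equal(c(d0$Ba_mm, d0$C_mm, d0$Bp_mm), c(0, 0, 0))
  expect_false(d0$Ba_not_evaluable)

  # rigid 5 mm caudal translation of everything but the fixed bony frame:
  # perpendicular distances all grow by the projected amount
  u <- matrix(rep(c(0, 0, -5), each = n), n, 3)
  u[mesh$node_sets$sacrum_coccyx_region, ] <- 0
  tr <- structure(list(displacement = u), class = "simulation_result")
  d5 <- measure_descent(model, geom, tr)
  line <- pcl_line(geom)
  expected <- sum(c(0, 0, -5) * line$normal)
  expect_equal(c(d5$Ba_mm, d5$C_mm, d5$Bp_mm), rep(expected, 3),
               tolerance = 1e-9)
  expect_equal(d5$C_total_mm, 5)

  # purely lateral motion: zero descent, Ba flagged not-evaluable
  ul <- matrix(0, n, 3)
  ul[mesh$node_sets$Ba, 1] <- 8
  lat <- structure(list(displacement = ul), class = "simulation_result")
  dl <- measure_descent(model, geom, lat)
  expect_equal(dl$Ba_mm, 0, tolerance = 1e-9)
  expect_true(dl$Ba_not_evaluable)

  # displaced bony frame invalidates the PCL frame
  ub <- matrix(0, n, 3); ub[mesh$node_sets$sacrum_coccyx_region, 3] <- -1
  expect_error(measure_descent(model, geom,
                               structure(list(displacement = ub),
                                         class = "simulation_result")),
               class = "pelvifem_state_error")
})

test_that("descent is invariant under rigid translation of the whole scene", {
  g <- fake_geometry(pubis = c(0, 52, -5), coccyx = c(0, -46, -22))
  line1 <- pcl_line(g)
  p <- c(0, 10, -20)
  d1 <- perpendicular_distance(p, line1)
  shift <- c(0, 13.7, 4.2)
  g2 <- fake_geometry(pubis = c(0, 52, -5) + shift,
                      coccyx = c(0, -46, -22) + shift)
  d2 <- perpendicular_distance(p + shift, pcl_line(g2))
  expect_equal(d1, d2, tolerance = 1e-9)
})
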