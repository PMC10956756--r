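test_that("parameter validation rejects invalid generator inputs", {
  expect_error(geometry_params(organ_scale = c(vagina = -1)),
               class = "pelvifem_parameter_error")
  expect_error(geometry_params(pcl_length = 0),
               class = "pelvifem_parameter_error")
  expect_error(geometry_params(ss_ligament_length = 25),
               class = "pelvifem_parameter_error")
  expect_error(geometry_params(target_edge_length = -2),
               class = "pelvifem_parameter_error")
  expect_error(geometry_params(organ_scale = c(spleen = 1)),
               class = "pelvifem_parameter_error")
})

test_that("the generic variant is strictly mirror-symmetric", {
  g <- build_pelvic_geometry(geometry_params(asymmetry_amplitude = 0, seed = 1))
  expect_true(g$symmetric)
  lm <- g$landmarks
  for (pair in list(c("ischial_spine_left", "ischial_spine_right"),
                    c("sacrospinous_insertion_left", "sacrospinous_insertion_right"))) {
    l <- lm[[pair[1]]]; r <- lm[[pair[2]]]
    expect_lt(max(abs(l - c(-r[1], r[2], r[3]))), 1e-9)
  }
  # midline landmarks lie exactly on the midsagittal plane
  expect_identical(lm$pubic_symphysis_inferior[1], 0)
  expect_identical(lm$coccyx_last_joint[1], 0)
})

test_that("PCL length and inter-spine width are honoured exactly", {
  for (L in c(90, 100, 115)) {
    g <- build_pelvic_geometry(geometry_params(pcl_length = L))
    d <- sqrt(sum((g$landmarks$pubic_symphysis_inferior -
                     g$landmarks$coccyx_last_joint)^2))
    expect_equal(d, L, tolerance = 1e-12)
  }
  g <- build_pelvic_geometry(geometry_params(inter_spine_width = 108))
  w <- sqrt(sum((g$landmarks$ischial_spine_left -
                   g$landmarks$ischial_spine_right)^2))
  expect_equal(w, 108, tolerance = 1e-12)
})

test_that("geometry generation is a pure function of (params, seed)", {
  p <- geometry_params(asymmetry_amplitude = 4, seed = 7)
  g1 <- build_pelvic_geometry(p)
  g2 <- build_pelvic_geometry(p)
  expect_identical(pelvic_landmarks(g1), pelvic_landmarks(g2))
  expect_identical(g1$organ_surfaces$bladder$vertices,
                   g2$organ_surfaces$bladder$vertices)
  g3 <- build_pelvic_geometry(geometry_params(asymmetry_amplitude = 4, seed = 8))
  expect_false(identical(pelvic_landmarks(g1), pelvic_landmarks(g3)))
})

test_that("sacrospinous polylines run spine-to-insertion with > 30 mm arc", {
  g <- build_pelvic_geometry()
  for (s in c("left", "right")) {
    lg <- g$ligaments[[paste0("sacrospinous_", s)]]
    expect_lt(max(abs(lg$points[1, ] - g$landmarks[[paste0("ischial_spine_", s)]])), 1e-9)
    expect_lt(max(abs(lg$points[nrow(lg$points), ] -
                        g$landmarks[[paste0("sacrospinous_insertion_", s)]])), 1e-9)
    expect_gt(pelvifem:::polyline_length(lg$points), 30)
  }
})

test_that("support condition disables exactly the broad and round ligaments", {
  g <- build_pelvic_geometry(geometry_params(support_condition = "physiological"))
  active0 <- vapply(g$ligaments, function(l) l$active, logical(1))
  expect_true(all(active0))

  gp <- apply_support_condition(g, "pathological")
  inact <- names(which(!vapply(gp$ligaments, function(l) l$active, logical(1))))
  expect_setequal(inact, c("broad_left", "broad_right", "round_left", "round_right"))
  # idempotent
  gp2 <- apply_support_condition(gp, "pathological")
  expect_identical(vapply(gp2$ligaments, function(l) l$active, logical(1)),
                   vapply(gp$ligaments, function(l) l$active, logical(1)))
  # everything else untouched
  expect_identical(gp$organ_surfaces, g$organ_surfaces)
  expect_identical(gp$landmarks, g$landmarks)
  # back to physiological restores all
  gb <- apply_support_condition(gp, "physiological")
  expect_true(all(vapply(gb$ligaments, function(l) l$active, logical(1))))
})

test_that("reflection mirrors landmarks and swaps sides", {
  g <- build_pelvic_geometry(geometry_params(asymmetry_amplitude = 3, seed = 2))
  gr <- reflect_pelvic_geometry(g)
  expect_equal(gr$landmarks$ischial_spine_left[1],
               -g$landmarks$ischial_spine_right[1])
  expect_equal(gr$landmarks$ischial_spine_left[2:3],
               g$landmarks$ischial_spine_right[2:3])
  expect_equal(gr$ligaments$sacrospinous_left$points[, 2:3],
               g$ligaments$sacrospinous_right$points[, 2:3])
  expect_equal(gr$ligaments$sacrospinous_left$points[, 1],
               -g$ligaments$sacrospinous_right$points[, 1])
})
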