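# Anchor placement and suture construction for the sacrospinous fixation.

test_that("anchors interpolate arc length along a polyline", {
  # straight 45 mm ligament
  p0 <- c(50, 0, 0); p1 <- c(5, -30, 10)
  p1 <- p0 + 45 * (p1 - p0) / sqrt(sum((p1 - p0)^2))
  pts <- rbind(p0, p0 + 0.4 * (p1 - p0), p1)
  a <- anchor_on_polyline(pts, 20)
  expect_equal(a$point, p0 + (20 / 45) * (p1 - p0), tolerance = 1e-9)
  expect_equal(a$arc_length, 45, tolerance = 1e-9)
  a0 <- anchor_on_polyline(pts, 0)
  expect_equal(a0$point, p0)
  expect_error(anchor_on_polyline(pts, 50), class = "pelvifem_parameter_error")
})

geom <- build_pelvic_geometry(geometry_params(support_condition = "pathological"))

test_that("place_anchor measures from the ischial spine along the ligament", {
  a <- place_anchor(geom, "left", 0)
  expect_equal(a$point, geom$landmarks$ischial_spine_left, tolerance = 1e-9)
  a20 <- place_anchor(geom, "left", 20)
  # arc-length distance from the spine equals the request
  pts <- geom$ligaments$sacrospinous_left$points
  upto <- anchor_on_polyline(pts, 20)
  expect_equal(a20$point, upto$point)
  expect_error(place_anchor(geom, "left", 80), class = "pelvifem_parameter_error")
  expect_error(place_anchor(geom, "middle", 10), class = "pelvifem_parameter_error")
})

test_that("ssf_config validates its fields", {
  expect_error(ssf_config(sides = "both"), class = "pelvifem_parameter_error")
  expect_error(ssf_config(sides = "left", anchor_distance_mm = -1),
               class = "pelvifem_parameter_error")
  expect_error(ssf_config(sutures_per_side = 0), class = "pelvifem_parameter_error")
  cfg <- ssf_config(sides = c("left", "right"))
  expect_equal(cfg$anchor_distance_mm, 20)
  expect_equal(cfg$sutures_per_side, 2L)
})

test_that("apply_ssf adds the configured sutures, tied into the mesh", {
  mesh <- mesh_geometry(geom)
  model <- fe_model(mesh)

  # no sides: model unchanged
  m0 <- apply_ssf(model, geom, ssf_config())
  expect_identical(nrow(m0$mesh$truss), nrow(mesh$truss))

  # bilateral, two sutures per side: exactly 4 suture filaments
  m2 <- apply_ssf(model, geom, ssf_config(sides = c("left", "right")))
  sut <- which(m2$mesh$truss_label == "suture")
  expect_length(sut, 4L)
  # each runs from a distinct vaginal-apex node to the side's anchor node
  apex_nodes <- unique(m2$mesh$truss[sut, 1])
  expect_length(apex_nodes, 2L)
  expect_true(all(apex_nodes %in% mesh$node_sets$nodes_vagina))
  anchors <- unique(m2$mesh$truss[sut, 2])
  expect_length(anchors, 2L)
  # anchor nodes sit on the meshed ligament chain at the right arc distance
  for (s in c("left", "right")) {
    chain <- m2$mesh$ligament_chains[[paste0("sacrospinous_", s)]]
    anchor <- m2$mesh$node_sets[[paste0("suture_anchor_", s)]]
    expect_true(anchor %in% chain)
    pts <- m2$mesh$nodes[chain, ]
    cum <- c(0, cumsum(pelvifem:::rownorms(diff(pts))))
    expect_equal(cum[match(anchor, chain)], 20, tolerance = 1e-9)
  }

  # unilateral adds exactly 2
  m1 <- apply_ssf(model, geom, ssf_config(sides = "left"))
  expect_length(which(m1$mesh$truss_label == "suture"), 2L)
})

test_that("left and right fixation are mirror images on the symmetric pelvis", {
  mesh <- mesh_geometry(geom)
  model <- fe_model(mesh)
  ml <- apply_ssf(model, geom, ssf_config(sides = "left"))
  mr <- apply_ssf(model, geom, ssf_config(sides = "right"))
  al <- ml$mesh$nodes[ml$mesh$node_sets$suture_anchor_left, ]
  ar <- mr$mesh$nodes[mr$mesh$node_sets$suture_anchor_right, ]
  expect_equal(al[1], -ar[1], tolerance = 1e-9)
  expect_equal(al[2:3], ar[2:3], tolerance = 1e-9)
  # suture reference lengths match side to side (gap-closed tie lengths)
  expect_equal(sort(ml$mesh$truss_ref_len[ml$mesh$truss_label == "suture"]),
               sort(mr$mesh$truss_ref_len[mr$mesh$truss_label == "suture"]),
               tolerance = 1e-9)
})
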