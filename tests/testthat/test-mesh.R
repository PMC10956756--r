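geom <- build_pelvic_geometry(geometry_params(support_condition = "pathological"))

test_that("default meshing lands in the intended desk-scale element range", {
  mesh <- mesh_geometry(geom)
  expect_gte(n_elements(mesh), 2000)
  expect_lte(n_elements(mesh), 12000)
})

test_that("halving the target edge length strictly increases element count", {
  m1 <- mesh_geometry(geom, target_edge_length = 8)
  m2 <- mesh_geometry(geom, target_edge_length = 4)
  expect_gt(n_elements(m2), n_elements(m1))
  m3 <- mesh_geometry(geom, target_edge_length = 2)
  expect_gt(n_elements(m3), n_elements(m2))
})

test_that("all required node sets exist and are non-empty", {
  mesh <- mesh_geometry(geom)
  required <- c("pelvic_floor_border", "sacrum_coccyx_region",
                "ischial_spine_region", "vagina_upper_surface",
                "bladder_top_surface", "rectum_wall_surface",
                "Ba", "C", "Bp", "fixed_boundary")
  for (s in required) {
    expect_false(is.null(mesh$node_sets[[s]]), info = s)
    expect_gt(length(mesh$node_sets[[s]]), 0)
  }
  # reference nodes belong to the right organ surfaces, near the midline
  expect_true(mesh$node_sets$Ba %in% mesh$node_sets$nodes_bladder)
  expect_true(mesh$node_sets$C %in% mesh$node_sets$nodes_vagina)
  expect_true(mesh$node_sets$Bp %in% mesh$node_sets$nodes_rectum)
  for (p in c("Ba", "C", "Bp"))
    expect_lt(abs(mesh$nodes[mesh$node_sets[[p]], 1]), 4)
})

test_that("the pelvic floor border is part of the floor surface", {
  mesh <- mesh_geometry(geom)
  expect_true(all(mesh$node_sets$pelvic_floor_border %in%
                    mesh$node_sets$nodes_pelvic_floor))
  # border nodes are fixed
  expect_true(all(mesh$node_sets$pelvic_floor_border %in%
                    mesh$node_sets$fixed_boundary))
})

test_that("mesh invariants are validated", {
  mesh <- mesh_geometry(geom)
  expect_silent(validate_fe_mesh(mesh))
  bad <- mesh
  bad$tri[1, ] <- c(1L, 1L, 2L)  # degenerate triangle
  expect_error(validate_fe_mesh(bad), class = "pelvifem_model_error")
  bad2 <- mesh
  bad2$tri_thickness[3] <- 0
  expect_error(validate_fe_mesh(bad2), class = "pelvifem_model_error")
})

test_that("ligament chains are connected truss paths from spine to sacrum", {
  mesh <- mesh_geometry(geom)
  for (s in c("left", "right")) {
    chain <- mesh$ligament_chains[[paste0("sacrospinous_", s)]]
    expect_gt(length(chain), 5)  # interior nodes exist for anchor placement
    pts <- mesh$nodes[chain, ]
    arc <- sum(pelvifem:::rownorms(diff(pts)))
    expect_gt(arc, 30)
    # consecutive chain nodes are joined by truss elements
    for (k in seq_len(length(chain) - 1)) {
      expect_silent(pelvifem:::find_truss_row(mesh, chain[k], chain[k + 1]))
    }
  }
})

test_that("meshing is deterministic", {
  m1 <- mesh_geometry(geom)
  m2 <- mesh_geometry(geom)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$truss, m2$truss)
  expect_identical(m1$node_sets, m2$node_sets)
})
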