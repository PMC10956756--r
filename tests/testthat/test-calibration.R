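# Load calibration: scalar root-finds on the magnitude -> displacement map.

# hand-solvable linear oracle: a single spring of stiffness k = E A / L
# loaded by a nodal force of magnitude m; displacement u = m / k, so the
# magnitude recovering a target u* is m = k u*.
spring_setup <- function(E = 20, A = 1, L = 10) {
  nodes <- rbind(c(0, 0, 0), c(L, 0, 0))
  mesh <- fe_mesh(nodes, truss = cbind(1, 2), truss_label = "rod",
                  truss_area = A, node_sets = list(fix = 1, tip = 2))
  mats <- default_materials()
  mats$rod <- material_model("linear_elastic", E = E)
  model <- fe_model(mesh, mats)
  case <- load_case(
    tractions = list(vagina = list(node_set = "tip", direction = c(1, 0, 0),
                                   magnitude = 0.5, type = "nodal")),
    fixed_sets = list(list(set = "fix"), list(set = "tip", comps = c("y", "z"))),
    n_load_steps = 1)
  measure <- function(res) c(C = res$displacement[2, 1])
  list(model = model, case = case, measure = measure, k = E * A / L)
}

test_that("calibration recovers the load of a hand-solvable spring", {
  s <- spring_setup()
  u_star <- 1.5
  spec <- calibration_spec(setpoints = c(C = u_star), driven = c(C = "vagina"),
                           tolerance = 1e-4)
  cal <- calibrate_loads(s$model, s$case, spec, measure_fn = s$measure)
  expect_true(cal$converged)
  # geometric nonlinearity is negligible at small stretch: m = k u*
  expect_equal(unname(cal$magnitudes["vagina"]), s$k * u_star,
               tolerance = 1e-2)
  expect_equal(unname(cal$achieved["C"]), u_star, tolerance = 1e-4)
  expect_s3_class(cal$trace, "tbl_df")
  expect_gt(nrow(cal$trace), 0)
})

test_that("an already-satisfied setpoint returns the initial magnitude", {
  s <- spring_setup()
  res0 <- solve_quasi_static(s$model, s$case)
  u0 <- s$measure(res0)[["C"]]
  spec <- calibration_spec(setpoints = c(C = u0), driven = c(C = "vagina"),
                           tolerance = 0.1)
  cal <- calibrate_loads(s$model, s$case, spec, measure_fn = s$measure)
  expect_true(cal$converged)
  expect_equal(unname(cal$magnitudes["vagina"]), 0.5)
  expect_equal(cal$n_solves, 1L)
})

test_that("an unreachable setpoint fails structurally with a trace", {
  s <- spring_setup()
  # measure saturates: no magnitude can reach the target
  meas_sat <- function(res) c(C = min(res$displacement[2, 1], 0.3))
  spec <- calibration_spec(setpoints = c(C = 5), driven = c(C = "vagina"),
                           tolerance = 1e-3, max_iter = 8)
  err <- tryCatch(
    calibrate_loads(s$model, s$case, spec, measure_fn = meas_sat),
    pelvifem_calibration_error = function(e) e)
  expect_s3_class(err, "pelvifem_calibration_error")
  expect_s3_class(err$trace, "tbl_df")
  expect_gt(nrow(err$trace), 2)
})

test_that("a non-monotone response is detected, not silently accepted", {
  s <- spring_setup()
  meas_bad <- function(res) {
    u <- res$displacement[2, 1]
    c(C = u * (1 - 0.8 * u))  # decreasing branch within the search range
  }
  spec <- calibration_spec(setpoints = c(C = 0.9), driven = c(C = "vagina"),
                           tolerance = 1e-4, max_iter = 12)
  expect_error(calibrate_loads(s$model, s$case, spec, measure_fn = meas_bad),
               class = "pelvifem_calibration_error")
})

test_that("calibration_spec validates its fields", {
  expect_error(calibration_spec(setpoints = c(C = -7)),
               class = "pelvifem_parameter_error")
  expect_error(calibration_spec(setpoints = c(C = 7), driven = c(Bp = "rectum")),
               class = "pelvifem_parameter_error")
  expect_error(calibration_spec(tolerance = 0),
               class = "pelvifem_parameter_error")
})
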