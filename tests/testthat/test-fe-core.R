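# Verification of the nonlinear membrane/truss solver: energy-gradient
# consistency, patch tests against closed-form constitutive solutions,
# objectivity, tie constraints and global force balance.

test_that("the residual is the gradient of the total potential energy", {
  mesh <- small_mixed_mesh()
  model <- fe_model(mesh)
  case <- load_case(
    tractions = list(pull = list(node_set = "tip", direction = c(0, 0, -1),
                                 magnitude = 0.5, type = "nodal")),
    fixed_sets = "base")
  dm <- pelvifem:::build_dofmap(model, case)
  set.seed(11)
  for (trial in 1:4) {
    u <- matrix(rnorm(3 * nrow(mesh$nodes), sd = 1.2), ncol = 3)
    u[c(1, 4), ] <- 0
    r <- assemble_residual(model, case, u, load_factor = 0.7)
    g <- numeric_gradient(model, case, reduce_guess(dm, u), dm, load_factor = 0.7)
    expect_lt(max(abs(r - g)) / max(abs(g)), 1e-5)
  }
})

test_that("residual vanishes at zero displacement and zero load", {
  model <- fe_model(small_mixed_mesh())
  case <- load_case(fixed_sets = "base")
  r <- assemble_residual(model, case, matrix(0, 7, 3))
  expect_lt(max(abs(r)), 1e-12)
})

test_that("internal forces are invariant under rigid-body translation", {
  mesh <- small_mixed_mesh()
  model <- fe_model(mesh)
  x0 <- mesh$nodes
  set.seed(3)
  u <- matrix(rnorm(21, sd = 0.5), ncol = 3)
  f1 <- pelvifem:::internal_force(model, x0 + u)$f
  shift <- matrix(c(3.2, -1.4, 5.9), nrow(x0), 3, byrow = TRUE)
  f2 <- pelvifem:::internal_force(model, x0 + u + shift)$f
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("zero-magnitude loads give zero displacement in one iteration", {
  model <- fe_model(square_membrane())
  case <- load_case(
    tractions = list(p = list(node_set = "right", direction = c(1, 0, 0),
                              magnitude = 0, type = "nodal")),
    fixed_sets = list(list(set = "all", comps = "z"),
                      list(set = "left", comps = c("x", "y"))),
    n_load_steps = 1)
  res <- solve_quasi_static(model, case)
  expect_true(res$converged)
  expect_identical(max(abs(res$displacement)), 0)
  expect_equal(res$steps$iterations, 1)
})

test_that("uniaxial membrane patch test matches the closed form", {
  for (cc in list(c(0.111, 0.27), c(0.0375, 0.07), c(0.085, 0.056))) {
    v <- uniaxial_patch(cc[1], cc[2])
    expect_lt(abs(v["fe"] - v["exact"]) / v["exact"], 1e-4)
    # free lateral contraction 1/sqrt(lambda) of the incompressible state
    expect_lt(abs(v["lat"] - 1 / sqrt(v["exact"])), 1e-4)
  }
})

test_that("equibiaxial membrane patch test matches the closed form", {
  for (cc in list(c(0.111, 0.27), c(0.0375, 0.07), c(0.085, 0.056))) {
    mesh <- square_membrane(L = 10, label = "organ")
    mats <- default_materials()
    mats$organ <- material_model("yeoh", C0 = cc[1], C1 = cc[2])
    model <- fe_model(mesh, mats)
    P <- 1.5
    case <- load_case(
      tractions = list(
        px = list(node_set = "right", direction = c(1, 0, 0), magnitude = P,
                  type = "nodal"),
        py = list(node_set = "top", direction = c(0, 1, 0), magnitude = P,
                  type = "nodal")),
      fixed_sets = list(list(set = "left", comps = "x"),
                        list(set = "bottom", comps = "y"),
                        list(set = "all", comps = "z")),
      n_load_steps = 4)
    res <- solve_quasi_static(model, case)
    expect_true(res$converged)
    lam_fe <- (10 + res$displacement[2, 1]) / 10
    lam_ex <- yeoh_equibiaxial_lambda(P / 10, cc[1], cc[2])
    expect_lt(abs(lam_fe - lam_ex) / lam_ex, 1e-4)
  }
})

test_that("a linear-elastic truss reproduces E A (lambda - 1)", {
  nodes <- rbind(c(0, 0, 0), c(40, 0, 0))
  mesh <- fe_mesh(nodes, truss = cbind(1, 2), truss_label = "rod",
                  truss_area = 3, node_sets = list(fix = 1, tip = 2))
  mats <- default_materials()
  mats$rod <- material_model("linear_elastic", E = 12)
  model <- fe_model(mesh, mats)
  P <- 4.5
  case <- load_case(
    tractions = list(p = list(node_set = "tip", direction = c(1, 0, 0),
                              magnitude = P, type = "nodal")),
    fixed_sets = list(list(set = "fix"), list(set = "tip", comps = c("y", "z"))),
    n_load_steps = 2)
  res <- solve_quasi_static(model, case)
  expect_true(res$converged)
  lam <- (40 + res$displacement[2, 1]) / 40
  expect_equal(12 * 3 * (lam - 1), P, tolerance = 1e-7)
})

test_that("global equilibrium: reactions balance applied loads", {
  mesh <- small_mixed_mesh()
  model <- fe_model(mesh)
  case <- load_case(
    tractions = list(pull = list(node_set = "tip", direction = unitize_t(c(1, 2, -3)),
                                 magnitude = 0.8, type = "nodal")),
    fixed_sets = "base", n_load_steps = 4)
  res <- solve_quasi_static(model, case)
  expect_true(res$converged)
  fext <- pelvifem:::external_force(model, case)
  imbalance <- reaction_sum(res, model) + colSums(fext)
  expect_lt(max(abs(imbalance)), 1e-6)
})

test_that("the solution is objective under rigid rotation of the scene", {
  mesh <- small_mixed_mesh()
  model <- fe_model(mesh)
  dir <- unitize_t(c(0.3, -0.2, -1))
  case <- load_case(
    tractions = list(pull = list(node_set = "tip", direction = dir,
                                 magnitude = 0.6, type = "nodal")),
    fixed_sets = "base", n_load_steps = 4)
  res <- solve_quasi_static(model, case)
  expect_true(res$converged)

  # random rotation
  set.seed(5)
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(Q)
  model_r <- fe_model(mesh_r)
  case_r <- case
  case_r$tractions$pull$direction <- as.numeric(Q %*% dir)
  res_r <- solve_quasi_static(model_r, case_r)
  expect_true(res_r$converged)
  expect_lt(max(abs(res_r$displacement - res$displacement %*% t(Q))), 1e-6)
})

test_that("tie links merge degrees of freedom exactly", {
  # two-spring chain: 1 --(k1)-- 2   3 --(k2)-- 4, middle nodes tied,
  # equals the single merged chain 1 -- 2=3 -- 4
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 0, 0) + 1e-15, c(20, 0, 0))
  mesh <- fe_mesh(nodes, truss = rbind(c(1, 2), c(3, 4)),
                  truss_label = "rod", truss_area = 1,
                  truss_ref_len = c(10, 10),
                  node_sets = list(fix = 1, tip = 4))
  mats <- default_materials()
  mats$rod <- material_model("linear_elastic", E = 20)
  model <- fe_model(mesh, mats)
  model <- apply_tie_links(model, cbind(2, 3))
  P <- 1.2
  case <- load_case(
    tractions = list(p = list(node_set = "tip", direction = c(1, 0, 0),
                              magnitude = P, type = "nodal")),
    fixed_sets = list(list(set = "fix"),
                      list(set = "tip", comps = c("y", "z"))),
    n_load_steps = 1)
  res <- solve_quasi_static(model, case)
  expect_true(res$converged)
  # tied nodes share displacement exactly
  expect_identical(res$displacement[2, ], res$displacement[3, ])
  # series stiffness: u_tip from two springs k = EA/L in series
  k <- 20 * 1 / 10
  expect_equal(res$displacement[4, 1], P / k * 2, tolerance = 1e-6)

  # tying a node to itself is a no-op
  m2 <- apply_tie_links(fe_model(mesh, mats), cbind(2, 2))
  expect_null(m2$ties)
})

test_that("tying two distant fixed nodes is a constraint conflict", {
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5, 0))
  mesh <- fe_mesh(nodes, truss = rbind(c(1, 3), c(2, 3)), truss_label = "rod",
                  truss_area = 1, node_sets = list(fix = c(1, 2), tip = 3))
  mats <- default_materials()
  mats$rod <- material_model("linear_elastic", E = 5)
  model <- apply_tie_links(fe_model(mesh, mats), cbind(1, 2))
  case <- load_case(fixed_sets = "fix")
  expect_error(solve_quasi_static(model, case),
               class = "pelvifem_model_error")
})

test_that("a pressurized circular membrane matches the flat-membrane series solution", {
  # Hencky problem: clamped circular membrane, uniform transverse pressure;
  # center deflection w0 = 0.662 a (p a / (E h))^(1/3) for nu = 0.3.
  a <- 50; h <- 0.4; E <- 10; p <- 0.002
  n_t <- 28L; n_r <- 9L
  theta <- 2 * pi * (seq_len(n_t) - 1) / n_t
  nodes <- rbind(c(0, 0, 0))
  for (i in seq_len(n_r)) {
    r <- a * i / n_r
    nodes <- rbind(nodes, cbind(r * cos(theta), r * sin(theta), 0))
  }
  idx <- function(i, j) 1L + (i - 1L) * n_t + (j - 1L) %% n_t + 1L
  faces <- NULL
  for (j in seq_len(n_t)) faces <- rbind(faces, c(1L, idx(1, j), idx(1, j + 1)))
  for (i in seq_len(n_r - 1)) for (j in seq_len(n_t)) {
    faces <- rbind(faces,
                   c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
                   c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  rim <- (nrow(nodes) - n_t + 1):nrow(nodes)
  mesh <- fe_mesh(nodes, tri = faces, tri_label = "disk", tri_thickness = h,
                  node_sets = list(rim = rim, interior = setdiff(1:nrow(nodes), rim),
                                   all = 1:nrow(nodes), center = 1))
  mats <- default_materials()
  mats$disk <- material_model("linear_elastic", E = E, nu = 0.3)
  model <- fe_model(mesh, mats, bending = FALSE)
  case <- load_case(
    tractions = list(pr = list(node_set = "all", direction = c(0, 0, 1),
                               magnitude = p, type = "traction")),
    fixed_sets = "rim", n_load_steps = 4, max_newton_iter = 100)
  # flat membranes have no transverse stiffness at zero state: start from a
  # small dome
  r2 <- rowSums(mesh$nodes[, 1:2]^2)
  guess <- matrix(0, nrow(nodes), 3)
  guess[, 3] <- 0.02 * a * (1 - r2 / a^2)
  res <- solve_quasi_static(model, case, initial_guess = guess)
  expect_true(res$converged)
  w0 <- res$displacement[1, 3]
  w_hencky <- 0.662 * a * (p * a / (E * h))^(1 / 3)
  expect_lt(abs(w0 - w_hencky) / w_hencky, 0.05)
})
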