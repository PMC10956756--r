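# Small model builders shared across tests.

# unit-thickness square membrane (2 triangles), side L mm
square_membrane <- function(L = 10, label = "vagina", thickness = 1) {
  nodes <- rbind(c(0, 0, 0), c(L, 0, 0), c(L, L, 0), c(0, L, 0))
  fe_mesh(nodes, tri = rbind(c(1, 2, 3), c(1, 3, 4)), tri_label = label,
          tri_thickness = thickness,
          node_sets = list(left = c(1, 4), right = c(2, 3),
                           bottom = c(1, 2), top = c(3, 4),
                           origin = 1, all = 1:4))
}

# irregular small mixed mesh (membranes + trusses) for gradient checks
small_mixed_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0),
                 c(5, 5, 4), c(15, 5, 2), c(18, 9, 6))
  fe_mesh(nodes,
          tri = rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5)),
          tri_label = c("vagina", "pelvic_floor", "rectum", "bladder"),
          tri_thickness = c(1, 2, 1.5, 1),
          truss = rbind(c(2, 6), c(6, 7), c(3, 6)),
          truss_label = c("uterosacral", "suture", "link"),
          truss_area = c(10, 0.2, 2),
          node_sets = list(base = c(1, 4), tip = 7, origin = 1))
}

# numeric central-difference gradient of total potential energy
numeric_gradient <- function(model, case, u_red, dm, load_factor = 1,
                             h = 1e-6) {
  en <- function(v) total_potential_energy(
    model, case, pelvifem:::expand_disp(dm, v), load_factor)
  vapply(seq_along(u_red), function(i) {
    vp <- u_red; vm <- u_red
    vp[i] <- vp[i] + h; vm[i] <- vm[i] - h
    (en(vp) - en(vm)) / (2 * h)
  }, numeric(1))
}

reduce_guess <- function(dm, u) {
  v <- numeric(dm$n_red)
  sel <- dm$map > 0
  v[dm$map[sel]] <- u[sel]
  v
}

# closed-form uniaxial stretch of an incompressible Yeoh membrane under a
# nominal (reference-area) traction T = sigma / lambda
yeoh_uniaxial_lambda <- function(Tn, C0, C1) {
  f <- function(l) {
    I1 <- l^2 + 2 / l
    2 * (l^2 - 1 / l) * (C0 + 2 * C1 * (I1 - 3)) / l - Tn
  }
  stats::uniroot(f, c(1 + 1e-9, 5), tol = 1e-12)$root
}

# closed-form equibiaxial stretch under equal nominal edge tractions
yeoh_equibiaxial_lambda <- function(Tn, C0, C1) {
  f <- function(l) {
    I1 <- 2 * l^2 + 1 / l^4
    2 * (l^2 - 1 / l^4) * (C0 + 2 * C1 * (I1 - 3)) / l - Tn
  }
  stats::uniroot(f, c(1 + 1e-9, 3), tol = 1e-12)$root
}

unitize_t <- function(v) v / sqrt(sum(v^2))

# solve a single-element uniaxial tension patch and return FE vs exact
uniaxial_patch <- function(C0, C1, P = 2) {
  mesh <- square_membrane(L = 10, label = "organ")
  mats <- default_materials()
  mats$organ <- material_model("yeoh", C0 = C0, C1 = C1)
  model <- fe_model(mesh, mats)
  case <- load_case(
    tractions = list(pull = list(node_set = "right", direction = c(1, 0, 0),
                                 magnitude = P, type = "nodal")),
    fixed_sets = list(list(set = "left", comps = "x"),
                      list(set = "origin", comps = "y"),
                      list(set = "all", comps = "z")),
    n_load_steps = 4)
  res <- solve_quasi_static(model, case)
  stopifnot(res$converged)
  lam_fe <- (10 + res$displacement[2, 1]) / 10
  lam_ex <- yeoh_uniaxial_lambda(P / 10, C0, C1)  # T per ref area, t = 1 mm
  c(fe = lam_fe, exact = lam_ex,
    lat = (10 + res$displacement[3, 2] - res$displacement[2, 2]) / 10)
}

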