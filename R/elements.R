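# Vectorised element kernels: analytic internal forces (energy gradients)
# for constant-strain membrane triangles (incompressible plane-stress Yeoh
# and plane-stress St. Venant-Kirchhoff) and linear trusses, plus element
# tangent stiffness by central differencing of the analytic forces.
# Units: mm, N, MPa (N/mm^2); energies in N mm.

# Precompute reference quantities per triangle.
# Local frame: e1 along edge 12; Dm = [[l, p], [0, q]] upper-triangular, so
# Dminv = [[1/l, -p/(l q)], [0, 1/q]] = [[u11, u12], [0, u22]].
precompute_membranes <- function(nodes, tri, tri_thickness, tri_label, materials,
                                 stab = 1e-3) {
  x1 <- nodes[tri[, 1], , drop = FALSE]
  e12 <- nodes[tri[, 2], , drop = FALSE] - x1
  e13 <- nodes[tri[, 3], , drop = FALSE] - x1
  l <- rownorms(e12)
  e1 <- e12 / l
  nrm <- cross3(e12, e13)
  A0 <- 0.5 * rownorms(nrm)
  e2 <- cross3(nrm / (2 * A0), e1)
  p <- rowSums(e13 * e1)
  q <- rowSums(e13 * e2)
  u11 <- 1 / l
  u22 <- 1 / q
  u12 <- -p / (l * q)
  detDm <- l * q
  labs <- unique(tri_label)
  C0 <- C1 <- Emod <- nu <- numeric(length(tri_label))
  kindy <- logical(length(tri_label))
  for (lb in labs) {
    m <- material_for(materials, lb)
    sel <- tri_label == lb
    if (m$kind == "yeoh") {
      kindy[sel] <- TRUE; C0[sel] <- m$C0; C1[sel] <- m$C1
    } else {
      Emod[sel] <- m$E; nu[sel] <- m$nu
    }
  }
  list(u11 = u11, u12 = u12, u22 = u22,
       M11 = u11^2 + u12^2, M12 = u12 * u22, M22 = u22^2,
       detDm2 = detDm^2, A0 = A0, t = tri_thickness,
       yeoh = kindy, C0 = C0, C1 = C1, E = Emod, nu = nu, stab = stab)
}

# gradients of element energy wrt edge vectors a = x2-x1, b = x3-x1.
# Returns list(ga, gb) (m x 3 each) and per-element energies.
#
# A membrane has no bending stiffness, so in-plane compression is a true
# instability (wrinkling). The element energy is therefore the blended
# tension-field form
#     W = (1 - eps) * W_relaxed + eps * W_full
# where W_relaxed classifies the state as taut (both principal stresses
# tensile: full biaxial law), wrinkled (minor principal stress would be
# compressive: energy of the uniaxial natural state at the major stretch)
# or slack (zero), and the small eps (stabilisation factor) keeps a
# residual material stiffness in compressed regions. In taut states the
# blend reduces exactly to the full biaxial law, and the equilibrium of a
# uniaxial state (free lateral contraction) coincides with the full law's
# closed form because the relaxed part carries no lateral stress.
membrane_grads <- function(pc, a, b, want_energy = FALSE) {
  m <- nrow(a)
  G11 <- rowSums(a * a); G12 <- rowSums(a * b); G22 <- rowSums(b * b)
  u11 <- pc$u11; u12 <- pc$u12; u22 <- pc$u22
  C11 <- u11^2 * G11
  C12 <- u11 * u12 * G11 + u11 * u22 * G12
  C22 <- u12^2 * G11 + 2 * u12 * u22 * G12 + u22^2 * G22
  # principal values of C (squared principal stretches)
  mid <- (C11 + C22) / 2
  disc <- sqrt(pmax(((C11 - C22) / 2)^2 + C12^2, 0))
  mu1 <- mid + disc; mu2 <- pmax(mid - disc, 1e-12)
  At <- pc$A0 * pc$t
  eps <- pc$stab

  # ---- full biaxial law, evaluated for every element --------------------
  ga_f <- matrix(0, m, 3); gb_f <- matrix(0, m, 3)
  en_f <- numeric(m)
  iy <- which(pc$yeoh)
  if (length(iy)) {
    detC2 <- pmax(mu1[iy] * mu2[iy], 1e-9)
    I1 <- C11[iy] + C22[iy] + 1 / detC2
    x <- I1 - 3
    Wp <- pc$C0[iy] + 2 * pc$C1[iy] * x
    coef <- At[iy] * Wp
    cc <- cross3(a[iy, , drop = FALSE], b[iy, , drop = FALSE])
    dfac <- 2 / (detC2^2 * pc$detDm2[iy])
    bxc <- cross3(b[iy, , drop = FALSE], cc)
    cxa <- cross3(cc, a[iy, , drop = FALSE])
    ga_f[iy, ] <- coef * (2 * (pc$M11[iy] * a[iy, , drop = FALSE] +
                                 pc$M12[iy] * b[iy, , drop = FALSE]) - dfac * bxc)
    gb_f[iy, ] <- coef * (2 * (pc$M22[iy] * b[iy, , drop = FALSE] +
                                 pc$M12[iy] * a[iy, , drop = FALSE]) - dfac * cxa)
    en_f[iy] <- At[iy] * (pc$C0[iy] * x + pc$C1[iy] * x^2)
  }
  il <- which(!pc$yeoh)
  if (length(il)) {
    E11 <- (C11[il] - 1) / 2; E22 <- (C22[il] - 1) / 2; E12 <- C12[il] / 2
    k <- pc$E[il] / (1 - pc$nu[il]^2)
    S11 <- k * (E11 + pc$nu[il] * E22)
    S22 <- k * (E22 + pc$nu[il] * E11)
    S12 <- k * (1 - pc$nu[il]) * E12
    H11 <- u11[il]^2 * S11 + 2 * u11[il] * u12[il] * S12 + u12[il]^2 * S22
    H12 <- u22[il] * (u11[il] * S12 + u12[il] * S22)
    H22 <- u22[il]^2 * S22
    ga_f[il, ] <- At[il] * (H11 * a[il, , drop = FALSE] + H12 * b[il, , drop = FALSE])
    gb_f[il, ] <- At[il] * (H12 * a[il, , drop = FALSE] + H22 * b[il, , drop = FALSE])
    en_f[il] <- At[il] * 0.5 * (S11 * E11 + 2 * S12 * E12 + S22 * E22)
  }

  # ---- tension-field classification -------------------------------------
  # boundaries classify as taut so the reference state keeps full stiffness
  slack <- mu1 < 1 - 1e-12
  crit <- ifelse(pc$yeoh, mu2^2 * mu1 - 1, (mu2 - 1) + pc$nu * (mu1 - 1))
  wrk <- !slack & crit < -1e-12
  ga <- ga_f; gb <- gb_f; energy <- en_f

  iw <- which(wrk)
  if (length(iw)) {
    # eigenvector of C for mu1, from the numerically better column
    dA <- C11[iw] - mu1[iw]; dB <- C22[iw] - mu1[iw]; c12 <- C12[iw]
    n1 <- c12^2 + dA^2; n2 <- dB^2 + c12^2
    use1 <- n1 >= n2
    vx <- ifelse(use1, c12, -dB)
    vy <- ifelse(use1, -dA, c12)
    nv <- pmax(sqrt(vx^2 + vy^2), 1e-12)
    deg <- nv < 1e-11
    vx <- ifelse(deg, 1, vx / nv)
    vy <- ifelse(deg, 0, vy / nv)
    # dmu1 = w' dG w with w = U v1
    w1 <- u11[iw] * vx + u12[iw] * vy
    w2 <- u22[iw] * vy
    m1 <- mu1[iw]
    ky <- pc$yeoh[iw]
    dWdmu <- numeric(length(iw)); en <- numeric(length(iw))
    if (any(ky)) {
      I1u <- m1[ky] + 2 / sqrt(m1[ky])
      x <- I1u - 3
      Wp <- pc$C0[iw][ky] + 2 * pc$C1[iw][ky] * x
      dWdmu[ky] <- Wp * (1 - m1[ky]^(-1.5))
      en[ky] <- pc$C0[iw][ky] * x + pc$C1[iw][ky] * x^2
    }
    if (any(!ky)) {
      E1 <- (m1[!ky] - 1) / 2
      dWdmu[!ky] <- 0.5 * pc$E[iw][!ky] * E1
      en[!ky] <- 0.5 * pc$E[iw][!ky] * E1^2
    }
    coef <- At[iw] * dWdmu
    ga[iw, ] <- coef * 2 * (w1^2 * a[iw, , drop = FALSE] +
                              w1 * w2 * b[iw, , drop = FALSE])
    gb[iw, ] <- coef * 2 * (w2^2 * b[iw, , drop = FALSE] +
                              w1 * w2 * a[iw, , drop = FALSE])
    energy[iw] <- At[iw] * en
  }
  isl <- which(slack)
  if (length(isl)) {
    ga[isl, ] <- 0; gb[isl, ] <- 0; energy[isl] <- 0
  }
  ib <- which(wrk | slack)
  if (length(ib) && eps > 0) {
    ga[ib, ] <- (1 - eps) * ga[ib, , drop = FALSE] + eps * ga_f[ib, , drop = FALSE]
    gb[ib, ] <- (1 - eps) * gb[ib, , drop = FALSE] + eps * gb_f[ib, , drop = FALSE]
    energy[ib] <- (1 - eps) * energy[ib] + eps * en_f[ib]
  }
  list(ga = ga, gb = gb, energy = if (want_energy) energy else NULL)
}

precompute_trusses <- function(mesh, materials) {
  if (is.null(mesh$truss) || nrow(mesh$truss) == 0)
    return(list(n = 0L))
  lab <- mesh$truss_label
  E <- numeric(length(lab)); cf <- numeric(length(lab)) + 1
  for (lb in unique(lab)) {
    m <- material_for(materials, lb)
    if (m$kind != "linear_elastic")
      abort_param(paste("truss structure", lb, "needs a linear_elastic material"))
    sel <- lab == lb
    E[sel] <- m$E
    cf[sel] <- m$compression_factor %||% if (m$tension_only) 0 else 1
  }
  act <- mesh$truss_active
  list(n = nrow(mesh$truss), EA = E * mesh$truss_area * as.numeric(act),
       L0 = mesh$truss_ref_len, cf = cf, band = 1e-3)
}

# axial gradients wrt d = xj - xi, plus exact energies.
#
# Force law: N = EA (lambda - 1) in tension, N = cf EA (lambda - 1) in
# compression (cf = compression factor; 0 = strictly tension-only). The
# tensile and slack branches are joined C1-continuously over a narrow
# strain band |lambda - 1| < band by a cubic Hermite blend: outside the
# band both branches are exact, and the huge tensile/slack stiffness jump
# no longer produces a nondifferentiable kink at lambda = 1 (which makes
# Newton chatter). The energy is the exact integral of the blended force.
truss_grads <- function(pt, d, want_energy = FALSE) {
  L <- rownorms(d)
  lam <- L / pt$L0
  s <- lam - 1
  dl <- pt$band
  t <- pmin(pmax((s + dl) / (2 * dl), 0), 1)
  w <- 3 * t^2 - 2 * t^3
  fac <- pt$cf + (1 - pt$cf) * w
  N <- fac * pt$EA * s
  g <- (N / L) * d
  en <- NULL
  if (want_energy) {
    # antiderivative of w(t(s)) * s over the band
    H <- function(tt) 2 * dl^2 * (-0.8 * tt^5 + 2 * tt^4 - tt^3)
    extra <- ifelse(s >= dl, (s^2 - dl^2) / 2 + 0.45 * dl^2,
                    ifelse(s <= -dl, 0.05 * dl^2, H(t) - H(0.5)))
    en <- pt$EA * pt$L0 * (pt$cf * s^2 / 2 + (1 - pt$cf) * extra)
  }
  list(g = g, N = N, energy = en)
}

# scatter-add element contributions (m x 3 values at node indices idx)
accumulate_force <- function(f, idx, vals) {
  s <- rowsum(vals, idx, reorder = FALSE)
  rows <- as.integer(rownames(s))
  f[rows, ] <- f[rows, ] + s
  f
}

# global internal force (gradient of internal energy) at current positions
internal_force <- function(model, x, want_energy = FALSE) {
  mesh <- model$mesh
  tri <- mesh$tri
  a <- x[tri[, 2], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  b <- x[tri[, 3], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  mg <- membrane_grads(model$prec_mem, a, b, want_energy = want_energy)
  f <- matrix(0, nrow(x), 3)
  f <- accumulate_force(f, tri[, 1], -(mg$ga + mg$gb))
  f <- accumulate_force(f, tri[, 2], mg$ga)
  f <- accumulate_force(f, tri[, 3], mg$gb)
  energy <- if (want_energy) sum(mg$energy) else NA_real_
  pt <- model$prec_truss
  if (pt$n > 0) {
    tr <- mesh$truss
    d <- x[tr[, 2], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
    tg <- truss_grads(pt, d, want_energy = want_energy)
    f <- accumulate_force(f, tr[, 1], -tg$g)
    f <- accumulate_force(f, tr[, 2], tg$g)
    if (want_energy) energy <- energy + sum(tg$energy)
  }
  ph <- model$prec_hinge
  if (!is.null(ph) && ph$n > 0) {
    hg <- hinge_grads(ph, x, want_energy = want_energy)
    f <- accumulate_force(f, ph$idx[, 1], hg$g0)
    f <- accumulate_force(f, ph$idx[, 2], hg$g1)
    f <- accumulate_force(f, ph$idx[, 3], hg$g2)
    f <- accumulate_force(f, ph$idx[, 4], hg$g3)
    if (want_energy) energy <- energy + sum(hg$energy)
  }
  list(f = f, energy = energy)
}

# current minimum membrane area ratio (detC2), used to flag inverted elements
min_area_ratio <- function(model, x) {
  tri <- model$mesh$tri
  a <- x[tri[, 2], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  b <- x[tri[, 3], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  cc <- cross3(a, b)
  min(rowSums(cc * cc) / model$prec_mem$detDm2)
}

# ---- element tangent stiffness (central difference of analytic forces) ----

# Jacobian of (ga, gb) wrt (a, b): m x 6 x 6 array, then expanded to the
# 9 x 9 nodal block via the incidence map a = x2 - x1, b = x3 - x1.
membrane_stiffness_blocks <- function(pc, a, b, h) {
  m <- nrow(a)
  J <- array(0, c(m, 6, 6))
  for (q in 1:6) {
    ap <- a; bp <- b; am <- a; bm <- b
    if (q <= 3) { ap[, q] <- ap[, q] + h; am[, q] <- am[, q] - h }
    else { bp[, q - 3] <- bp[, q - 3] + h; bm[, q - 3] <- bm[, q - 3] - h }
    gp <- membrane_grads(pc, ap, bp)
    gm <- membrane_grads(pc, am, bm)
    J[, 1:3, q] <- (gp$ga - gm$ga) / (2 * h)
    J[, 4:6, q] <- (gp$gb - gm$gb) / (2 * h)
  }
  # B maps nodal dofs (9) to (a, b) dofs (6): a_c = x2_c - x1_c, b_c = x3_c - x1_c
  B <- matrix(0, 6, 9)
  for (cpt in 1:3) {
    B[cpt, cpt] <- -1; B[cpt, 3 + cpt] <- 1
    B[3 + cpt, cpt] <- -1; B[3 + cpt, 6 + cpt] <- 1
  }
  K <- array(0, c(m, 9, 9))
  for (p in 1:6) for (q in 1:6) {
    Jpq <- J[, p, q]
    ip <- which(B[p, ] != 0); iq <- which(B[q, ] != 0)
    for (i in ip) for (j in iq) {
      K[, i, j] <- K[, i, j] + B[p, i] * B[q, j] * Jpq
    }
  }
  K
}

truss_stiffness_blocks <- function(pt, d, h) {
  m <- nrow(d)
  J <- array(0, c(m, 3, 3))
  for (q in 1:3) {
    dp <- d; dm <- d
    dp[, q] <- dp[, q] + h; dm[, q] <- dm[, q] - h
    J[, , q] <- (truss_grads(pt, dp)$g - truss_grads(pt, dm)$g) / (2 * h)
  }
  K <- array(0, c(m, 6, 6))
  K[, 4:6, 4:6] <- J
  K[, 1:3, 1:3] <- J
  K[, 1:3, 4:6] <- -J
  K[, 4:6, 1:3] <- -J
  K
}

# ---- discrete-hinge bending ------------------------------------------------
# The organs in the source model are thin shells; a pure membrane has no
# bending stiffness and wrinkles without a length scale, which makes the
# equilibrium problem ill-posed. Each interior mesh edge therefore carries a
# discrete-shells hinge energy
#     E = ce * (theta - theta0)^2,  ce = kb * 3 |e|^2 / (A1 + A2),
# with kb = E t^3 / (12 (1 - nu^2)) the plate bending modulus (for Yeoh
# organs the small-strain Young modulus 6 C0 and nu = 1/2 are used) and
# theta0 the reference dihedral angle, so the rest shape is stress-free.

# pair triangles of the same structure sharing an edge:
# hinge = (x0, x1) shared edge, x2 opposite in tri A, x3 opposite in tri B
build_hinges <- function(tri, tri_label) {
  m <- nrow(tri)
  if (m == 0) return(NULL)
  ev <- rbind(tri[, c(1, 2, 3)], tri[, c(2, 3, 1)], tri[, c(3, 1, 2)])
  lab <- rep(tri_label, 3)
  tri_id <- rep(seq_len(m), 3)
  lo <- pmin(ev[, 1], ev[, 2]); hi <- pmax(ev[, 1], ev[, 2])
  key <- paste(lo, hi, lab)
  first <- match(key, key)
  dup <- which(first != seq_along(key))
  if (!length(dup)) return(NULL)
  a <- first[dup]; b <- dup
  cbind(n0 = ev[a, 1], n1 = ev[a, 2], n2 = ev[a, 3], n3 = ev[b, 3],
        ta = tri_id[a], tb = tri_id[b])
}

hinge_theta <- function(x0, x1, x2, x3) {
  e <- x1 - x0
  n1 <- cross3(e, x2 - x0)
  n2 <- cross3(x3 - x0, e)
  s <- rowSums(cross3(n1, n2) * e) / rownorms(e)
  atan2(s, rowSums(n1 * n2))
}

precompute_hinges <- function(nodes, tri, tri_thickness, tri_label, materials) {
  H <- build_hinges(tri, tri_label)
  if (is.null(H)) return(list(n = 0L))
  x0 <- nodes[H[, 1], , drop = FALSE]; x1 <- nodes[H[, 2], , drop = FALSE]
  x2 <- nodes[H[, 3], , drop = FALSE]; x3 <- nodes[H[, 4], , drop = FALSE]
  theta0 <- hinge_theta(x0, x1, x2, x3)
  elen <- rownorms(x1 - x0)
  A1 <- 0.5 * rownorms(cross3(x1 - x0, x2 - x0))
  A2 <- 0.5 * rownorms(cross3(x3 - x0, x1 - x0))
  lab <- tri_label[H[, 5]]
  th <- (tri_thickness[H[, 5]] + tri_thickness[H[, 6]]) / 2
  kb <- numeric(nrow(H))
  for (lb in unique(lab)) {
    mt <- material_for(materials, lb)
    sel <- lab == lb
    if (mt$kind == "yeoh") {
      kb[sel] <- 6 * mt$C0 * th[sel]^3 / (12 * (1 - 0.25))
    } else {
      kb[sel] <- mt$E * th[sel]^3 / (12 * (1 - mt$nu^2))
    }
  }
  list(n = nrow(H), idx = H[, 1:4, drop = FALSE], theta0 = theta0,
       ce = kb * 3 * elen^2 / (A1 + A2))
}

# gradients of hinge energies wrt the four hinge nodes
hinge_grads <- function(ph, x, want_energy = FALSE) {
  i <- ph$idx
  x0 <- x[i[, 1], , drop = FALSE]; x1 <- x[i[, 2], , drop = FALSE]
  x2 <- x[i[, 3], , drop = FALSE]; x3 <- x[i[, 4], , drop = FALSE]
  e <- x1 - x0
  E <- rownorms(e)
  n1 <- cross3(e, x2 - x0); n2 <- cross3(x3 - x0, e)
  s <- rowSums(cross3(n1, n2) * e) / E
  theta <- atan2(s, rowSums(n1 * n2))
  N1 <- n1 / rowSums(n1 * n1); N2 <- n2 / rowSums(n2 * n2)
  f <- 2 * ph$ce * (theta - ph$theta0)
  g2 <- f * (-E * N1)
  g3 <- f * (-E * N2)
  g0 <- f * ((rowSums((x1 - x2) * e) / E) * N1 +
               (rowSums((x1 - x3) * e) / E) * N2)
  g1 <- f * ((rowSums((x2 - x0) * e) / E) * N1 +
               (rowSums((x3 - x0) * e) / E) * N2)
  en <- if (want_energy) ph$ce * (theta - ph$theta0)^2 else NULL
  list(g0 = g0, g1 = g1, g2 = g2, g3 = g3, energy = en)
}

# hinge tangent blocks (12 x 12) by central differencing of the analytic
# gradient wrt the 9 relative coordinates (translation invariance gives the
# x0 block)
hinge_stiffness_blocks <- function(ph, x, h) {
  i <- ph$idx
  m <- ph$n
  base <- list(x[i[, 1], , drop = FALSE], x[i[, 2], , drop = FALSE],
               x[i[, 3], , drop = FALSE], x[i[, 4], , drop = FALSE])
  eval_g <- function(xs) {
    e <- xs[[2]] - xs[[1]]
    E <- rownorms(e)
    n1 <- cross3(e, xs[[3]] - xs[[1]]); n2 <- cross3(xs[[4]] - xs[[1]], e)
    s <- rowSums(cross3(n1, n2) * e) / E
    theta <- atan2(s, rowSums(n1 * n2))
    N1 <- n1 / rowSums(n1 * n1); N2 <- n2 / rowSums(n2 * n2)
    f <- 2 * ph$ce * (theta - ph$theta0)
    cbind(f * ((rowSums((xs[[2]] - xs[[3]]) * e) / E) * N1 +
                 (rowSums((xs[[2]] - xs[[4]]) * e) / E) * N2),
          f * ((rowSums((xs[[3]] - xs[[1]]) * e) / E) * N1 +
                 (rowSums((xs[[4]] - xs[[1]]) * e) / E) * N2),
          f * (-E * N1),
          f * (-E * N2))
  }
  K <- array(0, c(m, 12, 12))
  for (q in 1:9) {
    node <- 2L + (q - 1L) %/% 3L  # perturb x1, x2, x3
    cpt <- 1L + (q - 1L) %% 3L
    xp <- base; xm <- base
    xp[[node]][, cpt] <- xp[[node]][, cpt] + h
    xm[[node]][, cpt] <- xm[[node]][, cpt] - h
    dg <- (eval_g(xp) - eval_g(xm)) / (2 * h)
    K[, , 3 + q] <- dg
  }
  # translation invariance: column block for x0
  for (cpt in 1:3) {
    K[, , cpt] <- -(K[, , 3 + cpt] + K[, , 6 + cpt] + K[, , 9 + cpt])
  }
  K
}
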