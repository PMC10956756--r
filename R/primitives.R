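# Structured parametric surface primitives used by the synthetic pelvic
# geometry generator. Each generator returns a triangulated surface:
#   list(vertices = n x 3 [mm], faces = m x 3 integer, boundary = list of
#        integer loops, attrs = list of named node index vectors)
# All grids are deterministic functions of their numeric arguments, and the
# sampling densities are strictly monotone in 1/edge so that refinement
# monotonicity holds by construction.

even_at_least <- function(x, lo) {
  n <- max(lo, ceiling(x))
  if (n %% 2 == 1) n <- n + 1
  as.integer(n)
}

# triangles for a structured (ni rows) x (nj cols) grid of vertex ids in
# `idx` (ni x nj integer matrix); wrap_j closes the grid in the j direction
grid_faces <- function(idx, wrap_j = FALSE) {
  ni <- nrow(idx); nj <- ncol(idx)
  jmax <- if (wrap_j) nj else nj - 1
  faces <- matrix(0L, nrow = 2 * (ni - 1) * jmax, ncol = 3)
  k <- 0L
  for (i in seq_len(ni - 1)) {
    for (j in seq_len(jmax)) {
      jn <- if (j == nj) 1L else j + 1L
      v00 <- idx[i, j]; v01 <- idx[i, jn]
      v10 <- idx[i + 1, j]; v11 <- idx[i + 1, jn]
      faces[k + 1L, ] <- c(v00, v10, v11)
      faces[k + 2L, ] <- c(v00, v11, v01)
      k <- k + 2L
    }
  }
  faces
}

#' Closed ellipsoid shell (lat-long triangulation, poles on the z axis)
#' @noRd
ellipsoid_surface <- function(center, radii, edge) {
  stopifnot(all(radii > 0), edge > 0)
  rbar <- mean(radii)
  n_th <- max(6L, as.integer(ceiling(pi * rbar / edge)))
  n_ph <- even_at_least(2 * pi * max(radii[1], radii[2]) / edge, 8)
  theta <- pi * seq_len(n_th - 1) / n_th        # interior rings
  phi <- 2 * pi * (seq_len(n_ph) - 1) / n_ph
  ring <- function(th) cbind(
    center[1] + radii[1] * sin(th) * cos(phi),
    center[2] + radii[2] * sin(th) * sin(phi),
    center[3] + radii[3] * cos(th)
  )
  verts <- do.call(rbind, lapply(theta, ring))
  top <- center + c(0, 0, radii[3])
  bot <- center - c(0, 0, radii[3])
  verts <- rbind(verts, top, bot)
  i_top <- nrow(verts) - 1L; i_bot <- nrow(verts)
  idx <- matrix(seq_len((n_th - 1) * n_ph), nrow = n_th - 1, ncol = n_ph, byrow = TRUE)
  faces <- grid_faces(idx, wrap_j = TRUE)
  # pole fans
  first <- idx[1, ]; last <- idx[n_th - 1, ]
  fan_top <- cbind(rep(i_top, n_ph), first, c(first[-1], first[1]))
  fan_bot <- cbind(rep(i_bot, n_ph), c(last[-1], last[1]), last)
  faces <- rbind(faces, fan_top, fan_bot)
  # enforce outward orientation (positive signed volume contribution)
  faces <- orient_outward(verts, faces, center)
  list(vertices = verts, faces = faces, boundary = list(),
       attrs = list(pole_top = i_top, pole_bottom = i_bot))
}

orient_outward <- function(verts, faces, center) {
  a <- verts[faces[, 2], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 3], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
  n <- cross3(a, b)
  ctr <- (verts[faces[, 1], , drop = FALSE] + verts[faces[, 2], , drop = FALSE] +
            verts[faces[, 3], , drop = FALSE]) / 3
  out <- ctr - matrix(center, nrow(faces), 3, byrow = TRUE)
  flip <- rowSums(n * out) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  faces
}

#' Tube along a parametric centerline with elliptical cross-section.
#'
#' `cl_fun(s)` maps s in [0,1] to a 1x3 point. Ends can be capped with a
#' fan (closed apex). Uncapped ends contribute boundary loops.
#' @noRd
tube_surface <- function(cl_fun, rx, ry, edge, cap_start = FALSE, cap_end = FALSE) {
  stopifnot(rx > 0, ry > 0, edge > 0)
  sfine <- seq(0, 1, length.out = 200)
  pts <- cl_fun(sfine)
  L <- sum(rownorms(diff(pts)))
  n_s <- max(5L, as.integer(ceiling(L / edge)) + 1L)
  perim <- pi * (3 * (rx + ry) - sqrt((3 * rx + ry) * (rx + 3 * ry)))
  # tubes carry strongly curved, ovalising walls: resolve the circumference
  # finer than the axial direction
  n_c <- even_at_least(perim / (0.6 * edge), 8)
  s <- seq(0, 1, length.out = n_s)
  c0 <- cl_fun(s)
  eps <- 1e-5
  tang <- cl_fun(pmin(s + eps, 1)) - cl_fun(pmax(s - eps, 0))
  tang <- tang / rownorms(tang)
  ex <- c(1, 0, 0)
  alpha <- 2 * pi * (seq_len(n_c) - 1) / n_c
  verts <- matrix(0, n_s * n_c, 3)
  for (i in seq_len(n_s)) {
    t <- tang[i, ]
    nlat <- ex - sum(ex * t) * t
    nlat <- unitize(nlat)
    bvec <- cross3(t, nlat)[1, ]
    ring <- matrix(c0[i, ], n_c, 3, byrow = TRUE) +
      rx * cos(alpha) %o% nlat + ry * sin(alpha) %o% bvec
    verts[((i - 1) * n_c + 1):(i * n_c), ] <- ring
  }
  idx <- matrix(seq_len(n_s * n_c), nrow = n_s, ncol = n_c, byrow = TRUE)
  faces <- grid_faces(idx, wrap_j = TRUE)
  boundary <- list()
  attrs <- list(s_param = rep(s, each = n_c))
  # caps are domed (apex raised along the axis) so the closed end has
  # geometric transverse stiffness like a real organ vault, not a flat disk
  dome <- 0.35 * min(rx, ry)
  if (cap_start) {
    verts <- rbind(verts, c0[1, ] - dome * tang[1, ]); ci <- nrow(verts)
    ring1 <- idx[1, ]
    faces <- rbind(faces, cbind(rep(ci, n_c), c(ring1[-1], ring1[1]), ring1))
    attrs$cap_start <- ci
    attrs$s_param <- c(attrs$s_param, 0)
  } else {
    boundary <- c(boundary, list(start = idx[1, ]))
  }
  if (cap_end) {
    verts <- rbind(verts, c0[n_s, ] + dome * tang[n_s, ]); ci <- nrow(verts)
    ringN <- idx[n_s, ]
    faces <- rbind(faces, cbind(rep(ci, n_c), ringN, c(ringN[-1], ringN[1])))
    attrs$cap_end <- ci
    attrs$s_param <- c(attrs$s_param, 1)
  } else {
    boundary <- c(boundary, list(end = idx[n_s, ]))
  }
  list(vertices = verts, faces = faces, boundary = boundary, attrs = attrs)
}

#' Basin-shaped membrane spanning a rim curve (polar triangulation).
#'
#' `rim_fun(theta)` maps angles to 3D rim points; the interior blends
#' linearly in plan view towards `center` and quadratically in height,
#' producing a smooth bowl that sags below the rim.
#' @noRd
basin_surface <- function(rim_fun, center, edge) {
  stopifnot(edge > 0)
  th_fine <- 2 * pi * (0:199) / 200
  rim_pts <- rim_fun(th_fine)
  rbar <- mean(rownorms(sweep(rim_pts[, 1:2, drop = FALSE], 2, center[1:2])))
  n_t <- even_at_least(2 * pi * rbar / edge, 12)
  n_r <- max(3L, as.integer(ceiling(rbar / edge)))
  theta <- 2 * pi * (seq_len(n_t) - 1) / n_t
  rim <- rim_fun(theta)
  rho <- seq_len(n_r) / n_r
  verts <- matrix(0, n_r * n_t, 3)
  for (i in seq_len(n_r)) {
    r <- rho[i]
    ring <- cbind(
      center[1] + r * (rim[, 1] - center[1]),
      center[2] + r * (rim[, 2] - center[2]),
      center[3] + r^2 * (rim[, 3] - center[3])
    )
    verts[((i - 1) * n_t + 1):(i * n_t), ] <- ring
  }
  verts <- rbind(verts, center)
  ci <- nrow(verts)
  idx <- matrix(seq_len(n_r * n_t), nrow = n_r, ncol = n_t, byrow = TRUE)
  faces <- grid_faces(idx, wrap_j = TRUE)
  ring1 <- idx[1, ]
  faces <- rbind(faces, cbind(rep(ci, n_t), ring1, c(ring1[-1], ring1[1])))
  list(vertices = verts, faces = faces,
       boundary = list(rim = idx[n_r, ]),
       attrs = list(center = ci, rim = idx[n_r, ]))
}

#' Ruled sheet between two parametric rails with lateral half-width.
#'
#' The sheet spans a midline curve `cl_fun(v)` laterally in +-x over
#' `half_width`, i.e. a gently curved rectangular membrane.
#' @noRd
sheet_surface <- function(cl_fun, half_width, edge) {
  stopifnot(half_width > 0, edge > 0)
  vfine <- seq(0, 1, length.out = 100)
  L <- sum(rownorms(diff(cl_fun(vfine))))
  n_v <- max(4L, as.integer(ceiling(L / edge)) + 1L)
  n_u <- even_at_least(2 * half_width / edge, 4) + 1L  # odd count: u = 0 column exists
  v <- seq(0, 1, length.out = n_v)
  u <- seq(-half_width, half_width, length.out = n_u)
  mid <- cl_fun(v)
  eps <- 1e-5
  tang <- cl_fun(pmin(v + eps, 1)) - cl_fun(pmax(v - eps, 0))
  tang <- tang / rownorms(tang)
  # gentle lateral camber (normal bow) so the sheet is not a flat strip
  bow <- 0.15 * half_width
  verts <- matrix(0, n_v * n_u, 3)
  for (i in seq_len(n_v)) {
    nrm <- cross3(tang[i, ], c(1, 0, 0))[1, ]
    nrm <- unitize(nrm)
    camber <- bow * (1 - (u / half_width)^2)
    verts[((i - 1) * n_u + 1):(i * n_u), ] <-
      cbind(mid[i, 1] + u, mid[i, 2] + camber * nrm[2], mid[i, 3] + camber * nrm[3])
  }
  idx <- matrix(seq_len(n_v * n_u), nrow = n_v, ncol = n_u, byrow = TRUE)
  faces <- grid_faces(idx, wrap_j = FALSE)
  list(vertices = verts, faces = faces,
       boundary = list(v0 = idx[1, ], v1 = idx[n_v, ],
                       u0 = idx[, 1], u1 = idx[, n_u]),
       attrs = list())
}
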