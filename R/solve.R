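# Quasi-static geometrically nonlinear solver: incremental dead loading,
# damped Newton iterations with an energy line search, Levenberg-style
# regularisation when the tangent is rank-deficient (flat membranes, slack
# filaments), and load-step bisection on divergence.

assemble_stiffness <- function(model, dm, u, cache = NULL) {
  if (is.null(cache)) cache <- build_assembly_cache(model, dm)
  mesh <- model$mesh
  x <- mesh$nodes + u
  h <- model$fd_step
  tri <- mesh$tri
  a <- x[tri[, 2], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  b <- x[tri[, 3], , drop = FALSE] - x[tri[, 1], , drop = FALSE]
  K9 <- membrane_stiffness_blocks(model$prec_mem, a, b, h)
  tx <- matrix(K9, nrow(tri), 81)[cache$keep9]
  pt <- model$prec_truss
  if (pt$n > 0) {
    tr <- mesh$truss
    d <- x[tr[, 2], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
    K6 <- truss_stiffness_blocks(pt, d, h)
    tx <- c(tx, matrix(K6, pt$n, 36)[cache$keep6])
  }
  ph <- model$prec_hinge
  if (!is.null(ph) && ph$n > 0) {
    K12 <- hinge_stiffness_blocks(ph, x, h)
    tx <- c(tx, matrix(K12, ph$n, 144)[cache$keep12])
  }
  K <- Matrix::sparseMatrix(i = cache$ti, j = cache$tj, x = tx,
                            dims = c(dm$n_red, dm$n_red))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# precompute the triplet index vectors of the global tangent (they depend
# only on connectivity and the dof map, not on the state)
build_assembly_cache <- function(model, dm) {
  mesh <- model$mesh
  tri <- mesh$tri
  m <- nrow(tri)
  D9 <- matrix(0L, m, 9)
  for (l in 1:3) for (cpt in 1:3) D9[, 3 * (l - 1) + cpt] <- dm$map[tri[, l], cpt]
  ii <- D9[, rep(1:9, times = 9)]
  jj <- D9[, rep(1:9, each = 9)]
  keep9 <- ii > 0 & jj > 0
  ti <- ii[keep9]; tj <- jj[keep9]
  keep6 <- NULL; keep12 <- NULL
  pt <- model$prec_truss
  if (pt$n > 0) {
    tr <- mesh$truss
    D6 <- matrix(0L, pt$n, 6)
    for (l in 1:2) for (cpt in 1:3) D6[, 3 * (l - 1) + cpt] <- dm$map[tr[, l], cpt]
    ii6 <- D6[, rep(1:6, times = 6)]
    jj6 <- D6[, rep(1:6, each = 6)]
    keep6 <- ii6 > 0 & jj6 > 0
    ti <- c(ti, ii6[keep6]); tj <- c(tj, jj6[keep6])
  }
  ph <- model$prec_hinge
  if (!is.null(ph) && ph$n > 0) {
    D12 <- matrix(0L, ph$n, 12)
    for (l in 1:4) for (cpt in 1:3)
      D12[, 3 * (l - 1) + cpt] <- dm$map[ph$idx[, l], cpt]
    ii12 <- D12[, rep(1:12, times = 12)]
    jj12 <- D12[, rep(1:12, each = 12)]
    keep12 <- ii12 > 0 & jj12 > 0
    ti <- c(ti, ii12[keep12]); tj <- c(tj, jj12[keep12])
  }
  list(ti = ti, tj = tj, keep9 = keep9, keep6 = keep6, keep12 = keep12)
}

# LDL' factorisation of K + mu I; LDL' succeeds on indefinite matrices
# (no partial-factor allocations), definiteness is checked on the D
# diagonal, and a fresh factorisation is used each time (the in-place
# CHMfactor update of this Matrix build retains native memory).
ldl_solve <- function(K, mu, rhs) {
  L <- suppressWarnings(tryCatch(
    Matrix::Cholesky(K, LDL = TRUE, perm = TRUE, Imult = mu),
    error = function(e) NULL))
  if (is.null(L)) return(NULL)
  dmin <- tryCatch(min(Matrix::diag(L)), error = function(e) -1)
  if (!is.finite(dmin) || dmin <= 0) return(NULL)
  d <- tryCatch(as.numeric(Matrix::solve(L, rhs)), error = function(e) NULL)
  if (is.null(d) || !all(is.finite(d))) NULL else d
}

newton_increment <- function(model, dm, fext_red, u_red, lf, tol, max_iter,
                             cache = NULL) {
  energy_at <- function(ur) {
    uf <- expand_disp(dm, ur)
    x <- model$mesh$nodes + uf
    en <- internal_force(model, x, want_energy = TRUE)$energy
    en - lf * sum(fext_red * ur)
  }
  res_hist <- numeric(0)
  mu <- 0  # Levenberg shift, persistent across iterations
  for (it in seq_len(max_iter)) {
    uf <- expand_disp(dm, u_red)
    fi <- internal_force(model, model$mesh$nodes + uf)$f
    r <- reduce_force(dm, fi) - lf * fext_red
    rn <- sqrt(sum(r^2))
    res_hist <- c(res_hist, rn)
    if (!is.finite(rn)) return(list(ok = FALSE, u = u_red, res = res_hist))
    if (rn <= tol) return(list(ok = TRUE, u = u_red, res = res_hist, iters = it))
    K <- assemble_stiffness(model, dm, uf, cache)
    mu0 <- 1e-7 * max(abs(Matrix::diag(K)), 1e-12)
    e0 <- energy_at(u_red)
    accepted <- FALSE
    for (attempt in 1:12) {
      delta <- ldl_solve(K, mu, -r)
      slope <- if (is.null(delta)) NA_real_ else sum(r * delta)
      if (is.null(delta) || !is.finite(slope) || slope >= 0) {
        mu <- if (mu == 0) mu0 else mu * 10
        next
      }
      # Armijo backtracking on the total potential energy; on acceptance
      # at full step, expand the step while the energy keeps dropping
      # (accelerates very soft, nearly force-free drift directions)
      alpha <- 1
      for (ls in 1:12) {
        utry <- u_red + alpha * delta
        etry <- energy_at(utry)
        if (is.finite(etry) && etry <= e0 + 1e-4 * alpha * slope) {
          if (alpha == 1) {
            ebest <- etry
            while (alpha < 8) {
              e2 <- energy_at(u_red + 2 * alpha * delta)
              if (!is.finite(e2) || e2 >= ebest) break
              alpha <- 2 * alpha; ebest <- e2
            }
            utry <- u_red + alpha * delta
          }
          u_red <- utry; accepted <- TRUE; break
        }
        alpha <- alpha / 2
      }
      if (accepted) {
        mu <- if (mu <= mu0) 0 else mu / 10
        break
      }
      mu <- if (mu == 0) mu0 else mu * 10
    }
    if (!accepted) {
      # energy landscape too irregular at this increment: report failure so
      # the caller bisects the load step
      return(list(ok = FALSE, u = u_red, res = res_hist))
    }
  }
  # final residual check after max_iter updates
  uf <- expand_disp(dm, u_red)
  fi <- internal_force(model, model$mesh$nodes + uf)$f
  rn <- sqrt(sum((reduce_force(dm, fi) - lf * fext_red)^2))
  res_hist <- c(res_hist, rn)
  list(ok = rn <= tol, u = u_red, res = res_hist, iters = max_iter)
}

#' Solve a quasi-static load case
#'
#' Applies the external tractions in incremental load steps; each increment
#' is solved by damped Newton iterations (analytic residual, element
#' tangents consistent with it) with an energy line search. A diverging
#' increment is bisected up to 5 times before the solve is reported as a
#' structured failure carrying the residual history. Displacements of fixed
#' nodes are exactly zero; tied node pairs share degrees of freedom exactly.
#'
#' @param model an [fe_model()].
#' @param case a [load_case()].
#' @param initial_guess optional full displacement matrix (n x 3) used as
#'   the starting state.
#' @param presmooth_iterations when a starting state is supplied (e.g. a
#'   solution interpolated from a coarser mesh), run this many limited-memory
#'   BFGS iterations on the total potential energy before the Newton solve.
#'   Interpolated states carry mesh-scale artifacts that make the initial
#'   residual enormous; the cheap first-order smoothing removes them.
#' @return an object of class `simulation_result` with fields
#'   `displacement` (n x 3 mm), `converged`, `residual_history`,
#'   `reactions` (n x 3 N, nonzero only at fixed dofs), `steps` (tibble).
#' @export
solve_quasi_static <- function(model, case, initial_guess = NULL,
                               presmooth_iterations = 0) {
  stopifnot(inherits(model, "fe_model"), inherits(case, "load_case"))
  dm <- build_dofmap(model, case)
  if (dm$n_red == nrow(model$mesh$nodes) * 3)
    abort_model("no fixed set is active: rigid-body modes present")
  fext <- external_force(model, case)
  fext_red <- reduce_force(dm, fext)
  cache <- build_assembly_cache(model, dm)
  u_red <- numeric(dm$n_red)
  if (!is.null(initial_guess)) {
    sel <- dm$map > 0
    u_red[dm$map[sel]] <- initial_guess[sel]
    if (presmooth_iterations > 0) {
      en <- function(v) {
        uf <- expand_disp(dm, v)
        internal_force(model, model$mesh$nodes + uf, want_energy = TRUE)$energy -
          sum(fext_red * v)
      }
      gr <- function(v) {
        uf <- expand_disp(dm, v)
        reduce_force(dm, internal_force(model, model$mesh$nodes + uf)$f) -
          fext_red
      }
      u_red <- stats::optim(u_red, en, gr, method = "L-BFGS-B",
                            control = list(maxit = presmooth_iterations,
                                           lmm = 25, factr = 1e5))$par
    }
    # a good starting state usually allows solving at full load directly;
    # fall back to cold incremental continuation if it does not
    nt <- newton_increment(model, dm, fext_red, u_red, 1,
                           case$newton_tol, case$max_newton_iter, cache)
    if (nt$ok) {
      steps <- list(tibble::tibble(load_factor = 1, iterations = nt$iters,
                                   final_residual = nt$res[length(nt$res)]))
      return(new_simulation_result(model, dm, nt$u, fext, 1, converged = TRUE,
                                   res_history = list(nt$res), steps = steps,
                                   n_bisect = 0L, tol = case$newton_tol))
    }
    u_red <- numeric(dm$n_red)
  }
  # quadratic load ramp: the unstressed structure is soft (membranes carry
  # no geometric stiffness yet), so early increments are small and later
  # ones larger; failed increments are bisected (max 5 bisections)
  n <- case$n_load_steps
  pending <- unique(c((seq_len(n) / n)^2, 1))
  lf <- 0
  n_bisect <- 0L
  res_history <- list()
  steps <- list()
  while (length(pending)) {
    target <- pending[1]
    nt <- newton_increment(model, dm, fext_red, u_red, target,
                           case$newton_tol, case$max_newton_iter, cache)
    if (nt$ok) {
      lf <- target
      u_red <- nt$u
      pending <- pending[-1]
      res_history[[length(res_history) + 1]] <- nt$res
      steps[[length(steps) + 1]] <- tibble::tibble(
        load_factor = lf, iterations = nt$iters,
        final_residual = nt$res[length(nt$res)])
    } else {
      n_bisect <- n_bisect + 1L
      res_history[[length(res_history) + 1]] <- nt$res
      if (n_bisect > 5L) {
        return(new_simulation_result(model, dm, u_red, fext, lf,
                                     converged = FALSE,
                                     res_history = res_history,
                                     steps = steps, n_bisect = n_bisect,
                                     tol = case$newton_tol))
      }
      pending <- c((lf + target) / 2, pending)
    }
  }
  out <- new_simulation_result(model, dm, u_red, fext, 1, converged = TRUE,
                               res_history = res_history, steps = steps,
                               n_bisect = n_bisect, tol = case$newton_tol)
  gc(FALSE)  # large per-iteration temporaries (tangents, factors)
  out
}

new_simulation_result <- function(model, dm, u_red, fext, lf, converged,
                                  res_history, steps, n_bisect, tol) {
  u <- expand_disp(dm, u_red)
  fi <- internal_force(model, model$mesh$nodes + u)$f
  reactions <- matrix(0, nrow(u), 3)
  reactions[dm$fixed] <- (fi - lf * fext)[dm$fixed]
  structure(list(
    displacement = u,
    converged = converged,
    load_factor = lf,
    residual_history = res_history,
    reactions = reactions,
    steps = if (length(steps)) dplyr::bind_rows(steps) else
      tibble::tibble(load_factor = numeric(), iterations = integer(),
                     final_residual = numeric()),
    n_bisections = n_bisect,
    newton_tol = tol
  ), class = "simulation_result")
}

#' Sum of reaction forces over a node set
#'
#' @param result a `simulation_result`.
#' @param model the `fe_model` that produced it.
#' @param set node-set name (default: all fixed nodes).
#' @return 3-vector of force components (N).
#' @export
reaction_sum <- function(result, model, set = NULL) {
  R <- result$reactions
  if (is.null(set)) return(colSums(R))
  colSums(R[resolve_set(model$mesh, set), , drop = FALSE])
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", if (x$converged) "converged" else "NOT converged",
      "at load factor", format(x$load_factor), "\n")
  cat("  increments:", nrow(x$steps), " bisections:", x$n_bisections,
      " max |u|:", format(max(rownorms(x$displacement)), digits = 4), "mm\n")
  invisible(x)
}
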