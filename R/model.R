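#' Assemble a finite-element model from a mesh and materials
#'
#' Binds the mesh to its material assignment table and precomputes the
#' reference-configuration element quantities used by the solver.
#'
#' @param mesh an [mesh_geometry()] result (class `fe_mesh`).
#' @param materials a named material table, see [default_materials()].
#' @param ties optional n x 2 matrix of node pairs whose displacements are
#'   constrained equal (see [apply_tie_links()]); defaults to the tie pairs
#'   recorded on the mesh (ligament attachments).
#' @param membrane_stabilization blending factor `eps` of the membrane
#'   energy `(1 - eps) W_relaxed + eps W_full`. The default `eps = 1` uses
#'   the full biaxial law everywhere (the standard thin-shell model:
#'   compressed regions buckle smoothly against the bending stiffness).
#'   Values below 1 blend toward the tension-field (wrinkling-relaxed)
#'   energy, which ignores compressive membrane stress; taut states are
#'   unaffected by the blend.
#' @param bending include the discrete-hinge bending energy of the thin
#'   shells (plate modulus `E t^3 / (12 (1 - nu^2))` per structure). The
#'   reference dihedral angles are stress-free, so the rest shape is
#'   unchanged.
#' @return an object of class `fe_model`.
#' @export
fe_model <- function(mesh, materials = default_materials(), ties = mesh$ties,
                     membrane_stabilization = 1, bending = TRUE) {
  stopifnot(inherits(mesh, "fe_mesh"))
  validate_fe_mesh(mesh)
  model <- structure(list(mesh = mesh, materials = materials, ties = ties,
                          membrane_stabilization = membrane_stabilization,
                          bending = bending),
                     class = "fe_model")
  finalize_model(model)
}

finalize_model <- function(model) {
  mesh <- model$mesh
  model$prec_mem <- precompute_membranes(mesh$nodes, mesh$tri,
                                         mesh$tri_thickness, mesh$tri_label,
                                         model$materials,
                                         stab = model$membrane_stabilization %||% 1)
  model$prec_truss <- precompute_trusses(mesh, model$materials)
  model$prec_hinge <- if (isTRUE(model$bending %||% TRUE))
    precompute_hinges(mesh$nodes, mesh$tri, mesh$tri_thickness,
                      mesh$tri_label, model$materials) else list(n = 0L)
  charlen <- mean(sqrt(model$prec_mem$A0))
  if (!is.finite(charlen)) charlen <- mean(model$prec_truss$L0 %||% 1)
  if (!is.finite(charlen)) charlen <- 1
  model$fd_step <- 1e-6 * (1 + charlen)
  model
}

#' Constrain node pairs to move together (tie links)
#'
#' Tied pairs share displacement degrees of freedom exactly via master-slave
#' elimination in the solver; a pair tying a node to itself is a no-op.
#'
#' @param model an `fe_model`.
#' @param pairs integer matrix (k x 2) of node indices.
#' @return the model with the tie constraints recorded.
#' @export
apply_tie_links <- function(model, pairs) {
  stopifnot(inherits(model, "fe_model"))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  n <- nrow(model$mesh$nodes)
  if (any(pairs < 1 | pairs > n)) abort_model("tie node index out of range")
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) model$ties <- rbind(model$ties, pairs)
  model
}

#' Define a quasi-static load case
#'
#' @param tractions a named list of loads. Each load is a list with
#'   `node_set` (name of a mesh node set), `direction` (unit 3-vector),
#'   `magnitude` (surface traction in MPa for `type = "traction"`, or a
#'   total force in N for `type = "nodal"` split equally over the set).
#' @param fixed_sets character vector of node-set names fixed in all
#'   components (Encastre), or a list whose elements are
#'   `list(set = name, comps = c("x","y","z"))` for partial fixity.
#' @param n_load_steps number of load increments (>= 1).
#' @param newton_tol Newton residual norm tolerance (N).
#' @param max_newton_iter maximum Newton iterations per increment.
#' @return an object of class `load_case`.
#' @export
load_case <- function(tractions = list(),
                      fixed_sets = "fixed_boundary",
                      n_load_steps = 10,
                      newton_tol = 1e-6,
                      max_newton_iter = 60) {
  if (n_load_steps < 1) abort_param("n_load_steps must be >= 1")
  if (newton_tol <= 0) abort_param("newton_tol must be > 0")
  for (nm in names(tractions)) {
    tr <- tractions[[nm]]
    if (abs(vnorm(tr$direction) - 1) > 1e-9)
      abort_param(paste("traction", nm, "direction must be unit-norm"))
    if (tr$magnitude < 0)
      abort_param(paste("traction", nm, "magnitude must be >= 0"))
    tractions[[nm]]$type <- tr$type %||% "traction"
  }
  structure(list(tractions = tractions, fixed_sets = fixed_sets,
                 n_load_steps = as.integer(n_load_steps),
                 newton_tol = newton_tol,
                 max_newton_iter = as.integer(max_newton_iter)),
            class = "load_case")
}

resolve_set <- function(mesh, name) {
  s <- mesh$node_sets[[name]]
  if (is.null(s)) abort_model(paste("unknown node set:", name))
  s
}

# external nodal force matrix (n x 3, N) at unit load factor
external_force <- function(model, case) {
  mesh <- model$mesh
  f <- matrix(0, nrow(mesh$nodes), 3)
  for (nm in names(case$tractions)) {
    tr <- case$tractions[[nm]]
    ids <- resolve_set(mesh, tr$node_set)
    if (identical(tr$type, "nodal")) {
      per <- tr$magnitude / length(ids)
      f[ids, ] <- f[ids, ] + matrix(tr$direction * per, length(ids), 3, byrow = TRUE)
    } else {
      inset <- logical(nrow(mesh$nodes)); inset[ids] <- TRUE
      tri_in <- which(inset[mesh$tri[, 1]] & inset[mesh$tri[, 2]] &
                        inset[mesh$tri[, 3]])
      if (!length(tri_in))
        abort_model(paste("traction", nm, "node set spans no complete triangles"))
      ar <- triangle_areas(mesh$nodes, mesh$tri[tri_in, , drop = FALSE])
      for (k in 1:3) {
        contrib <- (tr$magnitude * ar / 3) %o% tr$direction
        f <- accumulate_force(f, mesh$tri[tri_in, k], contrib)
      }
    }
  }
  f
}

# --- degree-of-freedom mapping: fixed dofs eliminated, tied nodes merged ---

comp_index <- c(x = 1L, y = 2L, z = 3L)

build_dofmap <- function(model, case) {
  mesh <- model$mesh
  n <- nrow(mesh$nodes)
  fixed <- matrix(FALSE, n, 3)
  fs <- case$fixed_sets
  if (is.character(fs)) fs <- lapply(fs, function(s) list(set = s, comps = c("x", "y", "z")))
  for (entry in fs) {
    ids <- resolve_set(mesh, entry$set)
    fixed[ids, comp_index[entry$comps %||% c("x", "y", "z")]] <- TRUE
  }
  # union-find over tied nodes
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (!is.null(model$ties) && nrow(model$ties)) {
    for (k in seq_len(nrow(model$ties))) {
      a <- find(model$ties[k, 1]); b <- find(model$ties[k, 2])
      if (a != b) parent[b] <- a
    }
    reps <- vapply(seq_len(n), find, integer(1))
    # a group containing any fixed component is fixed in that component;
    # tying two fixed nodes with a nonzero gap is a constraint conflict
    for (k in seq_len(nrow(model$ties))) {
      i <- model$ties[k, 1]; j <- model$ties[k, 2]
      if (any(fixed[i, ]) && any(fixed[j, ]) &&
          vnorm(mesh$nodes[i, ] - mesh$nodes[j, ]) > 1e-12)
        abort_model("tie constraint conflict: both nodes fixed with nonzero gap")
    }
    gfix <- rowsum(fixed + 0, reps, reorder = FALSE) > 0
    grows <- as.integer(rownames(gfix))
    fixed_g <- matrix(FALSE, n, 3)
    fixed_g[grows, ] <- gfix
    fixed <- fixed_g[reps, , drop = FALSE]
  } else {
    reps <- seq_len(n)
  }
  # reduced dof numbering on representative (node, comp) pairs
  key <- (reps - 1L) * 3L
  dofmap <- matrix(0L, n, 3)
  lookup <- new.env(hash = TRUE)
  next_id <- 0L
  rep_free <- !fixed
  rep_ids <- matrix(0L, n, 3)
  for (cpt in 1:3) {
    urep <- unique(reps[rep_free[, cpt]])
    ids <- seq.int(next_id + 1L, length.out = length(urep))
    next_id <- next_id + length(urep)
    idx <- integer(n); idx[urep] <- ids
    sel <- rep_free[, cpt]
    dofmap[sel, cpt] <- idx[reps[sel]]
  }
  list(map = dofmap, n_red = next_id, fixed = fixed, reps = reps)
}

# reduce a full n x 3 force to the reduced vector (summing tied groups)
reduce_force <- function(dm, f) {
  sel <- dm$map > 0
  v <- numeric(dm$n_red)
  idx <- dm$map[sel]
  s <- rowsum(f[sel], idx, reorder = FALSE)
  v[as.integer(rownames(s))] <- s
  v
}

# expand a reduced displacement vector to full n x 3 (fixed dofs zero)
expand_disp <- function(dm, u_red) {
  u <- matrix(0, nrow(dm$map), 3)
  sel <- dm$map > 0
  u[sel] <- u_red[dm$map[sel]]
  u
}

#' Global residual vector of a model state
#'
#' residual = internal forces - load_factor * external tractions, with
#' fixed degrees of freedom eliminated and tied groups summed. At zero
#' displacement under zero load the residual is identically zero.
#'
#' @param model an `fe_model`.
#' @param case a `load_case`.
#' @param u full displacement matrix (n x 3, mm).
#' @param load_factor scaling of the external loads in [0, 1].
#' @return reduced residual vector (N).
#' @export
assemble_residual <- function(model, case, u, load_factor = 1) {
  dm <- build_dofmap(model, case)
  fext <- external_force(model, case)
  x <- model$mesh$nodes + u
  fi <- internal_force(model, x)$f
  reduce_force(dm, fi - load_factor * fext)
}

#' Total potential energy of a model state
#'
#' Internal strain energy minus the work of the (dead) external loads,
#' in N mm. The solver's converged states are stationary points.
#'
#' @inheritParams assemble_residual
#' @return scalar energy (N mm).
#' @export
total_potential_energy <- function(model, case, u, load_factor = 1) {
  fext <- external_force(model, case)
  x <- model$mesh$nodes + u
  internal_force(model, x, want_energy = TRUE)$energy -
    load_factor * sum(fext * u)
}

#' @export
print.fe_model <- function(x, ...) {
  cat("<fe_model>", nrow(x$mesh$nodes), "nodes,", n_elements(x$mesh), "elements\n")
  invisible(x)
}
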