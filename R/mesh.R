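# Meshing of a pelvic_geometry into a global finite-element mesh:
# membrane triangles for all organ surfaces, truss chains for ligaments,
# and distributed elastic link trusses that carry the fascia-mediated
# load path between adjacent organ walls (no direct organ contact).

# resample a polyline to roughly uniform spacing, keeping both endpoints
resample_polyline <- function(pts, spacing) {
  seg <- rownorms(diff(pts))
  total <- sum(seg)
  n <- max(2L, as.integer(ceiling(total / spacing)))
  targets <- seq(0, total, length.out = n + 1L)
  cum <- c(0, cumsum(seg))
  out <- matrix(0, n + 1L, 3)
  for (k in seq_along(targets)) {
    t <- targets[k]
    i <- findInterval(t, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(seg))
    f <- if (seg[i] > 0) (t - cum[i]) / seg[i] else 0
    out[k, ] <- pts[i, ] + f * (pts[i + 1L, ] - pts[i, ])
  }
  out
}

# nearest node in `pool` (n x 3) for each row of `query`; returns indices
# into pool and distances
nearest_nodes <- function(query, pool) {
  idx <- integer(nrow(query)); d <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    dd <- rownorms(pool - matrix(query[i, ], nrow(pool), 3, byrow = TRUE))
    idx[i] <- which.min(dd)
    d[i] <- dd[idx[i]]
  }
  list(index = idx, dist = d)
}

default_thickness <- function() {
  c(vagina = 3, bladder = 3, rectum = 3, pelvic_floor = 2,
    fascia_pubocervical = 1, fascia_endopelvic = 1)
}

# cross-section areas (mm^2) for truss structures
default_truss_areas <- function() {
  c(sacrospinous = 40, uterosacral = 10, cardinal = 10, round = 5,
    broad = 5, ATFP = 5, suture = 0.2)
}

# total cross-section (mm^2) of each distributed link family; the total is
# divided over the links actually created, so the aggregate tether
# stiffness is independent of the mesh resolution
default_link_totals <- function() {
  c(link_fascia_pubocervical_bladder = 60,
    link_fascia_pubocervical_vagina = 50,
    link_fascia_endopelvic_vagina = 50,
    link_fascia_endopelvic_rectum = 60,
    link_vagina_floor = 12,
    link_rectum_floor = 14,
    link_rectum_sacrum = 14,
    link_bladder_floor = 70,
    link_fascia_floor = 7)
}

#' Mesh a pelvic geometry into a finite-element mesh
#'
#' Triangulates every organ surface at the requested edge length, chains the
#' ligament polylines into truss segments, builds the fascia link trusses
#' between adjacent organ walls, and emits the named node and element sets
#' used downstream (boundary conditions, load surfaces, reference points).
#'
#' @param geometry a [build_pelvic_geometry()] result.
#' @param target_edge_length target triangle edge length in mm (defaults to
#'   the geometry's parameter).
#' @param thickness named membrane thickness overrides (mm) per structure.
#' @return an object of class `fe_mesh` with fields `nodes`, `tri`,
#'   `tri_label`, `tri_thickness`, `truss`, `truss_label`, `truss_area`,
#'   `truss_active`, `node_sets`, `elem_sets`, `ligament_chains`.
#' @export
mesh_geometry <- function(geometry,
                          target_edge_length = geometry$params$target_edge_length,
                          thickness = NULL) {
  stopifnot(inherits(geometry, "pelvic_geometry"))
  if (target_edge_length <= 0) abort_param("target_edge_length must be > 0")
  th_tab <- default_thickness()
  if (!is.null(thickness)) th_tab[names(thickness)] <- thickness
  if (any(th_tab <= 0)) abort_param("membrane thickness must be > 0")

  nodes <- NULL
  tri <- NULL; tri_label <- character(); tri_thickness <- numeric()
  node_sets <- list()
  organ_range <- list()
  surf_info <- list()

  for (nm in names(geometry$surface_specs)) {
    surf <- surface_from_spec(geometry$surface_specs[[nm]], target_edge_length)
    areas <- triangle_areas(surf$vertices, surf$faces)
    if (any(areas <= 1e-6))
      abort_geometry(paste("degenerate (zero-area) triangles in surface", nm))
    off <- if (is.null(nodes)) 0L else nrow(nodes)
    nodes <- rbind(nodes, surf$vertices)
    tri <- rbind(tri, surf$faces + off)
    tri_label <- c(tri_label, rep(nm, nrow(surf$faces)))
    tri_thickness <- c(tri_thickness, rep(th_tab[[nm]], nrow(surf$faces)))
    organ_range[[nm]] <- off + seq_len(nrow(surf$vertices))
    node_sets[[paste0("nodes_", nm)]] <- organ_range[[nm]]
    surf_info[[nm]] <- list(offset = off, boundary = surf$boundary,
                            attrs = surf$attrs)
  }

  truss <- NULL; truss_label <- character(); truss_area <- numeric()
  truss_active <- logical()
  truss_ref_len <- numeric()
  tie_pairs <- NULL
  ligament_chains <- list()
  areas_tab <- default_truss_areas()
  link_totals <- default_link_totals()
  add_truss <- function(pairs, label, area, active = TRUE) {
    truss <<- rbind(truss, pairs)
    k <- nrow(pairs)
    truss_label <<- c(truss_label, rep(label, k))
    truss_area <<- c(truss_area, rep(area, k))
    truss_active <<- c(truss_active, rep(active, k))
    truss_ref_len <<- c(truss_ref_len,
                        rownorms(nodes[pairs[, 2], , drop = FALSE] -
                                   nodes[pairs[, 1], , drop = FALSE]))
  }

  lig_spacing <- min(5, target_edge_length)
  bone_nodes <- integer()
  spine_nodes <- integer()
  sacrum_nodes <- integer()
  for (nm in names(geometry$ligaments)) {
    lg <- geometry$ligaments[[nm]]
    # only the sacrospinous ligament needs interior chain nodes (the suture
    # anchor must be placeable along its arc); the other ligaments act as
    # single tension members, avoiding ill-conditioned free cable nodes
    pts <- if (lg$group == "sacrospinous")
      resample_polyline(lg$points, lig_spacing)
    else lg$points[c(1L, nrow(lg$points)), , drop = FALSE]
    off <- nrow(nodes)
    nodes <- rbind(nodes, pts)
    ids <- off + seq_len(nrow(pts))
    pairs <- cbind(ids[-length(ids)], ids[-1])
    add_truss(pairs, lg$group, areas_tab[[lg$group]], active = lg$active)
    ligament_chains[[nm]] <- ids
    node_sets[[paste0("lig_", nm)]] <- ids
    # bone attachments
    if (identical(lg$fixed_end, "both")) {
      bone_nodes <- c(bone_nodes, ids[1], ids[length(ids)])
    } else {
      bone_nodes <- c(bone_nodes, ids[length(ids)])
    }
    if (lg$group == "sacrospinous") {
      spine_nodes <- c(spine_nodes, ids[1])
      sacrum_nodes <- c(sacrum_nodes, ids[length(ids)])
    }
    if (lg$group == "ATFP") spine_nodes <- c(spine_nodes, ids[length(ids)])
    if (lg$group == "uterosacral") sacrum_nodes <- c(sacrum_nodes, ids[length(ids)])
    # proximal attachment into the organ wall: a kinematic tie to the
    # nearest wall node (mesh-resolution independent, unlike a short
    # stiff truss whose stiffness would scale with the edge length)
    if (!is.null(lg$attach_to)) {
      pool_ids <- organ_range[[lg$attach_to]]
      nn <- nearest_nodes(pts[1, , drop = FALSE],
                          nodes[pool_ids, , drop = FALSE])
      tie_pairs <- rbind(tie_pairs, c(ids[1], pool_ids[nn$index]))
    }
  }

  # fascia link trusses: each fascia sheet node connects to the nearest
  # node on each of its two partner organ walls (fascia-mediated load path)
  partners <- list(fascia_pubocervical = c("bladder", "vagina"),
                   fascia_endopelvic = c("vagina", "rectum"))
  link_cutoff <- 30
  # the fascial septa insert on the vaginal walls, not the apex: the vault
  # is suspended by the ligaments alone, so links into the vagina are only
  # formed below the apex region
  apex_z_cut <- geometry$surface_specs$vagina$p2[3] - 14
  for (fs in names(partners)) {
    fids <- organ_range[[fs]]
    for (org in partners[[fs]]) {
      oids <- organ_range[[org]]
      if (org == "vagina") oids <- oids[nodes[oids, 3] <= apex_z_cut]
      nn <- nearest_nodes(nodes[fids, , drop = FALSE],
                          nodes[oids, , drop = FALSE])
      keep <- which(nn$dist <= link_cutoff & nn$dist > 1e-6)
      if (org == "vagina")
        keep <- keep[nodes[fids[keep], 3] <= apex_z_cut]
      if (length(keep)) {
        lab <- paste0("link_", fs, "_", org)
        add_truss(cbind(fids[keep], oids[nn$index[keep]]), lab,
                  link_totals[[lab]] / length(keep))
      }
    }
  }

  # organ-to-floor links: inferior organ rings rest on the pelvic floor
  floor_ids <- organ_range[["pelvic_floor"]]
  link_to_floor <- function(ids, label) {
    if (!length(ids)) return(invisible())
    nn <- nearest_nodes(nodes[ids, , drop = FALSE],
                        nodes[floor_ids, , drop = FALSE])
    keep <- which(nn$dist > 1e-6)
    add_truss(cbind(ids[keep], floor_ids[nn$index[keep]]),
              label, link_totals[[label]] / length(keep))
  }
  vag_info <- surf_info[["vagina"]]
  vag_start <- vag_info$offset + vag_info$boundary$start
  link_to_floor(vag_start, "link_vagina_floor")
  # the rectovaginal septum fuses with the perineal body inferiorly: anchor
  # the endopelvic sheet's lower edge on the pelvic floor
  fep_info <- surf_info[["fascia_endopelvic"]]
  link_to_floor(fep_info$offset + fep_info$boundary$v0, "link_fascia_floor")
  rec_info <- surf_info[["rectum"]]
  rec_start <- rec_info$offset + rec_info$boundary$start
  link_to_floor(rec_start, "link_rectum_floor")
  bl_ids <- organ_range[["bladder"]]
  bc <- geometry$surface_specs$bladder$center
  baz <- geometry$surface_specs$bladder$radii[3]
  bl_bottom <- bl_ids[nodes[bl_ids, 3] < bc[3] - 0.7 * baz]
  link_to_floor(bl_bottom, "link_bladder_floor")

  # superior rectal ring tethered toward the sacrum by fixed anchor stubs
  rec_end <- rec_info$offset + rec_info$boundary$end
  anchor_pts <- nodes[rec_end, , drop = FALSE] +
    matrix(c(0, -10, 5), length(rec_end), 3, byrow = TRUE)
  off <- nrow(nodes)
  nodes <- rbind(nodes, anchor_pts)
  anchor_ids <- off + seq_along(rec_end)
  add_truss(cbind(rec_end, anchor_ids), "link_rectum_sacrum",
            link_totals[["link_rectum_sacrum"]] / length(rec_end))
  bone_nodes <- c(bone_nodes, anchor_ids)
  sacrum_nodes <- c(sacrum_nodes, anchor_ids)

  # fascia bone attachments: anterior pubocervical edge inserts on the pubis
  fpc_info <- surf_info[["fascia_pubocervical"]]
  pubis_edge <- fpc_info$offset + fpc_info$boundary$v0
  bone_nodes <- c(bone_nodes, pubis_edge)

  # named node sets -------------------------------------------------------
  floor_rim <- surf_info[["pelvic_floor"]]$offset +
    surf_info[["pelvic_floor"]]$boundary$rim
  node_sets$pelvic_floor_border <- floor_rim
  lm <- geometry$landmarks
  near_lm <- function(ids, p, r) ids[rownorms(nodes[ids, , drop = FALSE] -
      matrix(p, length(ids), 3, byrow = TRUE)) <= r]
  node_sets$sacrum_coccyx_region <- sort(unique(c(
    sacrum_nodes, near_lm(floor_rim, lm$coccyx_last_joint, 18))))
  node_sets$ischial_spine_region <- sort(unique(c(
    spine_nodes,
    near_lm(floor_rim, lm$ischial_spine_left, 12),
    near_lm(floor_rim, lm$ischial_spine_right, 12))))
  node_sets$bone_attachments <- sort(unique(bone_nodes))
  node_sets$fixed_boundary <- sort(unique(c(
    floor_rim, bone_nodes, node_sets$sacrum_coccyx_region,
    node_sets$ischial_spine_region)))

  vag_ids <- organ_range[["vagina"]]
  svag <- vag_info$attrs$s_param
  node_sets$vagina_upper_surface <- vag_ids[svag >= 0.75]
  node_sets$bladder_top_surface <-
    bl_ids[nodes[bl_ids, 3] >= bc[3] + 0.45 * baz]
  rec_ids <- organ_range[["rectum"]]
  srec <- rec_info$attrs$s_param
  node_sets$rectum_top_surface <- rec_ids[srec >= 0.75]
  # straining load surface on the rectal wall: the band just above the
  # anorectal junction, where the defecation-phase push acts
  node_sets$rectum_wall_surface <- rec_ids[srec >= 0.15 & srec <= 0.6]

  for (rp in names(geometry$reference_probes)) {
    pr <- geometry$reference_probes[[rp]]
    pool <- organ_range[[pr$surface]]
    v <- nearest_midsagittal_vertex(nodes[pool, , drop = FALSE], pr$probe)
    node_sets[[rp]] <- pool[v]
  }

  elem_sets <- list(
    membrane = split(seq_len(nrow(tri)), tri_label),
    truss = split(seq_along(truss_label), truss_label)
  )

  dimnames(nodes) <- NULL
  dimnames(tri) <- NULL
  dimnames(truss) <- NULL
  truss_ref_len <- unname(truss_ref_len)
  mesh <- structure(list(
    nodes = nodes,
    tri = tri, tri_label = tri_label, tri_thickness = tri_thickness,
    truss = truss, truss_label = truss_label, truss_area = truss_area,
    truss_active = truss_active, truss_ref_len = truss_ref_len,
    node_sets = node_sets, elem_sets = elem_sets,
    ligament_chains = ligament_chains,
    ties = tie_pairs,
    target_edge_length = target_edge_length
  ), class = "fe_mesh")
  validate_fe_mesh(mesh)
  mesh
}

#' Construct a finite-element mesh directly
#'
#' Low-level constructor for ad-hoc meshes (patch tests, verification
#' problems). [mesh_geometry()] is the anatomical route.
#'
#' @param nodes n x 3 coordinate matrix (mm).
#' @param tri m x 3 triangle connectivity (may be `NULL`).
#' @param tri_label structure label per triangle (recycled).
#' @param tri_thickness membrane thickness per triangle (mm, recycled).
#' @param truss k x 2 truss connectivity (may be `NULL`).
#' @param truss_label,truss_area,truss_active truss attributes (recycled).
#' @param truss_ref_len reference lengths; default as-built lengths.
#' @param node_sets named list of node index vectors.
#' @return an `fe_mesh`.
#' @export
fe_mesh <- function(nodes, tri = NULL, tri_label = "membrane",
                    tri_thickness = 1, truss = NULL, truss_label = "truss",
                    truss_area = 1, truss_active = TRUE,
                    truss_ref_len = NULL, node_sets = list()) {
  nodes <- matrix(as.numeric(nodes), ncol = 3)
  if (!is.null(tri)) tri <- matrix(as.integer(tri), ncol = 3)
  if (!is.null(truss)) truss <- matrix(as.integer(truss), ncol = 2)
  ntri <- if (is.null(tri)) 0L else nrow(tri)
  ntr <- if (is.null(truss)) 0L else nrow(truss)
  if (ntr > 0 && is.null(truss_ref_len))
    truss_ref_len <- rownorms(nodes[truss[, 2], , drop = FALSE] -
                                nodes[truss[, 1], , drop = FALSE])
  mesh <- structure(list(
    nodes = nodes,
    tri = if (ntri) tri else matrix(integer(0), 0, 3),
    tri_label = rep_len(tri_label, ntri),
    tri_thickness = rep_len(tri_thickness, ntri),
    truss = truss,
    truss_label = rep_len(truss_label, ntr),
    truss_area = rep_len(truss_area, ntr),
    truss_active = rep_len(truss_active, ntr),
    truss_ref_len = if (ntr) truss_ref_len else numeric(0),
    node_sets = node_sets,
    elem_sets = list(
      membrane = if (ntri) split(seq_len(ntri), rep_len(tri_label, ntri)) else list(),
      truss = if (ntr) split(seq_len(ntr), rep_len(truss_label, ntr)) else list()),
    ligament_chains = list(),
    target_edge_length = NA_real_
  ), class = "fe_mesh")
  if (ntri) validate_fe_mesh(mesh)
  mesh
}

triangle_areas <- function(nodes, tri) {
  a <- nodes[tri[, 2], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  b <- nodes[tri[, 3], , drop = FALSE] - nodes[tri[, 1], , drop = FALSE]
  0.5 * rownorms(cross3(a, b))
}

#' Validate finite-element mesh invariants
#'
#' Checks element index validity, strictly positive triangle areas and
#' membrane thicknesses, and nonzero truss reference lengths.
#'
#' @param mesh an `fe_mesh`.
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_fe_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  if (any(mesh$tri < 1 | mesh$tri > n)) abort_model("triangle index out of range")
  if (!is.null(mesh$truss) && any(mesh$truss < 1 | mesh$truss > n))
    abort_model("truss index out of range")
  if (any(triangle_areas(mesh$nodes, mesh$tri) <= 1e-6))
    abort_model("zero-area membrane triangle")
  if (any(mesh$tri_thickness <= 0)) abort_model("non-positive membrane thickness")
  if (!is.null(mesh$truss)) {
    len <- rownorms(mesh$nodes[mesh$truss[, 2], , drop = FALSE] -
                      mesh$nodes[mesh$truss[, 1], , drop = FALSE])
    if (any(len <= 1e-9)) abort_model("zero-length truss element")
  }
  invisible(mesh)
}

#' Total element count of a mesh
#' @param mesh an `fe_mesh`.
#' @return integer count of membrane plus truss elements.
#' @export
n_elements <- function(mesh) {
  nrow(mesh$tri) + if (is.null(mesh$truss)) 0L else nrow(mesh$truss)
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat("<fe_mesh>", nrow(x$nodes), "nodes,", nrow(x$tri), "membrane tris,",
      if (is.null(x$truss)) 0 else nrow(x$truss), "trusses\n")
  cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Interpolate a displacement field onto another mesh
#'
#' Inverse-distance-weighted average over the `k` nearest source nodes,
#' used to transfer a converged coarse-mesh state onto a refined mesh as a
#' solver starting guess. When both meshes come from [mesh_geometry()],
#' supply them directly so the transfer is structure-aware: each target
#' node is interpolated only from source nodes of the same anatomical
#' structure (mixing fields across organ gaps produces a useless guess).
#'
#' @param source an `fe_mesh` (or n x 3 coordinate matrix).
#' @param u n x 3 displacement field on the source.
#' @param target an `fe_mesh` (or m x 3 coordinate matrix).
#' @param k number of nearest neighbours (default 4).
#' @return m x 3 interpolated field.
#' @export
interpolate_displacement <- function(source, u, target, k = 4) {
  s_nodes <- if (inherits(source, "fe_mesh")) source$nodes else source
  t_nodes <- if (inherits(target, "fe_mesh")) target$nodes else target
  out <- matrix(NA_real_, nrow(t_nodes), 3)
  idw <- function(src_idx, tgt_idx) {
    kk <- min(k, length(src_idx))
    for (i in tgt_idx) {
      d2 <- rowSums((s_nodes[src_idx, , drop = FALSE] -
                       matrix(t_nodes[i, ], length(src_idx), 3,
                              byrow = TRUE))^2)
      nb <- src_idx[order(d2)[seq_len(kk)]]
      w <- 1 / pmax(sort(d2)[seq_len(kk)], 1e-12)
      w <- w / sum(w)
      out[i, ] <<- colSums(u[nb, , drop = FALSE] * w)
    }
  }
  if (inherits(source, "fe_mesh") && inherits(target, "fe_mesh")) {
    shared <- intersect(grep("^(nodes_|lig_)", names(source$node_sets),
                             value = TRUE),
                        grep("^(nodes_|lig_)", names(target$node_sets),
                             value = TRUE))
    for (nm in shared)
      idw(source$node_sets[[nm]], target$node_sets[[nm]])
  }
  rest <- which(!is.finite(out[, 1]))
  if (length(rest)) idw(seq_len(nrow(s_nodes)), rest)
  out
}
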