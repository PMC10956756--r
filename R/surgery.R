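# Posterior sacrospinous ligament fixation (SSF): suture filaments from
# the vaginal apex to an anchor point on the sacrospinous ligament at a
# configurable distance from the ischial spine, unilaterally or
# bilaterally. Suture endpoints are shared mesh nodes, i.e. tied exactly
# at both ends; the anchor connects to the fixed bony frame through the
# ligament's own truss chain.

#' Configuration of a sacrospinous fixation
#'
#' @param sides character subset of `c("left", "right")`; empty means no
#'   surgery.
#' @param anchor_distance_mm arc-length distance of the suture anchor from
#'   the ischial spine along the sacrospinous ligament (default 20 mm, the
#'   placement used in the absence of further precision; the study grid is
#'   10 / 20 / 30 mm).
#' @param sutures_per_side number of suture filaments per fixed side
#'   (default 2).
#' @param suture_E suture Young modulus (MPa; stiff filament).
#' @param suture_area suture cross-section (mm^2).
#' @param pretension_strain tightening pre-strain; 0 means the filament's
#'   reference length equals the tied (gap-closed) rest distance.
#' @param apex_spread_mm lateral spread of the distinct vaginal-apex
#'   attachment nodes (default 5 mm).
#' @return an object of class `ssf_config`.
#' @export
ssf_config <- function(sides = character(),
                       anchor_distance_mm = 20,
                       sutures_per_side = 2,
                       suture_E = 1000,
                       suture_area = 0.2,
                       pretension_strain = 0,
                       apex_spread_mm = 5) {
  sides <- unique(as.character(sides))
  if (length(sides) && !all(sides %in% c("left", "right")))
    abort_param("sides must be a subset of {left, right}")
  if (anchor_distance_mm < 0) abort_param("anchor_distance_mm must be >= 0")
  if (sutures_per_side < 1) abort_param("sutures_per_side must be >= 1")
  if (suture_E <= 0 || suture_area <= 0)
    abort_param("suture stiffness and area must be > 0")
  if (pretension_strain < 0) abort_param("pretension_strain must be >= 0")
  structure(list(sides = sides, anchor_distance_mm = anchor_distance_mm,
                 sutures_per_side = as.integer(sutures_per_side),
                 suture_E = suture_E, suture_area = suture_area,
                 pretension_strain = pretension_strain,
                 apex_spread_mm = apex_spread_mm),
            class = "ssf_config")
}

#' Point at a given arc-length distance along a polyline
#'
#' @param points polyline vertex matrix (k x 3).
#' @param distance_mm arc-length distance from the first vertex.
#' @return list with `point`, `nearest_vertex` (index into `points`),
#'   `segment` (index of the containing segment), `arc_length` (total).
#' @export
anchor_on_polyline <- function(points, distance_mm) {
  points <- unname(points)
  seg <- unname(rownorms(diff(points)))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (distance_mm < 0 || distance_mm > total + 1e-9)
    abort_param(sprintf(
      "anchor distance %.1f mm beyond ligament arc length %.1f mm",
      distance_mm, total))
  d <- min(distance_mm, total)
  i <- findInterval(d, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(seg))
  f <- if (seg[i] > 0) (d - cum[i]) / seg[i] else 0
  pt <- points[i, ] + f * (points[i + 1L, ] - points[i, ])
  nearest <- if (abs(d - cum[i]) <= abs(cum[i + 1L] - d)) i else i + 1L
  list(point = pt, nearest_vertex = nearest, segment = i, arc_length = total)
}

#' Place a suture anchor on a sacrospinous ligament
#'
#' The anchor lies on the ligament polyline at the requested arc-length
#' distance from the ischial spine (the polyline's first vertex).
#'
#' @param geometry a `pelvic_geometry`.
#' @param side `"left"` or `"right"`.
#' @param distance_mm arc-length distance from the ischial spine (mm).
#' @return list with `point` (3-vector), `nearest_vertex` (polyline index),
#'   `side`, `distance_mm`, `arc_length`.
#' @export
place_anchor <- function(geometry, side, distance_mm) {
  stopifnot(inherits(geometry, "pelvic_geometry"))
  nm <- paste0("sacrospinous_", side)
  lg <- geometry$ligaments[[nm]]
  if (is.null(lg)) abort_param(paste("no sacrospinous ligament for side", side))
  a <- anchor_on_polyline(lg$points, distance_mm)
  c(a[c("point", "nearest_vertex", "arc_length")],
    list(side = side, distance_mm = distance_mm))
}

# find the mesh truss row connecting the ordered pair (i, j)
find_truss_row <- function(mesh, i, j) {
  hit <- which((mesh$truss[, 1] == i & mesh$truss[, 2] == j) |
                 (mesh$truss[, 1] == j & mesh$truss[, 2] == i))
  if (!length(hit)) abort_model("ligament chain segment not found in mesh")
  hit[1]
}

# ensure a mesh node exists exactly at arc distance `d` along a ligament
# chain; splits the containing truss segment when needed. Returns
# list(mesh, node).
anchor_node_on_chain <- function(mesh, chain_name, d) {
  chain <- mesh$ligament_chains[[chain_name]]
  pts <- mesh$nodes[chain, , drop = FALSE]
  seg <- unname(rownorms(diff(pts)))
  cum <- c(0, cumsum(seg))
  if (d < 0 || d > cum[length(cum)] + 1e-9)
    abort_param("anchor distance beyond meshed ligament arc length")
  # reuse an existing chain node if the anchor lands on one
  hit <- which(abs(cum - d) <= 1e-9)
  if (length(hit)) return(list(mesh = mesh, node = chain[hit[1]]))
  i <- findInterval(d, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(seg))
  f <- (d - cum[i]) / seg[i]
  pt <- pts[i, ] + f * (pts[i + 1L, ] - pts[i, ])
  row <- find_truss_row(mesh, chain[i], chain[i + 1L])
  new_id <- nrow(mesh$nodes) + 1L
  mesh$nodes <- rbind(mesh$nodes, matrix(pt, 1, 3))
  lab <- mesh$truss_label[row]; ar <- mesh$truss_area[row]
  act <- mesh$truss_active[row]
  # replace the split segment by its two halves
  mesh$truss[row, ] <- c(chain[i], new_id)
  mesh$truss_ref_len[row] <- vnorm(pt - mesh$nodes[chain[i], ])
  mesh$truss <- rbind(mesh$truss, c(new_id, chain[i + 1L]))
  mesh$truss_label <- c(mesh$truss_label, lab)
  mesh$truss_area <- c(mesh$truss_area, ar)
  mesh$truss_active <- c(mesh$truss_active, act)
  mesh$truss_ref_len <- c(mesh$truss_ref_len,
                          vnorm(mesh$nodes[chain[i + 1L], ] - pt))
  mesh$ligament_chains[[chain_name]] <-
    append(chain, new_id, after = i)
  list(mesh = mesh, node = new_id)
}

#' Apply a sacrospinous fixation to a model
#'
#' Adds `sutures_per_side` stiff tension-only truss filaments per
#' configured side, each running from a distinct vaginal-apex node to the
#' anchor node on the sacrospinous ligament (an exact chain node, inserted
#' by splitting the containing segment when necessary). With no sides
#' configured the model is returned unchanged.
#'
#' @param model an `fe_model` built on `geometry`'s mesh.
#' @param geometry the `pelvic_geometry`.
#' @param config an [ssf_config()].
#' @return the modified `fe_model`.
#' @export
apply_ssf <- function(model, geometry, config) {
  stopifnot(inherits(model, "fe_model"), inherits(config, "ssf_config"))
  if (!length(config$sides)) return(model)
  mesh <- model$mesh
  vag_ids <- mesh$node_sets[["nodes_vagina"]]
  if (is.null(vag_ids)) abort_model("model lacks a vagina node set")
  apex_center <- geometry$surface_specs$vagina$p2
  nsut <- config$sutures_per_side
  offs <- if (nsut == 1) 0 else
    seq(-config$apex_spread_mm / 2, config$apex_spread_mm / 2, length.out = nsut)
  apex_nodes <- integer(0)
  pool <- mesh$nodes[vag_ids, , drop = FALSE]
  pick_nearest <- function(target, off_midline = FALSE) {
    dd <- rownorms(pool - matrix(target, nrow(pool), 3, byrow = TRUE))
    if (off_midline) dd[abs(pool[, 1]) < 0.2 * config$apex_spread_mm] <- Inf
    ord <- order(dd)
    vag_ids[ord[!(vag_ids[ord] %in% apex_nodes)][1]]
  }
  if (nsut == 2) {
    # a mirror pair: the first node is taken off the midline and the second
    # is its reflection, so on a symmetric vault left and right fixation
    # are exact mirror images
    n1 <- pick_nearest(apex_center + c(config$apex_spread_mm / 2, 0, 0),
                       off_midline = TRUE)
    apex_nodes <- n1
    p1 <- mesh$nodes[n1, ]
    apex_nodes <- c(apex_nodes, pick_nearest(c(-p1[1], p1[2], p1[3])))
  } else {
    for (o in offs) apex_nodes <- c(apex_nodes,
                                    pick_nearest(apex_center + c(o, 0, 0)))
  }
  for (side in config$sides) {
    a <- place_anchor(geometry, side, config$anchor_distance_mm)
    an <- anchor_node_on_chain(mesh, paste0("sacrospinous_", side),
                               config$anchor_distance_mm)
    mesh <- an$mesh
    anchor_id <- an$node
    for (ap in apex_nodes) {
      L <- vnorm(mesh$nodes[anchor_id, ] - mesh$nodes[ap, ])
      mesh$truss <- rbind(mesh$truss, c(ap, anchor_id))
      mesh$truss_label <- c(mesh$truss_label, "suture")
      mesh$truss_area <- c(mesh$truss_area, config$suture_area)
      mesh$truss_active <- c(mesh$truss_active, TRUE)
      mesh$truss_ref_len <- c(mesh$truss_ref_len,
                              L / (1 + config$pretension_strain))
    }
    mesh$node_sets[[paste0("suture_anchor_", side)]] <- anchor_id
  }
  mesh$node_sets$suture_apex <- apex_nodes
  mesh$elem_sets$truss <- split(seq_along(mesh$truss_label), mesh$truss_label)
  materials <- model$materials
  materials$suture <- material_model("linear_elastic", E = config$suture_E)
  fe_model(mesh, materials, ties = model$ties,
           membrane_stabilization = model$membrane_stabilization)
}
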