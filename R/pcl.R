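# Pubococcygeal-line (PCL) organ-descent measurement. The PCL is drawn on
# the midsagittal plane from the inferior border of the pubic symphysis to
# the last coccygeal joint; organ descent is the change in perpendicular
# distance of the Ba / C / Bp reference points to this line between rest
# and maximal strain. Sign convention: positive = motion toward the caudal
# side of the line (the prolapse direction).

#' The pubococcygeal reference line
#'
#' @param geometry a `pelvic_geometry` (landmarks are taken from the rest
#'   configuration; both landmarks are projected to the midsagittal plane
#'   x = 0 before the line is formed).
#' @return a list with `point` (on-line point), `direction` (unit, pubis to
#'   coccyx) and `normal` (unit, pointing to the caudal side), all with
#'   x = 0.
#' @export
pcl_line <- function(geometry) {
  p <- geometry$landmarks$pubic_symphysis_inferior
  c_ <- geometry$landmarks$coccyx_last_joint
  if (is.null(p) || is.null(c_)) abort_geometry("PCL landmarks missing")
  p[1] <- 0; c_[1] <- 0
  d <- c_ - p
  if (vnorm(d) < 1e-9) abort_geometry("PCL landmarks coincide")
  d <- d / vnorm(d)
  # in-plane perpendicular; pick the caudal (inferior) side
  n1 <- c(0, d[3], -d[2])
  if (n1[3] > 0 || (abs(n1[3]) < 1e-12 && n1[2] > 0)) n1 <- -n1
  list(point = p, direction = d, normal = n1)
}

#' Signed perpendicular distance of a point to the PCL
#'
#' The point is projected to the midsagittal plane (its x coordinate is
#' discarded); the distance is the 2-D point-to-line perpendicular
#' distance, positive on the caudal side of the line.
#'
#' @param point numeric 3-vector or n x 3 matrix (mm).
#' @param line a [pcl_line()] result.
#' @return signed distance(s) in mm.
#' @export
perpendicular_distance <- function(point, line) {
  if (is.null(dim(point))) point <- matrix(point, nrow = 1)
  point[, 1] <- 0
  v <- point - matrix(line$point, nrow(point), 3, byrow = TRUE)
  as.numeric(v %*% line$normal)
}

#' Measure Ba / C / Bp descent of a simulation result
#'
#' Computes, for each reference point, the PCL descent (strain minus rest
#' perpendicular distance) and the total Euclidean displacement. Ba is
#' flagged not-evaluable when its out-of-plane (lateral) displacement
#' exceeds `ba_lateral_fraction` of its total displacement, the rule used
#' to exclude an asymmetrically displacing bladder from the PCL analysis.
#'
#' @param model the `fe_model` that was solved.
#' @param geometry the `pelvic_geometry` the mesh came from.
#' @param strain_result `simulation_result` at maximal strain.
#' @param rest_result optional `simulation_result` for the rest state;
#'   `NULL` means the undeformed configuration.
#' @param ba_lateral_fraction threshold fraction (default 0.5).
#' @return a one-row tibble with columns `Ba_mm`, `C_mm`, `Bp_mm`,
#'   `Ba_total_mm`, `C_total_mm`, `Bp_total_mm`, `Ba_not_evaluable`.
#' @export
measure_descent <- function(model, geometry, strain_result,
                            rest_result = NULL,
                            ba_lateral_fraction = 0.5) {
  mesh <- model$mesh
  line <- pcl_line(geometry)
  u_rest <- if (is.null(rest_result)) matrix(0, nrow(mesh$nodes), 3) else
    rest_result$displacement
  u_strain <- strain_result$displacement
  # bony frame must not move: the PCL from the rest geometry is only valid
  # if the fixed bony nodes coincide between rest and strain
  bony <- resolve_set(mesh, "sacrum_coccyx_region")
  if (max(abs(u_strain[bony, ])) > 1e-9 || max(abs(u_rest[bony, ])) > 1e-9)
    abort_state("bony landmark nodes displaced; PCL frame invalid")
  out <- list()
  for (p in c("Ba", "C", "Bp")) {
    id <- mesh$node_sets[[p]]
    if (is.null(id)) abort_model(paste("reference node", p, "missing"))
    x0 <- mesh$nodes[id, ] + u_rest[id, ]
    x1 <- mesh$nodes[id, ] + u_strain[id, ]
    d0 <- perpendicular_distance(x0, line)
    d1 <- perpendicular_distance(x1, line)
    delta <- x1 - x0
    out[[paste0(p, "_mm")]] <- d1 - d0
    out[[paste0(p, "_total_mm")]] <- vnorm(delta)
    if (p == "Ba") {
      tot <- vnorm(delta)
      out$Ba_not_evaluable <- tot > 1e-9 &&
        abs(delta[1]) > ba_lateral_fraction * tot
    }
  }
  tibble::as_tibble(out[c("Ba_mm", "C_mm", "Bp_mm", "Ba_total_mm",
                          "C_total_mm", "Bp_total_mm", "Ba_not_evaluable")])
}
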