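#' Parameters of the synthetic pelvic geometry
#'
#' The generator stands in for MRI-derived anatomy: a midsagittally
#' (near-)symmetric pelvis with bony landmarks, a vaginal tube with closed
#' apex (post-hysterectomy vault), bladder and rectum shells, a basin-shaped
#' pelvic-floor membrane, two fascial sheets, and the ligamentous support
#' system. All dimensions are in millimetres; the coordinate convention is
#' x lateral (patient-right positive), y anterior, z superior, with the
#' midsagittal plane at x = 0.
#'
#' @param organ_scale named numeric scale factors (dimensionless) for
#'   `vagina`, `bladder`, `rectum`, `pelvic_floor`; unnamed entries default
#'   to 1.
#' @param inter_spine_width distance between the two ischial spines (mm).
#' @param pcl_length length of the pubococcygeal line, i.e. the distance
#'   from the inferior pubic symphysis to the last coccygeal joint (mm).
#' @param ss_ligament_length sacrospinous ligament length from the ischial
#'   spine to its sacral insertion (mm); must exceed 30 mm so anchors up to
#'   3 cm are placeable.
#' @param support_condition `"physiological"` (all ligaments active) or
#'   `"pathological"` (broad and round ligaments disabled, the apical
#'   support defect that produces prolapse-range mobility).
#' @param asymmetry_amplitude amplitude (mm) of the seeded right-side
#'   perturbation producing the patient-like asymmetric variant; 0 gives
#'   the strictly symmetric generic variant.
#' @param seed integer seed for the asymmetry perturbation.
#' @param target_edge_length target triangle edge length (mm) used when the
#'   organ surfaces are triangulated.
#' @return an object of class `geometry_params`.
#' @export
geometry_params <- function(organ_scale = NULL,
                            inter_spine_width = 100,
                            pcl_length = 100,
                            ss_ligament_length = 45,
                            support_condition = c("physiological", "pathological"),
                            asymmetry_amplitude = 0,
                            seed = 1L,
                            target_edge_length = 4) {
  support_condition <- match.arg(support_condition)
  scale <- c(vagina = 1, bladder = 1, rectum = 1, pelvic_floor = 1)
  if (!is.null(organ_scale)) {
    if (is.null(names(organ_scale)) || !all(names(organ_scale) %in% names(scale)))
      abort_param("organ_scale must be a named vector with names among vagina, bladder, rectum, pelvic_floor")
    scale[names(organ_scale)] <- organ_scale
  }
  if (any(scale <= 0)) abort_param("organ scale factors must be > 0")
  if (inter_spine_width <= 0) abort_param("inter_spine_width must be > 0")
  if (pcl_length <= 0) abort_param("pcl_length must be > 0")
  if (ss_ligament_length <= 30)
    abort_param("ss_ligament_length must exceed 30 mm (anchors up to 3 cm)")
  if (asymmetry_amplitude < 0) abort_param("asymmetry_amplitude must be >= 0")
  if (target_edge_length <= 0) abort_param("target_edge_length must be > 0")
  structure(list(
    organ_scale = scale,
    inter_spine_width = inter_spine_width,
    pcl_length = pcl_length,
    ss_ligament_length = ss_ligament_length,
    support_condition = support_condition,
    asymmetry_amplitude = asymmetry_amplitude,
    seed = as.integer(seed),
    target_edge_length = target_edge_length
  ), class = "geometry_params")
}

side_sign <- function(side) switch(side, left = -1, right = 1,
                                   abort_param("side must be 'left' or 'right'"))

# polyline between two points with optional perpendicular bow (mm)
polyline_between <- function(p0, p1, spacing = 5, bow = 0, bow_dir = c(0, 0, -1)) {
  L <- vnorm(p1 - p0)
  n <- max(3L, as.integer(ceiling(L / spacing)) + 1L)
  s <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1] + s * (p1[1] - p0[1]),
               p0[2] + s * (p1[2] - p0[2]),
               p0[3] + s * (p1[3] - p0[3]))
  if (bow != 0) {
    axis <- unitize(p1 - p0)
    perp <- bow_dir - sum(bow_dir * axis) * axis
    if (vnorm(perp) > 1e-9) {
      perp <- unitize(perp)
      pts <- pts + (bow * sin(pi * s)) %o% perp
    }
  }
  pts
}

polyline_length <- function(pts) sum(rownorms(diff(pts)))

surface_from_spec <- function(spec, edge) {
  switch(spec$type,
    ellipsoid = ellipsoid_surface(spec$center, spec$radii, edge),
    tube = tube_surface(function(s) bezier3(s, spec$p0, spec$p1, spec$p2),
                        spec$rx, spec$ry, edge,
                        cap_start = isTRUE(spec$cap_start),
                        cap_end = isTRUE(spec$cap_end)),
    basin = basin_surface(function(th) cbind(
      spec$rx * sin(th),
      spec$yc + spec$ry * cos(th),
      spec$z0 + spec$z1 * cos(th)
    ), spec$center, edge),
    sheet = sheet_surface(function(v) bezier3(v, spec$p0, spec$p1, spec$p2),
                          spec$half_width, edge),
    abort_geometry(paste("unknown surface spec type:", spec$type))
  )
}

#' Build the parametric synthetic pelvic geometry
#'
#' Constructs landmarks, organ surfaces, fascial sheets, ligament polylines
#' and reference-point definitions from [geometry_params()]. The result is a
#' pure function of the parameters (including the seed): identical inputs
#' give identical geometry.
#'
#' @param params a [geometry_params()] object (or a list coercible to one).
#' @return an object of class `pelvic_geometry`.
#' @export
build_pelvic_geometry <- function(params = geometry_params()) {
  if (!inherits(params, "geometry_params")) params <- do.call(geometry_params, params)
  w <- params$inter_spine_width
  Lpcl <- params$pcl_length
  sc <- params$organ_scale

  pubis <- c(0, 52, -5)
  pcl_dir <- unitize(c(0, -0.985, -0.174))
  coccyx <- pubis + Lpcl * pcl_dir
  sacrum <- c(0, -50, 15)
  spine <- list(left = c(-w / 2, -8, -8), right = c(w / 2, -8, -8))
  ss_target <- list(left = c(-6, -48, 0), right = c(6, -48, 0))
  insertion <- lapply(c(left = "left", right = "right"), function(s) {
    spine[[s]] + params$ss_ligament_length * unitize(ss_target[[s]] - spine[[s]])
  })

  bladder_center <- c(0, 22, 14)
  asym <- params$asymmetry_amplitude
  if (asym > 0) {
    with_local_seed(params$seed, {
      d1 <- stats::runif(3, -1, 1); d2 <- stats::runif(3, -1, 1)
      spine$right <- spine$right + asym * d1 / max(1, vnorm(d1))
      insertion$right <- insertion$right + asym * d2 / max(1, vnorm(d2))
      bladder_center <- bladder_center + c(0.5 * asym, 0, 0)
    })
  }

  landmarks <- list(
    pubic_symphysis_inferior = pubis,
    coccyx_last_joint = coccyx,
    sacrum_center = sacrum,
    ischial_spine_left = spine$left,
    ischial_spine_right = spine$right,
    sacrospinous_insertion_left = insertion$left,
    sacrospinous_insertion_right = insertion$right
  )

  surface_specs <- list(
    bladder = list(type = "ellipsoid", center = bladder_center,
                   radii = c(24, 19, 14) * sc[["bladder"]]),
    vagina = list(type = "tube", p0 = c(0, 8, -18), p1 = c(0, 4, 8),
                  p2 = c(0, -14, 28), rx = 13 * sc[["vagina"]],
                  ry = 6 * sc[["vagina"]], cap_end = TRUE),
    rectum = list(type = "tube", p0 = c(0, -12, -24), p1 = c(0, -38, 0),
                  p2 = c(0, -38, 30), rx = 13 * sc[["rectum"]],
                  ry = 13 * sc[["rectum"]]),
    pelvic_floor = list(type = "basin",
                        rx = 0.48 * w * sc[["pelvic_floor"]],
                        ry = 50 * sc[["pelvic_floor"]], yc = 2,
                        z0 = -13.7, z1 = 8.7,
                        center = c(0, 2, -28.7)),
    fascia_pubocervical = list(type = "sheet", p0 = c(0, 38, -4),
                               p1 = c(0, 15, 6), p2 = c(0, -6, 18),
                               half_width = 16),
    fascia_endopelvic = list(type = "sheet", p0 = c(0, 2, -16),
                             p1 = c(0, -8, 2), p2 = c(0, -22, 22),
                             half_width = 16)
  )
  organ_surfaces <- lapply(surface_specs, surface_from_spec,
                           edge = params$target_edge_length)

  lig <- list()
  for (s in c("left", "right")) {
    sg <- side_sign(s)
    sp <- spine[[s]]; ins <- insertion[[s]]
    ss <- polyline_between(sp, ins, bow = 2)
    if (polyline_length(ss) < 30)
      abort_geometry("sacrospinous ligament arc length below 30 mm; asymmetry too large")
    lig[[paste0("sacrospinous_", s)]] <- list(
      group = "sacrospinous", side = s, points = ss, active = TRUE,
      fixed_end = "both", attach_to = NULL)
    # apical suspension runs posteriorly (uterosacral, toward the sacrum)
    # and laterally (cardinal, toward the pelvic sidewall), slightly upward
    # so that it resists caudal apex motion
    lig[[paste0("uterosacral_", s)]] <- list(
      group = "uterosacral", side = s, active = TRUE, fixed_end = "distal",
      attach_to = "vagina",
      points = polyline_between(c(sg * 5, -13, 26), c(sg * 8, -46, 30), bow = 1.5))
    lig[[paste0("cardinal_", s)]] <- list(
      group = "cardinal", side = s, active = TRUE, fixed_end = "distal",
      attach_to = "vagina",
      points = polyline_between(c(sg * 10, -8, 22), c(sg * 0.45 * w, -15, 28), bow = 1.5))
    lig[[paste0("round_", s)]] <- list(
      group = "round", side = s, active = TRUE, fixed_end = "distal",
      attach_to = "vagina",
      points = polyline_between(c(sg * 8, 0, 24), c(sg * 30, 45, 8), bow = 1.5))
    lig[[paste0("broad_", s)]] <- list(
      group = "broad", side = s, active = TRUE, fixed_end = "distal",
      attach_to = "vagina",
      points = polyline_between(c(sg * 10, -8, 24), c(sg * 42, -4, 28), bow = 1.5))
    lig[[paste0("ATFP_", s)]] <- list(
      group = "ATFP", side = s, active = TRUE, fixed_end = "both",
      attach_to = NULL,
      points = polyline_between(c(sg * 8, 46, -6), sp, bow = 1.5))
  }

  br <- surface_specs$bladder$radii
  # Bp sits on the anterior rectal wall at the anorectal bend
  bp_cl <- bezier3(0.28, surface_specs$rectum$p0, surface_specs$rectum$p1,
                   surface_specs$rectum$p2)[1, ]
  reference_probes <- list(
    Ba = list(surface = "bladder",
              probe = bladder_center + c(0, -0.55 * br[2], -0.85 * br[3])),
    C = list(surface = "vagina", probe = surface_specs$vagina$p2),
    Bp = list(surface = "rectum",
              probe = bp_cl + c(0, surface_specs$rectum$rx, 0))
  )

  geom <- structure(list(
    landmarks = landmarks,
    organ_surfaces = organ_surfaces,
    surface_specs = surface_specs,
    ligaments = lig,
    reference_probes = reference_probes,
    reference_points = lapply(reference_probes, function(rp) {
      surf <- organ_surfaces[[rp$surface]]
      list(surface = rp$surface,
           vertex = nearest_midsagittal_vertex(surf$vertices, rp$probe))
    }),
    symmetric = asym == 0,
    params = params
  ), class = "pelvic_geometry")
  apply_support_condition(geom, params$support_condition)
}

# nearest vertex to `probe`, preferring vertices close to the midsagittal
# plane (|x| within one edge length of the smallest |x| available)
nearest_midsagittal_vertex <- function(verts, probe) {
  ax <- abs(verts[, 1])
  keep <- which(ax <= min(ax) + 3)
  d <- rownorms(verts[keep, , drop = FALSE] -
                  matrix(probe, length(keep), 3, byrow = TRUE))
  keep[which.min(d)]
}

#' Enable or disable the apical support system
#'
#' The pathological (prolapse) state is produced by disabling the broad and
#' round ligaments, i.e. flagging them inactive so they contribute no
#' stiffness downstream; every other structure is untouched. Idempotent.
#'
#' @param geometry a `pelvic_geometry`.
#' @param condition `"physiological"` or `"pathological"`.
#' @return the modified `pelvic_geometry`.
#' @export
apply_support_condition <- function(geometry,
                                    condition = c("physiological", "pathological")) {
  stopifnot(inherits(geometry, "pelvic_geometry"))
  condition <- match.arg(condition)
  disabled <- if (condition == "pathological") c("broad", "round") else character()
  groups <- vapply(geometry$ligaments, function(l) l$group, character(1))
  if (condition == "pathological" && !all(c("broad", "round") %in% groups))
    abort_model("geometry lacks broad/round ligament groups")
  for (nm in names(geometry$ligaments)) {
    geometry$ligaments[[nm]]$active <-
      !(geometry$ligaments[[nm]]$group %in% disabled)
  }
  geometry$params$support_condition <- condition
  geometry
}

#' Landmark table of a pelvic geometry
#'
#' @param geometry a `pelvic_geometry`.
#' @return a tibble with columns `landmark`, `x`, `y`, `z` (mm).
#' @export
pelvic_landmarks <- function(geometry) {
  stopifnot(inherits(geometry, "pelvic_geometry"))
  lm <- geometry$landmarks
  tibble::tibble(
    landmark = names(lm),
    x = vapply(lm, `[`, numeric(1), 1),
    y = vapply(lm, `[`, numeric(1), 2),
    z = vapply(lm, `[`, numeric(1), 3)
  )
}

#' Mirror a pelvic geometry through the midsagittal plane
#'
#' Reflects every coordinate x -> -x and swaps left/right structure names.
#' Used for mirror-consistency checks.
#'
#' @param geometry a `pelvic_geometry`.
#' @return the reflected `pelvic_geometry`.
#' @export
reflect_pelvic_geometry <- function(geometry) {
  stopifnot(inherits(geometry, "pelvic_geometry"))
  refl <- function(p) {
    if (is.matrix(p)) p[, 1] <- -p[, 1] else p[1] <- -p[1]
    p
  }
  swap_name <- function(nm) {
    out <- gsub("_left$", "_TMP", nm)
    out <- gsub("_right$", "_left", out)
    gsub("_TMP$", "_right", out)
  }
  g <- geometry
  g$landmarks <- lapply(g$landmarks, refl)
  names(g$landmarks) <- swap_name(names(g$landmarks))
  g$landmarks <- g$landmarks[names(geometry$landmarks)]
  g$organ_surfaces <- lapply(g$organ_surfaces, function(s) {
    s$vertices <- refl(s$vertices)
    s$faces <- s$faces[, c(1, 3, 2)]  # keep orientation after reflection
    s
  })
  g$ligaments <- lapply(g$ligaments, function(l) {
    l$points <- refl(l$points)
    l$side <- if (identical(l$side, "left")) "right" else if (identical(l$side, "right")) "left" else l$side
    l
  })
  names(g$ligaments) <- swap_name(names(g$ligaments))
  g$ligaments <- g$ligaments[names(geometry$ligaments)]
  for (nm in names(g$reference_probes)) {
    g$reference_probes[[nm]]$probe <- refl(g$reference_probes[[nm]]$probe)
  }
  g
}

#' @export
print.pelvic_geometry <- function(x, ...) {
  cat("<pelvic_geometry>\n")
  cat("  condition:", x$params$support_condition,
      if (x$symmetric) "(symmetric)" else "(asymmetric)", "\n")
  cat("  surfaces: ", paste(names(x$organ_surfaces), collapse = ", "), "\n")
  nact <- sum(vapply(x$ligaments, function(l) l$active, logical(1)))
  cat("  ligaments:", length(x$ligaments), "strands,", nact, "active\n")
  invisible(x)
}
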