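# Exchange formats: ASCII STL per organ surface, legacy-ASCII VTK
# unstructured grids with point-data displacement vectors, a JSON mesh
# dialect (nodes, elements, sets), a JSON geometry document (parameters +
# landmarks, seed recorded), and a commented Abaqus-INP-style solver deck
# for external cross-checking. All writers use fixed number formatting so
# output is bit-stable across identical runs.

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

#' Write a triangulated surface as ASCII STL (units mm)
#' @param vertices n x 3 matrix.
#' @param faces m x 3 integer matrix.
#' @param path output file.
#' @param name solid name recorded in the file.
#' @return path, invisibly.
#' @export
write_stl <- function(vertices, faces, path, name = "surface") {
  a <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  n <- cross3(a, b)
  nn <- pmax(rownorms(n), 1e-30)
  n <- n / nn
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  for (i in seq_len(nrow(faces))) {
    writeLines(c(
      paste("  facet normal", paste(fmt_num(n[i, ]), collapse = " ")),
      "    outer loop",
      paste("      vertex", paste(fmt_num(vertices[faces[i, 1], ]), collapse = " ")),
      paste("      vertex", paste(fmt_num(vertices[faces[i, 2], ]), collapse = " ")),
      paste("      vertex", paste(fmt_num(vertices[faces[i, 3], ]), collapse = " ")),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#' @param path STL file path.
#' @return list with `vertices` (deduplicated) and `faces`.
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(coords, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- coords[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

#' Export every organ surface of a geometry as STL files
#' @param geometry a `pelvic_geometry`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
export_geometry_stl <- function(geometry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(geometry$organ_surfaces)) {
    s <- geometry$organ_surfaces[[nm]]
    p <- file.path(dir, paste0(nm, ".stl"))
    write_stl(s$vertices, s$faces, p, name = nm)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Serialize geometry parameters and landmarks as a JSON document
#'
#' The document records the full generator parameter set (seed included)
#' plus the landmark table, so the geometry can be reproduced exactly by
#' [build_pelvic_geometry()].
#' @param geometry a `pelvic_geometry`.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  params <- unclass(geometry$params)
  params$organ_scale <- as.list(params$organ_scale)  # keep names in JSON
  doc <- list(
    params = params,
    landmarks = geometry$landmarks,
    symmetric = geometry$symmetric
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rebuild a geometry from its JSON document
#' @param path JSON file written by [write_geometry_json()].
#' @return a `pelvic_geometry`.
#' @export
read_geometry_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- doc$params
  params <- geometry_params(
    organ_scale = unlist(pr$organ_scale),
    inter_spine_width = pr$inter_spine_width,
    pcl_length = pr$pcl_length,
    ss_ligament_length = pr$ss_ligament_length,
    support_condition = pr$support_condition,
    asymmetry_amplitude = pr$asymmetry_amplitude,
    seed = pr$seed,
    target_edge_length = pr$target_edge_length)
  build_pelvic_geometry(params)
}

#' Write a mesh (optionally with a displacement field) as legacy ASCII VTK
#' @param mesh an `fe_mesh`.
#' @param path output file (.vtk).
#' @param displacement optional n x 3 point-data vector field (mm).
#' @return path, invisibly.
#' @export
write_vtk <- function(mesh, path, displacement = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  nt <- nrow(mesh$tri)
  nr <- if (is.null(mesh$truss)) 0L else nrow(mesh$truss)
  writeLines(c("# vtk DataFile Version 3.0",
               "pelvifem unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(apply(mesh$nodes, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(paste("CELLS", nt + nr, 4 * nt + 3 * nr), con)
  writeLines(apply(mesh$tri - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  if (nr > 0)
    writeLines(apply(mesh$truss - 1L, 1, function(r) paste(c(2L, r), collapse = " ")), con)
  writeLines(paste("CELL_TYPES", nt + nr), con)
  writeLines(as.character(c(rep(5L, nt), rep(3L, nr))), con)
  if (!is.null(displacement)) {
    writeLines(c(paste("POINT_DATA", n),
                 "VECTORS displacement double"), con)
    writeLines(apply(displacement, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  }
  invisible(path)
}

#' Write a mesh as a JSON document (nodes, elements, sets)
#' @param mesh an `fe_mesh`.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_mesh_json <- function(mesh, path) {
  doc <- list(
    nodes = mesh$nodes,
    membrane_elements = list(connectivity = mesh$tri, label = mesh$tri_label,
                             thickness = mesh$tri_thickness),
    truss_elements = list(connectivity = mesh$truss, label = mesh$truss_label,
                          area = mesh$truss_area, active = mesh$truss_active,
                          ref_length = mesh$truss_ref_len),
    node_sets = mesh$node_sets,
    target_edge_length = mesh$target_edge_length
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mesh from its JSON document
#' @param path JSON file written by [write_mesh_json()].
#' @return an `fe_mesh`.
#' @export
read_mesh_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  mesh <- structure(list(
    nodes = matrix(doc$nodes, ncol = 3),
    tri = matrix(as.integer(doc$membrane_elements$connectivity), ncol = 3),
    tri_label = doc$membrane_elements$label,
    tri_thickness = doc$membrane_elements$thickness,
    truss = if (length(doc$truss_elements$connectivity))
      matrix(as.integer(doc$truss_elements$connectivity), ncol = 2) else NULL,
    truss_label = doc$truss_elements$label,
    truss_area = doc$truss_elements$area,
    truss_active = doc$truss_elements$active,
    truss_ref_len = doc$truss_elements$ref_length,
    node_sets = lapply(doc$node_sets, as.integer),
    elem_sets = list(),
    ligament_chains = list(),
    target_edge_length = doc$target_edge_length
  ), class = "fe_mesh")
  mesh$elem_sets <- list(
    membrane = split(seq_len(nrow(mesh$tri)), mesh$tri_label),
    truss = if (!is.null(mesh$truss))
      split(seq_along(mesh$truss_label), mesh$truss_label) else list())
  validate_fe_mesh(mesh)
  mesh
}

#' Export the assembled model as a commented solver deck
#'
#' Writes *NODE, *ELEMENT and *BOUNDARY keyword blocks in an Abaqus-INP
#' style for external cross-checking. Write-only; ordering is bit-stable.
#' @param model an `fe_model`.
#' @param case a `load_case` (for the boundary blocks).
#' @param path output file.
#' @return path, invisibly.
#' @export
write_inp_deck <- function(model, case, path) {
  mesh <- model$mesh
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("** pelvifem solver deck (membrane triangles + truss filaments)", con)
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %s, %s, %s", seq_len(nrow(mesh$nodes)),
                     fmt_num(mesh$nodes[, 1]), fmt_num(mesh$nodes[, 2]),
                     fmt_num(mesh$nodes[, 3])), con)
  for (lb in sort(unique(mesh$tri_label))) {
    sel <- which(mesh$tri_label == lb)
    writeLines(sprintf("*ELEMENT, TYPE=S3, ELSET=%s", lb), con)
    writeLines(sprintf("%d, %d, %d, %d", sel, mesh$tri[sel, 1],
                       mesh$tri[sel, 2], mesh$tri[sel, 3]), con)
  }
  if (!is.null(mesh$truss)) {
    off <- nrow(mesh$tri)
    for (lb in sort(unique(mesh$truss_label))) {
      sel <- which(mesh$truss_label == lb)
      writeLines(sprintf("*ELEMENT, TYPE=T3D2, ELSET=%s", lb), con)
      writeLines(sprintf("%d, %d, %d", off + sel, mesh$truss[sel, 1],
                         mesh$truss[sel, 2]), con)
    }
  }
  fs <- case$fixed_sets
  if (is.character(fs)) fs <- lapply(fs, function(s) list(set = s))
  writeLines("*BOUNDARY", con)
  for (entry in fs) {
    ids <- sort(resolve_set(mesh, entry$set))
    comps <- comp_index[entry$comps %||% c("x", "y", "z")]
    for (id in ids)
      writeLines(sprintf("%d, %d, %d", id, min(comps), max(comps)), con)
  }
  invisible(path)
}
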