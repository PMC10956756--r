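# Study orchestration: build geometry -> mesh -> calibrate loads on the
# no-surgery model -> run the surgery matrix with the calibrated loads
# frozen -> emit descent reports, mesh snapshots and a run manifest.

#' The default surgery matrix of the study
#'
#' No surgery, left, right and bilateral fixation at the 2 cm anchor, plus
#' the anchor-distance variants 1 cm and 3 cm for both the bilateral and
#' the left-sided configuration (the anchor was varied bilaterally for the
#' generic model and on the left side for the patient model; both variants
#' are included).
#'
#' @return a list of configuration lists with `sides` and
#'   `anchor_distance_mm`.
#' @export
default_surgery_matrix <- function() {
  list(
    list(sides = character(0), anchor_distance_mm = 20),
    list(sides = "left", anchor_distance_mm = 20),
    list(sides = "right", anchor_distance_mm = 20),
    list(sides = c("left", "right"), anchor_distance_mm = 20),
    list(sides = c("left", "right"), anchor_distance_mm = 10),
    list(sides = c("left", "right"), anchor_distance_mm = 30),
    list(sides = "left", anchor_distance_mm = 10),
    list(sides = "left", anchor_distance_mm = 30)
  )
}

default_study_config <- function() {
  list(
    geometry = list(
      inter_spine_width = 100, pcl_length = 100, ss_ligament_length = 45,
      support_condition = "pathological", asymmetry_amplitude = 0,
      target_edge_length = 4),
    materials = list(),
    # initial traction magnitudes (MPa); vagina and rectum are calibrated
    # against the C and Bp setpoints, the anterior (bladder) traction is
    # held fixed at a small magnitude because Ba is excluded from the PCL
    # calibration (asymmetric bladder displacement)
    loads = list(vagina = 0.001, bladder = 2e-4, rectum = 0.001),
    solver = list(n_load_steps = 10, newton_tol = 1e-6, max_newton_iter = 60),
    calibration = list(enabled = TRUE,
                       setpoints = list(C = 7, Bp = 6),
                       driven = list(C = "vagina", Bp = "rectum"),
                       tolerance = 0.1, max_iter = 30, outer_sweeps = 5),
    surgery = list(sutures_per_side = 2, suture_E = 1000, suture_area = 0.2,
                   pretension_strain = 0, apex_spread_mm = 5),
    surgery_matrix = default_surgery_matrix(),
    output = list(dir = NULL),
    seed = 1L,
    log_level = "INFO"
  )
}

#' Validate a raw study configuration document
#'
#' Injects all defaults, rejects unknown keys, and reports every
#' out-of-range field with its path in a single validation error.
#'
#' @param raw a (possibly empty) named list, e.g. parsed from YAML or JSON
#'   (a file path to either format is also accepted).
#' @return an object of class `study_config` with all defaults injected.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (grepl("\\.ya?ml$", raw)) yaml::read_yaml(raw) else
      jsonlite::read_json(raw, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    if (is.null(raw)) raw <- list()
  }
  cfg <- default_study_config()
  errs <- character()
  err <- function(path, msg) errs <<- c(errs, paste0(path, ": ", msg))

  known_top <- names(cfg)
  unknown <- setdiff(names(raw), known_top)
  for (u in unknown) err(u, "unknown key")

  merge_block <- function(name) {
    blk <- raw[[name]]
    if (is.null(blk)) return()
    bad <- setdiff(names(blk), names(cfg[[name]]))
    for (b in bad) err(paste0(name, ".", b), "unknown key")
    for (k in intersect(names(blk), names(cfg[[name]])))
      cfg[[name]][[k]] <<- blk[[k]]
  }
  for (nm in c("geometry", "loads", "solver", "calibration", "surgery",
               "output")) merge_block(nm)
  if (!is.null(raw$seed)) cfg$seed <- raw$seed
  if (!is.null(raw$log_level)) cfg$log_level <- raw$log_level
  if (!is.null(raw$surgery_matrix)) cfg$surgery_matrix <- lapply(
    raw$surgery_matrix, function(row) list(
      sides = as.character(row$sides %||% character(0)),
      anchor_distance_mm = row$anchor_distance_mm %||% 20))
  if (!is.null(raw$materials)) cfg$materials <- raw$materials

  g <- cfg$geometry
  if (g$inter_spine_width <= 0) err("geometry.inter_spine_width", "must be > 0")
  if (g$pcl_length <= 0) err("geometry.pcl_length", "must be > 0")
  if (g$ss_ligament_length <= 30)
    err("geometry.ss_ligament_length", "must exceed 30 mm")
  if (g$asymmetry_amplitude < 0) err("geometry.asymmetry_amplitude", "must be >= 0")
  if (g$target_edge_length <= 0) err("geometry.target_edge_length", "must be > 0")
  if (!g$support_condition %in% c("physiological", "pathological"))
    err("geometry.support_condition", "must be physiological or pathological")
  for (ld in names(cfg$loads)) {
    if (cfg$loads[[ld]] < 0) err(paste0("loads.", ld), "must be >= 0")
  }
  s <- cfg$solver
  if (s$n_load_steps < 1) err("solver.n_load_steps", "must be >= 1")
  if (s$newton_tol <= 0) err("solver.newton_tol", "must be > 0")
  cal <- cfg$calibration
  if (cal$tolerance <= 0) err("calibration.tolerance", "must be > 0")
  if (any(unlist(cal$setpoints) <= 0)) err("calibration.setpoints", "must be > 0")
  if (!setequal(names(cal$setpoints) , intersect(names(cal$setpoints), names(cal$driven))))
    err("calibration.driven", "every setpoint needs a driving load")
  su <- cfg$surgery
  if (su$sutures_per_side < 1) err("surgery.sutures_per_side", "must be >= 1")
  if (su$suture_E <= 0) err("surgery.suture_E", "must be > 0")
  if (su$suture_area <= 0) err("surgery.suture_area", "must be > 0")
  for (i in seq_along(cfg$surgery_matrix)) {
    row <- cfg$surgery_matrix[[i]]
    if (length(row$sides) && !all(row$sides %in% c("left", "right")))
      err(sprintf("surgery_matrix[%d].sides", i), "must be subset of {left, right}")
    if (row$anchor_distance_mm < 0)
      err(sprintf("surgery_matrix[%d].anchor_distance_mm", i), "must be >= 0")
  }
  for (nm in names(cfg$materials)) {
    m <- cfg$materials[[nm]]
    if (inherits(m, "material_model")) next
    check <- tryCatch({ do.call(material_model, m); NULL },
                      error = function(e) conditionMessage(e))
    if (!is.null(check)) err(paste0("materials.", nm), check)
  }
  if (length(errs))
    abort_validation(paste0("invalid study configuration:\n  ",
                            paste(errs, collapse = "\n  ")))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "study_config")
}

config_materials <- function(cfg) {
  ov <- lapply(cfg$materials, function(m)
    if (inherits(m, "material_model")) m else do.call(material_model, m))
  default_materials(overrides = if (length(ov)) ov else NULL)
}

study_load_case <- function(cfg) {
  load_case(
    tractions = list(
      vagina = list(node_set = "vagina_upper_surface",
                    direction = c(0, 0, -1), magnitude = cfg$loads$vagina),
      bladder = list(node_set = "bladder_top_surface",
                     direction = c(0, 1, -1) / sqrt(2),
                     magnitude = cfg$loads$bladder),
      rectum = list(node_set = "rectum_wall_surface",
                    direction = c(0, 0, -1), magnitude = cfg$loads$rectum)),
    fixed_sets = "fixed_boundary",
    n_load_steps = cfg$solver$n_load_steps,
    newton_tol = cfg$solver$newton_tol,
    max_newton_iter = cfg$solver$max_newton_iter)
}

config_label <- function(sides, anchor) {
  s <- if (!length(sides)) "none" else
    if (setequal(sides, c("left", "right"))) "bilateral" else sides
  paste0(s, "@", anchor, "mm")
}

#' Run the full SSF simulation study
#'
#' Builds the configured geometry, meshes it, calibrates the straining
#' loads once on the no-surgery model (when enabled), then solves every
#' surgery configuration in the matrix with the calibrated loads frozen,
#' so that differences in descent are attributable to the repair. Writes
#' CSV/JSON descent reports, per-configuration VTK snapshots, organ STL
#' surfaces and a machine-readable run manifest when an output directory
#' is configured. Reruns with the same configuration are bit-identical.
#'
#' @param config a `study_config` (see [validate_config()]) or a raw list.
#' @param quiet suppress progress messages.
#' @return an object of class `pelvifem_study`: `report` (tibble, one row
#'   per configuration), `calibration`, `geometry`, `paths`.
#' @export
run_study <- function(config = validate_config(), quiet = FALSE) {
  if (!inherits(config, "study_config")) config <- validate_config(config)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message("[pelvifem] ", ...)
  out_dir <- config$output$dir
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("pelvifem")),
                   config_hash = config_hash(config))
  failed <- function(e, stage) {
    if (!is.null(out_dir)) {
      manifest$failure <- list(stage = stage, message = conditionMessage(e))
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    stop(e)
  }

  say("building geometry (", config$geometry$support_condition, ")")
  geometry <- tryCatch(build_pelvic_geometry(geometry_params(
    inter_spine_width = config$geometry$inter_spine_width,
    pcl_length = config$geometry$pcl_length,
    ss_ligament_length = config$geometry$ss_ligament_length,
    support_condition = config$geometry$support_condition,
    asymmetry_amplitude = config$geometry$asymmetry_amplitude,
    seed = config$seed,
    target_edge_length = config$geometry$target_edge_length)),
    error = function(e) failed(e, "geometry"))
  mesh <- tryCatch(mesh_geometry(geometry), error = function(e) failed(e, "mesh"))
  say("meshed: ", nrow(mesh$nodes), " nodes, ", n_elements(mesh), " elements")
  materials <- config_materials(config)
  model <- fe_model(mesh, materials)
  case <- study_load_case(config)

  calib <- NULL
  if (isTRUE(config$calibration$enabled)) {
    say("calibrating loads on the no-surgery model")
    spec <- calibration_spec(
      setpoints = unlist(config$calibration$setpoints),
      driven = unlist(config$calibration$driven),
      tolerance = config$calibration$tolerance,
      max_iter = config$calibration$max_iter,
      outer_sweeps = config$calibration$outer_sweeps)
    calib <- tryCatch(calibrate_loads(model, case, spec, geometry),
                      error = function(e) failed(e, "calibration"))
    case <- calib$case
    say("calibrated magnitudes: ",
        paste(sprintf("%s=%.5g", names(calib$magnitudes), calib$magnitudes),
              collapse = ", "))
  }

  base_result <- if (!is.null(calib)) calib$result else
    tryCatch(solve_quasi_static(model, case),
             error = function(e) failed(e, "baseline solve"))

  rows <- list()
  vtk_paths <- character()
  # converged states are reused as starting guesses for later configurations
  # with the same fixation sides (continuation across the anchor grid)
  side_cache <- list()
  for (i in seq_along(config$surgery_matrix)) {
    row <- config$surgery_matrix[[i]]
    lab <- config_label(row$sides, row$anchor_distance_mm)
    say("configuration ", i, "/", length(config$surgery_matrix), ": ", lab)
    sc <- ssf_config(sides = row$sides,
                     anchor_distance_mm = row$anchor_distance_mm,
                     sutures_per_side = config$surgery$sutures_per_side,
                     suture_E = config$surgery$suture_E,
                     suture_area = config$surgery$suture_area,
                     pretension_strain = config$surgery$pretension_strain,
                     apex_spread_mm = config$surgery$apex_spread_mm)
    m_i <- tryCatch(apply_ssf(model, geometry, sc),
                    error = function(e) failed(e, paste("surgery", lab)))
    n_i <- nrow(m_i$mesh$nodes)
    base_guess <- {
      g <- matrix(0, n_i, 3)
      g[seq_len(nrow(model$mesh$nodes)), ] <- base_result$displacement
      g
    }
    skey <- paste(sort(row$sides), collapse = "+")
    cached <- side_cache[[skey]]
    guess <- if (!is.null(cached) && nrow(cached) == n_i) cached else base_guess
    res <- tryCatch(solve_quasi_static(m_i, case, initial_guess = guess),
                    error = function(e) failed(e, paste("solve", lab)))
    if (!res$converged && !identical(guess, base_guess)) {
      res <- tryCatch(solve_quasi_static(m_i, case, initial_guess = base_guess),
                      error = function(e) failed(e, paste("solve", lab)))
    }
    if (res$converged && length(row$sides)) side_cache[[skey]] <- res$displacement
    d <- measure_descent(m_i, geometry, res)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(configuration = lab,
                     sides = paste(sort(row$sides), collapse = "+"),
                     anchor_distance_mm = row$anchor_distance_mm,
                     support_condition = config$geometry$support_condition),
      d,
      tibble::tibble(converged = res$converged,
                     increments = nrow(res$steps)))
    if (!is.null(out_dir)) {
      dir.create(file.path(out_dir, "vtk"), showWarnings = FALSE, recursive = TRUE)
      p <- file.path(out_dir, "vtk", paste0(gsub("[@+]", "_", lab), ".vtk"))
      write_vtk(m_i$mesh, p, displacement = res$displacement)
      vtk_paths <- c(vtk_paths, p)
    }
  }
  report <- dplyr::bind_rows(rows)
  key <- report[, c("sides", "anchor_distance_mm", "support_condition")]
  if (anyDuplicated(key))
    abort_validation("surgery matrix produced duplicate report keys")
  class(report) <- c("descent_report", class(report))

  paths <- list()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths$csv <- file.path(out_dir, "descent_report.csv")
    utils::write.csv(as.data.frame(report), paths$csv, row.names = FALSE)
    paths$json <- file.path(out_dir, "descent_report.json")
    jsonlite::write_json(report, paths$json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    paths$geometry <- file.path(out_dir, "geometry.json")
    write_geometry_json(geometry, paths$geometry)
    paths$stl <- export_geometry_stl(geometry, file.path(out_dir, "stl"))
    paths$vtk <- vtk_paths
    if (!is.null(calib)) {
      paths$calibration <- file.path(out_dir, "calibration_trace.csv")
      utils::write.csv(as.data.frame(calib$trace), paths$calibration,
                       row.names = FALSE)
    }
    artifacts <- unlist(paths, use.names = FALSE)
    manifest$artifacts <- lapply(artifacts, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
    manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    paths$manifest <- file.path(out_dir, "manifest.json")
    manifest_out <- manifest
    manifest_out$elapsed_s <- NULL  # keep the manifest bit-reproducible
    jsonlite::write_json(manifest_out, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  structure(list(report = report, calibration = calib, geometry = geometry,
                 base_model = model, base_case = case, paths = paths),
            class = "pelvifem_study")
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.pelvifem_study <- function(x, ...) {
  cat("<pelvifem_study>", nrow(x$report), "configurations\n")
  print(x$report[, c("configuration", "Ba_mm", "C_mm", "Bp_mm",
                     "Ba_not_evaluable", "converged")])
  invisible(x)
}
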