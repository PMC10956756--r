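# Empirical load calibration: scale the surface-traction magnitudes until
# the simulated reference-point displacements match imaging-derived
# setpoints. Each driven load is a scalar root-find (damped secant with
# bracket fallback) on the map magnitude -> achieved displacement; the
# weak coupling between loads is handled by outer fixed-point sweeps.

#' Specification of a load calibration
#'
#' @param setpoints named numeric vector of target PCL displacements (mm),
#'   names among `Ba`, `C`, `Bp`. Defaults to the pre-operative
#'   patient-state targets C = 7 mm and Bp = 6 mm (the anterior point is
#'   reported passively: an asymmetrically displacing bladder is excluded
#'   from PCL calibration).
#' @param driven named character vector mapping each driven reference
#'   point to the load (traction name) that drives it. The vaginal
#'   traction drives the apex (C), the bladder traction drives Ba, and a
#'   rectal-wall traction drives Bp.
#' @param tolerance convergence tolerance on each setpoint (mm).
#' @param max_iter maximum scalar iterations per driven load per sweep.
#' @param outer_sweeps maximum fixed-point sweeps over the driven loads.
#' @return an object of class `calibration_spec`.
#' @export
calibration_spec <- function(setpoints = c(C = 7, Bp = 6),
                             driven = c(C = "vagina", Bp = "rectum"),
                             tolerance = 0.1,
                             max_iter = 30,
                             outer_sweeps = 5) {
  if (is.null(names(setpoints)) || any(!nzchar(names(setpoints))))
    abort_param("setpoints must be a named vector")
  if (any(setpoints <= 0)) abort_param("setpoint targets must be positive")
  if (tolerance <= 0) abort_param("tolerance must be > 0")
  if (!all(names(setpoints) %in% names(driven)))
    abort_param("every setpoint must be mapped to exactly one driving load")
  structure(list(setpoints = setpoints, driven = driven[names(setpoints)],
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 outer_sweeps = as.integer(outer_sweeps)),
            class = "calibration_spec")
}

calibration_failure <- function(msg, trace) {
  stop(structure(
    class = c("pelvifem_calibration_error", "pelvifem_error",
              "error", "condition"),
    list(message = msg, call = NULL, trace = trace)))
}

#' Calibrate traction magnitudes to displacement setpoints
#'
#' Adjusts the magnitude of each driven traction until the corresponding
#' reference-point displacement matches its setpoint within tolerance.
#' Deterministic given model and spec; the full iteration trace is
#' returned. A non-monotone or non-bracketable magnitude-displacement
#' response raises a structured calibration failure carrying the trace.
#'
#' @param model an `fe_model` (typically the no-surgery model).
#' @param case a `load_case` whose tractions include the driven loads; the
#'   magnitudes in `case` are the initial guesses.
#' @param spec a [calibration_spec()].
#' @param geometry the `pelvic_geometry` (needed for the PCL measurement
#'   unless `measure_fn` is supplied).
#' @param measure_fn optional function(simulation_result) returning a named
#'   vector of achieved values for the setpoint names; defaults to the PCL
#'   descent of the driven reference points.
#' @param initial_state optional displacement matrix used to warm-start the
#'   first solve (e.g. a previously converged state of the same model).
#' @return an object of class `calibration_result`: `magnitudes` (MPa),
#'   `case` (calibrated), `result` (final `simulation_result`), `achieved`,
#'   `trace` (tibble), `converged`, `n_solves`.
#' @export
calibrate_loads <- function(model, case, spec, geometry = NULL,
                            measure_fn = NULL, initial_state = NULL) {
  stopifnot(inherits(model, "fe_model"), inherits(case, "load_case"),
            inherits(spec, "calibration_spec"))
  pts <- names(spec$setpoints)
  for (ld in spec$driven) {
    if (is.null(case$tractions[[ld]]))
      abort_param(paste("case lacks the driven traction", ld))
  }
  if (is.null(measure_fn)) {
    if (is.null(geometry))
      abort_param("geometry is required for the default PCL measurement")
    measure_fn <- function(res) {
      d <- measure_descent(model, geometry, res)
      v <- c(Ba = d$Ba_mm, C = d$C_mm, Bp = d$Bp_mm)
      v[pts]
    }
  }
  trace <- list()
  n_solves <- 0L
  warm <- initial_state
  evaluate <- function(cs) {
    res <- solve_quasi_static(model, cs, initial_guess = warm)
    n_solves <<- n_solves + 1L
    if (res$converged) warm <<- res$displacement
    res
  }
  log_row <- function(sweep, point, iter, mag, ach) {
    trace[[length(trace) + 1]] <<- tibble::tibble(
      sweep = sweep, point = point, load = spec$driven[[point]],
      iteration = iter, magnitude = mag, achieved = ach,
      target = spec$setpoints[[point]])
  }
  trace_tbl <- function() if (length(trace)) dplyr::bind_rows(trace) else
    tibble::tibble(sweep = integer(), point = character(), load = character(),
                   iteration = integer(), magnitude = numeric(),
                   achieved = numeric(), target = numeric())

  res <- evaluate(case)
  if (!res$converged)
    calibration_failure("model not solvable at the initial magnitudes",
                        trace_tbl())
  achieved <- measure_fn(res)

  for (sweep in seq_len(spec$outer_sweeps)) {
    for (p in pts) {
      ld <- spec$driven[[p]]
      target <- spec$setpoints[[p]]
      m0 <- case$tractions[[ld]]$magnitude
      g0 <- achieved[[p]]
      log_row(sweep, p, 0L, m0, g0)
      if (abs(g0 - target) <= spec$tolerance) next
      # history of (magnitude, achieved) pairs for this scalar solve
      hist_m <- m0; hist_g <- g0
      m_prev <- m0; g_prev <- g0
      m_cur <- if (g0 > 1e-6) m0 * min(max(target / g0, 0.2), 5) else m0 * 2
      ok <- FALSE
      for (it in seq_len(spec$max_iter)) {
        cs <- case
        cs$tractions[[ld]]$magnitude <- m_cur
        r <- evaluate(cs)
        if (!r$converged) {
          # magnitude overshoots the solvable range; retreat toward the
          # last solvable magnitude
          m_cur <- (m_cur + m_prev) / 2
          log_row(sweep, p, it, m_cur, NA_real_)
          next
        }
        g_cur <- measure_fn(r)[[p]]
        hist_m <- c(hist_m, m_cur); hist_g <- c(hist_g, g_cur)
        log_row(sweep, p, it, m_cur, g_cur)
        case <- cs; res <- r; achieved <- measure_fn(r)
        if (abs(g_cur - target) <= spec$tolerance) { ok <- TRUE; break }
        # monotone response check over the sampled points
        ord <- order(hist_m)
        if (any(diff(hist_g[ord]) <= -1e-6))
          calibration_failure(sprintf(
            "non-monotone displacement response for load '%s'", ld),
            trace_tbl())
        # damped secant update with bracket/bisection fallback
        denom <- g_cur - g_prev
        m_new <- if (abs(denom) > 1e-12)
          m_cur - (g_cur - target) * (m_cur - m_prev) / denom else m_cur * 1.5
        lo <- hist_m[hist_g < target]; hi <- hist_m[hist_g > target]
        if (length(lo) && length(hi)) {
          blo <- max(lo); bhi <- min(hi)
          if (!is.finite(m_new) || m_new <= blo || m_new >= bhi)
            m_new <- (blo + bhi) / 2
        } else if (!is.finite(m_new) || m_new <= 0) {
          m_new <- m_cur * if (g_cur < target) 2 else 0.5
        }
        m_new <- min(max(m_new, m_cur / 5), m_cur * 5)
        m_prev <- m_cur; g_prev <- g_cur; m_cur <- m_new
      }
      if (!ok)
        calibration_failure(sprintf(
          "setpoint %s not bracketable within %d iterations", p,
          spec$max_iter), trace_tbl())
    }
    achieved <- measure_fn(res)
    if (all(abs(achieved - spec$setpoints[pts]) <= spec$tolerance)) {
      mags <- vapply(case$tractions, function(tr) tr$magnitude, numeric(1))
      return(structure(list(
        magnitudes = mags, case = case, result = res,
        achieved = achieved, setpoints = spec$setpoints,
        trace = trace_tbl(), converged = TRUE, n_solves = n_solves,
        sweeps = sweep), class = "calibration_result"))
    }
  }
  calibration_failure("calibration sweeps exhausted without joint convergence",
                      trace_tbl())
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> converged in", x$sweeps, "sweep(s),",
      x$n_solves, "solves\n")
  for (p in names(x$achieved))
    cat(sprintf("  %s: achieved %.3f mm (target %.3f)\n", p,
                x$achieved[[p]], x$setpoints[[p]]))
  cat("  magnitudes (MPa):",
      paste(sprintf("%s=%.5g", names(x$magnitudes), x$magnitudes),
            collapse = ", "), "\n")
  invisible(x)
}
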