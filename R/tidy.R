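# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation result into a per-node tibble
#'
#' @param x a `simulation_result`.
#' @param model the `fe_model` that produced it (for node coordinates).
#' @param ... unused.
#' @return a tibble with node id, reference coordinates, displacement
#'   components and magnitude (mm).
#' @method tidy simulation_result
#' @export
tidy.simulation_result <- function(x, model = NULL, ...) {
  u <- x$displacement
  out <- tibble::tibble(
    node = seq_len(nrow(u)),
    ux = u[, 1], uy = u[, 2], uz = u[, 3],
    magnitude = rownorms(u))
  if (!is.null(model)) {
    out$x <- model$mesh$nodes[, 1]
    out$y <- model$mesh$nodes[, 2]
    out$z <- model$mesh$nodes[, 3]
  }
  out
}

#' One-row summary of a simulation result
#' @param x a `simulation_result`.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance simulation_result
#' @export
glance.simulation_result <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    load_factor = x$load_factor,
    increments = nrow(x$steps),
    bisections = x$n_bisections,
    total_iterations = sum(x$steps$iterations),
    final_residual = if (nrow(x$steps)) x$steps$final_residual[nrow(x$steps)]
      else NA_real_,
    max_displacement_mm = max(rownorms(x$displacement)))
}

#' Tidy a calibration result into its iteration trace
#' @param x a `calibration_result`.
#' @param ... unused.
#' @return the trace tibble (sweep, point, load, iteration, magnitude,
#'   achieved, target).
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) x$trace

#' One-row summary of a calibration result
#' @param x a `calibration_result`.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    sweeps = x$sweeps,
    n_solves = x$n_solves,
    max_setpoint_error_mm = max(abs(x$achieved - x$setpoints[names(x$achieved)])))
}

#' Plot a descent report
#'
#' Bar chart of the Ba / C / Bp PCL descents per surgery configuration,
#' mirroring the study's per-configuration comparison figures.
#'
#' @param object a `descent_report` tibble (from [run_study()]).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot descent_report
#' @export
autoplot.descent_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr_pivot(df)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$configuration,
                                     y = .data$descent_mm,
                                     fill = .data$point)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "PCL descent (mm)", fill = "point") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df) {
  parts <- lapply(c("Ba", "C", "Bp"), function(p)
    tibble::tibble(configuration = df$configuration, point = p,
                   descent_mm = df[[paste0(p, "_mm")]]))
  dplyr::bind_rows(parts)
}

#' @importFrom rlang .data
NULL
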