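# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

rownorms <- function(m) sqrt(rowSums(m^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  # vectorised cross product for n x 3 matrices (or length-3 vectors)
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' Evaluate a quadratic Bezier curve
#' @noRd
bezier3 <- function(s, p0, p1, p2) {
  s <- as.numeric(s)
  b0 <- (1 - s)^2
  b1 <- 2 * s * (1 - s)
  b2 <- s^2
  cbind(
    b0 * p0[1] + b1 * p1[1] + b2 * p2[1],
    b0 * p0[2] + b1 * p1[2] + b2 * p2[2],
    b0 * p0[3] + b1 * p1[3] + b2 * p2[3]
  )
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_pelvifem <- function(msg, class) {
  stop(structure(
    class = c(class, "pelvifem_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_param <- function(msg) stop_pelvifem(msg, "pelvifem_parameter_error")
abort_geometry <- function(msg) stop_pelvifem(msg, "pelvifem_geometry_error")
abort_model <- function(msg) stop_pelvifem(msg, "pelvifem_model_error")
abort_state <- function(msg) stop_pelvifem(msg, "pelvifem_state_error")
abort_validation <- function(msg) stop_pelvifem(msg, "pelvifem_validation_error")
abort_calibration <- function(msg) stop_pelvifem(msg, "pelvifem_calibration_error")
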