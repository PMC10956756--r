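#' Constitutive material models
#'
#' Two kinds are supported: a two-term Yeoh hyperelastic solid,
#' W(I1) = C0 (I1 - 3) + C1 (I1 - 3)^2 (MPa), used for the hollow organs
#' under an incompressible plane-stress membrane reduction, and a linear
#' St. Venant-Kirchhoff solid (E, nu) used for the pelvic floor, fasciae,
#' ligaments, links and sutures.
#'
#' @param kind `"yeoh"` or `"linear_elastic"`.
#' @param C0,C1 Yeoh coefficients (MPa); C0 > 0, C1 >= 0.
#' @param E Young modulus (MPa), > 0.
#' @param nu Poisson ratio, in [0, 0.5).
#' @param tension_only for truss use: the element carries no force in
#'   compression (a filament cannot push).
#' @param compression_factor for truss use: fraction of the tensile
#'   stiffness retained in compression. Defaults to 0 when `tension_only`
#'   and 1 otherwise; intermediate values model connective-tissue strands
#'   that buckle rather than push (and keep the tangent regular).
#' @return an object of class `material_model`.
#' @export
material_model <- function(kind = c("yeoh", "linear_elastic"),
                           C0 = NULL, C1 = NULL, E = NULL, nu = 0.45,
                           tension_only = FALSE, compression_factor = NULL) {
  kind <- match.arg(kind)
  if (kind == "yeoh") {
    if (is.null(C0) || is.null(C1)) abort_param("yeoh material needs C0 and C1")
    if (C0 <= 0) abort_param("C0 must be > 0")
    if (C1 < 0) abort_param("C1 must be >= 0")
  } else {
    if (is.null(E)) abort_param("linear_elastic material needs E")
    if (E <= 0) abort_param("E must be > 0")
    if (nu < 0 || nu >= 0.5) abort_param("nu must be in [0, 0.5)")
  }
  if (is.null(compression_factor))
    compression_factor <- if (isTRUE(tension_only)) 0 else 1
  if (compression_factor < 0 || compression_factor > 1)
    abort_param("compression_factor must be in [0, 1]")
  structure(list(kind = kind, C0 = C0, C1 = C1, E = E, nu = nu,
                 tension_only = isTRUE(tension_only),
                 compression_factor = compression_factor),
            class = "material_model")
}

yeoh <- function(C0, C1) material_model("yeoh", C0 = C0, C1 = C1)
linel <- function(E, nu = 0.45, tension_only = FALSE, compression_factor = NULL)
  material_model("linear_elastic", E = E, nu = nu, tension_only = tension_only,
                 compression_factor = compression_factor)

#' Default material assignment table
#'
#' Yeoh coefficients for the hollow organs: vagina C0 0.111 / C1 0.27,
#' bladder 0.0375 / 0.07, rectum 0.085 / 0.056 (MPa). Linear elasticity for
#' the pelvic floor (E 0.1 MPa) and fasciae (E 0.18 MPa), nu 0.45.
#' Ligament and link trusses use linear elasticity; sutures are stiff
#' (E 1000 MPa) tension-only filaments.
#'
#' @param overrides named list of `material_model` objects replacing
#'   defaults by structure label.
#' @return named list of `material_model` objects keyed by structure label.
#' @export
default_materials <- function(overrides = NULL) {
  mats <- list(
    vagina = yeoh(0.111, 0.27),
    bladder = yeoh(0.0375, 0.07),
    rectum = yeoh(0.085, 0.056),
    pelvic_floor = linel(0.1, 0.45),
    fascia_pubocervical = linel(0.18, 0.45),
    fascia_endopelvic = linel(0.18, 0.45),
    sacrospinous = linel(10, tension_only = TRUE, compression_factor = 1e-3),
    uterosacral = linel(2, tension_only = TRUE, compression_factor = 1e-3),
    cardinal = linel(2, tension_only = TRUE, compression_factor = 1e-3),
    round = linel(1, tension_only = TRUE, compression_factor = 1e-3),
    broad = linel(1, tension_only = TRUE, compression_factor = 1e-3),
    ATFP = linel(5, tension_only = TRUE, compression_factor = 1e-3),
    link = linel(0.18, tension_only = TRUE, compression_factor = 1e-3),
    # the rectovaginal space is loose areolar tissue, and in a stage-III
    # apical prolapse the septal attachment is defective: its tether links
    # are orders of magnitude softer than the condensed fascial sheets
    link_endopelvic = linel(2e-4, tension_only = TRUE, compression_factor = 1e-3),
    # the tightened fixation acts as a tie: the filament constrains the
    # apex to the ligament in both directions
    suture = linel(1000)
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!inherits(overrides[[nm]], "material_model"))
        abort_param(paste("override", nm, "is not a material_model"))
      mats[[nm]] <- overrides[[nm]]
    }
  }
  mats
}

# resolve a structure label to its material: exact match first, then the
# endopelvic (rectovaginal) link family, then the generic link material
material_for <- function(materials, label) {
  if (!is.null(materials[[label]])) return(materials[[label]])
  if (startsWith(label, "link_fascia_endopelvic") &&
      !is.null(materials[["link_endopelvic"]]))
    return(materials[["link_endopelvic"]])
  if (startsWith(label, "link_")) return(materials[["link"]])
  abort_param(paste("no material assigned for structure label", label))
}

#' Yeoh strain-energy density
#'
#' W(I1) = C0 (I1 - 3) + C1 (I1 - 3)^2, with I1 the first invariant of the
#' right Cauchy-Green tensor. W(3) = 0 and W is strictly increasing in I1
#' for I1 > 3 (C0 > 0).
#'
#' @param I1 first invariant (>= 3 up to round-off for an incompressible
#'   attainable state); vectorised.
#' @param material a `material_model` of kind `"yeoh"`.
#' @return energy density in MPa.
#' @export
yeoh_energy_density <- function(I1, material) {
  if (!inherits(material, "material_model") || material$kind != "yeoh")
    abort_state("yeoh_energy_density requires a yeoh material")
  if (any(I1 < 3 - 1e-12)) abort_state("I1 below 3 is not attainable")
  x <- pmax(I1 - 3, 0)
  material$C0 * x + material$C1 * x^2
}

#' In-plane principal Cauchy stresses of a membrane under plane stress
#'
#' For a Yeoh membrane the incompressible plane-stress reduction gives
#' thickness stretch lambda3 = 1/(lambda1 lambda2),
#' I1 = lambda1^2 + lambda2^2 + lambda3^2, and principal Cauchy stresses
#' sigma_i = 2 W'(I1) (lambda_i^2 - lambda3^2) with the transverse normal
#' stress identically zero. For a linear (St. Venant-Kirchhoff) membrane
#' the 2-D plane-stress law is used. Stress vanishes in the reference
#' configuration lambda1 = lambda2 = 1.
#'
#' @param lambda1,lambda2 in-plane principal stretches (> 0).
#' @param material a `material_model`.
#' @return a list with `sigma1`, `sigma2` (MPa), `lambda3`, `I1`.
#' @export
membrane_stress <- function(lambda1, lambda2, material) {
  if (any(lambda1 <= 0) || any(lambda2 <= 0))
    abort_state("principal stretches must be > 0")
  if (material$kind == "yeoh") {
    l3 <- 1 / (lambda1 * lambda2)
    I1 <- lambda1^2 + lambda2^2 + l3^2
    Wp <- material$C0 + 2 * material$C1 * (I1 - 3)
    list(sigma1 = 2 * Wp * (lambda1^2 - l3^2),
         sigma2 = 2 * Wp * (lambda2^2 - l3^2),
         lambda3 = l3, I1 = I1)
  } else {
    E1 <- (lambda1^2 - 1) / 2; E2 <- (lambda2^2 - 1) / 2
    k <- material$E / (1 - material$nu^2)
    S1 <- k * (E1 + material$nu * E2)
    S2 <- k * (E2 + material$nu * E1)
    J <- lambda1 * lambda2
    list(sigma1 = lambda1^2 * S1 / J, sigma2 = lambda2^2 * S2 / J,
         lambda3 = 1, I1 = lambda1^2 + lambda2^2 + 1)
  }
}

#' Axial force of a linear-elastic truss filament
#'
#' N = E A (lambda - 1) for lambda >= 1; a tension-only filament carries
#' zero force when slack (lambda < 1).
#'
#' @param lambda axial stretch (current length / reference length).
#' @param material a linear-elastic `material_model`.
#' @param area cross-section area (mm^2).
#' @param tension_only logical; defaults to the material's flag.
#' @return axial force in N (positive in tension).
#' @export
truss_force <- function(lambda, material, area,
                        tension_only = material$tension_only) {
  if (material$kind != "linear_elastic")
    abort_state("truss_force requires a linear_elastic material")
  N <- material$E * area * (lambda - 1)
  if (tension_only) N[lambda < 1] <- 0
  N
}
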