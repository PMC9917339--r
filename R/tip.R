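#' Tip geometry for contact-mechanics models
#'
#' Describes the AFM tip used to convert force--indentation data into moduli.
#' Spheres and paraboloids share the same Hertz force law
#' \eqn{F = (4/3) (E/(1-\nu^2)) \sqrt{R} \delta^{3/2}}; cones follow
#' \eqn{F = (2/\pi) \tan\theta (E/(1-\nu^2)) \delta^2}.
#'
#' @param kind one of `"sphere"`, `"paraboloid"`, `"cone"`.
#' @param radius tip radius in m (sphere/paraboloid only).
#' @param half_angle cone half-opening angle in rad (cone only).
#' @param poisson Poisson's ratio of the sample; default 0.5
#'   (incompressible cell).
#' @return an object of class `tip_geometry`.
#' @examples
#' tip_geometry("sphere", radius = 5.5e-6)
#' tip_geometry("cone", half_angle = 20 * pi / 180)
#' @export
tip_geometry <- function(kind = c("sphere", "paraboloid", "cone"),
                         radius = NULL, half_angle = NULL, poisson = 0.5) {
  kind <- match.arg(kind)
  if (kind %in% c("sphere", "paraboloid")) {
    if (is.null(radius) || !is.finite(radius) || radius <= 0)
      stop("tip_geometry: '", kind, "' requires radius > 0", call. = FALSE)
    if (!is.null(half_angle))
      stop("tip_geometry: half_angle is only valid for kind = 'cone'",
           call. = FALSE)
  } else {
    if (is.null(half_angle) || !is.finite(half_angle) ||
        half_angle <= 0 || half_angle >= pi / 2)
      stop("tip_geometry: 'cone' requires 0 < half_angle < pi/2",
           call. = FALSE)
    if (!is.null(radius))
      stop("tip_geometry: radius is only valid for sphere/paraboloid",
           call. = FALSE)
  }
  if (!is.finite(poisson) || poisson < 0 || poisson > 0.5)
    stop("tip_geometry: poisson must be in [0, 0.5]", call. = FALSE)
  structure(list(kind = kind, radius = radius, half_angle = half_angle,
                 poisson = poisson),
            class = "tip_geometry")
}

#' @export
print.tip_geometry <- function(x, ...) {
  if (x$kind == "cone") {
    cat(sprintf("<tip_geometry> cone, half angle %.1f deg, nu = %.2f\n",
                x$half_angle * 180 / pi, x$poisson))
  } else {
    cat(sprintf("<tip_geometry> %s, R = %.3g m, nu = %.2f\n",
                x$kind, x$radius, x$poisson))
  }
  invisible(x)
}

# geometric prefactor c and exponent p of the contact law F = c * E * delta^p
contact_law <- function(tip) {
  stopifnot(inherits(tip, "tip_geometry"))
  nu2 <- 1 - tip$poisson^2
  if (tip$kind == "cone") {
    list(coef = 2 * tan(tip$half_angle) / (pi * nu2), exponent = 2)
  } else {
    list(coef = 4 * sqrt(tip$radius) / (3 * nu2), exponent = 1.5)
  }
}

#' Hertz contact force at a given indentation
#'
#' @param delta indentation in m (values < 0 give zero force).
#' @param E Young's modulus in Pa.
#' @param tip a [tip_geometry()].
#' @return force in N, same length as `delta`.
#' @examples
#' tip <- tip_geometry("sphere", radius = 5.5e-6)
#' hertz_force(500e-9, E = 1000, tip = tip) # 1.474 nN
#' @export
hertz_force <- function(delta, E, tip) {
  law <- contact_law(tip)
  ifelse(delta > 0, law$coef * E * delta^law$exponent, 0)
}

# dF/ddelta at operating indentation delta0; with a complex modulus this is
# the linearized contact transfer H(f) [N/m] relating force to indentation
# oscillations about delta0
contact_stiffness <- function(E, tip, delta0) {
  stopifnot(delta0 > 0)
  nu2 <- 1 - tip$poisson^2
  if (tip$kind == "cone") {
    4 * tan(tip$half_angle) * delta0 / (pi * nu2) * E
  } else {
    2 * sqrt(tip$radius * delta0) / nu2 * E
  }
}

# inverse of contact_stiffness: modulus per unit transfer
modulus_from_transfer <- function(transfer, tip, delta0) {
  transfer / contact_stiffness(1, tip, delta0)
}
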