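#' Radial chemoattractant field around a spherical egg
#'
#' Radially symmetric concentration field established by diffusion from a
#' spherical source of radius `source_radius` (the egg). The profile is
#' the \eqn{1/R} solution of spherical diffusion multiplied by a
#' stretched-exponential cut-off,
#' \deqn{c(R) = c_s \frac{R_{egg}}{R}
#'   \exp\!\left[-\left(\frac{R-R_{egg}}{\ell}\right)^{\beta}\right],}
#' which reduces to the bare \eqn{1/R} solution for `ell = Inf`.
#' `shape = 1` is steady-state diffusion with first-order clearance of
#' the chemoattractant (a screened point source); `shape = 2` mimics the
#' Gaussian front of a finite-duration release; intermediate values
#' interpolate. The cut-off confines detectable signal to a finite
#' neighbourhood of the egg, which is what places the noise-zone
#' boundaries and attraction radii at millimetre distances.
#'
#' The gradient points towards the egg centre everywhere (the profile is
#' strictly decreasing).
#'
#' @param surface_concentration concentration at the egg surface (pM).
#' @param source_radius egg radius (\eqn{\mu}m).
#' @param ell screening length (\eqn{\mu}m); `Inf` for pure \eqn{1/R}.
#' @param shape stretching exponent \eqn{\beta \ge 1} of the cut-off.
#' @return Object of class `helitax_field`.
#' @seealso [concentration()], [snr()], [zone_boundaries()]
#' @export
radial_field <- function(surface_concentration, source_radius = 100,
                         ell = Inf, shape = 1) {
  stopifnot(surface_concentration > 0, source_radius > 0, ell > 0,
            shape >= 1)
  structure(list(type = "radial", type_code = 0L,
                 c_surf = surface_concentration,
                 source_radius = source_radius, ell = ell, shape = shape),
            class = "helitax_field")
}

#' Uniform concentration field (testing hook)
#'
#' Constant concentration, zero gradient everywhere. Used to probe the
#' noise-driven rotational diffusion of the centreline in isolation.
#'
#' @param c0 concentration (pM).
#' @export
uniform_field <- function(c0) {
  stopifnot(c0 >= 0)
  structure(list(type = "uniform", type_code = 1L, c0 = c0),
            class = "helitax_field")
}

#' Linear concentration gradient (testing hook)
#'
#' \eqn{c(x) = c_0 + g\,(\hat d \cdot x)}, clipped at zero. The
#' weak-gradient limit of the coarse-grained theory is exact in this field
#' because the gradient direction is constant in space.
#'
#' @param c0 background concentration (pM).
#' @param slope gradient magnitude (pM/\eqn{\mu}m).
#' @param direction gradient direction (3-vector, normalized internally).
#' @export
linear_field <- function(c0, slope, direction = c(0, 0, 1)) {
  stopifnot(c0 > 0, length(direction) == 3)
  structure(list(type = "linear", type_code = 2L, c0 = c0, slope = slope,
                 direction = direction / sqrt(sum(direction^2))),
            class = "helitax_field")
}

#' @export
print.helitax_field <- function(x, ...) {
  switch(x$type,
    radial = cat(sprintf(
      "radial field: c_surface = %g pM at R_egg = %g um, ell = %g um\n",
      x$c_surf, x$source_radius, x$ell)),
    uniform = cat(sprintf("uniform field: c0 = %g pM\n", x$c0)),
    linear = cat(sprintf("linear field: c0 = %g pM, slope = %g pM/um\n",
                         x$c0, x$slope)))
  invisible(x)
}

#' Concentration at distance R from the egg centre
#'
#' @param field a [radial_field()].
#' @param R distance(s) from the egg centre (\eqn{\mu}m); must be
#'   \eqn{\ge} the egg radius.
#' @return concentration (pM).
#' @export
concentration <- function(field, R) {
  stopifnot(inherits(field, "helitax_field"))
  if (field$type == "uniform") return(rep(field$c0, length(R)))
  if (field$type != "radial")
    stop("concentration(field, R) requires a radially symmetric field")
  if (any(R < field$source_radius))
    stop("R inside the egg (R < source radius)")
  c0 <- field$c_surf * field$source_radius / R
  if (is.finite(field$ell))
    c0 <- c0 * exp(-((R - field$source_radius) / field$ell)^field$shape)
  c0
}

#' Magnitude of the radial concentration gradient
#'
#' \eqn{|dc/dR|}; the gradient vector points towards the egg centre.
#'
#' @inheritParams concentration
#' @return gradient magnitude (pM/\eqn{\mu}m).
#' @export
gradient_magnitude <- function(field, R) {
  if (field$type == "uniform") return(rep(0, length(R)))
  if (field$type == "linear") return(rep(abs(field$slope), length(R)))
  cc <- concentration(field, R)
  screen <- if (is.finite(field$ell)) {
    (field$shape / field$ell) *
      ((R - field$source_radius) / field$ell)^(field$shape - 1)
  } else 0
  cc * (1 / R + screen)
}

# internal: concentration + gradient vector at a 3D position (egg at origin)
field_eval <- function(field, x) {
  if (field$type == "radial") {
    R <- sqrt(sum(x^2))
    cc <- concentration(field, R)
    g <- -gradient_magnitude(field, R) * x / R
    list(c = cc, grad = g)
  } else if (field$type == "uniform") {
    list(c = field$c0, grad = c(0, 0, 0))
  } else {
    list(c = max(field$c0 + field$slope * sum(field$direction * x), 0),
         grad = field$slope * field$direction)
  }
}

#' Signal-to-noise ratio of helical gradient sensing
#'
#' Ratio between the power of the periodic binding-rate modulation caused
#' by helical swimming perpendicular to the gradient (amplitude
#' \eqn{\lambda |\nabla c| r_0}) and the shot-noise strength of the
#' binding input relative to one helix period,
#' \deqn{\mathrm{SNR}(R) = \frac{(\lambda|\nabla c| r_0)^2 / 2}
#'   {\lambda c / T}.}
#'
#' @inheritParams concentration
#' @param params a [model_params()] object supplying \eqn{r_0},
#'   \eqn{\lambda} and the helix period \eqn{T}.
#' @return dimensionless SNR.
#' @export
snr <- function(field, R, params) {
  g <- gradient_magnitude(field, R)
  cc <- concentration(field, R)
  out <- (params$lambda * g * params$r0)^2 / 2 /
    (params$lambda * cc / params$T_helix)
  out[cc <= 0] <- 0   # signal underflow far from the source
  out
}

#' Noise-zone geometry of a radial field
#'
#' Computes the noise-zone boundary `N`, where the signal-to-noise ratio of
#' gradient sensing equals one, and the spatial limit of chemosensation
#' `S`, where on average a single molecule is detected per helical turn,
#' \eqn{c(S) = (\lambda T)^{-1}}. Detectable-but-unreliable signal exists
#' in the annulus \eqn{N < R < S} (the noise zone).
#'
#' Both radii are found by bracketed root finding on
#' \eqn{[R_{egg}, R_{max}]} to relative tolerance 1e-10; a root whose
#' bracket shows no sign change is reported as `NA` with a warning
#' ("boundary outside domain").
#'
#' @inheritParams snr
#' @param R_max outer end of the search bracket (\eqn{\mu}m); defaults to
#'   `10 * params$R_th`.
#' @return List with elements `N` and `S` (\eqn{\mu}m).
#' @export
zone_boundaries <- function(field, params, R_max = 10 * params$R_th) {
  stopifnot(field$type == "radial")
  root <- function(f, what) {
    lo <- field$source_radius
    if (f(lo) * f(R_max) > 0) {
      warning(sprintf("%s boundary outside domain [R_egg, R_max]", what))
      return(NA_real_)
    }
    uniroot(f, c(lo, R_max), tol = 1e-10 * R_max)$root
  }
  N <- root(function(R) snr(field, R, params) - 1, "noise (N)")
  S <- root(function(R) concentration(field, R) -
              1 / (params$lambda * params$T_helix), "sensation (S)")
  list(N = N, S = S)
}

#' Default calibrated chemoattractant field
#'
#' The screened radial field shipped as the package's study condition.
#' Surface concentration and screening length are calibration constants:
#' they were fixed once so that the noise-free attraction radii of low-
#' and high-gain steering and the noise-zone geometry fall at the
#' millimetre distances characteristic of sea-urchin egg chemoattraction
#' (see the package vignette); both are plain arguments and can be
#' overridden.
#'
#' @param surface_concentration egg-surface concentration (pM).
#' @param ell screening length (\eqn{\mu}m).
#' @param shape stretching exponent of the cut-off.
#' @param source_radius egg radius (\eqn{\mu}m).
#' @export
default_field <- function(surface_concentration = 24000, ell = 1305,
                          shape = 1.6, source_radius = 100) {
  radial_field(surface_concentration, source_radius, ell, shape)
}
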