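#' Helix geometry from radius and pitch
#'
#' Inverts the perfect-helix relations. A cell swimming with speed `v` at
#' constant curvature \eqn{\kappa_0} and torsion \eqn{\tau_0} traces a helix
#' with radius \eqn{r_0 = \kappa_0/(\kappa_0^2+\tau_0^2)}, pitch
#' \eqn{2\pi h_0} with \eqn{h_0 = \tau_0/(\kappa_0^2+\tau_0^2)}, angular
#' frequency \eqn{\Omega_0 = v\sqrt{\kappa_0^2+\tau_0^2}} and period
#' \eqn{T = 2\pi/\Omega_0}.
#'
#' @param v swimming speed (\eqn{\mu}m/s).
#' @param r0 helix radius (\eqn{\mu}m).
#' @param pitch helix pitch \eqn{2\pi h_0} (\eqn{\mu}m); `0` gives a planar
#'   circle.
#' @return List with `kappa0`, `tau0` (1/\eqn{\mu}m), `Omega0` (rad/s) and
#'   `T` (s).
#' @examples
#' helix_geometry(v = 200, r0 = 7.5, pitch = 48.3)$T # about 0.34 s
#' @export
helix_geometry <- function(v, r0, pitch) {
  stopifnot(v > 0, r0 > 0, pitch >= 0)
  h0 <- pitch / (2 * pi)
  s2 <- r0^2 + h0^2
  list(kappa0 = r0 / s2,
       tau0 = h0 / s2,
       Omega0 = v / sqrt(s2),
       T = 2 * pi * sqrt(s2) / v)
}

#' Physical and numerical model parameters
#'
#' Collects every constant of the closed control loop: swimming kinematics,
#' ligand binding, signalling time scales, the two steering gain factors,
#' and the stopping rules of a single search attempt. Derived helix
#' quantities (curvature \eqn{\kappa_0}, torsion \eqn{\tau_0}, angular
#' frequency \eqn{\Omega_0}, period `T_helix`, axial drift speed
#' `v_parallel`, geometric factor `eps`) are computed on construction.
#'
#' Defaults reproduce the sea-urchin study conditions: speed 200
#' \eqn{\mu}m/s, helix radius 7.5 \eqn{\mu}m, pitch 48.3 \eqn{\mu}m (period
#' 0.34 s), binding constant \eqn{\lambda} = 7 s\eqn{^{-1}}pM\eqn{^{-1}},
#' egg radius 100 \eqn{\mu}m, gain factors \eqn{\rho_{low}} = 1 and
#' \eqn{\rho_{high}} = 10, maximum search time 300 s.
#'
#' The adaptation time `mu` defaults to \eqn{1/\Omega_0} so that the
#' band-pass formed by adaptive signalling is centred on the helix
#' frequency (unit normalized gain, zero phase lag at \eqn{\Omega_0}); the
#' trigger relaxation time `eta` defaults to a few helix periods so that
#' the trigger variable suppresses within-turn oscillations while tracking
#' baseline shifts.
#'
#' @param v swimming speed (\eqn{\mu}m/s).
#' @param r0 helix radius (\eqn{\mu}m).
#' @param pitch helix pitch (\eqn{\mu}m).
#' @param rho_low,rho_high gain factors of the two steering modes.
#' @param lambda binding constant (s\eqn{^{-1}} pM\eqn{^{-1}}).
#' @param mu adaptation/relaxation time of the signalling module (s).
#' @param eta relaxation time of the trigger variable (s).
#' @param c_b concentration threshold of sensory adaptation (pM).
#' @param R_egg egg radius = capture distance (\eqn{\mu}m).
#' @param R_th failure threshold distance (\eqn{\mu}m); crossing it ends a
#'   search attempt.
#' @param t_max maximum search time (s).
#' @param dt integration step (s); default `T_helix / 200`.
#' @return Object of class `helitax_params` (a list).
#' @examples
#' par <- model_params()
#' par$T_helix
#' @export
model_params <- function(v = 200, r0 = 7.5, pitch = 48.3,
                         rho_low = 1, rho_high = 10,
                         lambda = 7, mu = NULL, eta = NULL, c_b = 12,
                         R_egg = 100, R_th = 10000, t_max = 300,
                         dt = NULL) {
  g <- helix_geometry(v, r0, pitch)
  if (is.null(mu)) mu <- 1 / g$Omega0
  if (is.null(eta)) eta <- 4 * g$T
  if (is.null(dt)) dt <- g$T / 200
  stopifnot(mu > 0, eta > 0, c_b >= 0, R_egg > 0, R_th > R_egg,
            t_max > 0, dt > 0)
  if (dt > mu / 5 || dt > eta / 5)
    stop("dt too large relative to signalling time scales mu, eta")
  p <- list(v = v, r0 = r0, pitch = pitch, h0 = pitch / (2 * pi),
            kappa0 = g$kappa0, tau0 = g$tau0,
            Omega0 = g$Omega0, T_helix = g$T,
            v_parallel = g$Omega0 * pitch / (2 * pi),
            eps = geometric_factor(g$kappa0, g$tau0),
            rho_low = rho_low, rho_high = rho_high,
            lambda = lambda, mu = mu, eta = eta, c_b = c_b,
            R_egg = R_egg, R_th = R_th, t_max = t_max, dt = dt)
  class(p) <- "helitax_params"
  p
}

#' @export
print.helitax_params <- function(x, ...) {
  cat("helitax model parameters\n")
  cat(sprintf("  swimming: v = %g um/s, r0 = %g um, pitch = %g um\n",
              x$v, x$r0, x$pitch))
  cat(sprintf("  helix: kappa0 = %.5g 1/um, tau0 = %.5g 1/um, T = %.4g s\n",
              x$kappa0, x$tau0, x$T_helix))
  cat(sprintf("  signalling: lambda = %g /s/pM, mu = %.4g s, eta = %.4g s, c_b = %g pM\n",
              x$lambda, x$mu, x$eta, x$c_b))
  cat(sprintf("  gains: rho_low = %g, rho_high = %g\n", x$rho_low, x$rho_high))
  cat(sprintf("  search: R_egg = %g um, R_th = %g um, t_max = %g s, dt = %.4g s\n",
              x$R_egg, x$R_th, x$t_max, x$dt))
  invisible(x)
}

# internal: flatten params for the C++ core
par_list <- function(params) {
  params[c("v", "kappa0", "tau0", "lambda", "mu", "eta", "c_b",
           "R_egg", "R_th", "t_max", "dt", "rho_low", "rho_high")]
}
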