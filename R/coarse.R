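#' Geometric factor of helical steering
#'
#' \eqn{\epsilon = 2\pi\kappa_0\tau_0/(\kappa_0^2+\tau_0^2)}: how
#' efficiently a modulation of curvature and torsion at the helix
#' frequency re-orients the helix axis. It vanishes for a planar circle
#' (\eqn{\tau_0 = 0}, no out-of-plane steering) and is maximal
#' (\eqn{\epsilon = \pi}) for \eqn{\kappa_0 = \tau_0}.
#'
#' @param kappa0,tau0 curvature and torsion (1/\eqn{\mu}m).
#' @return dimensionless factor.
#' @export
geometric_factor <- function(kappa0, tau0) {
  2 * pi * kappa0 * tau0 / (kappa0^2 + tau0^2)
}

#' Deterministic bending rate of the helix centreline
#'
#' Noise-averaged rate at which the centreline tangent rotates towards
#' the local concentration gradient, valid in the weak-gradient limit
#' \eqn{|\nabla c| r_0 / c \ll 1}:
#' \deqn{\gamma = \frac{\rho\,\epsilon}{T}\,
#'   \frac{|\nabla c| \sin\Psi \; r_0}{c_b + c}.}
#' The perpendicular gradient component \eqn{|\nabla_\perp c| =
#' |\nabla c|\sin\Psi} is what helical sampling can detect. The rate is
#' linear in the gain factor \eqn{\rho}.
#'
#' @param R distance from the egg centre (\eqn{\mu}m).
#' @param Psi angle between centreline tangent and gradient (rad).
#' @param rho gain factor.
#' @param field a `helitax_field` (radial).
#' @param params a [model_params()] object.
#' @return bending rate (rad/s).
#' @export
bending_rate <- function(R, Psi, rho, field, params) {
  gperp <- gradient_magnitude(field, R) * sin(Psi)
  cc <- concentration(field, R)
  rho * params$eps / params$T_helix * gperp * params$r0 / (params$c_b + cc)
}

#' Effective rotational diffusion of the helix centreline
#'
#' Directional fluctuations of the centreline tangent caused by shot
#' noise in the binding input, amplified quadratically by the gain:
#' \deqn{D = \left(\frac{\rho\,\epsilon}{T}\right)^{\!2}
#'   \frac{c}{\lambda (c_b + c)^2}.}
#' The convention counts both transverse directions: the mean squared
#' angular displacement of the tangent grows as \eqn{4 D t}.
#'
#' @inheritParams bending_rate
#' @return rotational diffusion coefficient (rad\eqn{^2}/s).
#' @export
rotational_diffusion <- function(R, rho, field, params) {
  cc <- concentration(field, R)
  (rho * params$eps / params$T_helix)^2 * cc /
    (params$lambda * (params$c_b + cc)^2)
}

#' Residual of the steering/fluctuation coupling identity
#'
#' The analytic forms of the bending rate and rotational diffusion obey
#' \deqn{\frac{\gamma^2}{D} = \frac{2\sin^2\Psi}{T}\,\mathrm{SNR}(R)}
#' identically -- the gain factor cancels, so fast steering cannot be had
#' without proportionally stronger directional noise. Returns
#' \eqn{\gamma^2/D - (2\sin^2\Psi/T)\,\mathrm{SNR}}, zero to machine
#' precision for any arguments.
#'
#' @inheritParams bending_rate
#' @return residual (rad\eqn{^2}/s\eqn{^2}).
#' @export
snr_identity_check <- function(R, Psi, rho, field, params) {
  g <- bending_rate(R, Psi, rho, field, params)
  D <- rotational_diffusion(R, rho, field, params)
  g^2 / D - 2 * sin(Psi)^2 / params$T_helix * snr(field, R, params)
}

#' Empirical bending rate from noise-free simulation
#'
#' Measures the alignment rate of the simulated centreline tangent in a
#' linear concentration field (where the gradient direction is constant,
#' so \eqn{d\Psi/dt = -\gamma} exactly) and compares it with the analytic
#' weak-gradient prediction. The rate is estimated from the initial decay
#' of \eqn{\Psi(t)} started at \eqn{\Psi = \pi/2}, averaged over initial
#' helix phases.
#'
#' @param field a [linear_field()].
#' @param rho gain factor.
#' @param params a [model_params()] object.
#' @param t_run simulated duration (s).
#' @param n_phases initial helix phases averaged over.
#' @return List with `gamma_emp` (rad/s) and `gamma_theory` evaluated at
#'   the background concentration and \eqn{\Psi = \pi/2}.
#' @export
empirical_bending_rate <- function(field, rho, params, t_run = 40,
                                   n_phases = 4) {
  stopifnot(field$type == "linear")
  par2 <- params
  par2$t_max <- t_run
  par2$R_th <- Inf
  rates <- vapply(seq_len(n_phases), function(i) {
    ph <- (i - 1) * 2 * pi / n_phases
    # helix axis perpendicular to the gradient (gradient along z)
    tr <- simulate_path(par2, field, rho, R0 = 1e6,
                        orientation = c(1, 0, 0), seed = i, noise = FALSE,
                        phase = ph)
    cl <- extract_centreline(tr, field)
    # fit only while Psi stays near pi/2, where sin(Psi) ~ 1
    ok <- is.finite(cl$Psi) & abs(cl$Psi - pi / 2) < 0.25
    fit <- lm(Psi ~ t, data = cl[ok, ])
    -coef(fit)[["t"]]
  }, numeric(1))
  gt <- rho * params$eps / params$T_helix * abs(field$slope) * params$r0 /
    (params$c_b + field$c0)
  list(gamma_emp = mean(rates), gamma_theory = gt)
}

#' Empirical rotational diffusion from noisy simulation
#'
#' In a uniform concentration (no deterministic steering) the centreline
#' tangent performs a random walk on the sphere; its mean squared
#' angular displacement grows as \eqn{4 D t} at short times. `D` is
#' fitted from the ensemble MSD of the tangent over `n_paths`
#' noise-driven simulations and compared with the analytic prediction.
#'
#' @param c0 uniform concentration (pM).
#' @param rho gain factor.
#' @param params a [model_params()] object.
#' @param n_paths ensemble size.
#' @param t_run simulated duration per path (s).
#' @param seed integer seed.
#' @return List with `D_emp` and `D_theory` (rad\eqn{^2}/s).
#' @export
empirical_rotational_diffusion <- function(c0, rho, params, n_paths = 200,
                                           t_run = 30, seed = 1) {
  fld <- uniform_field(c0)
  par2 <- params
  par2$t_max <- t_run
  par2$R_th <- Inf
  # angular MSD at a set of lags, averaged over paths and time origins;
  # lags start beyond the one-period centreline smoothing window, whose
  # residual correlation is absorbed by the fitted intercept
  npp <- 20L
  lag_steps <- seq(3L, 24L, by = 3L)    # units of one helix period
  msd_sum <- numeric(length(lag_steps))
  msd_n <- numeric(length(lag_steps))
  lag_t <- lag_steps * params$T_helix
  for (j in seq_len(n_paths)) {
    tr <- simulate_path(par2, fld, rho, R0 = 1e6, orientation = c(0, 0, 1),
                        seed = seed + j, noise = TRUE)
    cl <- extract_centreline(tr, fld)
    k <- seq(1, nrow(cl), by = npp)     # one tangent sample per period
    Tx <- diff(cl$Cx[k]); Ty <- diff(cl$Cy[k]); Tz <- diff(cl$Cz[k])
    nn <- sqrt(Tx^2 + Ty^2 + Tz^2)
    Tx <- Tx / nn; Ty <- Ty / nn; Tz <- Tz / nn
    m <- length(Tx)
    for (il in seq_along(lag_steps)) {
      L <- lag_steps[il]
      if (m <= L) next
      i <- seq_len(m - L)
      dotp <- pmin(1, pmax(-1, Tx[i] * Tx[i + L] + Ty[i] * Ty[i + L] +
                             Tz[i] * Tz[i + L]))
      msd_sum[il] <- msd_sum[il] + sum(acos(dotp)^2)
      msd_n[il] <- msd_n[il] + length(i)
    }
  }
  msd <- msd_sum / pmax(msd_n, 1)
  keep <- msd_n > 0 & msd < 1         # stay clear of spherical saturation
  fit <- lm(msd[keep] ~ lag_t[keep])
  list(D_emp = coef(fit)[["lag_t[keep]"]] / 4, msd = msd, lag = lag_t,
       D_theory = (rho * params$eps / params$T_helix)^2 * c0 /
         (params$lambda * (params$c_b + c0)^2))
}
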