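#' Curvature and torsion modulation by the signalling output
#'
#' The steering law couples the signalling output to the path geometry:
#' \deqn{\kappa = \kappa_0 [1 - \rho (a - 1)], \qquad
#'       \tau = \tau_0 [1 + \rho (a - 1)].}
#' Curvature is clipped at zero from below (an attribute `clipped` flags
#' when this occurred). The gain factor \eqn{\rho} sets both the steering
#' speed and the amplification of sensing noise.
#'
#' @param a signalling output (dimensionless, rest state 1).
#' @param rho sensori-motor gain factor.
#' @param kappa0,tau0 unperturbed curvature and torsion (1/\eqn{\mu}m).
#' @return List with `kappa`, `tau`.
#' @export
modulate_geometry <- function(a, rho, kappa0, tau0) {
  kap <- kappa0 * (1 - rho * (a - 1))
  clipped <- kap < 0
  kap[clipped] <- 0
  structure(list(kappa = kap, tau = tau0 * (1 + rho * (a - 1))),
            clipped = any(clipped))
}

#' Advance a Frenet frame by one step of constant curvature and torsion
#'
#' Rotates the orthonormal triad (tangent, normal, binormal) by the exact
#' rotation about the Darboux vector \eqn{\tau \hat t + \kappa \hat b}
#' over arc length `v * dt` and advances the position by the exact
#' integral of the rotating tangent, then re-orthonormalizes. A perfect
#' helix therefore closes to machine precision.
#'
#' @param frame 3x3 matrix with rows tangent, normal, binormal.
#' @param position 3-vector (\eqn{\mu}m).
#' @param kappa,tau curvature and torsion (1/\eqn{\mu}m).
#' @param v speed (\eqn{\mu}m/s).
#' @param dt step (s).
#' @return List with updated `frame` and `position`.
#' @export
step_path <- function(frame, position, kappa, tau, v, dt) {
  .frenet_step_cpp(frame, position, kappa, tau, v, dt)
}

# initial condition: centreline at distance R0 from the egg (origin) along
# +x, helix axis along `axis`; `phase` sets the position on the helix circle
helix_start <- function(R0, axis, phase, params) {
  e3 <- axis / sqrt(sum(axis^2))
  ref <- if (abs(e3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  r0 <- params$r0; h0 <- params$h0
  x0 <- c(R0, 0, 0) + r0 * (cos(phase) * e1 + sin(phase) * e2)
  sc <- params$Omega0 / params$v
  tg <- sc * (-r0 * sin(phase) * e1 + r0 * cos(phase) * e2 + h0 * e3)
  nm <- -(cos(phase) * e1 + sin(phase) * e2)
  bn <- c(tg[2] * nm[3] - tg[3] * nm[2],
          tg[3] * nm[1] - tg[1] * nm[3],
          tg[1] * nm[2] - tg[2] * nm[1])
  c(x0, tg, nm, bn)
}

# normalize a policy argument to what the C++ core expects
normalize_policy <- function(policy, params) {
  if (inherits(policy, "decision_boundary")) {
    return(list(code = 1L, rho = 0,
                knots = cbind(policy$knots$p, policy$knots$theta),
                p_valid = policy$validity_limit))
  }
  rho <- if (identical(policy, "low")) params$rho_low
         else if (identical(policy, "high")) params$rho_high
         else if (is.numeric(policy) && length(policy) == 1) policy
         else stop("policy must be 'low', 'high', a numeric gain, ",
                   "or a decision_boundary")
  list(code = 0L, rho = rho, knots = matrix(0, 1, 2), p_valid = Inf)
}

#' Simulate one closed-loop helical swimming path
#'
#' Integrates the full control loop field -> binding -> signalling ->
#' (curvature, torsion) -> path until the cell reaches the egg (success:
#' distance \eqn{\le R_{egg}}), strays beyond the failure threshold
#' (\eqn{R \ge R_{th}}), or times out at `t_max`. With `noise = TRUE` the
#' signalling input is the stochastic train of binding events (Poisson
#' counts per step); otherwise the deterministic rate
#' \eqn{b(t) = \lambda c(r(t))} drives the dynamics.
#'
#' @param params a [model_params()] object.
#' @param field a `helitax_field`.
#' @param policy `"low"`, `"high"`, a numeric constant gain, or a fitted
#'   [decision_boundary] (state-fed gain switching).
#' @param R0 initial centreline distance to the egg centre (\eqn{\mu}m).
#' @param orientation `"isotropic"` (axis drawn uniformly on the sphere)
#'   or a 3-vector giving the initial helix axis.
#' @param seed integer seed (also consumed by the in-loop event noise).
#' @param noise logical; molecular shot noise on or off.
#' @param phase initial phase on the helix circle (rad); random for
#'   isotropic orientation unless given.
#' @param n_per_period samples recorded per helix period.
#' @param store_path record positions (needed for centreline extraction).
#' @return Object of class `helitax_traj`: outcome (`"success"`,
#'   `"failure"`, `"timeout"`), `t_end`, `min_dist`, a `record`
#'   data.frame (t, x, y, z, a, p, q, rho, events), and bookkeeping.
#' @export
simulate_path <- function(params, field, policy = "low", R0,
                          orientation = "isotropic", seed = 1,
                          noise = TRUE, phase = NULL, n_per_period = 20,
                          store_path = TRUE) {
  stopifnot(inherits(params, "helitax_params"),
            inherits(field, "helitax_field"), R0 > params$R_egg)
  set.seed(seed)
  if (identical(orientation, "isotropic")) {
    z <- runif(1, -1, 1); ph <- runif(1, 0, 2 * pi)
    axis <- c(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
    if (is.null(phase)) phase <- runif(1, 0, 2 * pi)
  } else {
    axis <- orientation
    if (is.null(phase)) phase <- 0
  }
  pol <- normalize_policy(policy, params)
  stride <- max(1L, round(params$T_helix / params$dt / n_per_period))
  start <- helix_start(R0, axis, phase, params)
  res <- .sim_path_cpp(par_list(params), unclass(field), start, pol$code,
                       pol$rho, pol$knots, pol$p_valid, noise, stride,
                       store_path)
  rec <- as.data.frame(res$record)
  structure(list(outcome = c("timeout", "success", "failure")[res$outcome + 1],
                 t_end = res$t_end, min_dist = res$min_dist,
                 clip_count = res$clip_count, record = rec,
                 params = params, field = field, R0 = R0, axis = axis,
                 phase = phase, seed = seed, noise = noise,
                 n_per_period = n_per_period,
                 sample_dt = stride * params$dt,
                 final_frame = matrix(res$final_frame, 3, 3, byrow = TRUE),
                 final_position = res$final_position,
                 final_signal = res$final_signal),
            class = "helitax_traj")
}

#' @export
print.helitax_traj <- function(x, ...) {
  cat(sprintf("helitax trajectory: R0 = %g um, outcome = %s at t = %.1f s, min distance %.0f um\n",
              x$R0, x$outcome, x$t_end, x$min_dist))
  invisible(x)
}

#' Extract the helix centreline and coarse state (R, Psi)
#'
#' The centreline is the centred moving average of the recorded position
#' over one helix period (the window holds exactly one period of samples,
#' so the circular component of a perfect helix cancels identically). Its
#' tangent is a central finite difference spanning one period; `Psi` is
#' the angle between that tangent and the local concentration gradient at
#' the centreline point (gradient points towards the egg, so
#' \eqn{\Psi \le \pi/2} means swimming up-gradient); `R` is the
#' centreline distance to the egg centre.
#'
#' @param traj a `helitax_traj` with stored path.
#' @param field field used for the gradient direction; defaults to the
#'   trajectory's own field.
#' @return data.frame with columns `t`, `R`, `Psi`, centreline
#'   coordinates `Cx`, `Cy`, `Cz`, and the signalling samples `a`, `p`,
#'   `q`, `rho` taken at the centre of each window. `Psi` is `NA` where
#'   the gradient vanishes.
#' @export
extract_centreline <- function(traj, field = traj$field) {
  rec <- traj$record
  if (is.null(rec$x)) stop("trajectory was simulated without store_path")
  npp <- traj$n_per_period
  n <- nrow(rec)
  if (n < 2 * npp + 2) stop("trajectory shorter than one helix period")
  roll <- function(v) {
    cs <- cumsum(c(0, v))
    (cs[(npp + 1):(n + 1)] - cs[1:(n - npp + 1)]) / npp
  }
  Cx <- roll(rec$x); Cy <- roll(rec$y); Cz <- roll(rec$z)
  tc <- roll(rec$t)
  m <- length(Cx)
  half <- max(1L, npp %/% 2L)
  idx <- (half + 1):(m - half)
  dtn <- tc[idx + half] - tc[idx - half]
  Tx <- (Cx[idx + half] - Cx[idx - half]) / dtn
  Ty <- (Cy[idx + half] - Cy[idx - half]) / dtn
  Tz <- (Cz[idx + half] - Cz[idx - half]) / dtn
  tn <- sqrt(Tx^2 + Ty^2 + Tz^2)
  cx <- Cx[idx]; cy <- Cy[idx]; cz <- Cz[idx]
  R <- sqrt(cx^2 + cy^2 + cz^2)
  if (field$type == "radial") {
    gx <- -cx / R; gy <- -cy / R; gz <- -cz / R
  } else if (field$type == "linear") {
    d <- field$direction
    gx <- rep(d[1], length(R)); gy <- rep(d[2], length(R)); gz <- rep(d[3], length(R))
  } else {
    gx <- gy <- gz <- rep(NA_real_, length(R))
  }
  cosPsi <- (Tx * gx + Ty * gy + Tz * gz) / tn
  Psi <- acos(pmin(1, pmax(-1, cosPsi)))
  # signalling sampled at the centre of each averaging window
  ic <- pmin(idx + half, n)
  data.frame(t = tc[idx], R = R, Psi = Psi, Cx = cx, Cy = cy, Cz = cz,
             a = rec$a[ic], p = rec$p[ic], q = rec$q[ic], rho = rec$rho[ic])
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

#' Probability to find the egg versus initial distance
#'
#' Monte-Carlo estimate of the success probability \eqn{P(R_0)} over an
#' ensemble of closed-loop simulations with isotropic initial
#' orientations. Timeouts count as failures. Wilson score intervals
#' quantify the binomial uncertainty.
#'
#' @inheritParams simulate_path
#' @param R0_grid vector of initial distances (\eqn{\mu}m).
#' @param n_paths paths per grid point.
#' @param conf confidence level of the Wilson interval.
#' @return data.frame with `R0`, `P`, `lower`, `upper`, `n`.
#' @export
success_probability <- function(params, field, policy, R0_grid, n_paths,
                                seed = 1, noise = TRUE, conf = 0.95) {
  out <- lapply(seq_along(R0_grid), function(i) {
    R0 <- R0_grid[i]
    if (R0 <= params$R_egg) {
      return(data.frame(R0 = R0, P = 1, lower = 1, upper = 1, n = n_paths))
    }
    succ <- 0L
    for (j in seq_len(n_paths)) {
      tr <- simulate_path(params, field, policy, R0,
                          orientation = "isotropic",
                          seed = seed + 7919L * i + j, noise = noise,
                          store_path = FALSE)
      succ <- succ + (tr$outcome == "success")
    }
    ci <- wilson_interval(succ, n_paths, conf)
    data.frame(R0 = R0, P = succ / n_paths, lower = ci["lower"],
               upper = ci["upper"], n = n_paths)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# does a noise-free path started with helix axis perpendicular to the
# gradient approach the egg?  Averaged over initial helix phases.
approaches_egg <- function(params, field, rho, R0, phases, eps_tol) {
  md <- vapply(phases, function(ph) {
    tr <- simulate_path(params, field, rho, R0, orientation = c(0, 0, 1),
                        seed = 1, noise = FALSE, phase = ph,
                        store_path = FALSE)
    tr$min_dist
  }, numeric(1))
  mean(md) < R0 - eps_tol
}

#' Attraction radii and target zone from noise-free simulations
#'
#' Scans the initial distance \eqn{R_0} for the predicate "a noise-free
#' swimmer started with its helix axis perpendicular to the gradient
#' comes closer to the egg than \eqn{R_0 - \epsilon}" and locates the
#' edges of the interval where it holds by bisection. The lower edge for
#' low-gain steering is the target-zone radius `T_zone` (inside it the
#' gradient direction turns faster than low-gain bending can follow); the
#' upper edges for the two gains are the attraction radii `A_low` and
#' `A_high`. The minimum distance is averaged over initial helix phases;
#' the margin `eps_tol` (default two helix radii) excludes the trivial
#' excursion of the helix turn itself.
#'
#' @inheritParams simulate_path
#' @param n_phases initial helix phases averaged over.
#' @param eps_tol approach margin (\eqn{\mu}m).
#' @param scan_step coarse scan resolution (\eqn{\mu}m).
#' @param tol bisection resolution (\eqn{\mu}m).
#' @return List with `T_zone`, `A_low`, `A_high` (\eqn{\mu}m) and the
#'   coarse scan tables (`scan_low`, `scan_high`).
#' @export
attraction_radii <- function(params, field, n_phases = 4,
                             eps_tol = 2 * params$r0, scan_step = 250,
                             tol = 50) {
  phases <- (seq_len(n_phases) - 1) * 2 * pi / n_phases
  edges <- function(rho) {
    grid <- seq(params$R_egg + scan_step, params$R_th - scan_step,
                by = scan_step)
    ok <- vapply(grid, function(R0)
      approaches_egg(params, field, rho, R0, phases, eps_tol), logical(1))
    if (!any(ok)) {
      warning("predicate never holds: no attraction zone in scan")
      return(list(lower = NA_real_, upper = NA_real_,
                  scan = data.frame(R0 = grid, approaches = ok)))
    }
    runs <- rle(ok)
    if (sum(runs$values) > 1)
      warning("approach predicate non-monotone in R0; see scan table")
    bisect <- function(lo, hi, want_true_low) {
      # invariant: predicate differs between lo and hi
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (approaches_egg(params, field, rho, mid, phases, eps_tol) ==
            want_true_low) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    i1 <- which(ok)[1]; i2 <- max(which(ok))
    lower <- if (i1 == 1) grid[1] else bisect(grid[i1 - 1], grid[i1], FALSE)
    upper <- if (i2 == length(grid)) grid[i2]
             else bisect(grid[i2], grid[i2 + 1], TRUE)
    list(lower = lower, upper = upper,
         scan = data.frame(R0 = grid, approaches = ok))
  }
  lo <- edges(params$rho_low)
  hi <- edges(params$rho_high)
  list(T_zone = lo$lower, A_low = lo$upper, A_high = hi$upper,
       scan_low = lo$scan, scan_high = hi$scan)
}
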