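#' Generate a train of stochastic binding events
#'
#' Draws arrival times of an inhomogeneous Poisson process with rate
#' `rate_fn(t)` on `[0, t_end]` by thinning a homogeneous process at
#' `rate_ceiling`: candidate arrivals at the ceiling rate are accepted
#' with probability `rate_fn(t) / rate_ceiling`. This is the molecular
#' shot noise of chemoattractant detection: each event is the binding of
#' one ligand molecule to a receptor.
#'
#' @param rate_fn vectorized function of time returning the event rate
#'   (events/s); must not exceed `rate_ceiling` anywhere on the horizon.
#' @param t_end time horizon (s).
#' @param rate_ceiling finite upper bound on `rate_fn` (events/s).
#' @param seed integer seed; the train is reproducible given the seed.
#' @return Object of class `binding_events`: list with `times` (strictly
#'   increasing event times) and the generating `rate_fn`.
#' @export
generate_binding_events <- function(rate_fn, t_end, rate_ceiling, seed) {
  stopifnot(is.function(rate_fn), t_end > 0, is.finite(rate_ceiling),
            rate_ceiling > 0)
  set.seed(seed)
  # homogeneous candidates via exponential inter-arrival times (strictly
  # increasing by construction), generated in chunks
  cand <- numeric(0)
  t_last <- 0
  repeat {
    chunk <- cumsum(stats::rexp(ceiling(rate_ceiling * (t_end - t_last)) +
                                  100, rate_ceiling)) + t_last
    cand <- c(cand, chunk)
    t_last <- chunk[length(chunk)]
    if (t_last > t_end) break
  }
  cand <- cand[cand <= t_end]
  r <- rate_fn(cand)
  if (any(r > rate_ceiling * (1 + 1e-12)))
    stop("rate_fn exceeds rate_ceiling; thinning invalid")
  keep <- runif(length(cand)) < r / rate_ceiling
  structure(list(times = cand[keep], rate_fn = rate_fn, t_end = t_end),
            class = "binding_events")
}

#' Steady state of the adaptive signalling module
#'
#' Under constant input rate `s0` the signalling module
#' \deqn{\mu\dot a = p[\lambda c_b + s(t)] - a, \qquad
#'       \mu\dot p = p(1 - a)}
#' adapts perfectly: the output settles at \eqn{a = 1} and the dynamic
#' sensitivity at \eqn{p = 1/(\lambda c_b + s_0)}.
#'
#' @param s0 constant input rate (events/s).
#' @param params a [model_params()] object.
#' @return List with `a`, `p`, `q` at steady state.
#' @export
signaling_steady_state <- function(s0, params) {
  list(a = 1, p = 1 / (params$lambda * params$c_b + s0), q = 1)
}

#' Integrate the adaptive signalling dynamics
#'
#' Advances the output `a`, dynamic sensitivity `p` and low-pass trigger
#' `q` over a time grid, driven either by a deterministic rate function
#' (noise-free mode, `s(t) = b(t)`) or by a discrete train of binding
#' events, each applying an instantaneous jump \eqn{a \gets a + p/\mu}
#' (the exact integral of a delta input). Between events the linear-in-a
#' part is integrated by an exponential integrator with the sensitivity
#' predicted at midstep, `p` by an exponential-trapezoidal update (its
#' dynamics is exactly \eqn{p \propto e^{\int (1-a)/\mu}}), and the
#' trigger \eqn{\eta\dot q = a - q} exactly under linearly interpolated
#' `a`; the same scheme is used inside the compiled closed-loop
#' simulator.
#'
#' @param input either a function of time (deterministic rate, events/s)
#'   or a `binding_events` object.
#' @param t_end integration horizon (s).
#' @param params a [model_params()] object (`lambda`, `mu`, `eta`, `c_b`).
#' @param dt time step (s); default `params$dt`.
#' @param init named list with starting `a`, `p`, `q`; default is the
#'   steady state for zero input.
#' @return data.frame with columns `t`, `a`, `p`, `q`, `events` (events
#'   applied in each step).
#' @export
simulate_signaling <- function(input, t_end, params, dt = params$dt,
                               init = NULL) {
  stopifnot(dt < params$mu / 5, dt < params$eta / 5)
  if (is.null(init)) init <- signaling_steady_state(0, params)
  n <- ceiling(t_end / dt)
  tgrid <- (0:n) * dt
  a <- p <- q <- numeric(n + 1)
  ev <- numeric(n + 1)
  a[1] <- init$a; p[1] <- init$p; q[1] <- init$q
  ema <- exp(-dt / params$mu)
  emq <- exp(-dt / params$eta)
  deterministic <- is.function(input)
  if (!deterministic) {
    stopifnot(inherits(input, "binding_events"))
    counts <- tabulate(pmin(floor(input$times / dt) + 1L, n), nbins = n)
  }
  lcb <- params$lambda * params$c_b
  for (k in seq_len(n)) {
    p_mid <- p[k] * exp(0.5 * dt * (1 - a[k]) / params$mu)
    if (deterministic) {
      P <- p_mid * (lcb + input(tgrid[k]))
      a[k + 1] <- P + (a[k] - P) * ema
    } else {
      P <- p_mid * lcb
      a[k + 1] <- P + (a[k] - P) * ema + counts[k] * p[k] / params$mu
      ev[k + 1] <- counts[k]
    }
    p[k + 1] <- p[k] * exp(dt * (1 - (a[k] + a[k + 1]) / 2) / params$mu)
    r <- (a[k + 1] - a[k]) / dt
    q[k + 1] <- a[k + 1] - r * params$eta +
      (q[k] - a[k] + r * params$eta) * emq
    if (!is.finite(a[k + 1]) || !is.finite(p[k + 1]))
      stop("non-finite signalling state")
  }
  data.frame(t = tgrid, a = a, p = p, q = q, events = ev)
}
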