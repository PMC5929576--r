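#' Discretization of the (R, Psi) phase space
#'
#' By radial symmetry, the coarse state of a helical swimmer in a radial
#' field is its centreline distance to the egg `R` and the angle `Psi`
#' between centreline tangent and local gradient. The grid partitions
#' \eqn{[R_{egg}, R_{th}] \times [0, \pi]} into uniform bins and appends
#' two absorbing states: `success` (egg found) and `failure` (beyond
#' `R_th`).
#'
#' @param params a [model_params()] object (supplies `R_egg`, `R_th`).
#' @param n_R,n_Psi number of distance / angle bins.
#' @return Object of class `state_grid`.
#' @export
state_grid <- function(params, n_R = 40, n_Psi = 18) {
  R_edges <- seq(params$R_egg, params$R_th, length.out = n_R + 1)
  Psi_edges <- seq(0, pi, length.out = n_Psi + 1)
  K <- n_R * n_Psi
  structure(list(R_edges = R_edges, Psi_edges = Psi_edges,
                 n_R = n_R, n_Psi = n_Psi, K = K,
                 success = K + 1L, failure = K + 2L,
                 R_centers = (head(R_edges, -1) + tail(R_edges, -1)) / 2,
                 Psi_centers = (head(Psi_edges, -1) + tail(Psi_edges, -1)) / 2),
            class = "state_grid")
}

#' Map coarse states to grid bins
#'
#' @param grid a [state_grid()].
#' @param R,Psi coarse state coordinates (vectors).
#' @return integer bin indices in `1:grid$K`.
#' @export
bin_index <- function(grid, R, Psi) {
  iR <- findInterval(R, grid$R_edges, all.inside = TRUE)
  iP <- findInterval(Psi, grid$Psi_edges, all.inside = TRUE)
  (iR - 1L) * grid$n_Psi + iP
}

#' Simulate an ensemble of coarse trajectories
#'
#' Launches closed-loop simulations from initial conditions stratified
#' over \eqn{(R_0, \Psi_0)} (so that every phase-space bin receives
#' transition counts) and reduces each path to its coarse series sampled
#' once per helix period: `(t, R, Psi, a, p, q)` along the centreline.
#' The outcome and the launch state are kept as attributes of each
#' element.
#'
#' @inheritParams simulate_path
#' @param n_paths ensemble size.
#' @param psi_stratified logical; stratify the initial helix-axis angle
#'   over \eqn{[0, \pi]} (otherwise isotropic).
#' @return List of per-path data.frames (class `coarse_ensemble`).
#' @export
simulate_coarse_ensemble <- function(params, field, policy, n_paths,
                                     seed = 1, noise = TRUE,
                                     psi_stratified = TRUE) {
  set.seed(seed)
  # low-discrepancy stratified lattice over launch states, jittered
  ii <- seq_len(n_paths)
  u1 <- ((ii - 1) + runif(n_paths)) / n_paths
  u2 <- (ii * 0.6180339887498949 + runif(n_paths) * 0.05) %% 1
  R0s <- params$R_egg + 2 * params$r0 +
    u1 * (params$R_th - params$R_egg - 4 * params$r0)
  Psi0s <- if (psi_stratified) u2 * pi else acos(1 - 2 * u2)
  out <- vector("list", n_paths)
  npp <- 20L
  for (j in ii) {
    axis <- c(-cos(Psi0s[j]), 0, sin(Psi0s[j]))
    tr <- simulate_path(params, field, policy, R0s[j], orientation = axis,
                        seed = seed + 7919L * j, noise = noise,
                        phase = runif(1, 0, 2 * pi), n_per_period = npp)
    cl <- try(extract_centreline(tr), silent = TRUE)
    if (inherits(cl, "try-error")) {         # absorbed within one period
      co <- data.frame(t = 0, R = R0s[j], Psi = Psi0s[j],
                       a = 1, p = NA_real_, q = 1)
    } else {
      keep <- seq(1, nrow(cl), by = npp)
      co <- cl[keep, c("t", "R", "Psi", "a", "p", "q")]
    }
    attr(co, "outcome") <- tr$outcome
    attr(co, "R0") <- R0s[j]
    attr(co, "Psi0") <- Psi0s[j]
    out[[j]] <- co
  }
  structure(out, class = "coarse_ensemble",
            lag = params$T_helix, params = params)
}

# per-path encoded transitions: integer codes (from - 1) * n_states + to
encode_transitions <- function(coarse, grid) {
  n_states <- grid$K + 2L
  lapply(coarse, function(co) {
    b <- bin_index(grid, co$R, co$Psi)
    b[is.na(co$Psi)] <- NA_integer_
    from <- b[-length(b)]
    to <- b[-1]
    code <- (from - 1L) * n_states + to
    code <- code[!is.na(code)]
    outc <- attr(co, "outcome")
    if (outc != "timeout" && length(b) > 0 && !is.na(b[length(b)])) {
      absorb <- if (outc == "success") grid$success else grid$failure
      code <- c(code, (b[length(b)] - 1L) * n_states + absorb)
    }
    code
  })
}

counts_from_codes <- function(codes, grid) {
  n_states <- grid$K + 2L
  tab <- tabulate(unlist(codes, use.names = FALSE), nbins = n_states^2)
  matrix(tab, n_states, n_states, byrow = TRUE)
}

normalize_counts <- function(counts, grid) {
  n_states <- grid$K + 2L
  rs <- rowSums(counts)
  empty <- which(rs == 0)
  L <- counts / ifelse(rs > 0, rs, 1)
  for (i in empty) L[i, i] <- 1      # unvisited bins become self-loops
  # absorbing states are unit self-loops regardless of counts
  for (i in c(grid$success, grid$failure)) {
    L[i, ] <- 0
    L[i, i] <- 1
  }
  list(L = L, empty_rows = setdiff(empty, c(grid$success, grid$failure)))
}

#' Estimate a transition matrix from coarse trajectories
#'
#' Maximum-likelihood (row-normalized count) estimate of the bin-to-bin
#' transition probabilities at a lag of one helix period, the sampling
#' interval of the coarse series. A path absorbed after its last coarse
#' sample contributes a transition into the corresponding absorbing
#' state. Bins never visited become unit self-loops and are flagged in
#' `empty_rows`.
#'
#' @param coarse a `coarse_ensemble` (simulated under one constant gain).
#' @param grid a [state_grid()].
#' @return List with row-stochastic matrix `L`
#'   (`(K+2) x (K+2)`), raw `counts`, and `empty_rows`.
#' @export
estimate_transitions <- function(coarse, grid) {
  if (length(coarse) == 0) stop("empty trajectory set")
  codes <- encode_transitions(coarse, grid)
  counts <- counts_from_codes(codes, grid)
  nc <- normalize_counts(counts, grid)
  list(L = nc$L, counts = counts, empty_rows = nc$empty_rows)
}

#' Build the two-action transition model
#'
#' Simulates one coarse ensemble per steering mode (constant
#' \eqn{\rho_{low}} and \eqn{\rho_{high}}) and estimates the per-action
#' transition matrices over a common state grid.
#'
#' @inheritParams simulate_coarse_ensemble
#' @param grid a [state_grid()]; default `state_grid(params)`.
#' @param n_paths paths per action.
#' @return Object of class `transition_model`: `L_low`, `L_high`,
#'   counts, the grid, the decision lag, and the raw ensembles.
#' @export
build_transition_model <- function(params, field, n_paths = 1000,
                                   grid = state_grid(params), seed = 1,
                                   noise = TRUE, keep_ensembles = TRUE) {
  ens_low <- simulate_coarse_ensemble(params, field, "low", n_paths,
                                      seed = seed, noise = noise)
  ens_high <- simulate_coarse_ensemble(params, field, "high", n_paths,
                                       seed = seed + 1000003L, noise = noise)
  est_low <- estimate_transitions(ens_low, grid)
  est_high <- estimate_transitions(ens_high, grid)
  structure(list(L_low = est_low$L, L_high = est_high$L,
                 counts_low = est_low$counts, counts_high = est_high$counts,
                 empty_low = est_low$empty_rows,
                 empty_high = est_high$empty_rows,
                 grid = grid, lag = params$T_helix, params = params,
                 ensembles = if (keep_ensembles)
                   list(low = ens_low, high = ens_high) else NULL),
            class = "transition_model")
}

# assemble a transition model directly from matrices (used in tests)
transition_model <- function(L_low, L_high, grid, lag = 1) {
  structure(list(L_low = L_low, L_high = L_high, grid = grid, lag = lag),
            class = "transition_model")
}

check_stochastic <- function(L) {
  if (any(L < 0) || any(abs(rowSums(L) - 1) > 1e-12))
    stop("transition matrix rows must be non-negative and sum to 1")
}

#' Optimal memoryless switching strategy
#'
#' Maximum-reachability solution of the two-action decision process:
#' the value of a state is the largest achievable probability of
#' eventually reaching the success state,
#' \deqn{V_i = \max_{a \in \{low, high\}} \sum_j L^a_{ij} V_j,}
#' with \eqn{V(\mathrm{success}) = 1}, \eqn{V(\mathrm{failure}) = 0}.
#' Value iteration starts from \eqn{V = 0} (iterates are monotone
#' non-decreasing) and stops when the sup-norm change drops below `tol`;
#' the optimal action is the argmax, with ties broken in favour of
#' low-gain steering (less noise amplification).
#'
#' @param model a `transition_model`.
#' @param tol sup-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return Object of class `mdp_strategy`: `action` (character per bin),
#'   `value` (success probability per bin), `iterations`, `converged`.
#' @export
solve_optimal_strategy <- function(model, tol = 1e-10,
                                   max_iter = 100000) {
  check_stochastic(model$L_low)
  check_stochastic(model$L_high)
  grid <- model$grid
  K <- grid$K
  s <- grid$success
  V <- numeric(K + 2)
  V[s] <- 1
  Ll <- model$L_low[1:K, ]
  Lh <- model$L_high[1:K, ]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    vl <- as.vector(Ll %*% V)
    vh <- as.vector(Lh %*% V)
    Vnew <- pmax(vl, vh)
    if (max(abs(Vnew - V[1:K])) < tol) {
      V[1:K] <- Vnew
      converged <- TRUE
      break
    }
    V[1:K] <- Vnew
  }
  vl <- as.vector(Ll %*% V)
  vh <- as.vector(Lh %*% V)
  act <- ifelse(vh > vl + 1e-12, "high", "low")
  structure(list(action = act, value = V[1:K], iterations = it,
                 converged = converged), class = "mdp_strategy")
}

#' Success probability of a fixed strategy
#'
#' Absorption probability into the success state for the Markov chain
#' induced by a fixed action per bin, solved exactly as the linear system
#' \eqn{(I - Q)V = r} over transient states (`Q`: transient-to-transient
#' block, `r`: one-step probability into success). Bins flagged as
#' empty (unit self-loops) get value 0 and are excluded from the solve.
#'
#' @param model a `transition_model`.
#' @param strategy `"low"`, `"high"`, a character vector of actions per
#'   bin, or an `mdp_strategy`.
#' @return List with `value` (per-bin success probability) and
#'   `singular` flag.
#' @export
evaluate_strategy <- function(model, strategy) {
  grid <- model$grid
  K <- grid$K
  act <- if (inherits(strategy, "mdp_strategy")) strategy$action
         else if (length(strategy) == 1) rep(strategy, K)
         else strategy
  stopifnot(length(act) == K, all(act %in% c("low", "high")))
  L <- model$L_low
  hi <- act == "high"
  L[which(hi), ] <- model$L_high[which(hi), ]
  check_stochastic(L)
  # exclude pure self-loop states (unvisited bins): value 0
  selfloop <- which(abs(diag(L)[1:K] - 1) < 1e-14)
  keep <- setdiff(seq_len(K), selfloop)
  Q <- L[keep, keep, drop = FALSE]
  r <- L[keep, grid$success]
  A <- diag(length(keep)) - Q
  V <- numeric(K)
  singular <- FALSE
  sol <- tryCatch(solve(A, r), error = function(e) NULL)
  if (is.null(sol)) {
    singular <- TRUE
    warning("singular absorption system; falling back to iteration")
    v <- numeric(length(keep))
    for (i in seq_len(50000)) {
      vn <- as.vector(Q %*% v) + r
      if (max(abs(vn - v)) < 1e-12) break
      v <- vn
    }
    sol <- v
  }
  V[keep] <- pmin(1, pmax(0, sol))
  list(value = V, singular = singular)
}

#' Success probability versus initial distance under an isotropic prior
#'
#' Averages per-bin values over the orientation bins with the isotropic
#' weight \eqn{w(\Psi) \propto \int \sin\Psi \, d\Psi} per bin.
#'
#' @param model a `transition_model`.
#' @param value per-bin value vector (length `K`), e.g. from
#'   [evaluate_strategy()] or [solve_optimal_strategy()].
#' @return data.frame with `R` (bin centres) and `P`.
#' @export
success_profile <- function(model, value) {
  grid <- model$grid
  if (inherits(value, "mdp_strategy")) value <- value$value
  w <- diff(-cos(grid$Psi_edges))
  w <- w / sum(w)
  Vmat <- matrix(value, nrow = grid$n_Psi)   # Psi varies fastest
  data.frame(R = grid$R_centers, P = as.vector(crossprod(Vmat, w)))
}

#' Effective chemotactic range of a success profile
#'
#' Radius of the sphere whose volume equals the success-weighted search
#' volume: \eqn{\mathcal{R} = [3\int_0^\infty R^2 P(R)\,dR]^{1/3}}
#' (trapezoidal quadrature; `P` is taken as `P[1]` from 0 to the first
#' grid point and 0 beyond the last).
#'
#' @param R distances (\eqn{\mu}m), increasing.
#' @param P success probabilities on `R`.
#' @return range (\eqn{\mu}m).
#' @export
chemotactic_range <- function(R, P) {
  stopifnot(length(R) == length(P), !is.unsorted(R), all(P >= -1e-9))
  f <- R^2 * P
  integral <- sum(diff(R) * (head(f, -1) + tail(f, -1)) / 2)
  integral <- integral + P[1] * R[1]^3 / 3     # inner disc at constant P[1]
  (3 * integral)^(1 / 3)
}

#' Bootstrap frequency of high-gain steering per bin
#'
#' Resamples the two coarse ensembles with replacement `B` times,
#' re-estimates both transition matrices, re-solves the decision
#' process, and reports per bin the fraction of bootstrap replicates in
#' which the optimal action is high-gain steering. Stable regions of the
#' optimal strategy show frequencies near 0 or 1; bins where the choice
#' is immaterial fluctuate around 1/2.
#'
#' @param model a `transition_model` built with `keep_ensembles = TRUE`.
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return List with `freq_high` (per-bin frequency in `[0,1]`) and `B`.
#' @export
bootstrap_strategy_frequency <- function(model, B = 30, seed = 1) {
  stopifnot(B >= 2, !is.null(model$ensembles))
  grid <- model$grid
  set.seed(seed)
  codes_low <- encode_transitions(model$ensembles$low, grid)
  codes_high <- encode_transitions(model$ensembles$high, grid)
  nl <- length(codes_low)
  nh <- length(codes_high)
  high_count <- numeric(grid$K)
  for (b in seq_len(B)) {
    cl <- codes_low[sample.int(nl, nl, replace = TRUE)]
    ch <- codes_high[sample.int(nh, nh, replace = TRUE)]
    Ll <- normalize_counts(counts_from_codes(cl, grid), grid)$L
    Lh <- normalize_counts(counts_from_codes(ch, grid), grid)$L
    mb <- transition_model(Ll, Lh, grid, model$lag)
    st <- solve_optimal_strategy(mb, tol = 1e-8)
    high_count <- high_count + (st$action == "high")
  }
  list(freq_high = high_count / B, B = B)
}

#' Chemotactic range of hybrid strategies versus cut-off distance
#'
#' A hybrid strategy follows the optimal strategy at distances below the
#' cut-off `Rc` and a fixed fallback gain outside. The derivative of the
#' resulting chemotactic range with respect to `Rc` localizes where
#' decision making pays: positive values mean switching matters at that
#' distance.
#'
#' @param model a `transition_model`.
#' @param optimal an `mdp_strategy`.
#' @param fallback `"low"` or `"high"`.
#' @param Rc_grid cut-off distances (\eqn{\mu}m).
#' @return data.frame with `Rc`, `range`, and central-difference
#'   `drange_dRc`.
#' @export
hybrid_range_curve <- function(model, optimal, fallback, Rc_grid) {
  grid <- model$grid
  Rbin <- rep(grid$R_centers, each = grid$n_Psi)
  rng <- vapply(Rc_grid, function(Rc) {
    act <- ifelse(Rbin < Rc, optimal$action, fallback)
    v <- evaluate_strategy(model, act)$value
    pr <- success_profile(model, v)
    chemotactic_range(pr$R, pr$P)
  }, numeric(1))
  d <- rep(NA_real_, length(Rc_grid))
  if (length(Rc_grid) > 2) {
    i <- 2:(length(Rc_grid) - 1)
    d[i] <- (rng[i + 1] - rng[i - 1]) / (Rc_grid[i + 1] - Rc_grid[i - 1])
  }
  data.frame(Rc = Rc_grid, range = rng, drange_dRc = d)
}
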