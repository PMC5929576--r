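#' Decision boundary on the internal signalling variables
#'
#' A cell has no access to its coarse state \eqn{(R, \Psi)}, only to its
#' internal variables: the dynamic sensitivity `p` (in the noise-free
#' limit \eqn{p^{-1} = \lambda[c_b + c(R)]}, a proxy for distance) and
#' the trigger `q` (baseline \eqn{1 + \mu\Omega_0 h_0 p \lambda
#' |dc/dR|\cos\Psi}, a proxy for swimming direction). The rule
#' \deqn{\rho(p,q) = \rho_{low} \;\mathrm{if}\; q \ge \Theta(p)
#'   \;\mathrm{or}\; p > p_{max}, \qquad \rho_{high}
#'   \;\mathrm{otherwise}}
#' switches to high-gain steering when the trigger falls below a
#' piecewise-linear boundary \eqn{\Theta(p)}. Beyond the validity limit
#' `validity_limit` (state estimation unreliable; large `p` means low
#' concentration, i.e. far from the egg) the rule always returns
#' low-gain.
#'
#' @param p knot positions (s), increasing.
#' @param theta boundary values at the knots (dimensionless q units).
#' @param validity_limit largest `p` (s) for which the rule is active;
#'   default 5 ms.
#' @return Object of class `decision_boundary`.
#' @export
decision_boundary <- function(p, theta, validity_limit = 0.005) {
  stopifnot(length(p) == length(theta), length(p) >= 2, !is.unsorted(p))
  structure(list(knots = data.frame(p = p, theta = theta),
                 validity_limit = validity_limit),
            class = "decision_boundary")
}

#' @export
print.decision_boundary <- function(x, ...) {
  cat(sprintf("decision boundary: %d knots, valid for p <= %g ms\n",
              nrow(x$knots), 1000 * x$validity_limit))
  print(data.frame(p_ms = 1000 * x$knots$p, theta = x$knots$theta))
  invisible(x)
}

theta_of_p <- function(boundary, p) {
  k <- boundary$knots
  approx(k$p, k$theta, xout = pmin(pmax(p, k$p[1]), k$p[nrow(k)]),
         rule = 2)$y
}

#' Evaluate the gain-switching rule
#'
#' @param p,q signalling variables (vectors; `p` in seconds).
#' @param boundary a [decision_boundary()].
#' @param rho_low,rho_high the two gain values.
#' @return gain factor per sample.
#' @export
apply_decision_rule <- function(p, q, boundary, rho_low = 1,
                                rho_high = 10) {
  low <- q >= theta_of_p(boundary, p) | p > boundary$validity_limit
  ifelse(low, rho_low, rho_high)
}

#' Harvest (p, q) samples at a given distance from the egg
#'
#' Launches constant-gain simulations from a shell at `R_target` with
#' isotropic orientations and collects the once-per-period
#' centreline-aligned samples (so that residual within-turn oscillations
#' of `q` are suppressed) whose coarse distance lies within
#' `width` of the target. Each sample carries the joint record
#' \eqn{(R, \Psi, p, q)} and the class label `upgradient`
#' (\eqn{\Psi \le \pi/2}).
#'
#' @inheritParams simulate_path
#' @param R_target shell distance (\eqn{\mu}m).
#' @param width half-width of the accepted distance window (\eqn{\mu}m).
#' @param n_per_class stop once both classes have this many samples.
#' @param t_run duration of each harvesting run (s).
#' @param max_paths hard cap on the number of runs.
#' @return data.frame with `R`, `Psi`, `p`, `q`, `upgradient`.
#' @export
pq_samples <- function(params, field, policy = "low", R_target,
                       width = 250, n_per_class = 2000, seed = 1,
                       noise = TRUE, t_run = 30, max_paths = 5000) {
  par2 <- params
  par2$t_max <- t_run
  acc <- vector("list", 256)
  ai <- 0L
  n_up <- n_down <- 0L
  j <- 0L
  npp <- 20L
  while ((n_up < n_per_class || n_down < n_per_class) && j < max_paths) {
    j <- j + 1L
    tr <- simulate_path(par2, field, policy, R_target,
                        orientation = "isotropic", seed = seed + j,
                        noise = noise, n_per_period = npp)
    cl <- try(extract_centreline(tr), silent = TRUE)
    if (inherits(cl, "try-error")) next
    cl <- cl[seq(1, nrow(cl), by = npp), ]
    cl <- cl[is.finite(cl$Psi) & abs(cl$R - R_target) < width, ]
    if (nrow(cl) == 0) next
    ai <- ai + 1L
    if (ai > length(acc)) acc <- c(acc, vector("list", length(acc)))
    up <- cl$Psi <= pi / 2
    n_up <- n_up + sum(up)
    n_down <- n_down + sum(!up)
    acc[[ai]] <- data.frame(R = cl$R, Psi = cl$Psi, p = cl$p, q = cl$q,
                            upgradient = up)
  }
  out <- do.call(rbind, acc[seq_len(ai)])
  if (is.null(out) || min(sum(out$upgradient), sum(!out$upgradient)) < 100)
    stop("insufficient samples per class (< 100)")
  out
}

pq_grid_edges <- function(samples, n_p = 30, n_q = 30) {
  pr <- range(samples$p)
  qr <- range(samples$q)
  list(p = seq(pr[1], pr[2], length.out = n_p + 1),
       q = seq(qr[1], qr[2], length.out = n_q + 1))
}

hist2d <- function(p, q, p_edges, q_edges) {
  ip <- findInterval(p, p_edges, all.inside = TRUE)
  iq <- findInterval(q, q_edges, all.inside = TRUE)
  np <- length(p_edges) - 1
  nq <- length(q_edges) - 1
  matrix(tabulate((iq - 1L) * np + ip, nbins = np * nq), np, nq)
}

#' Conditional (p, q) densities for up- and down-gradient swimming
#'
#' Empirical joint densities of the signalling variables conditioned on
#' the swimming direction class, \eqn{P(p,q \mid \Psi \le \pi/2)} and
#' \eqn{P(p,q \mid \Psi > \pi/2)}, estimated as normalized 2-D
#' histograms on a common grid. Each density integrates to 1.
#'
#' @param samples output of [pq_samples()].
#' @param n_p,n_q number of grid cells per axis.
#' @return List with matrices `dens_up`, `dens_down` (p by q), edges and
#'   midpoints.
#' @export
pq_conditional_densities <- function(samples, n_p = 30, n_q = 30) {
  if (min(sum(samples$upgradient), sum(!samples$upgradient)) < 100)
    stop("insufficient samples per class (< 100)")
  ed <- pq_grid_edges(samples, n_p, n_q)
  cell <- diff(ed$p)[1] * diff(ed$q)[1]
  up <- samples[samples$upgradient, ]
  dn <- samples[!samples$upgradient, ]
  H_up <- hist2d(up$p, up$q, ed$p, ed$q)
  H_dn <- hist2d(dn$p, dn$q, ed$p, ed$q)
  list(dens_up = H_up / sum(H_up) / cell,
       dens_down = H_dn / sum(H_dn) / cell,
       p_edges = ed$p, q_edges = ed$q,
       p_mid = (head(ed$p, -1) + tail(ed$p, -1)) / 2,
       q_mid = (head(ed$q, -1) + tail(ed$q, -1)) / 2,
       cell_area = cell)
}

#' Frequency of high-gain steering over the (p, q) plane
#'
#' Projects the optimal \eqn{(R, \Psi)} strategy into the internal
#' coordinates of the cell: for each (p, q) cell, the expectation of the
#' indicator "optimal action is high-gain" over the empirical posterior
#' of states \eqn{(R, \Psi)} falling in that cell.
#'
#' @param samples data.frame with joint records `R`, `Psi`, `p`, `q`
#'   (e.g. pooled [pq_samples()] over several shells).
#' @param strategy an `mdp_strategy`.
#' @param grid the [state_grid()] the strategy was solved on.
#' @param n_p,n_q (p, q) grid resolution.
#' @return List with `freq` matrix (p by q; `NA` for empty cells),
#'   counts, edges and midpoints.
#' @export
strategy_to_pq_frequency <- function(samples, strategy, grid,
                                     n_p = 30, n_q = 30) {
  ed <- pq_grid_edges(samples, n_p, n_q)
  b <- bin_index(grid, samples$R, samples$Psi)
  high <- strategy$action[b] == "high"
  ip <- findInterval(samples$p, ed$p, all.inside = TRUE)
  iq <- findInterval(samples$q, ed$q, all.inside = TRUE)
  code <- (iq - 1L) * n_p + ip
  cnt <- tabulate(code, nbins = n_p * n_q)
  hi <- tabulate(code[high], nbins = n_p * n_q)
  freq <- matrix(ifelse(cnt > 0, hi / pmax(cnt, 1), NA_real_), n_p, n_q)
  list(freq = freq, counts = matrix(cnt, n_p, n_q),
       p_edges = ed$p, q_edges = ed$q,
       p_mid = (head(ed$p, -1) + tail(ed$p, -1)) / 2,
       q_mid = (head(ed$q, -1) + tail(ed$q, -1)) / 2)
}

#' Fit the decision boundary to the 50% contour
#'
#' For each `p` column of the high-gain frequency map, locates the `q`
#' value where the frequency crosses 1/2 (high-gain frequency is high at
#' low `q`; the first downward crossing is interpolated linearly), then
#' fits a continuous piecewise-linear function with a small fixed number
#' of segments to the contour points by least squares.
#'
#' @param freq_map output of [strategy_to_pq_frequency()].
#' @param n_segments number of linear segments (default 3).
#' @param validity_limit rule validity limit on `p` (s); columns beyond
#'   it are ignored in the fit.
#' @param min_count minimum samples per cell for a cell to count.
#' @return A [decision_boundary()].
#' @export
fit_decision_boundary <- function(freq_map, n_segments = 3,
                                  validity_limit = 0.005, min_count = 20) {
  fm <- freq_map$freq
  fm[freq_map$counts < min_count] <- NA
  pc <- numeric(0)
  qc <- numeric(0)
  for (i in seq_along(freq_map$p_mid)) {
    if (freq_map$p_mid[i] > validity_limit) next
    col <- fm[i, ]
    ok <- which(!is.na(col))
    if (length(ok) < 2) next
    v <- col[ok]
    qs <- freq_map$q_mid[ok]
    cross <- which(v[-length(v)] >= 0.5 & v[-1] < 0.5)
    if (length(cross) == 0) next
    k <- cross[1]
    w <- (0.5 - v[k]) / (v[k + 1] - v[k])
    pc <- c(pc, freq_map$p_mid[i])
    qc <- c(qc, qs[k] + w * (qs[k + 1] - qs[k]))
  }
  if (length(pc) < n_segments + 1)
    stop("no 50% crossing in enough columns to trace a contour")
  # continuous piecewise-linear least squares with interior hinge knots
  kts <- quantile(pc, probs = seq(0, 1, length.out = n_segments + 1))
  basis <- cbind(pc, vapply(kts[2:n_segments],
                            function(k) pmax(pc - k, 0), numeric(length(pc))))
  fit <- lm(qc ~ basis)
  bound_at <- function(pp) {
    bb <- cbind(1, pp, vapply(kts[2:n_segments],
                              function(k) pmax(pp - k, 0),
                              numeric(length(pp))))
    as.vector(bb %*% coef(fit))
  }
  decision_boundary(as.numeric(kts), bound_at(as.numeric(kts)),
                    validity_limit = validity_limit)
}

#' Accuracy of discriminating swimming direction from (p, q)
#'
#' Balanced accuracy of the Bayes-optimal classifier (equal priors)
#' built from the two empirical conditional densities of
#' \eqn{(p, q)}, estimated on a held-out split. 50% means the internal
#' variables carry no directional information; 100% perfect
#' discrimination.
#'
#' @param samples output of [pq_samples()].
#' @param train_frac fraction used to build the densities.
#' @param n_p,n_q histogram resolution.
#' @param seed split seed.
#' @return balanced accuracy in `[0, 1]` (attribute `per_class` holds
#'   the two class accuracies).
#' @export
estimation_accuracy <- function(samples, train_frac = 0.6, n_p = 25,
                                n_q = 25, seed = 1) {
  set.seed(seed)
  up <- samples[samples$upgradient, ]
  dn <- samples[!samples$upgradient, ]
  n <- min(nrow(up), nrow(dn))
  if (n < 100) stop("insufficient samples per class (< 100)")
  up <- up[sample.int(nrow(up), n), ]
  dn <- dn[sample.int(nrow(dn), n), ]
  ntr <- floor(train_frac * n)
  bal <- rbind(up, dn)
  ed <- pq_grid_edges(bal, n_p, n_q)
  idx2 <- function(s) {
    ip <- findInterval(s$p, ed$p, all.inside = TRUE)
    iq <- findInterval(s$q, ed$q, all.inside = TRUE)
    (iq - 1L) * n_p + ip
  }
  smooth <- 0.5   # Laplace pseudo-count
  H_up <- tabulate(idx2(up[seq_len(ntr), ]), nbins = n_p * n_q) + smooth
  H_dn <- tabulate(idx2(dn[seq_len(ntr), ]), nbins = n_p * n_q) + smooth
  H_up <- H_up / sum(H_up)
  H_dn <- H_dn / sum(H_dn)
  test_up <- idx2(up[(ntr + 1):n, ])
  test_dn <- idx2(dn[(ntr + 1):n, ])
  acc_up <- mean((H_up[test_up] > H_dn[test_up]) +
                   0.5 * (H_up[test_up] == H_dn[test_up]))
  acc_dn <- mean((H_dn[test_dn] > H_up[test_dn]) +
                   0.5 * (H_dn[test_dn] == H_up[test_dn]))
  structure((acc_up + acc_dn) / 2, per_class = c(up = acc_up, down = acc_dn))
}
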