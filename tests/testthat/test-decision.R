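test_that("noise-free signalling collapses onto the deterministic state map", {
  par <- default_params()
  par$t_max <- 30; par$R_th <- Inf
  slope <- 0.004
  lf <- linear_field(c0 = 40, slope = slope)
  for (psi0 in c(pi / 4, 3 * pi / 4)) {
    # rho = 0: no steering feedback, Psi stays fixed, clean quasi-static ramp
    tr <- simulate_path(par, lf, 0, 1e6,
                        orientation = c(sin(psi0), 0, cos(psi0)),
                        seed = 1, noise = FALSE, phase = 0)
    cl <- extract_centreline(tr, lf)
    cl <- cl[cl$t > 10, ]
    k <- seq(1, nrow(cl), by = 20)
    cz <- 40 + slope * cl$Cz[k]
    p_th <- 1 / (par$lambda * (par$c_b + cz))
    expect_equal(cl$p[k], p_th, tolerance = 0.01)
    q_th <- 1 + par$mu * par$Omega0 * par$h0 * p_th * par$lambda * slope *
      cos(cl$Psi[k])
    expect_equal(cl$q[k] - 1, q_th - 1, tolerance = 0.05)
    # up-gradient raises the trigger baseline, down-gradient lowers it
    expect_true(all(sign(cl$q[k] - 1) == sign(cos(psi0))))
  }
})

test_that("conditional (p,q) densities normalize and lose contrast with distance", {
  par <- default_params()
  f <- study_field()
  s15 <- pq_samples(par, f, "low", 1500, n_per_class = 1500, seed = 5)
  s30 <- pq_samples(par, f, "low", 3000, n_per_class = 1500, seed = 6)
  d15 <- pq_conditional_densities(s15)
  d30 <- pq_conditional_densities(s30)
  expect_equal(sum(d15$dens_up) * d15$cell_area, 1, tolerance = 1e-9)
  expect_equal(sum(d15$dens_down) * d15$cell_area, 1, tolerance = 1e-9)
  ovl <- function(d) sum(pmin(d$dens_up, d$dens_down)) * d$cell_area
  expect_lt(ovl(d15), ovl(d30))   # separation decreases with R
  expect_error(
    pq_conditional_densities(s15[sample(which(s15$upgradient), 50), ]),
    "insufficient")
})

test_that("strategy projection into (p,q) is an expectation of an indicator", {
  par <- default_params()
  g <- state_grid(par, n_R = 6, n_Psi = 4)
  set.seed(8)
  n <- 4000
  samples <- data.frame(R = runif(n, par$R_egg, par$R_th),
                        Psi = runif(n, 0, pi),
                        p = runif(n, 1e-3, 8e-3), q = runif(n, 0.98, 1.02))
  all_low <- structure(list(action = rep("low", g$K)), class = "mdp_strategy")
  all_high <- structure(list(action = rep("high", g$K)), class = "mdp_strategy")
  fr_l <- strategy_to_pq_frequency(samples, all_low, g)
  fr_h <- strategy_to_pq_frequency(samples, all_high, g)
  expect_true(all(fr_l$freq[!is.na(fr_l$freq)] == 0))
  expect_true(all(fr_h$freq[!is.na(fr_h$freq)] == 1))
  mixed <- structure(list(action = sample(c("low", "high"), g$K, TRUE)),
                     class = "mdp_strategy")
  fr_m <- strategy_to_pq_frequency(samples, mixed, g)
  v <- fr_m$freq[!is.na(fr_m$freq)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("the 50% contour fit recovers synthetic boundaries", {
  # frequency = step in q, constant in p  ->  Theta(p) = q*
  p_mid <- seq(5e-4, 5e-3, length.out = 30)
  q_mid <- seq(0.98, 1.02, length.out = 40)
  qstar <- 0.998
  mk_map <- function(freqfun) {
    fr <- outer(p_mid, q_mid, freqfun)
    list(freq = fr, counts = matrix(1000, 30, 40), p_mid = p_mid,
         q_mid = q_mid, p_edges = NULL, q_edges = NULL)
  }
  bd <- fit_decision_boundary(mk_map(function(p, q) as.numeric(q < qstar)),
                              validity_limit = 0.005)
  expect_equal(theta_of_p <- sapply(bd$knots$p, function(p)
    apply_decision_rule(p, qstar + 1e-9, bd)), rep(1, nrow(bd$knots)))
  expect_equal(bd$knots$theta, rep(qstar, nrow(bd$knots)), tolerance = 2e-3)
  # frequency = high iff q < 1 + alpha p: fitted slope within 5%
  alpha <- 3
  bd2 <- fit_decision_boundary(
    mk_map(function(p, q) as.numeric(q < 1 + alpha * p)),
    validity_limit = 0.005)
  pk <- bd2$knots$p
  expect_equal(bd2$knots$theta, 1 + alpha * pk, tolerance = 0.05)
  slope <- diff(range(bd2$knots$theta)) / diff(range(pk))
  expect_equal(slope, alpha, tolerance = 0.05)
  expect_error(
    fit_decision_boundary(mk_map(function(p, q) 0 * q), 0.005),
    "no 50% crossing")
})

test_that("the gain rule switches exactly at the boundary", {
  bd <- decision_boundary(p = c(1e-3, 5e-3), theta = c(1.0, 0.99),
                          validity_limit = 0.005)
  # on the boundary: low (inclusive)
  expect_equal(apply_decision_rule(3e-3, 0.995, bd), 1)
  expect_equal(apply_decision_rule(3e-3, 0.9949, bd), 10)  # just below
  expect_equal(apply_decision_rule(3e-3, 1.2, bd), 1)
  expect_equal(apply_decision_rule(6e-3, 0.5, bd), 1)      # beyond validity
  expect_equal(apply_decision_rule(c(2e-3, 2e-3), c(0.9, 1.1), bd,
                                   rho_low = 1, rho_high = 10), c(10, 1))
})

test_that("direction-estimation accuracy spans its information limits", {
  par <- default_params()
  # no gradient information: 50%
  flat <- linear_field(c0 = 30, slope = 0)
  s0 <- pq_samples(par, flat, "low", 3000, n_per_class = 1500, seed = 3)
  expect_lt(abs(as.numeric(estimation_accuracy(s0)) - 0.5), 0.05)
  # noise-free: deterministic separation via the sign of q - 1
  # (rho = 0 sampling keeps Psi fixed per path: clean quasi-static limit)
  sdet <- pq_samples(par, study_field(), 0, 2500, width = 400,
                     n_per_class = 2000, seed = 4, noise = FALSE,
                     t_run = 25, max_paths = 1500)
  expect_gte(as.numeric(estimation_accuracy(sdet)), 0.95)
})

test_that("switching concentrates in the noise zone, not the target zone", {
  par <- default_params()
  f <- study_field()
  bd <- fitted_boundary()
  # rate of low->high switching events per recorded sample, by zone
  sw <- den <- c(noise = 0, target = 0)
  for (j in seq_len(15)) {
    tr <- simulate_path(par, f, bd, 3000, "isotropic", seed = 100 + j)
    rec <- tr$record
    rec$R <- sqrt(rec$x^2 + rec$y^2 + rec$z^2)
    ev <- c(FALSE, diff(rec$rho == par$rho_high) == 1)
    inz <- rec$R > 1500 & rec$R < 4000
    tz <- rec$R < 900
    sw <- sw + c(sum(ev[inz], na.rm = TRUE), sum(ev[tz], na.rm = TRUE))
    den <- den + c(sum(inz, na.rm = TRUE), sum(tz, na.rm = TRUE))
  }
  rate <- sw / pmax(den, 1)
  # high-gain steering is initiated frequently in the noise zone and
  # only sporadically in the target zone
  expect_gt(rate[["noise"]], 1.3 * rate[["target"]])
})

test_that("the fitted rule outperforms both constant gains in the noise zone", {
  par <- default_params()
  f <- study_field()
  bd <- fitted_boundary()
  n <- 150
  separated <- FALSE
  for (R0 in c(3500, 4000)) {
    p_rule <- success_probability(par, f, bd, R0, n, seed = 61)
    p_low <- success_probability(par, f, "low", R0, n, seed = 62)
    p_high <- success_probability(par, f, "high", R0, n, seed = 63)
    expect_gt(p_rule$P, p_low$P)
    expect_gt(p_rule$P, p_high$P)
    if (p_rule$lower > max(p_low$upper, p_high$upper)) separated <- TRUE
  }
  # outside overlapping confidence intervals for at least one distance
  expect_true(separated)
})

test_that("the same boundary still helps in a rescaled concentration field", {
  par <- default_params()
  f2 <- default_field(surface_concentration = 24000 * 0.7, ell = 1305 * 0.9)
  bd <- fitted_boundary()
  R0 <- 3200
  n <- 80
  p_rule <- success_probability(par, f2, bd, R0, n, seed = 71)$P
  p_low <- success_probability(par, f2, "low", R0, n, seed = 72)$P
  p_high <- success_probability(par, f2, "high", R0, n, seed = 73)$P
  expect_gte(p_rule, max(p_low, p_high) - 0.05)
})
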