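test_that("the state grid partitions phase space", {
  par <- default_params()
  g <- state_grid(par, n_R = 10, n_Psi = 6)
  set.seed(2)
  R <- runif(500, par$R_egg, par$R_th)
  Psi <- runif(500, 0, pi)
  b <- bin_index(g, R, Psi)
  expect_true(all(b >= 1 & b <= g$K))
  expect_true(g$success != g$failure && g$success > g$K)
  # edges map inside
  expect_equal(bin_index(g, par$R_egg, 0), 1)
  expect_equal(bin_index(g, par$R_th, pi), g$K)
})

test_that("transition counting reproduces a hand-built path", {
  par <- default_params()
  g <- state_grid(par, n_R = 4, n_Psi = 1)
  # bins 1 -> 2 -> 3 at exactly the lag spacing, then absorbed successfully
  co <- synthetic_coarse(R = g$R_centers[1:3], Psi = rep(1, 3),
                         outcome = "success")
  est <- estimate_transitions(list(co), g)
  expect_equal(est$L[1, 2], 1)
  expect_equal(est$L[2, 3], 1)
  expect_equal(est$L[3, g$success], 1)
  expect_true(all(abs(rowSums(est$L) - 1) < 1e-12))
  expect_true(4 %in% est$empty_rows)   # never visited -> flagged self-loop
  expect_error(estimate_transitions(list(), g), "empty")
})

test_that("value iteration solves a one-step decision and beats pure gains", {
  par <- model_params(R_th = 500)
  g <- state_grid(par, n_R = 1, n_Psi = 1)
  Ll <- matrix(0, 3, 3); Lh <- matrix(0, 3, 3)
  Ll[1, ] <- c(0, 0.3, 0.7); Lh[1, ] <- c(0, 0.7, 0.3)
  Ll[2, 2] <- Lh[2, 2] <- 1; Ll[3, 3] <- Lh[3, 3] <- 1
  m <- transition_model(Ll, Lh, g)
  st <- solve_optimal_strategy(m)
  expect_equal(st$action, "high")
  expect_equal(st$value, 0.7, tolerance = 1e-10)
})

test_that("value iteration matches exhaustive strategy enumeration", {
  for (s in 1:8) {
    m <- random_mdp(6, seed = 100 + s)
    vi <- solve_optimal_strategy(m)
    expect_true(vi$converged)
    brute <- enumerate_optimal(m)
    expect_equal(vi$value, brute, tolerance = 1e-8)
    # optimal dominates both pure strategies componentwise
    vl <- evaluate_strategy(m, "low")$value
    vh <- evaluate_strategy(m, "high")$value
    expect_true(all(vi$value >= pmax(vl, vh) - 1e-9))
  }
})

test_that("strategy evaluation agrees with Monte-Carlo rollouts", {
  m <- random_mdp(5, seed = 77)
  act <- rep(c("low", "high"), length.out = 5)
  v <- evaluate_strategy(m, act)$value
  n_roll <- 4000
  p_mc <- rollout_success(m, act, start = 2, n_roll = n_roll, seed = 11)
  se <- sqrt(v[2] * (1 - v[2]) / n_roll)
  expect_lt(abs(p_mc - v[2]), 3 * se + 1e-6)
  # degenerate chains
  gK <- m$grid$K
  Lfail <- matrix(0, gK + 2, gK + 2)
  Lfail[cbind(1:gK, gK + 2)] <- 1
  Lfail[gK + 1, gK + 1] <- 1; Lfail[gK + 2, gK + 2] <- 1
  mf <- transition_model(Lfail, Lfail, m$grid)
  expect_true(all(evaluate_strategy(mf, "low")$value == 0))
  Lwin <- matrix(0, gK + 2, gK + 2)
  Lwin[cbind(1:gK, c(2:gK, gK + 1))] <- 1    # chain to success in k steps
  Lwin[gK + 1, gK + 1] <- 1; Lwin[gK + 2, gK + 2] <- 1
  mw <- transition_model(Lwin, Lwin, m$grid)
  expect_true(all(evaluate_strategy(mw, "low")$value == 1))
})

test_that("isotropic success profile weights orientation bins by sin(Psi)", {
  par <- default_params()
  g <- state_grid(par, n_R = 5, n_Psi = 8)
  m <- transition_model(diag(g$K + 2), diag(g$K + 2), g)
  pr <- success_profile(m, rep(1, g$K))
  expect_equal(pr$P, rep(1, 5), tolerance = 1e-12)  # weights sum to 1
  # value = indicator(Psi bin j0): profile equals that bin's sin weight
  j0 <- 3
  v <- as.numeric(rep(seq_len(g$n_Psi), g$n_R) == j0)
  w <- diff(-cos(g$Psi_edges)) / 2
  expect_equal(success_profile(m, v)$P, rep(w[j0], 5), tolerance = 1e-12)
})

test_that("chemotactic range matches closed forms for step and exponential P", {
  # step profile: P = 1 inside a, 0 outside -> range = a
  a <- 3800
  R <- c(seq(0, a, length.out = 2000), a * (1 + 1e-12), a * 2)
  P <- as.numeric(R <= a)
  expect_equal(chemotactic_range(R, P), a, tolerance = 1e-6)
  # exponential: P = exp(-R/l) -> range = 6^(1/3) l
  l <- 1000
  R <- seq(0, 30 * l, length.out = 40000)
  expect_equal(chemotactic_range(R, exp(-R / l)), 6^(1 / 3) * l,
               tolerance = 1e-3)
})

test_that("bootstrap frequencies are exact for a dominant action and reproducible", {
  par <- model_params(R_th = 2100)
  g <- state_grid(par, n_R = 2, n_Psi = 1)
  # high from bin 1 reaches success, low fails; bin 2 vice versa
  mk_ens <- function(variant) {
    lapply(1:6, function(i) {
      if (variant == "low")
        list(synthetic_coarse(c(g$R_centers[1], g$R_centers[1]), c(1, 1), "failure"),
             synthetic_coarse(c(g$R_centers[2], g$R_centers[2]), c(1, 1), "success"))[[
               (i %% 2) + 1]]
      else
        list(synthetic_coarse(c(g$R_centers[1], g$R_centers[1]), c(1, 1), "success"),
             synthetic_coarse(c(g$R_centers[2], g$R_centers[2]), c(1, 1), "failure"))[[
               (i %% 2) + 1]]
    })
  }
  m <- transition_model(NULL, NULL, g)
  m$ensembles <- list(low = mk_ens("low"), high = mk_ens("high"))
  b1 <- bootstrap_strategy_frequency(m, B = 8, seed = 4)
  expect_equal(b1$freq_high, c(1, 0))
  b2 <- bootstrap_strategy_frequency(m, B = 8, seed = 4)
  expect_identical(b1$freq_high, b2$freq_high)
})

test_that("the coarse dynamics is approximately Markovian in effect size", {
  # History dependence beyond the current (R, Psi) bin is small: the
  # second-order conditional next-bin distributions stay within modest
  # total-variation distance of the first-order (pooled) ones. (A formal
  # chi-square detects the residual ~0.1 TV memory at these counts; the
  # first-order chain is adequate in effect, as the success-prediction
  # control below confirms.)
  tm <- noisy_model()
  g <- tm$grid
  trip <- do.call(rbind, lapply(tm$ensembles$low, function(co) {
    b <- bin_index(g, co$R, co$Psi)
    b <- b[!is.na(co$Psi)]
    if (length(b) < 7) return(NULL)
    b <- b[-(1:2)]                      # drop launch transient
    cbind(prev = b[1:(length(b) - 2)], cur = b[2:(length(b) - 1)],
          nxt = b[3:length(b)])
  }))
  tvs <- numeric(0)
  for (i in unique(trip[, "cur"])) {
    sub <- trip[trip[, "cur"] == i, , drop = FALSE]
    if (nrow(sub) < 400) next
    pooled <- table(factor(sub[, "nxt"]))
    pooled <- pooled / sum(pooled)
    for (pv in names(which(table(sub[, "prev"]) >= 100))) {
      cond <- table(factor(sub[sub[, "prev"] == as.integer(pv), "nxt"],
                           levels = names(pooled)))
      cond <- cond / sum(cond)
      tvs <- c(tvs, 0.5 * sum(abs(cond - pooled)))
    }
  }
  expect_gt(length(tvs), 50)
  expect_lt(median(tvs), 0.15)
  expect_lt(quantile(tvs, 0.9), 0.30)
})

test_that("Markov-chain success predictions match closed-loop simulation", {
  tm <- noisy_model()
  par <- tm$params
  vh <- evaluate_strategy(tm, "high")$value
  pr <- success_profile(tm, vh)
  R0 <- 2000
  p_mdp <- approx(pr$R, pr$P, R0)$y
  sp <- success_probability(par, study_field(), "high", R0, n_paths = 150,
                            seed = 31)
  expect_lt(abs(p_mdp - sp$P), 0.12)
})

test_that("hybrid strategies interpolate between fallback and optimal", {
  tm <- noisy_model()
  opt <- noisy_optimal()
  par <- tm$params
  Rc <- c(par$R_egg, 3000, 6000, par$R_th)
  hy <- hybrid_range_curve(tm, opt, "low", Rc)
  vl <- evaluate_strategy(tm, "low")$value
  pl <- success_profile(tm, vl)
  expect_equal(hy$range[1], chemotactic_range(pl$R, pl$P), tolerance = 1e-9)
  po <- success_profile(tm, opt$value)
  expect_equal(hy$range[length(Rc)], chemotactic_range(po$R, po$P),
               tolerance = 1e-9)
  expect_true(all(diff(hy$range) > -1e-6))   # coverage cannot hurt
})
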