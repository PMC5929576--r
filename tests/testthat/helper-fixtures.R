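# shared fixtures: built lazily, cached for the whole test session

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

default_params <- function() memo("params", function() model_params())
study_field <- function() memo("field", function() default_field())

# noisy two-action transition model at the reduced study scale
noisy_model <- function() memo("noisy_model", function() {
  build_transition_model(default_params(), study_field(),
                         n_paths = 1000, seed = 42)
})

noisy_optimal <- function() memo("noisy_optimal", function() {
  solve_optimal_strategy(noisy_model())
})

# fitted decision boundary from the noisy model
fitted_boundary <- function() memo("fitted_boundary", function() {
  tm <- noisy_model()
  samp <- do.call(rbind, lapply(tm$ensembles$low, function(co)
    co[is.finite(co$Psi) & is.finite(co$p), c("R", "Psi", "p", "q")]))
  fr <- strategy_to_pq_frequency(samp, noisy_optimal(), tm$grid,
                                 n_p = 40, n_q = 40)
  fit_decision_boundary(fr, validity_limit = 0.005)
})

# random 2-action absorbing MDP on K transient states; success = K+1,
# failure = K+2.  Rows mix transitions among transient states and into
# the absorbing pair.
random_mdp <- function(K, seed) {
  set.seed(seed)
  par <- model_params(R_th = 100 * (K + 1) + 100)
  grid <- state_grid(par, n_R = K, n_Psi = 1)
  mk <- function() {
    L <- matrix(0, K + 2, K + 2)
    for (i in seq_len(K)) {
      w <- rexp(K + 2) * rbinom(K + 2, 1, 0.6)
      w[i] <- w[i] + 0.1
      L[i, ] <- w / sum(w)
    }
    L[K + 1, K + 1] <- 1
    L[K + 2, K + 2] <- 1
    L
  }
  transition_model(mk(), mk(), grid)
}

# exhaustive enumeration oracle: evaluate every memoryless strategy by a
# direct linear solve and take the componentwise maximum
enumerate_optimal <- function(model) {
  K <- model$grid$K
  best <- rep(-Inf, K)
  for (mask in 0:(2^K - 1)) {
    act <- ifelse(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0, "high", "low")
    v <- evaluate_strategy(model, act)$value
    best <- pmax(best, v)
  }
  best
}

# Monte-Carlo rollout oracle for a fixed-strategy absorbing chain
rollout_success <- function(model, strategy, start, n_roll, seed) {
  grid <- model$grid
  K <- grid$K
  L <- model$L_low
  hi <- strategy == "high"
  L[which(hi), ] <- model$L_high[which(hi), ]
  set.seed(seed)
  succ <- 0L
  for (r in seq_len(n_roll)) {
    s <- start
    for (step in seq_len(10000)) {
      s <- sample.int(K + 2, 1, prob = L[s, ])
      if (s > K) break
    }
    succ <- succ + (s == grid$success)
  }
  succ / n_roll
}

# synthetic coarse trajectory visiting given (R, Psi) states at lag
# spacing, with a declared outcome
synthetic_coarse <- function(R, Psi, outcome = "timeout") {
  co <- data.frame(t = seq_along(R) - 1, R = R, Psi = Psi,
                   a = 1, p = 1e-3, q = 1)
  attr(co, "outcome") <- outcome
  co
}
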