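# Independent oracles used across the suite.

# Stationary distribution by plain power iteration on the lazy kernel
# (I + M)/2; suitable for well-conditioned chains drawn in the tests.
power_iteration_stationary <- function(M, tol = 1e-13, max_iter = 1e6L) {
  pi_ <- rep(1 / nrow(M), nrow(M))
  L <- (diag(nrow(M)) + M) / 2
  for (i in seq_len(max_iter)) {
    nxt <- as.numeric(pi_ %*% L)
    if (max(abs(nxt - pi_)) < tol) return(nxt / sum(nxt))
    pi_ <- nxt
  }
  stop("oracle power iteration did not converge")
}

# Naive per-dose loop over the 3-state penalized objective (pairwise
# binding equilibria), written independently of the vectorised package
# code.
naive_objective_3state <- function(model, curves, penalty = 10000) {
  total <- 0
  violated <- FALSE
  for (i in seq_along(curves$dox)) {
    d <- curves$dox[i]
    a1 <- eval_hill(model$A1, d); a2 <- eval_hill(model$A2, d)
    r1 <- eval_hill(model$R1, d); r2 <- eval_hill(model$R2, d)
    p_act <- if (a1 + a2 == 0) 0 else a1 / (a1 + a2)
    p_rep <- if (r1 + r2 == 0) 1 else r1 / (r1 + r2)
    total <- total + (p_act - curves$obs_act[i])^2 +
      (p_rep - curves$obs_rep[i])^2
    if (a1 + r1 >= 1) violated <- TRUE
  }
  unname(total) + if (violated) penalty else 0
}

naive_objective_2state <- function(model, curves, chain) {
  total <- 0
  for (i in seq_along(curves$dox)) {
    d <- curves$dox[i]
    p <- eval_switching(model, d)
    p_on <- if (p[1, "p1"] + p[1, "p2"] == 0) 0
            else unname(p[1, "p1"] / (p[1, "p1"] + p[1, "p2"]))
    obs <- if (chain == "activator") curves$obs_act[i] else curves$obs_rep[i]
    val <- if (chain == "activator") p_on else 1 - p_on
    total <- total + (val - obs)^2
  }
  unname(total)
}

# Dense grid search over (K, H) for Hill least squares; returns the
# minimal residual sum of squares on the grid.
grid_search_hill_rss <- function(doses, responses, n_grid = 100L) {
  Ks <- 10^seq(-3, 3, length.out = n_grid)
  Hs <- seq(0.1, 10, length.out = n_grid)
  best <- Inf
  for (K in Ks) {
    r <- (doses / K)
    for (H in Hs) {
      f <- r^H / (1 + r^H)
      rss <- sum((responses - f)^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# A fixed, moderately-switching 3-state model with binding contingency
# satisfied on the default grid; used to generate synthetic target curves.
reference_test_model <- function() {
  switching_model(A1 = hill(4, 1.2), A2 = hill(4, 1.0),
                  R1 = hill(40, 1.1), R2 = hill(0.8, 1.3),
                  chain = "three_state")
}

random_valid_sp3 <- function() {
  p_A1 <- runif(1, 0.01, 0.6)
  p_R1 <- runif(1, 0.01, min(0.95 - p_A1, 0.6))
  step_probs3(p_A1, runif(1, 0.05, 0.95), p_R1, runif(1, 0.05, 0.95))
}
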