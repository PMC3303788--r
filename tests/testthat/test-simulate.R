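noise_free <- function(...) sim_config(deg_noise_sd = 0, bl_noise_sd = 0, ...)

test_that("the expression update follows the stated birth-death arithmetic", {
  cfg <- noise_free()
  # with noise off: BL = gamma * 10^0 = gamma
  expect_equal(step_expression(10, 1, cfg), 10 + (2 + 0.2 - 2) * 1)
  # fixed point at (alpha * f + gamma) / gamma for f = 10
  xf <- (2 * 10 + 0.2) / 0.2
  expect_equal(step_expression(xf, 10, cfg), xf)
  # clamped at zero under a forced large degradation draw
  expect_equal(step_expression(1, 0, sim_config(), delta = 50, z = 0), 0)
})

test_that("expression update consumes exactly two normal draws in order", {
  cfg <- sim_config()
  set.seed(123)
  a <- step_expression(5, 1, cfg)
  after <- rnorm(1)                    # stream position after the call
  set.seed(123)
  delta <- rnorm(1, 1, 0.5)            # draw 1: degradation noise
  z <- rnorm(1, 0, 0.5)                # draw 2: basal-level exponent
  manual <- max(0, 5 + (2 * 1 + 0.2 * 10^z - 0.2 * delta * 5) * 1)
  third <- rnorm(1)
  expect_equal(a, manual, tolerance = 1e-12)
  expect_identical(after, third)       # exactly two draws consumed
})

test_that("the basal-level noise has the lognormal mean predicted in closed form", {
  cfg <- sim_config()
  set.seed(88)
  n <- 1e5
  x1 <- step_expression(rep(0, n), 1, cfg)
  # E[X'] = alpha*f*dt + gamma*E[10^z], E[10^z] = exp((sd*ln10)^2/2)
  mu <- 2 * 1 + 0.2 * exp((0.5 * log(10))^2 / 2)
  se <- sd(x1) / sqrt(n)
  expect_lt(abs(mean(x1) - mu), 3 * se)
})

test_that("noise-free trajectories follow the deterministic recursion", {
  cfg <- noise_free(t_end = 200L)
  tr <- simulate_cell("activator", step_probs2(0, 0), cfg, seed = 1)
  expect_true(all(tr$state == "unbound"))
  expect_true(all(diff(tr$X) >= 0))
  expect_equal(tr$X[nrow(tr)], (2 * 1 + 0.2) / 0.2, tolerance = 1e-9)
  # absorbing activator-bound state from cycle 1 onward
  tr2 <- simulate_cell("three_state", step_probs3(1, 0, 0, 1),
                       noise_free(t_end = 50L), seed = 2,
                       init = "unbound")
  expect_true(all(tr2$state[-1] == "activator_bound"))
})

test_that("trajectories and populations are bit-exact under a fixed seed", {
  cfg <- sim_config(t_end = 50L, n_cells = 200L)
  m <- reference_test_model()
  t1 <- simulate_cell("three_state", m, cfg, seed = 9, dox = 1)
  t2 <- simulate_cell("three_state", m, cfg, seed = 9, dox = 1)
  expect_identical(t1, t2)
  p1 <- simulate_population("three_state", m, 1, cfg, seed = 10)
  p2 <- simulate_population("three_state", m, 1, cfg, seed = 10)
  expect_identical(p1$values, p2$values)
  expect_false(identical(
    p1$values, simulate_population("three_state", m, 1, cfg, seed = 11)$values))
})

test_that("degenerate populations collapse to the deterministic limit", {
  cfg <- noise_free(t_end = 200L, n_cells = 1000L)
  s <- simulate_population("activator", step_probs2(0, 0), 0, cfg, seed = 3)
  expect_equal(s$sd, 0)
  expect_equal(unique(s$values), (2 * 1 + 0.2) / 0.2, tolerance = 1e-9)
  expect_equal(length(s$values), 1000L)
})

test_that("a saturated activator population matches the birth-death mean field", {
  cfg <- sim_config(n_cells = 2000L)
  s <- simulate_population("activator", step_probs2(1, 0), 10, cfg, seed = 4)
  mf <- (2 * 10 + 0.2 * exp((0.5 * log(10))^2 / 2)) / 0.2
  expect_lt(abs(s$mean - mf) / mf, 0.10)
  expect_true(all(s$values >= 0))
})

test_that("pooled promoter-state occupancy matches the configured stationary law", {
  sp <- step_probs3(0.2, 0.3, 0.1, 0.4)
  cfg <- sim_config(t_end = 200L, n_cells = 300L)
  set.seed(12)
  out <- promcm:::.simulate_ensemble("three_state", sp, cfg, n = 300L,
                                     record = "full", init = "stationary")
  states <- out$state[101:201, ]
  freq <- tabulate(states, 3) / length(states)
  pi_ <- steady_state_3state(sp, "two_jump")
  se <- sqrt(pi_ * (1 - pi_) / 300)   # conservative: independent cells
  expect_true(all(abs(freq - unname(pi_)) < 3 * unname(se) + 0.02))
})

test_that("saturating activation, basal transcription and repression are ordered", {
  cfg <- sim_config(n_cells = 1000L)
  hi <- simulate_population("activator", step_probs2(1, 0), 10, cfg, seed = 5)
  basal <- simulate_population("activator", step_probs2(0, 0), 0, cfg, seed = 6)
  off <- simulate_population("repressor", step_probs2(0, 0), 0, cfg, seed = 7)
  expect_gt(hi$mean, basal$mean)
  expect_gt(basal$mean, off$mean)
})

test_that("ensemble traces settle and settling cycles are computed correctly", {
  synth <- data.frame(cycle = 0:6,
                      mean_X = c(0, 50, 80, 96, 99, 100, 100))
  expect_equal(settling_cycle(synth), 3)   # 96 is within 5% of 100
  cfg <- sim_config(n_cells = 2000L)
  tr <- ensemble_mean_trace("three_state", reference_test_model(), 1,
                            cfg, seed = 8)
  expect_equal(tr$mean_X[1], 0)
  expect_equal(nrow(tr), cfg$t_end + 1L)
  expect_lte(settling_cycle(tr), 50)
})
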