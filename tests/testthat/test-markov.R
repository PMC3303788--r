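test_that("2-state stationary law matches the analytical and iterative solutions", {
  expect_equal(steady_state_2state(0.2, 0.2)[["P_ON"]], 0.5)
  expect_equal(steady_state_2state(1, 0)[["P_ON"]], 1.0)
  ss <- steady_state_2state(0.3, 0.1)
  expect_equal(ss[["P_ON"]], 0.75)
  M <- matrix(c(0.7, 0.3, 0.1, 0.9), 2, 2, byrow = TRUE)  # rows OFF, ON
  pi_ <- power_iteration_stationary(M)
  expect_equal(unname(ss), pi_, tolerance = 1e-12)
  expect_equal(sum(ss), 1, tolerance = 1e-12)
  expect_error(steady_state_2state(0, 0), "degenerate")
})

test_that("3-state single-jump stationary law matches closed form and matrix oracle", {
  ss <- steady_state_3state(step_probs3(0.2, 0.2, 0.2, 0.2))
  expect_equal(unname(ss), rep(1 / 3, 3), tolerance = 1e-12)
  sp <- step_probs3(0.4, 0.2, 0.1, 0.2)
  ss <- steady_state_3state(sp)
  expect_equal(unname(ss), c(1 / 7, 2 / 7, 4 / 7), tolerance = 1e-12)
  expect_equal(unname(ss),
               power_iteration_stationary(transition_matrix(sp, "single_jump")),
               tolerance = 1e-10)
  ss0 <- steady_state_3state(step_probs3(0, 0.5, 0, 0.5))
  expect_equal(ss0[["pi_U"]], 1)
  expect_error(steady_state_3state(step_probs3(0.2, 0, 0.2, 0.2)),
               "degenerate")
})

test_that("two-jump composite stationary law differs from single-jump and matches its kernel", {
  sp <- step_probs3(0.2, 0.2, 0.2, 0.2)
  ss <- steady_state_3state(sp, mode = "two_jump")
  expect_equal(ss[["pi_U"]], 1 / 3.5, tolerance = 1e-12)
  expect_equal(ss[["pi_A"]], ss[["pi_R"]], tolerance = 1e-12)
  expect_equal(unname(ss),
               power_iteration_stationary(transition_matrix(sp, "two_jump")),
               tolerance = 1e-10)
  ss0 <- steady_state_3state(step_probs3(0, 0.3, 0, 0.7), mode = "two_jump")
  expect_equal(ss0[["pi_U"]], 1)
})

test_that("both stationary modes agree with power iteration over many random chains", {
  set.seed(99)
  for (i in 1:1000) {
    sp <- random_valid_sp3()
    for (mode in c("single_jump", "two_jump")) {
      expect_lt(max(abs(unname(steady_state_3state(sp, mode)) -
                        power_iteration_stationary(transition_matrix(sp, mode)))),
                1e-10)
    }
  }
})

test_that("single-step updates follow the strict threshold rule", {
  sp2 <- step_probs2(0.3, 0.1)
  expect_identical(step_2state("off", sp2, r = 0.25), "on")
  expect_identical(step_2state("off", sp2, r = 0.30), "off")  # r < p strict
  expect_identical(step_2state("on", sp2, r = 0.05), "off")
  sp3 <- step_probs3(0.3, 0.5, 0.2, 0.5)
  expect_identical(step_3state("unbound", sp3, r1 = 0.25), "activator_bound")
  expect_identical(step_3state("unbound", sp3, r1 = 0.45), "repressor_bound")
  expect_identical(step_3state("unbound", sp3, r1 = 0.55), "unbound")
  forced <- step_probs3(0, 1, 1, 0)  # p_A2 = 1, p_R1 = 1
  expect_identical(step_3state("activator_bound", forced,
                               r1 = 0.9, r2 = 0.9), "repressor_bound")
  expect_identical(step_3state("activator_bound", forced, r1 = 0.9,
                               r2 = 0.9, mode = "single_jump"), "unbound")
  expect_error(step_probs3(0.7, 0.5, 0.6, 0.5), "contingency")
})

test_that("long-run state frequencies match the stationary law", {
  set.seed(4)
  sp <- step_probs3(0.25, 0.35, 0.15, 0.3)
  for (mode in c("single_jump", "two_jump")) {
    n <- 1e5L
    state <- "unbound"
    counts <- c(repressor_bound = 0L, unbound = 0L, activator_bound = 0L)
    for (i in seq_len(n)) {
      state <- step_3state(state, sp, mode = mode)
      counts[state] <- counts[state] + 1L
    }
    pi_ <- steady_state_3state(sp, mode)
    se <- sqrt(pi_ * (1 - pi_) / n)
    # correlated samples: allow 3 SE inflated by the chain's mixing time
    infl <- 6
    expect_true(all(abs(counts / n - unname(pi_)) < 3 * infl * unname(se) + 1e-3))
  }
})

test_that("single-jump trajectories never jump directly between bound states", {
  set.seed(5)
  cfg <- sim_config(t_end = 500, n_cells = 1, update_mode = "single_jump")
  tr <- simulate_cell("three_state", step_probs3(0.4, 0.5, 0.4, 0.5),
                      cfg, seed = 21)
  s <- tr$state
  pairs <- cbind(s[-length(s)], s[-1])
  bad <- (pairs[, 1] == "repressor_bound" & pairs[, 2] == "activator_bound") |
         (pairs[, 1] == "activator_bound" & pairs[, 2] == "repressor_bound")
  expect_false(any(bad))
})
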