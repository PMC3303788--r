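test_that("observed curves have the documented endpoints and orientation", {
  cur <- observed_curves(hill(0.6, 1.6), hill(0.6, 1.8),
                         dox = c(0, 0.1, 0.3, 0.6, 1, 3, 10))
  expect_equal(cur$obs_act[cur$dox == 0.6], 0.5, tolerance = 1e-12)
  expect_equal(cur$obs_rep[cur$dox == 0], 1.0)
  expect_equal(cur$obs_rep[cur$dox == 0.6], 0.5, tolerance = 1e-12)
  expect_true(all(diff(cur$obs_act) >= 0))
  expect_true(all(diff(cur$obs_rep) <= 0))
  expect_error(observed_curves(dox = c(0, 1, 2)), "7")
})

test_that("3-state objective is zero at a perfect fit and matches the loop oracle", {
  m <- reference_test_model()
  g <- dose_grid()
  p <- eval_switching(m, g)
  cur <- observed_curves(dox = g,
                         obs_act = ifelse(g == 0, 0, p[, "A1"] / (p[, "A1"] + p[, "A2"])),
                         obs_rep = ifelse(g == 0, 1,
                                          p[, "R1"] / (p[, "R1"] + p[, "R2"])))
  expect_equal(objective_3state(m, cur), 0, tolerance = 1e-20)
  set.seed(31)
  ref <- observed_curves()
  for (i in 1:20) {
    rnd <- switching_model(A1 = hill(10^runif(1, -1, 1), runif(1, 0.5, 3)),
                           A2 = hill(10^runif(1, 0, 2), runif(1, 0.5, 3)),
                           R1 = hill(10^runif(1, 0, 2), runif(1, 0.5, 3)),
                           R2 = hill(10^runif(1, -1, 1), runif(1, 0.5, 3)),
                           chain = "three_state")
    expect_equal(objective_3state(rnd, ref), naive_objective_3state(rnd, ref),
                 tolerance = 1e-12)
  }
})

test_that("binding-contingency violations incur the 10000 penalty", {
  bad <- switching_model(A1 = hill(0.1, 0.5), A2 = hill(100, 2),
                         R1 = hill(0.1, 0.5), R2 = hill(1, 1),
                         chain = "three_state")
  p <- eval_switching(bad, 10)
  expect_gte(p[1, "A1"] + p[1, "R1"], 1)
  expect_gte(objective_3state(bad, observed_curves()), 10000)
  # penalty dominance: a satisfying model's squared error is bounded by
  # 2 per dose, far below the penalty
  good <- reference_test_model()
  expect_lt(objective_3state(good, observed_curves()), 10000)
})

test_that("2-state objective matches the loop oracle for both orientations", {
  ref <- observed_curves()
  set.seed(32)
  for (chain in c("activator", "repressor")) {
    for (i in 1:10) {
      m <- switching_model(p1 = hill(10^runif(1, -1, 1), runif(1, 0.5, 3)),
                           p2 = hill(10^runif(1, 0, 2), runif(1, 0.5, 3)),
                           chain = chain)
      expect_equal(objective_2state(m, ref),
                   naive_objective_2state(m, ref, chain),
                   tolerance = 1e-12)
    }
  }
  # perfect dependent fit: P_ON = p1 reproduces the activator curve exactly
  dep <- switching_model(p1 = hill(0.6, 1.6), chain = "activator",
                         dependent = TRUE)
  expect_equal(objective_2state(dep, ref), 0, tolerance = 1e-20)
})

test_that("estimation recovers synthetic binding curves up to identifiability", {
  m_true <- reference_test_model()
  g <- dose_grid()
  p <- eval_switching(m_true, g)
  cur <- observed_curves(dox = g,
                         obs_act = ifelse(g == 0, 0, p[, "A1"] / (p[, "A1"] + p[, "A2"])),
                         obs_rep = ifelse(g == 0, 1,
                                          p[, "R1"] / (p[, "R1"] + p[, "R2"])))
  fit <- estimate_switching(cur, "three_state", seed = 1L, budget = 50000L)
  expect_lte(fit$objective_value, 1e-4)
  expect_true(fit$constraint_satisfied)
  # the test surface is the fitted binding curves, not raw parameters
  pr <- predict(fit, dox = g, type = "binding")
  expect_lt(max(abs(pr$P_Act - cur$obs_act)), 0.01)
  expect_lt(max(abs(pr$P_Rep - cur$obs_rep)), 0.01)
})

test_that("2-state estimation from the reference curves achieves a near-perfect fit", {
  fit <- cached_fit("activator")
  expect_lt(fit$objective_value, 1e-3)
  fit_r <- cached_fit("repressor")
  expect_lt(fit_r$objective_value, 1e-3)
})

test_that("estimation is bit-exactly reproducible for a fixed seed", {
  cur <- observed_curves()
  a <- estimate_switching(cur, "activator", seed = 77L, budget = 2000L)
  b <- estimate_switching(cur, "activator", seed = 77L, budget = 2000L)
  expect_identical(coef(a), coef(b))
  expect_identical(a$objective_value, b$objective_value)
  expect_identical(a$n_evaluations, b$n_evaluations)
})

test_that("fitted mcm objects expose coherent methods", {
  fit <- cached_fit("three_state")
  expect_s3_class(fit, "mcm")
  co <- coef(fit)
  expect_equal(rownames(co), c("A1", "A2", "R1", "R2"))
  expect_true(all(co[, "K"] > 0 & co[, "H"] > 0))
  r <- residuals(fit)
  expect_equal(dim(r), c(length(fit$curves$dox), 2L))
  expect_lt(max(abs(r)), 0.05)
  pr <- predict(fit, dox = c(0, 0.6, 10), type = "probabilities")
  expect_true(all(pr[, -1] >= 0 & pr[, -1] <= 1))
  occ <- predict(fit, dox = c(0.1, 1, 5), type = "occupancy",
                 mode = "two_jump")
  expect_equal(rowSums(occ[, c("pi_R", "pi_U", "pi_A")]), rep(1, 3),
               tolerance = 1e-12)
  s <- summary(fit)
  expect_output(print(s), "three_state")
})
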