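test_that("the default dose grid matches the study design", {
  g <- dose_grid()
  expect_length(g, 34L)
  expect_equal(g[1], 0)
  expect_equal(g[2], 0.01)
  expect_equal(g[34], 10)
  expect_true(!is.unsorted(g))
  g2 <- dose_grid(10, 0.1, 5, include_zero = FALSE)
  expect_length(g2, 10L)
  expect_gt(min(g2), 0)
})

test_that("min-max normalization is idempotent with exact endpoints", {
  set.seed(2)
  x <- rnorm(20)
  n1 <- normalize_minmax(x)
  expect_equal(normalize_minmax(n1), n1)
  expect_equal(range(n1), c(0, 1))
  expect_error(normalize_minmax(rep(3, 5)), "constant")
})

test_that("dose-response tables satisfy the normalization and ordering contracts", {
  cfg <- sim_config(n_cells = 100L, t_end = 60L)
  g <- dose_grid(7)
  tab <- run_dose_response("activator", step_probs2(0.5, 0.5), g, cfg,
                           seed = 5)
  expect_s3_class(tab, "dose_response")
  expect_equal(nrow(tab), 7L)
  expect_true(!is.unsorted(tab$dox))
  expect_true(all(tab$norm_mean >= 0 & tab$norm_mean <= 1))
  expect_equal(min(tab$norm_mean), 0)
  expect_equal(max(tab$norm_mean), 1)
})

test_that("single-factor tables are monotone and repression is minimal at zero dox", {
  cfg <- sim_config(n_cells = 1000L)
  fa <- cached_fit("activator")
  ta <- run_dose_response("activator", fa, dose_grid(12), cfg, seed = 21)
  expect_true(all(diff(ta$norm_mean) > -0.05))
  fr <- cached_fit("repressor")
  tr <- run_dose_response("repressor", fr, dose_grid(12), cfg, seed = 22)
  expect_lte(tr$mean_X[1], min(tr$mean_X) + 0.2)   # dox = 0 row at the floor
})

test_that("Hill prediction from an analytic table recovers the generator exactly", {
  g <- dose_grid()
  tab <- structure(data.frame(dox = g, mean_X = NA, sd_X = NA,
                              norm_mean = eval_hill(hill(0.8, 2.5), g)),
                   class = c("dose_response", "data.frame"))
  hf <- predict_hill(tab)
  expect_equal(unname(coef(hf)), c(0.8, 2.5), tolerance = 1e-6)
})

test_that("customary Hill-coefficient combinations are exact", {
  expect_equal(combine_hill(1.6, 1.8, "add"), 3.4)
  expect_identical(combine_hill(1.6, 1.8, "multiply"), 1.6 * 1.8)
  expect_equal(combine_hill(1.6, 1.8, "multiply"), 2.88)
  expect_equal(combine_hill(1, 7, "multiply"), 7)
  expect_error(combine_hill(1.6, 1.8, "divide"))
})

test_that("mode counting distinguishes constructed unimodal and bimodal samples", {
  expect_equal(mode_count(rep(5, 200)), 1L)
  set.seed(10)
  uni <- 10^rnorm(2000, 1.5, 0.2)
  expect_equal(mode_count(uni), 1L)
  bi <- c(10^rnorm(1000, 0.3, 0.15), 10^rnorm(1000, 2, 0.15))
  expect_equal(mode_count(bi), 2L)
  # minor maxima below 5% of the global peak are ignored
  spiked <- c(10^rnorm(5000, 2, 0.1), 10^rnorm(30, 0.3, 0.02))
  expect_equal(mode_count(spiked), 1L)
})

test_that("Hill fits are stable under grid refinement", {
  cfg <- sim_config(n_cells = 2000L)
  fit <- cached_fit("three_state")
  h34 <- predict_hill(run_dose_response("three_state", fit, dose_grid(34),
                                        cfg, seed = 31))
  h68 <- predict_hill(run_dose_response("three_state", fit, dose_grid(68),
                                        cfg, seed = 32))
  expect_lt(abs(coef(h34)["H"] - coef(h68)["H"]), 0.1)
})

test_that("prediction reports are reproducible and correctly assembled", {
  cfg <- sim_config(n_cells = 150L, t_end = 60L)
  g <- dose_grid(8)
  r1 <- mcm_report(dox = g, cfg = cfg, seed = 5L, budget = 2000L)
  r2 <- mcm_report(dox = g, cfg = cfg, seed = 5L, budget = 2000L)
  expect_identical(lapply(r1$hill, coef), lapply(r2$hill, coef))
  expect_equal(r1$calc_add, 3.4)
  expect_equal(r1$calc_mult, 2.88)
  expect_named(r1$hill, c("activator", "repressor", "three_state"))
  expect_output(print(r1), "Calculated")
})
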