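## Telegraph + birth-death stochastic simulator.
##
## Expression of a single cell follows the discrete-time birth-death update
##   X' = max(0, X + (alpha * f + BL - gamma * delta * X) * dt)
## where f is the promoter activity of the current promoter state
## (0 repressor_bound / 1 unbound / 10 activator_bound), delta ~ N(1, 0.5^2)
## perturbs degradation, and BL = gamma * 10^z with z ~ N(0, 0.5^2) is the
## basal (leaky) expression level including background noise.  Promoter
## states switch per cycle according to the Markov chain, producing the
## telegraph that drives bursts of expression.

#' Simulation configuration
#'
#' Defaults are the reference study conditions: transcription rate
#' `alpha = 2.0` (arbitrary units per cycle), degradation rate
#' `gamma = 0.2` per cycle, time step `dt = 1` cycle, `t_end = 200` cycles,
#' `n_cells = 10000`, degradation-noise SD 0.5 (`delta ~ N(1, 0.5^2)`),
#' basal-level noise SD 0.5 (`BL = gamma * 10^z`, `z ~ N(0, 0.5^2)`), and
#' promoter activities 0 / 1 / 10 for the repressor-bound / unbound /
#' activator-bound states.  The default 3-state update mode is
#' `"two_jump"` (see [step_3state()]).
#'
#' @param alpha transcription rate (units/cycle, > 0).
#' @param gamma first-order mRNA degradation rate (per cycle, > 0).
#' @param dt time step (cycles, > 0).
#' @param t_end number of simulated cycles (>= 1).
#' @param n_cells number of independent cells (>= 1).
#' @param deg_noise_sd SD of the degradation-noise factor `delta`.
#' @param bl_noise_sd SD of the basal-level exponent `z`.
#' @param activity named promoter-activity map for the three states.
#' @param update_mode `"two_jump"` or `"single_jump"` (3-state chains).
#' @param seed integer seed for population simulations.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(alpha = 2.0, gamma = 0.2, dt = 1, t_end = 200L,
                       n_cells = 10000L, deg_noise_sd = 0.5,
                       bl_noise_sd = 0.5,
                       activity = c(repressor_bound = 0, unbound = 1,
                                    activator_bound = 10),
                       update_mode = c("two_jump", "single_jump"),
                       seed = 1L) {
  update_mode <- match.arg(update_mode)
  stopifnot(alpha > 0, gamma > 0, dt > 0, t_end >= 1, n_cells >= 1,
            deg_noise_sd >= 0, bl_noise_sd >= 0)
  if (!all(promoter_states() %in% names(activity)))
    stop("'activity' must be named for all of: ",
         paste(promoter_states(), collapse = ", "))
  if (any(activity < 0)) stop("promoter activities must be nonnegative")
  structure(list(alpha = alpha, gamma = gamma, dt = dt,
                 t_end = as.integer(t_end), n_cells = as.integer(n_cells),
                 deg_noise_sd = deg_noise_sd, bl_noise_sd = bl_noise_sd,
                 activity = activity[promoter_states()],
                 update_mode = update_mode, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  cat(sprintf("  alpha = %g, gamma = %g, dt = %g, t_end = %d, n_cells = %d\n",
              x$alpha, x$gamma, x$dt, x$t_end, x$n_cells))
  cat(sprintf("  noise: delta ~ N(1, %g^2), BL = gamma * 10^z, z ~ N(0, %g^2)\n",
              x$deg_noise_sd, x$bl_noise_sd))
  cat(sprintf("  activity map: R=%g U=%g A=%g; update mode: %s; seed: %d\n",
              x$activity[1], x$activity[2], x$activity[3],
              x$update_mode, x$seed))
  invisible(x)
}

#' One birth-death expression update
#'
#' Applies `X' = max(0, X + (alpha*f + BL - gamma*delta*X)*dt)` with
#' `delta ~ N(1, deg_noise_sd^2)` and `BL = gamma*10^z`,
#' `z ~ N(0, bl_noise_sd^2)`.  Exactly two normal draws are consumed per
#' element of `X` (delta first, then z) unless both are supplied.
#' Setting the noise SDs to 0 in `cfg` recovers the deterministic update.
#'
#' @param X current expression level(s), >= 0.
#' @param f promoter activity (scalar or vector matching `X`).
#' @param cfg a [sim_config()].
#' @param delta,z optional pre-drawn noise values (for deterministic tests).
#' @return Updated expression level(s), clamped at 0.
#' @export
step_expression <- function(X, f, cfg, delta = NULL, z = NULL) {
  stopifnot(inherits(cfg, "sim_config"), all(X >= 0))
  n <- length(X)
  if (is.null(delta)) delta <- stats::rnorm(n, mean = 1, sd = cfg$deg_noise_sd)
  if (is.null(z))     z     <- stats::rnorm(n, mean = 0, sd = cfg$bl_noise_sd)
  bl <- cfg$gamma * 10^z
  pmax(0, X + (cfg$alpha * f + bl - cfg$gamma * delta * X) * cfg$dt)
}

## Uninduced promoter state: the chain's configuration without inducer.
## Without dox the repressor (when present) occupies the site, so the
## repressor-only and 3-state chains start repressor_bound; the
## activator-only chain starts unbound (its OFF state).  Expression starts
## at X = 0.
.initial_state <- function(chain) {
  switch(chain,
         activator = "unbound",
         repressor = "repressor_bound",
         three_state = "repressor_bound")
}

## Initial promoter-state codes for n cells.  init = "stationary" draws
## each cell's state from the stationary law of the configured update mode
## at this dose, so the recorded steady-state population is free of
## telegraph burn-in (expression still starts at X = 0 and relaxes within
## a few 1/gamma cycles).  Falls back to the uninduced state where no
## stationary law exists (dox = 0: all switching probabilities vanish).
## init = "uninduced" (or an explicit state name) starts every cell in
## that fixed state.
.initial_codes <- function(chain, sp, cfg, n, init) {
  if (init == "stationary") {
    if (inherits(sp, "step_probs3")) {
      if (sp$p_A1 + sp$p_A2 + sp$p_R1 + sp$p_R2 > 0 &&
          sp$p_A2 > 0 && sp$p_R2 > 0) {
        pi_ <- steady_state_3state(sp, mode = cfg$update_mode)
        return(sample.int(3L, n, replace = TRUE, prob = pi_))
      }
    } else if (sp$p1 + sp$p2 > 0) {
      on_code <- if (chain == "activator") 3L else 2L
      off_code <- if (chain == "activator") 2L else 1L
      p_on <- sp$p1 / (sp$p1 + sp$p2)
      return(ifelse(stats::runif(n) < p_on, on_code, off_code))
    }
    init <- .initial_state(chain)
  } else if (init == "uninduced") {
    init <- .initial_state(chain)
  } else {
    init <- match.arg(init, promoter_states())
  }
  rep(.state_code(init), n)
}

## Integer state codes used by the vectorised engine: 1 = repressor_bound,
## 2 = unbound, 3 = activator_bound.
.state_code <- function(state) match(state, promoter_states())

## Resolve the per-step probabilities of `model` at a dox level for the
## engine.  `model` may already be a step_probs2/step_probs3 object (then
## `dox` is ignored) or a switching_model evaluated at `dox`.
.resolve_sp <- function(chain, model, dox) {
  if (inherits(model, "step_probs2") || inherits(model, "step_probs3"))
    return(model)
  if (inherits(model, "switching_model"))
    return(switching_at(model, dox))
  if (inherits(model, "mcm"))
    return(switching_at(model$model, dox))
  stop("'model' must be a step_probs2/step_probs3, switching_model or mcm object")
}

## Vectorised ensemble engine.  All n cells advance one cycle at a time with
## a synchronized draw order: state uniforms first (one vector, plus a
## second for the two-jump continuation), then the degradation-noise and
## basal-level normal vectors.  record = "final" returns X at t_end,
## "trace" the per-cycle ensemble mean/sd, "full" the per-cycle X and state
## matrices.
.simulate_ensemble <- function(chain, sp, cfg, n, record = "final",
                               init = "uninduced") {
  chain <- match.arg(chain, chain_kinds())
  act <- unname(cfg$activity)            # f by state code 1, 2, 3
  state <- .initial_codes(chain, sp, cfg, n, init)
  X <- numeric(n)
  two <- cfg$update_mode == "two_jump"
  if (record == "trace") {
    mean_X <- numeric(cfg$t_end + 1L)
    sd_X <- numeric(cfg$t_end + 1L)
    sd_X[1L] <- 0
  } else if (record == "full") {
    Xs <- matrix(0, nrow = cfg$t_end + 1L, ncol = n)
    Ss <- matrix(state, nrow = cfg$t_end + 1L, ncol = n, byrow = TRUE)
  }
  if (inherits(sp, "step_probs3")) {
    pA1 <- sp$p_A1; pA2 <- sp$p_A2; pR1 <- sp$p_R1; pR2 <- sp$p_R2
  } else {
    p1 <- sp$p1; p2 <- sp$p2
    ## map OFF/ON to promoter-state codes for the 2-state chains
    on_code  <- if (chain == "activator") 3L else 2L
    off_code <- if (chain == "activator") 2L else 1L
  }
  for (t in seq_len(cfg$t_end)) {
    r1 <- stats::runif(n)
    if (inherits(sp, "step_probs3")) {
      r2 <- if (two) stats::runif(n) else NULL
      new <- state
      isU <- state == 2L
      if (any(isU)) {
        rU <- r1[isU]
        new[isU] <- ifelse(rU < pA1, 3L, ifelse(rU < pA1 + pR1, 1L, 2L))
      }
      isA <- state == 3L
      if (any(isA)) {
        leave <- r1[isA] < pA2
        dest <- rep(3L, sum(isA))
        if (two) dest[leave] <- ifelse(r2[isA][leave] < pR1, 1L, 2L)
        else dest[leave] <- 2L
        new[isA] <- dest
      }
      isR <- state == 1L
      if (any(isR)) {
        leave <- r1[isR] < pR2
        dest <- rep(1L, sum(isR))
        if (two) dest[leave] <- ifelse(r2[isR][leave] < pA1, 3L, 2L)
        else dest[leave] <- 2L
        new[isR] <- dest
      }
      state <- new
    } else {
      off <- state == off_code
      state <- ifelse(off,
                      ifelse(r1 < p1, on_code, off_code),
                      ifelse(r1 < p2, off_code, on_code))
    }
    f <- act[state]
    X <- step_expression(X, f, cfg)
    if (record == "trace") {
      mean_X[t + 1L] <- mean(X)
      sd_X[t + 1L] <- stats::sd(X)
    } else if (record == "full") {
      Xs[t + 1L, ] <- X
      Ss[t + 1L, ] <- state
    }
  }
  switch(record,
         final = X,
         trace = data.frame(cycle = 0:cfg$t_end, mean_X = mean_X,
                            sd_X = sd_X),
         full = list(X = Xs, state = Ss))
}

#' Simulate a single-cell trajectory
#'
#' One cell, starting at `X = 0` in the chain's uninduced promoter state
#' (activator-only chain: unbound; repressor-only and 3-state chains:
#' repressor-bound), alternating one promoter-state update and one
#' expression update per cycle.  Bit-exact reproducible for a fixed
#' `seed`.
#'
#' @param chain one of [chain_kinds()].
#' @param sp concrete step probabilities ([step_probs2()]/[step_probs3()]),
#'   or a `switching_model` together with `dox`.
#' @param cfg a [sim_config()].
#' @param seed integer seed for this cell.
#' @param dox dox level at which to evaluate `sp` if it is a model.
#' @param init `"uninduced"` (default), `"stationary"`, or an explicit
#'   state from [promoter_states()].
#' @return A data.frame with columns `cycle`, `X`, `state` (class
#'   `"mcm_trajectory"`), the telegraph aligned with the expression
#'   trajectory.
#' @export
simulate_cell <- function(chain, sp, cfg = sim_config(), seed = cfg$seed,
                          dox = NULL, init = "uninduced") {
  chain <- match.arg(chain, chain_kinds())
  sp <- .resolve_sp(chain, sp, dox)
  set.seed(as.integer(seed))
  out <- .simulate_ensemble(chain, sp, cfg, n = 1L, record = "full",
                            init = init)
  structure(data.frame(cycle = 0:cfg$t_end,
                       X = out$X[, 1L],
                       state = promoter_states()[out$state[, 1L]],
                       stringsAsFactors = FALSE),
            class = c("mcm_trajectory", "data.frame"))
}

#' @export
plot.mcm_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$cycle, x$X, type = "l", xlab = "cycle", ylab = "X", ...)
  plot(x$cycle, .state_code(x$state), type = "s", xlab = "cycle",
       ylab = "promoter state", yaxt = "n")
  graphics::axis(2, at = 1:3, labels = c("R", "U", "A"), las = 1)
  invisible(x)
}

#' Simulate a steady-state cell population
#'
#' Simulates `cfg$n_cells` independent cells at one dox level and records
#' expression at the final cycle.  By default each cell's telegraph starts
#' from the stationary promoter-state law at this dose (so the recorded
#' population is a steady-state sample free of telegraph burn-in;
#' expression starts at 0 and relaxes within a few `1/gamma` cycles); at
#' `dox = 0`, where all switching probabilities vanish, cells are frozen
#' in the uninduced state.  Identical configuration and seed yield
#' identical samples.
#'
#' @inheritParams simulate_cell
#' @param model a `switching_model` (or fitted [mcm()] object), or concrete
#'   step probabilities.
#' @param dox dox concentration (ug/ml); used to evaluate `model`.
#' @param seed integer seed (default `cfg$seed`).
#' @param init `"stationary"` (default), `"uninduced"`, or an explicit
#'   state from [promoter_states()].
#' @return Object of class `"population_sample"`: list with `dox`, `values`
#'   (length `n_cells`), `mean`, `sd`, `chain`.
#' @export
simulate_population <- function(chain, model, dox, cfg = sim_config(),
                                seed = cfg$seed, init = "stationary") {
  chain <- match.arg(chain, chain_kinds())
  sp <- .resolve_sp(chain, model, dox)
  set.seed(as.integer(seed))
  values <- .simulate_ensemble(chain, sp, cfg, n = cfg$n_cells,
                               record = "final", init = init)
  structure(list(dox = dox, values = values, mean = mean(values),
                 sd = stats::sd(values), chain = chain),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf(
    "Population sample (%s chain) at dox = %g: n = %d, mean = %.4g, sd = %.4g\n",
    x$chain, x$dox, length(x$values), x$mean, x$sd))
  invisible(x)
}

#' Per-cycle ensemble mean of expression
#'
#' @inheritParams simulate_population
#' @return A data.frame with columns `cycle`, `mean_X`, `sd_X`.
#' @export
ensemble_mean_trace <- function(chain, model, dox, cfg = sim_config(),
                                seed = cfg$seed, init = "stationary") {
  chain <- match.arg(chain, chain_kinds())
  sp <- .resolve_sp(chain, model, dox)
  set.seed(as.integer(seed))
  .simulate_ensemble(chain, sp, cfg, n = cfg$n_cells, record = "trace",
                     init = init)
}

#' First cycle at which an ensemble-mean trace has settled
#'
#' Returns the first cycle after which the ensemble mean stays within
#' `tol` (relative) of its value at the final recorded cycle.
#'
#' @param trace a data.frame from [ensemble_mean_trace()].
#' @param tol relative tolerance (default 0.05, i.e. 5%).
#' @return The settling cycle (integer).
#' @export
settling_cycle <- function(trace, tol = 0.05) {
  stopifnot(is.data.frame(trace), all(c("cycle", "mean_X") %in% names(trace)))
  final <- trace$mean_X[nrow(trace)]
  ok <- abs(trace$mean_X - final) <= tol * abs(final)
  ## first index from which all later cycles are within tolerance
  idx <- which(rev(cumprod(rev(ok))) == 1)[1]
  trace$cycle[idx]
}
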