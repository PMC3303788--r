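## Estimation of dose-dependent switching probabilities.
##
## All switching probabilities are Hill functions of the inducer (dox)
## concentration.  The 3-state competing-factor model has four of them
## (P_A1, P_A2, P_R1, P_R2; 8 parameters); a 2-state single-factor model
## has two (p1 OFF->ON, p2 ON->OFF; 4 parameters).  Parameters are chosen
## to make the chain's stationary bound-state occupancies match the
## occupancy curves implied by the observed activator-only and
## repressor-only dose-response experiments, with a large additive penalty
## when the binding contingency P_A1 + P_R1 < 1 fails anywhere on the
## dose grid.

#' Observed single-factor occupancy curves
#'
#' Builds the target curves for estimation from the Hill parameters of the
#' observed activator-only and repressor-only dose-response experiments
#' (reference Hill coefficients 1.6 and 1.8).  The activator-bound
#' occupancy equals the observed normalized expression,
#' `obs_act(d) = h_act(d)`; the repressor-bound occupancy is the complement
#' of the observed (rising) expression curve,
#' `obs_rep(d) = 1 - h_rep(d)`, since repressor occupancy falls as
#' expression rises.  Explicit curves can be supplied instead via
#' `obs_act` / `obs_rep` (e.g. synthetic curves from a known model).
#'
#' @param activator [hill()] parameters of the activator-only expression
#'   curve.
#' @param repressor [hill()] parameters of the repressor-only expression
#'   curve.
#' @param dox dose grid (>= 7 nonnegative concentrations, ug/ml).
#' @param obs_act,obs_rep optional explicit occupancy curves on `dox`.
#' @return Object of class `"observed_curves"`.
#' @export
observed_curves <- function(activator = hill(0.6, 1.6),
                            repressor = hill(0.6, 1.8),
                            dox = dose_grid(),
                            obs_act = NULL, obs_rep = NULL) {
  stopifnot(is.numeric(dox), length(dox) >= 7L, all(dox >= 0))
  dox <- sort(dox)
  if (is.null(obs_act)) obs_act <- eval_hill(activator, dox)
  if (is.null(obs_rep)) obs_rep <- 1 - eval_hill(repressor, dox)
  stopifnot(length(obs_act) == length(dox), length(obs_rep) == length(dox),
            all(obs_act >= 0 & obs_act <= 1),
            all(obs_rep >= 0 & obs_rep <= 1))
  structure(list(dox = dox, obs_act = obs_act, obs_rep = obs_rep,
                 activator = activator, repressor = repressor),
            class = "observed_curves")
}

#' @export
print.observed_curves <- function(x, ...) {
  cat(sprintf("Observed occupancy curves on %d doses in [%g, %g] ug/ml\n",
              length(x$dox), min(x$dox), max(x$dox)))
  invisible(x)
}

#' Dose-dependent switching model
#'
#' A set of Hill functions giving the per-step switching probabilities at
#' any dox level: four ([hill()] objects `A1`, `A2`, `R1`, `R2`) for the
#' 3-state chain, two (`p1`, `p2`) for a 2-state chain.
#'
#' @param ... named [hill()] objects: `A1, A2, R1, R2` (3-state) or
#'   `p1, p2` (2-state; just `p1` with `dependent = TRUE`).
#' @param chain one of [chain_kinds()].
#' @param dependent logical; 2-state dependent parameterization
#'   `p2 = 1 - p1` (only `p1` is supplied).
#' @return Object of class `"switching_model"`.
#' @export
switching_model <- function(..., chain = "three_state",
                            dependent = FALSE) {
  chain <- match.arg(chain, chain_kinds())
  if (dependent && chain == "three_state")
    stop("'dependent' applies only to 2-state chains")
  hp <- list(...)
  want <- if (chain == "three_state") c("A1", "A2", "R1", "R2")
          else if (dependent) "p1"
          else c("p1", "p2")
  if (!setequal(names(hp), want))
    stop("switching model for chain '", chain, "' needs Hill functions ",
         "named: ", paste(want, collapse = ", "))
  ok <- vapply(hp, inherits, logical(1), what = "hill")
  if (!all(ok)) stop("all components must be hill() objects")
  structure(hp[want], chain = chain, dependent = dependent,
            class = "switching_model")
}

#' @export
print.switching_model <- function(x, ...) {
  cat(sprintf("Switching model (%s chain):\n", attr(x, "chain")))
  for (nm in names(x))
    cat(sprintf("  %-3s: K = %.4g, H = %.4g\n", nm, x[[nm]]$K, x[[nm]]$H))
  invisible(x)
}

#' Evaluate a switching model on a dose grid
#'
#' @param model a `switching_model`.
#' @param dox vector of dox levels.
#' @return Matrix with one row per dose and one column per Hill function.
#' @export
eval_switching <- function(model, dox) {
  stopifnot(inherits(model, "switching_model"))
  p <- sapply(model, function(hp) eval_hill(hp, dox)) |>
    matrix(nrow = length(dox), dimnames = list(NULL, names(model)))
  if (isTRUE(attr(model, "dependent")))
    p <- cbind(p1 = p[, "p1"], p2 = 1 - p[, "p1"])
  p
}

#' Switching probabilities at one dox level
#'
#' @param model a `switching_model`.
#' @param dox a single dox level.
#' @return A [step_probs3()] or [step_probs2()] object.  Errors if the
#'   3-state binding contingency is violated at this dose.
#' @export
switching_at <- function(model, dox) {
  stopifnot(inherits(model, "switching_model"), length(dox) == 1L)
  p <- eval_switching(model, dox)
  if (attr(model, "chain") == "three_state")
    step_probs3(p[1, "A1"], p[1, "A2"], p[1, "R1"], p[1, "R2"])
  else
    step_probs2(p[1, "p1"], p[1, "p2"])
}

## Binding-equilibrium curves used inside the objectives, vectorised over
## the dose grid.  Each transcription factor's bound-state probability
## "from the unbound state" is the 2-state steady state of its own
## binding/unbinding pair: P_Act = p_A1/(p_A1 + p_A2) and
## P_Rep = p_R1/(p_R1 + p_R2).  This is the quantity the single-factor
## dose-response experiments observe, and assuming the factors keep the
## same physical binding properties in the competing system it is what the
## estimation matches.  Frozen-chain convention: at a dose where a pair
## has no transitions at all (in this Hill family exactly dox = 0) the
## factor keeps its uninduced configuration — activator unbound
## (P_Act = 0), repressor bound (P_Rep = 1) — which matches the observed
## endpoints for every model, so the convention is equivalent to excluding
## dox = 0 from the fit.
.binding3 <- function(p) {
  cbind(P_Act = ifelse(p[, "A1"] + p[, "A2"] == 0, 0,
                       p[, "A1"] / (p[, "A1"] + p[, "A2"])),
        P_Rep = ifelse(p[, "R1"] + p[, "R2"] == 0, 1,
                       p[, "R1"] / (p[, "R1"] + p[, "R2"])))
}

.occupancy2 <- function(p) {
  tot <- p[, "p1"] + p[, "p2"]
  ifelse(tot == 0, 0, p[, "p1"] / tot)   # P_ON; frozen at OFF when tot = 0
}

## Stationary occupancies of the full 3-state chain (closed forms of
## steady_state_3state, vectorised, frozen uninduced state at dox = 0).
.chain_occupancy3 <- function(p, mode = "single_jump") {
  frozen <- p[, "A1"] + p[, "A2"] + p[, "R1"] + p[, "R2"] == 0
  if (mode == "single_jump") {
    rA <- ifelse(p[, "A1"] == 0, 0, p[, "A1"] / p[, "A2"])
    rR <- ifelse(p[, "R1"] == 0, 0, p[, "R1"] / p[, "R2"])
  } else {
    q <- 1 - p[, "A1"] * p[, "R1"]
    rA <- ifelse(p[, "A1"] == 0, 0,
                 p[, "A1"] * (1 + p[, "R1"]) / (p[, "A2"] * q))
    rR <- ifelse(p[, "R1"] == 0, 0,
                 p[, "R1"] * (1 + p[, "A1"]) / (p[, "R2"] * q))
  }
  z <- 1 + rA + rR
  cbind(pi_R = ifelse(frozen, 1, rR / z),
        pi_U = ifelse(frozen, 0, 1 / z),
        pi_A = ifelse(frozen, 0, rA / z))
}

#' Penalized objective for the 3-state model
#'
#' Sum over the dose grid of squared deviations of the factor binding
#' equilibria — `P_Act = p_A1/(p_A1 + p_A2)` and
#' `P_Rep = p_R1/(p_R1 + p_R2)`, the bound-state probabilities attained
#' from the unbound state — from the observed occupancy curves, plus a
#' penalty `C = 10000` added once if the binding contingency
#' `P_A1(d) + P_R1(d) < 1` fails at any grid dose (`C = 0` otherwise).
#'
#' @param model a 3-state `switching_model`.
#' @param curves an [observed_curves()] object.
#' @param penalty the contingency penalty (default 10000).
#' @return Nonnegative objective value.
#' @export
objective_3state <- function(model, curves, penalty = 10000) {
  stopifnot(inherits(model, "switching_model"),
            attr(model, "chain") == "three_state",
            inherits(curves, "observed_curves"))
  p <- eval_switching(model, curves$dox)
  occ <- .binding3(p)
  sse <- sum((occ[, "P_Act"] - curves$obs_act)^2 +
             (occ[, "P_Rep"] - curves$obs_rep)^2)
  C <- if (any(p[, "A1"] + p[, "R1"] >= 1)) penalty else 0
  sse + C
}

#' Objective for a 2-state model
#'
#' Sum of squared deviations of the stationary bound-state occupancy from
#' the corresponding observed occupancy curve; no contingency penalty.
#' For the activator chain the ON (activator-bound) occupancy is compared
#' with `obs_act`; for the repressor chain the OFF (repressor-bound)
#' occupancy is compared with `obs_rep`.
#'
#' @param model a 2-state `switching_model` (chain `"activator"` or
#'   `"repressor"`).
#' @param curves an [observed_curves()] object.
#' @return Nonnegative objective value.
#' @export
objective_2state <- function(model, curves) {
  stopifnot(inherits(model, "switching_model"),
            attr(model, "chain") %in% c("activator", "repressor"),
            inherits(curves, "observed_curves"))
  p <- eval_switching(model, curves$dox)
  p_on <- .occupancy2(p)
  if (attr(model, "chain") == "activator")
    sum((p_on - curves$obs_act)^2)
  else
    sum(((1 - p_on) - curves$obs_rep)^2)
}

## ---- seeded differential evolution (rand/1/bin) -------------------------
## No population-based global optimizer is available as a package in the
## build environment, so a compact DE is implemented here.  Box-bounded,
## deterministic given the seed, with a final L-BFGS-B polish.
.de_optimize <- function(fn, lower, upper, seed, budget,
                         np = 60L, f = 0.8, cr = 0.9, polish = TRUE) {
  d <- length(lower)
  set.seed(as.integer(seed))
  pop <- matrix(stats::runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  cost <- apply(pop, 1, fn)
  evals <- np
  gens <- max(0L, floor((budget - np) / np))
  for (g in seq_len(gens)) {
    for (i in seq_len(np)) {
      idx <- sample(seq_len(np)[-i], 3L)
      v <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      v <- pmin(pmax(v, lower), upper)
      jrand <- sample.int(d, 1L)
      cross <- stats::runif(d) < cr
      cross[jrand] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      tc <- fn(trial)
      if (tc <= cost[i]) { pop[i, ] <- trial; cost[i] <- tc }
    }
    evals <- evals + np
  }
  best <- which.min(cost)
  theta <- pop[best, ]; val <- cost[best]
  if (polish) {
    pol <- tryCatch(
      stats::optim(theta, fn, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(pol)) {
      evals <- evals + pol$counts[[1]]
      if (pol$value <= val) { theta <- pol$par; val <- pol$value }
    }
  }
  list(par = theta, value = val, evals = evals)
}

.theta_to_model <- function(theta, chain, dependent = FALSE) {
  nm <- if (chain == "three_state") c("A1", "A2", "R1", "R2")
        else if (dependent) "p1"
        else c("p1", "p2")
  hp <- lapply(seq_along(nm), function(i)
    hill(K = 10^theta[2 * i - 1], H = theta[2 * i]))
  names(hp) <- nm
  do.call(switching_model,
          c(hp, list(chain = chain, dependent = dependent)))
}

#' Estimate a switching model from observed curves
#'
#' Minimizes the penalized squared-deviation objective
#' ([objective_3state()] / [objective_2state()]) over the Hill parameters
#' of the switching probabilities with a seeded differential-evolution
#' search (box bounds `K` in `[1e-3, 1e2]` — searched as `log10 K` — and
#' `H` in `[0.1, 10]` per Hill function), followed by a local polish.
#' Results are reproducible bit-exactly for a fixed seed.
#'
#' Only the binding-equilibrium ratios enter the objective, so the
#' absolute switching-probability scale (how fast the telegraph flickers)
#' is not identified by steady-state dose-response data; the pure optimum
#' settles in the slow-switching regime, which is the regime producing
#' the all-or-none single-cell phenotypes.  Two documented knobs act on
#' this null direction: `speed > 0` adds a weak log-scale preference for
#' faster switching, `speed * mean(-log10(sum of probabilities))`, to the
#' search fitness (never to the reported `objective_value`); and for
#' 2-state chains `dependent = TRUE` fits the dependent parameterization
#' `p2 = 1 - p1` (so `P_ON = p1` exactly), whose one-step mixing yields
#' graded single-cell responses.
#'
#' @param curves an [observed_curves()] object.
#' @param chain one of [chain_kinds()].
#' @param seed integer optimizer seed.
#' @param budget number of objective evaluations for the global search
#'   (>= 1000).
#' @param penalty binding-contingency penalty (3-state only).
#' @param speed nonnegative speed-preference weight (default 0: pure
#'   objective).
#' @param dependent logical; for 2-state chains, constrain `p2 = 1 - p1`
#'   (2 free parameters instead of 4).
#' @return A fitted model of class `"mcm"` (see [mcm()]).
#' @export
estimate_switching <- function(curves, chain = "three_state", seed = 1L,
                               budget = 50000L, penalty = 10000,
                               speed = 0, dependent = FALSE) {
  stopifnot(inherits(curves, "observed_curves"))
  chain <- match.arg(chain, chain_kinds())
  if (budget < 1000L) stop("'budget' must be at least 1000 evaluations")
  stopifnot(is.numeric(speed), length(speed) == 1L, speed >= 0)
  if (dependent && chain == "three_state")
    stop("'dependent' applies only to 2-state chains")
  nfun <- if (chain == "three_state") 4L else if (dependent) 1L else 2L
  lower <- rep(c(-3, 0.1), nfun)
  upper <- rep(c(2, 10), nfun)
  obj <- if (chain == "three_state") {
    function(model) objective_3state(model, curves, penalty = penalty)
  } else {
    function(model) objective_2state(model, curves)
  }
  fn <- function(theta) {
    model <- .theta_to_model(theta, chain, dependent)
    val <- obj(model)
    if (speed > 0) {
      p <- eval_switching(model, curves$dox)
      val <- val + speed * mean(-log10(pmax(rowSums(p), 1e-12)))
    }
    val
  }
  res <- .de_optimize(fn, lower, upper, seed = seed, budget = budget)
  model <- .theta_to_model(res$par, chain, dependent)
  res$value <- obj(model)     # report the pure objective of the final model
  satisfied <- if (chain == "three_state") {
    p <- eval_switching(model, curves$dox)
    all(p[, "A1"] + p[, "R1"] < 1)
  } else TRUE
  if (chain == "three_state" && !satisfied)
    stop("no binding-contingency-satisfying model found within budget; ",
         "best penalized objective = ", format(res$value))
  structure(list(model = model, chain = chain,
                 objective_value = res$value,
                 constraint_satisfied = satisfied,
                 seed = as.integer(seed),
                 n_evaluations = res$evals,
                 curves = curves,
                 call = match.call()),
            class = "mcm")
}

#' Fit a Markov-chain model of gene induction by competing factors
#'
#' The central fitting function.  From the Hill parameters of the observed
#' activator-only and repressor-only dose-response curves it estimates the
#' dose-dependent switching probabilities of the requested promoter-state
#' chain, returning a fitted model object with the usual accessor methods
#' (`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#' `simulate`, `plot`).
#'
#' @param activator [hill()] parameters of the activator-only observed
#'   curve (reference: `H = 1.6`; `K` is configurable, default 0.6 ug/ml).
#' @param repressor [hill()] parameters of the repressor-only observed
#'   curve (reference: `H = 1.8`).
#' @param chain one of [chain_kinds()] (default the 3-state competing
#'   chain).
#' @param dox estimation dose grid (default [dose_grid()]: 0 plus 33
#'   log-spaced doses in `[0.01, 10]` ug/ml).
#' @param seed optimizer seed.
#' @param budget objective-evaluation budget for the global search.
#' @param ... further arguments passed to [estimate_switching()]
#'   (`speed`, `dependent`, `penalty`).
#' @return Object of class `"mcm"`.
#' @examples
#' \donttest{
#' fit <- mcm(hill(0.6, 1.6), hill(0.6, 1.8), chain = "activator",
#'            budget = 5000)
#' coef(fit)
#' }
#' @export
mcm <- function(activator = hill(0.6, 1.6), repressor = hill(0.6, 1.8),
                chain = "three_state", dox = dose_grid(), seed = 1L,
                budget = 50000L, ...) {
  curves <- observed_curves(activator, repressor, dox)
  out <- estimate_switching(curves, chain = chain, seed = seed,
                            budget = budget, ...)
  out$call <- match.call()
  out
}

#' @export
print.mcm <- function(x, ...) {
  cat(sprintf("Markov-chain gene-induction model (%s chain)\n", x$chain))
  print(x$model)
  cat(sprintf("objective = %.6g (%d evaluations, seed %d); contingency %s\n",
              x$objective_value, x$n_evaluations, x$seed,
              if (x$constraint_satisfied) "satisfied" else "VIOLATED"))
  invisible(x)
}

#' @export
coef.mcm <- function(object, ...) {
  t(vapply(object$model, function(hp) c(K = hp$K, H = hp$H), numeric(2)))
}

#' Predicted curves of a fitted switching model
#'
#' @param object a fitted `"mcm"` object.
#' @param dox dose grid (defaults to the estimation grid).
#' @param type `"binding"` (default) for the per-factor binding equilibria
#'   fitted during estimation (`P_Act`, `P_Rep`, or `P_ON`/`P_OFF` for
#'   2-state chains); `"occupancy"` for the stationary occupancies of the
#'   full chain (see `mode`); `"probabilities"` for the raw Hill-valued
#'   switching probabilities.
#' @param mode update mode for `type = "occupancy"` on the 3-state chain.
#' @param ... unused.
#' @return A data.frame indexed by `dox`.
#' @export
predict.mcm <- function(object, dox = object$curves$dox,
                        type = c("binding", "occupancy", "probabilities"),
                        mode = c("single_jump", "two_jump"), ...) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  p <- eval_switching(object$model, dox)
  if (type == "probabilities") return(data.frame(dox = dox, p))
  if (object$chain == "three_state") {
    if (type == "binding") data.frame(dox = dox, .binding3(p))
    else data.frame(dox = dox, .chain_occupancy3(p, mode))
  } else {
    p_on <- .occupancy2(p)
    data.frame(dox = dox, P_ON = p_on, P_OFF = 1 - p_on)
  }
}

#' @export
fitted.mcm <- function(object, ...) {
  pr <- predict(object)
  if (object$chain == "three_state")
    cbind(P_Act = pr$P_Act, P_Rep = pr$P_Rep)
  else if (object$chain == "activator") cbind(P_ON = pr$P_ON)
  else cbind(P_OFF = pr$P_OFF)
}

#' @export
residuals.mcm <- function(object, ...) {
  ft <- fitted(object)
  cv <- object$curves
  if (object$chain == "three_state")
    cbind(P_Act = ft[, "P_Act"] - cv$obs_act,
          P_Rep = ft[, "P_Rep"] - cv$obs_rep)
  else if (object$chain == "activator")
    cbind(P_ON = ft[, "P_ON"] - cv$obs_act)
  else
    cbind(P_OFF = ft[, "P_OFF"] - cv$obs_rep)
}

#' @export
summary.mcm <- function(object, ...) {
  r <- residuals(object)
  structure(list(chain = object$chain, coef = coef(object),
                 objective = object$objective_value,
                 max_abs_residual = apply(abs(r), 2, max),
                 constraint_satisfied = object$constraint_satisfied,
                 seed = object$seed,
                 n_evaluations = object$n_evaluations),
            class = "summary.mcm")
}

#' @export
print.summary.mcm <- function(x, ...) {
  cat(sprintf("Markov-chain gene-induction model (%s chain)\n", x$chain))
  print(round(x$coef, 4))
  cat(sprintf("objective = %.6g; max |occupancy residual|: %s\n",
              x$objective,
              paste(sprintf("%s %.4f", names(x$max_abs_residual),
                            x$max_abs_residual), collapse = ", ")))
  cat(sprintf("contingency %s; seed %d; %d evaluations\n",
              if (x$constraint_satisfied) "satisfied" else "VIOLATED",
              x$seed, x$n_evaluations))
  invisible(x)
}

#' Simulate populations from a fitted model
#'
#' @param object a fitted `"mcm"` object.
#' @param nsim number of cells per population (default `cfg$n_cells`).
#' @param seed integer seed.
#' @param dox dox level(s) at which to simulate.
#' @param cfg a [sim_config()].
#' @param ... unused.
#' @return A single `"population_sample"` (one dox) or a list of them.
#' @export
simulate.mcm <- function(object, nsim = cfg$n_cells, seed = cfg$seed,
                         dox = 0.6, cfg = sim_config(), ...) {
  cfg$n_cells <- as.integer(nsim)
  out <- lapply(seq_along(dox), function(i)
    simulate_population(object$chain, object$model, dox[i], cfg,
                        seed = seed + (i - 1L)))
  if (length(out) == 1L) out[[1]] else out
}

#' @export
plot.mcm <- function(x, ...) {
  cv <- x$curves
  pos <- cv$dox[cv$dox > 0]
  grid <- c(0, exp(seq(log(min(pos)), log(max(pos)), length.out = 200)))
  pr <- predict(x, dox = grid)
  if (x$chain == "three_state") {
    plot(cv$dox, cv$obs_act, col = "darkgreen", ylim = c(0, 1), log = "",
         xlab = "dox (ug/ml)", ylab = "occupancy", ...)
    graphics::points(cv$dox, cv$obs_rep, col = "red")
    graphics::lines(grid, pr$P_Act, col = "darkgreen")
    graphics::lines(grid, pr$P_Rep, col = "red")
    graphics::legend("right", c("activator-bound", "repressor-bound"),
                     col = c("darkgreen", "red"), lty = 1, bty = "n")
  } else {
    obs <- if (x$chain == "activator") cv$obs_act else cv$obs_rep
    fitcol <- if (x$chain == "activator") pr$P_ON else pr$P_OFF
    plot(cv$dox, obs, ylim = c(0, 1), xlab = "dox (ug/ml)",
         ylab = "occupancy", ...)
    graphics::lines(grid, fitcol)
  }
  invisible(x)
}
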