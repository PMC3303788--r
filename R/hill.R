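#' Hill-function parameters
#'
#' A gene-regulatory function (GRF) mapping an input concentration to a
#' promoter occupancy or switching probability is represented as the
#' two-parameter Hill function
#' \deqn{h(x) = \frac{x^H}{K^H + x^H}}
#' with fixed asymptotes 0 (at zero input) and 1 (at saturating input).
#' `K` is the effective concentration giving half-maximal output and `H`
#' the Hill coefficient (steepness / apparent cooperativity).
#'
#' @param K effective concentration (same units as the input, here ug/ml);
#'   must be > 0.
#' @param H Hill coefficient (dimensionless); must be > 0.
#' @return An object of class `"hill"`: a list with elements `K` and `H`.
#' @examples
#' hp <- hill(K = 0.6, H = 1.6)
#' eval_hill(hp, c(0, 0.6, 10))
#' @export
hill <- function(K, H) {
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K),
            is.numeric(H), length(H) == 1L, is.finite(H))
  if (K <= 0) stop("'K' must be > 0, got ", K)
  if (H <= 0) stop("'H' must be > 0, got ", H)
  structure(list(K = as.numeric(K), H = as.numeric(H)), class = "hill")
}

#' @export
print.hill <- function(x, ...) {
  cat(sprintf("Hill function: K = %g, H = %g\n", x$K, x$H))
  invisible(x)
}

#' Evaluate a Hill function
#'
#' @param params a [hill()] object.
#' @param x nonnegative concentration(s).
#' @return Numeric vector in `[0, 1]`, 0 at `x = 0`, 0.5 at `x = K`.
#' @export
eval_hill <- function(params, x) {
  stopifnot(inherits(params, "hill"), is.numeric(x))
  if (any(x < 0)) stop("concentration 'x' must be nonnegative")
  ## (x/K)^H form avoids overflow of x^H for large H and x
  r <- (x / params$K)^params$H
  r / (1 + r)
}

#' Fit a Hill function by nonlinear least squares
#'
#' Fits the two-parameter Hill curve `x^H / (K^H + x^H)` to responses
#' normalized to `[0, 1]`.  The lower and upper asymptotes are fixed at 0
#' and 1; normalization of raw means is done upstream (see
#' [run_dose_response()]).  Standard errors come from the local curvature
#' of the residual surface at the optimum (the usual nls linearization).
#'
#' The fit is deterministic: it starts from `K` = geometric mean of the
#' positive doses and `H = 1`, with box constraints
#' `1e-3 <= K <= 1e3`, `0.1 <= H <= 10`.
#'
#' @param doses nonnegative concentrations (>= 4 points, at least one > 0).
#' @param responses responses in `[0, 1]`, same length as `doses`.
#' @return An object of class `"hill_fit"`: list with `params` ([hill()]),
#'   `se_K`, `se_H`, `rss`, `n_points`, `fitted`, `residuals`, `doses`,
#'   `responses`.
#' @seealso [predict_hill()] which applies this to a simulated
#'   dose-response table.
#' @examples
#' d <- c(0, 10^seq(-2, 1, length.out = 12))
#' y <- eval_hill(hill(0.5, 3.2), d)
#' coef(fit_hill(d, y))
#' @export
fit_hill <- function(doses, responses) {
  stopifnot(is.numeric(doses), is.numeric(responses),
            length(doses) == length(responses))
  if (length(doses) < 4L) stop("need at least 4 points to fit a Hill curve")
  if (any(doses < 0)) stop("doses must be nonnegative")
  if (!any(doses > 0)) stop("need at least one positive dose")
  if (any(!is.finite(responses)))
    stop("responses must be finite")
  if (diff(range(responses)) == 0)
    stop("degenerate input: all responses are equal; ",
         "a Hill curve cannot be identified")

  start <- c(K = exp(mean(log(doses[doses > 0]))), H = 1)
  lower <- c(K = 1e-3, H = 0.1)
  upper <- c(K = 1e3,  H = 10)
  df <- data.frame(x = doses, y = responses)
  fit <- minpack.lm::nlsLM(
    y ~ (x / K)^H / (1 + (x / K)^H),
    data = df, start = start, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-15, ptol = 1e-15, maxiter = 500))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(K = NA_real_, H = NA_real_))
  res <- stats::residuals(fit)
  structure(list(
    params = hill(est[["K"]], est[["H"]]),
    se_K = unname(se[["K"]]),
    se_H = unname(se[["H"]]),
    rss = sum(res^2),
    n_points = length(doses),
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(res),
    doses = doses,
    responses = responses
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (n = %d): K = %.6g (SE %.3g), H = %.6g (SE %.3g)\n",
              x$n_points, x$params$K, x$se_K, x$params$H, x$se_H))
  cat(sprintf("  residual sum of squares: %.6g\n", x$rss))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(K = object$params$K, H = object$params$H)
}

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- cbind(Estimate = c(object$params$K, object$params$H),
               `Std. Error` = c(object$se_K, object$se_H))
  rownames(tab) <- c("K", "H")
  structure(list(coefficients = tab, rss = object$rss,
                 n_points = object$n_points), class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat("Hill-function fit\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("RSS %.6g on %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$doses
       else if (is.list(newdata)) newdata$x else newdata
  eval_hill(object$params, x)
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
plot.hill_fit <- function(x, n = 200, ...) {
  pos <- x$doses[x$doses > 0]
  grid <- c(0, exp(seq(log(min(pos)), log(max(pos)), length.out = n)))
  plot(x$doses, x$responses, xlab = "dose (ug/ml)",
       ylab = "normalized response", ...)
  graphics::lines(grid, eval_hill(x$params, grid))
  invisible(x)
}
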