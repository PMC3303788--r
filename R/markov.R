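## Promoter-state chains.
##
## States of the 3-state chain: "repressor_bound" (no transcription),
## "unbound" (basal transcription), "activator_bound" (full transcription).
## The activator and repressor compete for the same site ("binding
## contingency"): there is no direct jump repressor_bound <-> activator_bound,
## and from the unbound state the two binding events are mutually exclusive.
##
## 2-state chains are expressed transcriptionally as OFF/ON with switching
## probabilities p1 (OFF -> ON) and p2 (ON -> OFF); the activator-only chain
## has ON = activator_bound, the repressor-only chain has ON = unbound
## (repression is relieved when the repressor leaves).

#' Promoter states of the 3-state chain
#'
#' @return Character vector `c("repressor_bound", "unbound",
#'   "activator_bound")`, in the internal coding order.
#' @export
promoter_states <- function() c("repressor_bound", "unbound", "activator_bound")

#' Supported chain kinds
#'
#' `"activator"` and `"repressor"` are the 2-state single-factor chains;
#' `"three_state"` is the competing activator+repressor chain.
#'
#' @return Character vector of the three chain kinds.
#' @export
chain_kinds <- function() c("activator", "repressor", "three_state")

.check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("'", name, "' must be a single probability in [0, 1]")
  as.numeric(p)
}

#' Per-step switching probabilities of a 2-state chain
#'
#' @param p1 probability of switching OFF -> ON in one time step.
#' @param p2 probability of switching ON -> OFF in one time step.
#' @return Object of class `"step_probs2"`.
#' @export
step_probs2 <- function(p1, p2) {
  structure(list(p1 = .check_prob(p1, "p1"), p2 = .check_prob(p2, "p2")),
            class = "step_probs2")
}

#' Per-step switching probabilities of the 3-state chain
#'
#' The four transition probabilities of the competing-factor chain:
#' `p_A1` unbound -> activator_bound, `p_A2` activator_bound -> unbound,
#' `p_R1` unbound -> repressor_bound, `p_R2` repressor_bound -> unbound.
#' Binding contingency requires `p_A1 + p_R1 <= 1` (the two exits from the
#' unbound state are mutually exclusive).
#'
#' @param p_A1,p_A2,p_R1,p_R2 probabilities in `[0, 1]`.
#' @return Object of class `"step_probs3"`.
#' @export
step_probs3 <- function(p_A1, p_A2, p_R1, p_R2) {
  sp <- list(p_A1 = .check_prob(p_A1, "p_A1"), p_A2 = .check_prob(p_A2, "p_A2"),
             p_R1 = .check_prob(p_R1, "p_R1"), p_R2 = .check_prob(p_R2, "p_R2"))
  if (sp$p_A1 + sp$p_R1 > 1)
    stop("binding contingency violated: p_A1 + p_R1 = ",
         sp$p_A1 + sp$p_R1, " > 1")
  structure(sp, class = "step_probs3")
}

#' Stationary occupancy of the 2-state chain
#'
#' Analytical steady state of the telegraph chain:
#' `P_ON = p1 / (p1 + p2)`, `P_OFF = p2 / (p1 + p2)`.
#'
#' @param p1,p2 switching probabilities (OFF -> ON and ON -> OFF).
#' @return Named numeric vector `c(P_OFF, P_ON)` summing to 1.
#' @export
steady_state_2state <- function(p1, p2) {
  p1 <- .check_prob(p1, "p1"); p2 <- .check_prob(p2, "p2")
  if (p1 + p2 == 0)
    stop("degenerate chain: p1 = p2 = 0 has no unique stationary distribution")
  c(P_OFF = p2 / (p1 + p2), P_ON = p1 / (p1 + p2))
}

#' Stationary occupancy of the 3-state chain
#'
#' In `"single_jump"` mode at most one transition occurs per time step and
#' the stationary law has the closed form
#' `pi_A = (p_A1/p_A2)/Z`, `pi_R = (p_R1/p_R2)/Z`, `pi_U = 1/Z` with
#' `Z = 1 + p_A1/p_A2 + p_R1/p_R2`: the bound-state odds against the unbound
#' state are the binding/unbinding probability ratios.  In `"two_jump"` mode
#' (the simulator's default update, see [step_3state()]) a cell leaving a
#' bound state may continue to the opposite bound state within the same step;
#' the stationary law of the composite kernel is computed from its closed
#' form, `pi_A/pi_U = p_A1 (1 + p_R1) / (p_A2 (1 - p_A1 p_R1))` and
#' symmetrically for `pi_R/pi_U` (agreeing with power iteration of the
#' composite matrix to better than 1e-12, including chains with
#' vanishingly small switching probabilities where iteration would not
#' converge).
#'
#' @param sp a [step_probs3()] object; `p_A2` and `p_R2` must be positive.
#' @param mode `"single_jump"` or `"two_jump"`.
#' @return Named numeric vector `c(pi_R, pi_U, pi_A)` summing to 1.
#' @export
steady_state_3state <- function(sp, mode = c("single_jump", "two_jump")) {
  stopifnot(inherits(sp, "step_probs3"))
  mode <- match.arg(mode)
  if (sp$p_A2 <= 0 || sp$p_R2 <= 0)
    stop("degenerate chain: p_A2 and p_R2 must be positive ",
         "(a bound state would be absorbing)")
  if (mode == "single_jump") {
    rA <- sp$p_A1 / sp$p_A2
    rR <- sp$p_R1 / sp$p_R2
  } else {
    ## balance equations of the composite kernel, solved for the odds
    ## against the unbound state; p_A1 p_R1 < 1 always holds under the
    ## binding contingency
    q <- 1 - sp$p_A1 * sp$p_R1
    rA <- sp$p_A1 * (1 + sp$p_R1) / (sp$p_A2 * q)
    rR <- sp$p_R1 * (1 + sp$p_A1) / (sp$p_R2 * q)
  }
  z <- 1 + rA + rR
  c(pi_R = rR / z, pi_U = 1 / z, pi_A = rA / z)
}

#' One-step transition matrix of the 3-state chain
#'
#' Rows/columns are ordered `repressor_bound`, `unbound`, `activator_bound`.
#' In two-jump mode the matrix is the composite per-step kernel: a cell
#' leaving `activator_bound` (prob `p_A2`) continues to `repressor_bound`
#' within the same step with prob `p_R1`, and symmetrically from
#' `repressor_bound`; exits from `unbound` are a single partitioned draw.
#'
#' @param sp a [step_probs3()] object.
#' @param mode `"single_jump"` or `"two_jump"`.
#' @return A 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(sp, mode = c("single_jump", "two_jump")) {
  stopifnot(inherits(sp, "step_probs3"))
  mode <- match.arg(mode)
  s <- promoter_states()
  M <- matrix(0, 3, 3, dimnames = list(s, s))
  if (mode == "single_jump") {
    M["unbound", ] <- c(sp$p_R1, 1 - sp$p_A1 - sp$p_R1, sp$p_A1)
    M["activator_bound", ] <- c(0, sp$p_A2, 1 - sp$p_A2)
    M["repressor_bound", ] <- c(1 - sp$p_R2, sp$p_R2, 0)
  } else {
    M["unbound", ] <- c(sp$p_R1, 1 - sp$p_A1 - sp$p_R1, sp$p_A1)
    M["activator_bound", ] <- c(sp$p_A2 * sp$p_R1,
                                sp$p_A2 * (1 - sp$p_R1),
                                1 - sp$p_A2)
    M["repressor_bound", ] <- c(1 - sp$p_R2,
                                sp$p_R2 * (1 - sp$p_A1),
                                sp$p_R2 * sp$p_A1)
  }
  M
}


#' Advance a 2-state chain by one step
#'
#' Switching occurs iff the uniform draw `r` is strictly below the relevant
#' switching probability, so `p = 0` means never and `p = 1` means always.
#'
#' @param state `"off"` or `"on"`.
#' @param sp a [step_probs2()] object.
#' @param r uniform draw in `[0, 1)`; defaults to a fresh `runif(1)`.
#' @return The new state.
#' @export
step_2state <- function(state, sp, r = stats::runif(1)) {
  stopifnot(inherits(sp, "step_probs2"))
  state <- match.arg(state, c("off", "on"))
  if (state == "off") {
    if (r < sp$p1) "on" else "off"
  } else {
    if (r < sp$p2) "off" else "on"
  }
}

#' Advance the 3-state chain by one step
#'
#' In the default `"two_jump"` mode the per-step update allows two successive
#' jumps through the unbound state: from `activator_bound`, the cell moves to
#' `unbound` with prob `p_A2` and, having done so, continues to
#' `repressor_bound` with prob `p_R1` within the same step (symmetrically
#' from `repressor_bound`).  This avoids over-occupancy of the transient
#' unbound state.  From `unbound`, a single partitioned draw is used:
#' `r1 < p_A1` binds the activator, `p_A1 <= r1 < p_A1 + p_R1` binds the
#' repressor, otherwise the state is unchanged — the two binding events are
#' mutually exclusive, which is well defined because `p_A1 + p_R1 <= 1`.
#' `"single_jump"` mode drops the within-step continuation.
#'
#' @param state one of [promoter_states()].
#' @param sp a [step_probs3()] object.
#' @param r1 uniform draw for the first (or only) jump.
#' @param r2 uniform draw for the within-step continuation (two-jump mode).
#' @param mode `"two_jump"` (default) or `"single_jump"`.
#' @return The new state.
#' @export
step_3state <- function(state, sp, r1 = stats::runif(1),
                        r2 = stats::runif(1),
                        mode = c("two_jump", "single_jump")) {
  stopifnot(inherits(sp, "step_probs3"))
  mode <- match.arg(mode)
  state <- match.arg(state, promoter_states())
  two <- mode == "two_jump"
  switch(state,
    unbound = {
      if (r1 < sp$p_A1) "activator_bound"
      else if (r1 < sp$p_A1 + sp$p_R1) "repressor_bound"
      else "unbound"
    },
    activator_bound = {
      if (r1 < sp$p_A2) {
        if (two && r2 < sp$p_R1) "repressor_bound" else "unbound"
      } else "activator_bound"
    },
    repressor_bound = {
      if (r1 < sp$p_R2) {
        if (two && r2 < sp$p_A1) "activator_bound" else "unbound"
      } else "repressor_bound"
    })
}
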