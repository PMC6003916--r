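#' State values of a policy
#'
#' A `state_values` object holds the pair (v(prosperous), v(degraded)) of
#' normalized discounted values of the two states under a policy. Values use
#' the normalized discounted sum (prefactor `1 - gamma`), so they live on the
#' reward scale and compare directly with `r_min`.
#'
#' @param v_p,v_d Values of the prosperous and degraded state.
#' @param policy Policy name.
#' @param method Computation route (`"closed"`, `"linear"`, `"stationary"`).
#' @param degenerate TRUE if a vanishing denominator was resolved by its
#'   limiting value (e.g. `gamma = 1` with `delta = rho = 0`).
#' @return An object of class `state_values`.
#' @keywords internal
state_values <- function(v_p, v_d, policy, method, degenerate = FALSE) {
  structure(list(v_p = v_p, v_d = v_d, policy = policy,
                 method = method, degenerate = degenerate),
            class = "state_values")
}

#' @export
print.state_values <- function(x, ...) {
  cat(sprintf("State values under the %s policy (%s):\n", x$policy, x$method))
  cat(sprintf("  v(prosperous) = %.10g\n  v(degraded)   = %.10g\n",
              x$v_p, x$v_d))
  if (isTRUE(x$degenerate))
    cat("  (degenerate denominator resolved by its limit)\n")
  invisible(x)
}

#' Effective Markov chain of a policy
#'
#' Substituting the policy's action into the transition tables leaves a plain
#' two-state Markov chain. `effective_chain()` returns its transition matrix
#' `P` (rows = from-state, so every row sums to 1), the expected one-step
#' reward per state `r_vec`, and the stationary distribution `sigma`
#' (the normalized left eigenvector of `P` with eigenvalue one). When the
#' chain is reducible (an absorbing state exists, e.g. under a trap policy or
#' with `rho = 0`), `sigma` is the stationary distribution of the recurrent
#' class reachable from the prosperous state, and `reducible` is flagged.
#'
#' @param policy A policy object or name.
#' @param model A [tipping_model()].
#' @return A list with `P`, `r_vec`, `sigma`, `reducible`.
#' @examples
#' ch <- effective_chain("risky", tipping_model(0.2, 0.2, 0.9, r_l = 0.5))
#' ch$sigma  # (0.5, 0.5): symmetric collapse and recovery rates
#' @export
effective_chain <- function(policy, model) {
  policy <- as_policy(policy)
  stopifnot(is_tipping_model(model))
  tm <- transition_model(model)
  s <- mdp_states()
  P <- rbind(tm$prob[s[1], policy$mapping[[s[1]]], ],
             tm$prob[s[2], policy$mapping[[s[2]]], ])
  dimnames(P) <- list(from = s, to = s)
  r_vec <- c(
    sum(tm$prob[s[1], policy$mapping[[s[1]]], ] *
        tm$reward[s[1], policy$mapping[[s[1]]], ]),
    sum(tm$prob[s[2], policy$mapping[[s[2]]], ] *
        tm$reward[s[2], policy$mapping[[s[2]]], ])
  )
  names(r_vec) <- s
  # two-state chain: off-diagonal rates determine the stationary state
  a <- P[1, 2]  # prosperous -> degraded
  b <- P[2, 1]  # degraded -> prosperous
  reducible <- (a == 0 || b == 0)
  if (a + b > 0) {
    sigma <- c(b, a) / (a + b)
  } else {
    # both states absorbing; recurrent class reachable from prosperous is {p}
    sigma <- c(1, 0)
  }
  names(sigma) <- s
  list(P = P, r_vec = r_vec, sigma = sigma, reducible = reducible)
}

#' Policy evaluation by linear solve
#'
#' Solves the Bellman consistency equations for the normalized discounted
#' value exactly: `v = (1 - gamma) r + gamma P v`, i.e.
#' `(I - gamma P) v = (1 - gamma) r`, a 2 x 2 linear system. Works for all
#' four deterministic policies and serves as the independent check of the
#' closed-form expressions in [value_risky()] and [value_cautious()].
#'
#' @inheritParams effective_chain
#' @return A `state_values` object.
#' @examples
#' evaluate_policy_linear("cautious", tipping_model(0.3, 0.2, 0.9, r_l = 0.5))
#' @export
evaluate_policy_linear <- function(policy, model) {
  policy <- as_policy(policy)
  stopifnot(is_tipping_model(model))
  if (model$gamma >= 1)
    stop("evaluate_policy_linear() requires gamma < 1; use value_gamma1()",
         call. = FALSE)
  ch <- effective_chain(policy, model)
  v <- solve(diag(2) - model$gamma * ch$P, (1 - model$gamma) * ch$r_vec)
  state_values(v[[1]], v[[2]], policy$name, "linear")
}

#' Closed-form values of the risky policy
#'
#' The risky policy (high pressure when prosperous, low when degraded) has
#' the explicit normalized values
#' \deqn{v(p) = r_h (1-\delta)(1-(1-\rho)\gamma) / (1-(1-\delta-\rho)\gamma)}
#' \deqn{v(d) = r_h (1-\delta)\rho\gamma / (1-(1-\delta-\rho)\gamma).}
#' The formulas stay finite at `gamma = 1` whenever `delta + rho > 0`; at
#' the single degenerate point `gamma = 1`, `delta = rho = 0` the
#' `delta -> 0` limit `(v_p, v_d) = (r_h, 0)` is returned and flagged.
#'
#' @param model A [tipping_model()].
#' @return A `state_values` object.
#' @examples
#' value_risky(tipping_model(0.2, 0.2, 0.9, r_l = 0.5))  # v_p ~ 0.487
#' @export
value_risky <- function(model) {
  stopifnot(is_tipping_model(model))
  d <- model$delta; rho <- model$rho; g <- model$gamma; rh <- model$r_h
  denom <- 1 - (1 - d - rho) * g
  if (denom == 0)  # gamma = 1 and delta + rho = 0
    return(state_values(rh, 0, "risky", "closed", degenerate = TRUE))
  state_values(
    v_p = rh * (1 - d) * (1 - (1 - rho) * g) / denom,
    v_d = rh * (1 - d) * rho * g / denom,
    policy = "risky", method = "closed"
  )
}

#' Closed-form values of the cautious policy
#'
#' The cautious policy (low pressure in both states) keeps the prosperous
#' state forever, so `v(p) = r_l` identically; from the degraded state
#' \deqn{v(d) = \rho\gamma r_l / (1-(1-\rho)\gamma).}
#' At the degenerate point `gamma = 1`, `rho = 0` the `rho -> 0` limit
#' `v(d) = 0` is returned and flagged.
#'
#' @param model A [tipping_model()].
#' @return A `state_values` object.
#' @examples
#' value_cautious(tipping_model(0.2, 0.2, 0.9, r_l = 1))$v_d  # 0.18/0.28
#' @export
value_cautious <- function(model) {
  stopifnot(is_tipping_model(model))
  rho <- model$rho; g <- model$gamma; rl <- model$r_l
  denom <- 1 - (1 - rho) * g
  if (denom == 0)  # gamma = 1 and rho = 0
    return(state_values(rl, 0, "cautious", "closed", degenerate = TRUE))
  state_values(rl, rho * g * rl / denom, "cautious", "closed")
}

#' Undiscounted (gamma = 1) value via the stationary distribution
#'
#' For an absolutely farsighted agent the normalized value is the long-run
#' average reward, independent of the initial state: the stationary
#' distribution of the effective chain dotted with the expected one-step
#' reward vector. For reducible chains the stationary distribution of the
#' recurrent class reachable from the prosperous state is used (so a trap
#' policy with `delta > 0` scores 0: the agent is absorbed in the degraded
#' state and never rewarded again).
#'
#' @inheritParams effective_chain
#' @return A `state_values` object with `v_p == v_d`.
#' @examples
#' value_gamma1("risky", tipping_model(0.2, 0.2, 1, r_l = 0.5))  # 0.4
#' @export
value_gamma1 <- function(policy, model) {
  policy <- as_policy(policy)
  stopifnot(is_tipping_model(model))
  ch <- effective_chain(policy, model)
  v <- sum(ch$sigma * ch$r_vec)
  state_values(v, v, policy$name, "stationary", degenerate = ch$reducible)
}

#' Value of any deterministic policy
#'
#' Convenience dispatcher: closed forms for the risky and cautious policies
#' (valid for all `gamma` in `[0, 1]`), the linear Bellman solve for the two
#' trap policies when `gamma < 1`, and the stationary-distribution route at
#' `gamma = 1`.
#'
#' @inheritParams effective_chain
#' @return A `state_values` object.
#' @export
policy_value <- function(policy, model) {
  policy <- as_policy(policy)
  if (policy$name == "risky") return(value_risky(model))
  if (policy$name == "cautious") return(value_cautious(model))
  if (model$gamma < 1) evaluate_policy_linear(policy, model)
  else value_gamma1(policy, model)
}

# Vectorized closed-form values over parameter vectors (r_h fixed per call).
# Returns the four value vectors with degenerate denominators resolved by
# their limits, so parameter sweeps never abort on measure-zero points.
values_closed_vec <- function(delta, rho, gamma, r_l, r_h = 1) {
  denom_r <- 1 - (1 - delta - rho) * gamma
  denom_c <- 1 - (1 - rho) * gamma
  vr_p <- r_h * (1 - delta) * denom_c / denom_r
  vr_d <- r_h * (1 - delta) * rho * gamma / denom_r
  vc_d <- rho * gamma * r_l / denom_c
  bad_r <- denom_r == 0           # gamma = 1, delta + rho = 0
  if (any(bad_r)) { vr_p[bad_r] <- r_h; vr_d[bad_r] <- 0 }
  bad_c <- denom_c == 0           # gamma = 1, rho = 0
  if (any(bad_c)) vc_d[bad_c] <- 0
  list(vr_p = vr_p, vr_d = vr_d, vc_p = r_l + 0 * delta, vc_d = vc_d)
}
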