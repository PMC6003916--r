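#' Construct a tipping-element model
#'
#' Defines the six-parameter stylized model of a human-environment tipping
#' element. The environment is either `prosperous` or `degraded`; a decision
#' maker exerts `high` or `low` pressure each (yearly) time step. Under high
#' pressure in the prosperous state the agent earns `r_h` but risks collapse
#' with probability `delta`; under low pressure it earns `r_l` with no
#' collapse risk. From the degraded state (no reward) only low pressure opens
#' recovery, with probability `rho` per step.
#'
#' Policy classification depends on the rewards only through the ratios
#' `r_l / r_h` and `r_min / r_h`, so `r_h = 1` is a convenient normalization.
#'
#' @param delta Collapse probability per time step under high pressure, in
#'   `[0, 1]`.
#' @param rho Recovery probability per time step under low pressure, in
#'   `[0, 1]`.
#' @param gamma Discount factor in `[0, 1]`; `gamma = 1` means absolute
#'   farsightedness (no discounting), `gamma = 0` a fully myopic agent.
#' @param r_l Reward of the low-pressure action in the prosperous state
#'   (arbitrary reward units, >= 0).
#' @param r_h Reward of the high-pressure action in the prosperous state
#'   (>= 0); defaults to 1.
#' @param r_min Normative minimum acceptable state value (>= 0); defaults
#'   to 0, under which every state is acceptable.
#' @return An object of class `tipping_model`: a named list with the six
#'   parameters.
#' @examples
#' m <- tipping_model(delta = 0.2, rho = 0.2, gamma = 0.9, r_l = 0.5)
#' value_risky(m)
#' @export
tipping_model <- function(delta, rho, gamma, r_l, r_h = 1, r_min = 0) {
  for (nm in c("delta", "rho", "gamma", "r_l", "r_h", "r_min")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  for (nm in c("delta", "rho", "gamma")) {
    x <- get(nm)
    if (x < 0 || x > 1)
      stop(sprintf("'%s' must lie in [0, 1], got %g", nm, x), call. = FALSE)
  }
  for (nm in c("r_l", "r_h", "r_min")) {
    x <- get(nm)
    if (x < 0)
      stop(sprintf("'%s' must be non-negative, got %g", nm, x), call. = FALSE)
  }
  structure(
    list(delta = delta, rho = rho, gamma = gamma,
         r_l = r_l, r_h = r_h, r_min = r_min),
    class = "tipping_model"
  )
}

#' @export
print.tipping_model <- function(x, ...) {
  cat("Tipping-element model (1 time step = 1 year)\n")
  cat(sprintf("  collapse probability  delta = %g\n", x$delta))
  cat(sprintf("  recovery probability  rho   = %g\n", x$rho))
  cat(sprintf("  discount factor       gamma = %g\n", x$gamma))
  cat(sprintf("  rewards r_h = %g, r_l = %g (r_l/r_h = %s)\n",
              x$r_h, x$r_l,
              if (x$r_h > 0) format(x$r_l / x$r_h) else "NA"))
  cat(sprintf("  acceptability threshold r_min = %g\n", x$r_min))
  invisible(x)
}

is_tipping_model <- function(x) inherits(x, "tipping_model")

#' Model states and actions
#'
#' The state space is `c("prosperous", "degraded")`; the action space is
#' `c("high", "low")`. The safe operating space is the singleton
#' `{prosperous}`.
#'
#' @name state_space
#' @export
mdp_states <- function() c("prosperous", "degraded")

#' @rdname state_space
#' @export
mdp_actions <- function() c("high", "low")

#' Deterministic policies
#'
#' A policy maps each state to an action. With two states and two actions
#' there are exactly four deterministic policies:
#' \describe{
#'   \item{risky}{high pressure when prosperous, low when degraded}
#'   \item{cautious}{low pressure in both states}
#'   \item{trap_hh}{high pressure in both states; once degraded, stays
#'     degraded forever}
#'   \item{trap_lh}{low pressure when prosperous, high when degraded; also
#'     traps the agent in the degraded state}
#' }
#' The two trap policies are (weakly) dominated by the risky and cautious
#' policies, so optimality can be decided between risky and cautious.
#'
#' @param name One of `"risky"`, `"cautious"`, `"trap_hh"`, `"trap_lh"`.
#' @return An object of class `mdp_policy` with fields `name` and `mapping`
#'   (named character vector state -> action).
#' @examples
#' policy("risky")$mapping
#' @export
policy <- function(name = c("risky", "cautious", "trap_hh", "trap_lh")) {
  name <- match.arg(name)
  mapping <- switch(name,
    risky    = c(prosperous = "high", degraded = "low"),
    cautious = c(prosperous = "low",  degraded = "low"),
    trap_hh  = c(prosperous = "high", degraded = "high"),
    trap_lh  = c(prosperous = "low",  degraded = "high")
  )
  structure(list(name = name, mapping = mapping), class = "mdp_policy")
}

#' @rdname policy
#' @export
policies <- function() {
  nms <- c("risky", "cautious", "trap_hh", "trap_lh")
  stats::setNames(lapply(nms, policy), nms)
}

#' @export
print.mdp_policy <- function(x, ...) {
  cat(sprintf("Policy '%s': prosperous -> %s, degraded -> %s\n",
              x$name, x$mapping[["prosperous"]], x$mapping[["degraded"]]))
  invisible(x)
}

as_policy <- function(x) {
  if (inherits(x, "mdp_policy")) return(x)
  if (is.character(x) && length(x) == 1L) return(policy(x))
  stop("expected a policy object or a policy name", call. = FALSE)
}

#' Transition probabilities and rewards
#'
#' Assembles the fixed transition structure of the model as probability and
#' reward tables indexed by (state, action, next state):
#' high pressure at prosperous stays prosperous with probability
#' `1 - delta` (reward `r_h`) and collapses with probability `delta`
#' (reward 0); low pressure at prosperous stays put with certainty (reward
#' `r_l`); low pressure at degraded recovers with probability `rho`; high
#' pressure at degraded stays degraded with certainty. All transitions out
#' of the degraded state pay zero reward.
#'
#' @param model A [tipping_model()].
#' @return A list with 2 x 2 x 2 arrays `prob` and `reward`, dimensions
#'   named (state, action, next).
#' @examples
#' tm <- transition_model(tipping_model(0.1, 0.2, 0.9, r_l = 0.5))
#' apply(tm$prob, c(1, 2), sum)  # rows sum to one for every (state, action)
#' @export
transition_model <- function(model) {
  stopifnot(is_tipping_model(model))
  s <- mdp_states(); a <- mdp_actions()
  dn <- list(state = s, action = a, next_state = s)
  p <- array(0, dim = c(2, 2, 2), dimnames = dn)
  r <- array(0, dim = c(2, 2, 2), dimnames = dn)
  p["prosperous", "high", "prosperous"] <- 1 - model$delta
  p["prosperous", "high", "degraded"]   <- model$delta
  p["prosperous", "low",  "prosperous"] <- 1
  p["degraded",   "low",  "prosperous"] <- model$rho
  p["degraded",   "low",  "degraded"]   <- 1 - model$rho
  p["degraded",   "high", "degraded"]   <- 1
  r["prosperous", "high", "prosperous"] <- model$r_h
  r["prosperous", "low",  "prosperous"] <- model$r_l
  list(prob = p, reward = r)
}
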