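#' Paradigm labels
#'
#' A paradigm label is the boolean triple (optimal, sustainable, safe); the
#' eight combinations are encoded as a stable 3-letter code with one position
#' per paradigm: `O` (optimal), `S` (sustainable), `F` (saFe), with `-` for a
#' paradigm that does not hold. Example: `"O--"` is optimal but neither
#' sustainable nor safe; `"OSF"` is the sweet spot where all three paradigms
#' agree.
#'
#' @param optimal,sustainable,safe Logical vectors (recycled).
#' @return `paradigm_code()` returns a character vector of 3-letter codes;
#'   `paradigm_codes()` the eight codes in canonical order;
#'   `decode_paradigm()` a data frame with the three logical columns.
#' @examples
#' paradigm_code(TRUE, FALSE, FALSE)
#' paradigm_codes()
#' @export
paradigm_code <- function(optimal, sustainable, safe) {
  paste0(ifelse(optimal, "O", "-"),
         ifelse(sustainable, "S", "-"),
         ifelse(safe, "F", "-"))
}

#' @rdname paradigm_code
#' @export
paradigm_codes <- function() {
  c("OSF", "OS-", "O-F", "O--", "-SF", "-S-", "--F", "---")
}

#' @rdname paradigm_code
#' @param code Character vector of 3-letter codes.
#' @export
decode_paradigm <- function(code) {
  stopifnot(all(nchar(code) == 3L))
  data.frame(
    code = code,
    optimal = substr(code, 1, 1) == "O",
    sustainable = substr(code, 2, 2) == "S",
    safe = substr(code, 3, 3) == "F"
  )
}

#' Economic welfare optimality
#'
#' A policy is optimal if its value in every state is at least the value of
#' any other policy in that state. Because the two trap policies (high
#' pressure at the degraded state) are weakly dominated, optimality is
#' decided between the risky and the cautious policy; the comparison uses the
#' closed-form values and is non-strict, so both policies are optimal exactly
#' on the boundary surface where their values coincide. The verdict is
#' independent of the state in which the values are compared.
#'
#' @param policy `"risky"` or `"cautious"` (or the policy object).
#' @param model A [tipping_model()].
#' @return Logical.
#' @examples
#' m <- tipping_model(0.3, 0.2, 0.9, r_l = 0.5)
#' is_optimal("cautious", m)  # collapse too likely for the risky policy
#' @export
is_optimal <- function(policy, model) {
  policy <- as_policy(policy)
  if (!policy$name %in% c("risky", "cautious"))
    stop("optimality is classified for the risky and cautious policies",
         call. = FALSE)
  vr <- value_risky(model)
  vc <- value_cautious(model)
  if (policy$name == "risky") vr$v_p >= vc$v_p && vr$v_d >= vc$v_d
  else vc$v_p >= vr$v_p && vc$v_d >= vr$v_d
}

#' State acceptability
#'
#' A state is acceptable under a policy if its value meets the normative
#' threshold: `v(state) >= r_min` (non-strict, so the boundary itself is
#' acceptable).
#'
#' @inheritParams is_optimal
#' @param state `"prosperous"` or `"degraded"`.
#' @return Logical.
#' @export
is_acceptable <- function(policy, model,
                          state = c("prosperous", "degraded")) {
  state <- match.arg(state)
  v <- policy_value(policy, model)
  (if (state == "prosperous") v$v_p else v$v_d) >= model$r_min
}

#' Sustainability
#'
#' A policy is sustainable if every state the agent eventually visits under
#' it is acceptable. The risky policy recurrently visits both states, so it
#' is sustainable only if both the prosperous and the degraded state are
#' acceptable; the cautious policy eventually settles in the prosperous
#' state, so it is sustainable exactly when the prosperous state is
#' acceptable, i.e. `r_l >= r_min`.
#'
#' @inheritParams is_optimal
#' @return Logical.
#' @export
is_sustainable <- function(policy, model) {
  policy <- as_policy(policy)
  if (!policy$name %in% c("risky", "cautious"))
    stop("sustainability is classified for the risky and cautious policies",
         call. = FALSE)
  if (policy$name == "risky")
    is_acceptable(policy, model, "prosperous") &&
      is_acceptable(policy, model, "degraded")
  else
    is_acceptable(policy, model, "prosperous")
}

#' Safe operating space membership
#'
#' The safe operating space is taken as the prosperous state only, with no
#' risk tolerance. The cautious policy never leaves it, so it is safe for
#' every parameter combination; the risky policy accepts a collapse risk, so
#' it is never safe — including at `delta = 0`, by convention (the blanket
#' rule; [reachability_safe()] provides the reachability-based cross-check
#' that differs only on that measure-zero boundary).
#'
#' @inheritParams is_optimal
#' @return Logical.
#' @export
is_safe <- function(policy, model) {
  policy <- as_policy(policy)
  if (!policy$name %in% c("risky", "cautious"))
    stop("safety is classified for the risky and cautious policies",
         call. = FALSE)
  policy$name == "cautious"
}

#' Reachability-based safety cross-check
#'
#' Declares a policy safe iff every state reachable (with positive
#' probability) from the prosperous state under its effective chain lies in
#' the safe operating space. Agrees with [is_safe()] whenever `delta > 0`;
#' at `delta = 0` the risky policy never actually leaves the prosperous
#' state and this check returns TRUE where the conventional rule says FALSE.
#'
#' @inheritParams is_optimal
#' @return Logical.
#' @export
reachability_safe <- function(policy, model) {
  ch <- effective_chain(policy, model)
  ch$P["prosperous", "degraded"] == 0
}

#' Classify a policy under the three paradigms
#'
#' Evaluates optimality, sustainability and safety and returns the combined
#' label.
#'
#' @inheritParams is_optimal
#' @return An object of class `paradigm_label`: a list with logical fields
#'   `optimal`, `sustainable`, `safe`, the 3-letter `code`, and the policy
#'   name.
#' @examples
#' classify_policy("cautious",
#'                 tipping_model(0.3, 0.2, 0.9, r_l = 0.5, r_min = 0.3))
#' @export
classify_policy <- function(policy, model) {
  policy <- as_policy(policy)
  opt <- is_optimal(policy, model)
  sus <- is_sustainable(policy, model)
  saf <- is_safe(policy, model)
  structure(
    list(policy = policy$name, optimal = opt, sustainable = sus, safe = saf,
         code = paradigm_code(opt, sus, saf)),
    class = "paradigm_label"
  )
}

#' @export
print.paradigm_label <- function(x, ...) {
  cat(sprintf("%s policy: %s  (optimal: %s, sustainable: %s, safe: %s)\n",
              x$policy, x$code, x$optimal, x$sustainable, x$safe))
  invisible(x)
}

#' Signed residuals of the classification boundary surfaces
#'
#' Each regime boundary is an implicit hypersurface in the five-parameter
#' space; the residual is the difference of its two sides, positive exactly
#' where the corresponding predicate holds and zero on the surface:
#' \describe{
#'   \item{optimality}{`r_h (1-delta)(1-gamma(1-rho)) - r_l (1-gamma(1-delta-rho))`;
#'     positive where the risky policy is optimal.}
#'   \item{risky_acceptable_p}{same left side against
#'     `r_min (1-gamma(1-delta-rho))`; positive where the prosperous state is
#'     acceptable under the risky policy.}
#'   \item{risky_acceptable_d}{`r_h (1-delta) rho gamma - r_min (1-gamma(1-delta-rho))`.}
#'   \item{cautious_acceptable_p}{`r_l - r_min`.}
#'   \item{cautious_acceptable_d}{`r_l rho gamma - r_min (1-gamma(1-rho))`.}
#' }
#'
#' @param kind One of the five boundary kinds above.
#' @param model A [tipping_model()].
#' @return A signed scalar.
#' @examples
#' m <- tipping_model(0, 0.2, 0.5, r_l = 0.5)
#' boundary_residual("optimality", m) > 0  # no collapse risk: risky optimal
#' @export
boundary_residual <- function(kind = c("optimality",
                                       "risky_acceptable_p",
                                       "risky_acceptable_d",
                                       "cautious_acceptable_p",
                                       "cautious_acceptable_d"),
                              model) {
  kind <- match.arg(kind)
  d <- model$delta; rho <- model$rho; g <- model$gamma
  rh <- model$r_h; rl <- model$r_l; rmin <- model$r_min
  switch(kind,
    optimality =
      rh * (1 - d) * (1 - g * (1 - rho)) - rl * (1 - g * (1 - d - rho)),
    risky_acceptable_p =
      rh * (1 - d) * (1 - g * (1 - rho)) - rmin * (1 - g * (1 - d - rho)),
    risky_acceptable_d =
      rh * (1 - d) * rho * g - rmin * (1 - g * (1 - d - rho)),
    cautious_acceptable_p = rl - rmin,
    cautious_acceptable_d = rl * rho * g - rmin * (1 - g * (1 - rho))
  )
}

#' Locate a boundary by bisection
#'
#' Finds the root of a boundary residual along one model parameter, holding
#' the others fixed. Residuals are continuous and monotone in each single
#' parameter over the relevant ranges, so plain bisection to a tight interval
#' tolerance suffices.
#'
#' @param kind A boundary kind, see [boundary_residual()].
#' @param model A [tipping_model()]; the varying parameter's entry is
#'   ignored.
#' @param parameter Name of the parameter to vary (`"delta"`, `"rho"`,
#'   `"gamma"`, `"r_l"`, `"r_min"`).
#' @param interval Search interval, default `c(0, 1)`.
#' @param tol Interval tolerance, default `1e-12`.
#' @return The located root, or `NA` if the residual does not change sign on
#'   the interval.
#' @examples
#' m <- tipping_model(0, 0.2, 0.9, r_l = 0.5)
#' boundary_root("optimality", m, "delta")  # critical collapse probability
#' @export
boundary_root <- function(kind, model, parameter,
                          interval = c(0, 1), tol = 1e-12) {
  stopifnot(parameter %in% c("delta", "rho", "gamma", "r_l", "r_min"))
  f <- function(x) {
    m <- model
    m[[parameter]] <- x
    boundary_residual(kind, m)
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Vectorized classification of both policies over parameter vectors.
# Optimality compares values at the prosperous state (the verdict is
# state-independent); safety follows the blanket rule. Returns a list of
# logical vectors, one per (policy, paradigm).
classify_vec <- function(delta, rho, gamma, r_l, r_min, r_h = 1) {
  v <- values_closed_vec(delta, rho, gamma, r_l, r_h)
  list(
    risky_optimal = v$vr_p >= v$vc_p,
    risky_sustainable = v$vr_p >= r_min & v$vr_d >= r_min,
    risky_safe = FALSE,
    cautious_optimal = v$vc_p >= v$vr_p,
    cautious_sustainable = r_l >= r_min,
    cautious_safe = TRUE
  )
}

# Integer index of the paradigm code in paradigm_codes() order, avoiding
# string assembly in the volume-sampling hot path.
paradigm_index <- function(optimal, sustainable, safe) {
  (!optimal) * 4L + (!sustainable) * 2L + (!safe) + 1L
}

#' Classify policies over a two-parameter grid
#'
#' Sweeps two of the five ratio parameters (`delta`, `rho`, `gamma`,
#' `r_l`, `r_min`, all on `[0, 1]` with `r_h = 1`) over a rectangular grid,
#' holding the others fixed, and classifies the requested policies at every
#' grid point. This reproduces the data behind the two-dimensional regime
#' maps (e.g. collapse probability vs. discount factor).
#'
#' @param axis1,axis2 Names of the two swept parameters.
#' @param values1,values2 Numeric vectors of grid values in `[0, 1]`.
#' @param fixed Named list giving the remaining parameters (defaults
#'   `delta = 0.1`, `rho = 0.2`, `gamma = 0.9`, `r_l = 0.5`, `r_min = 0.3`
#'   for whichever are not swept).
#' @param policies Character vector, subset of `c("risky", "cautious")`.
#' @return A long-format data frame with columns `axis1_name`, `axis1`,
#'   `axis2_name`, `axis2`, `policy`, `optimal`, `sustainable`, `safe`.
#' @examples
#' sw <- sweep_classification("delta", "gamma",
#'                            seq(0, 1, 0.25), seq(0, 1, 0.25),
#'                            fixed = list(rho = 0.2, r_l = 0.5, r_min = 0.3))
#' all(sw$safe[sw$policy == "cautious"])
#' @export
sweep_classification <- function(axis1, axis2, values1, values2,
                                 fixed = list(),
                                 policies = c("risky", "cautious")) {
  pars <- c("delta", "rho", "gamma", "r_l", "r_min")
  stopifnot(axis1 %in% pars, axis2 %in% pars, axis1 != axis2,
            all(policies %in% c("risky", "cautious")))
  if (any(values1 < 0 | values1 > 1) || any(values2 < 0 | values2 > 1))
    stop("grid values must lie within [0, 1]", call. = FALSE)
  defaults <- list(delta = 0.1, rho = 0.2, gamma = 0.9,
                   r_l = 0.5, r_min = 0.3)
  fixed <- utils::modifyList(defaults[setdiff(pars, c(axis1, axis2))],
                             fixed[intersect(names(fixed), pars)])
  g <- expand.grid(a1 = values1, a2 = values2,
                   KEEP.OUT.ATTRS = FALSE)
  p <- fixed
  p[[axis1]] <- g$a1
  p[[axis2]] <- g$a2
  cl <- classify_vec(p$delta, p$rho, p$gamma, p$r_l, p$r_min)
  out <- do.call(rbind, lapply(policies, function(pol) {
    data.frame(
      axis1_name = axis1, axis1 = g$a1,
      axis2_name = axis2, axis2 = g$a2,
      policy = pol,
      optimal = cl[[paste0(pol, "_optimal")]],
      sustainable = cl[[paste0(pol, "_sustainable")]],
      safe = cl[[paste0(pol, "_safe")]]
    )
  }))
  rownames(out) <- NULL
  out
}
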