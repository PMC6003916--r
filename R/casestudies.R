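#' Convert a residence timescale to a transition probability
#'
#' A state with per-step exit probability `p` is occupied for a geometric
#' number of steps with mean `<N> = (1 - p) / p`. Inverting gives
#' `p = 1 / (<N> + 1)`. One model time step corresponds to one year, so a
#' mean residence of 50 years maps to a transition probability of
#' `1/51 ~ 0.02` per year.
#'
#' @param mean_residence_years Mean residence time `<N>` in years (>= 0;
#'   0 means the state is left every step).
#' @return Transition probability per yearly time step, in `(0, 1]`.
#' @examples
#' timescale_to_probability(50)   # ~0.02
#' probability_to_timescale(0.05) # 19 years
#' @export
timescale_to_probability <- function(mean_residence_years) {
  if (!is.numeric(mean_residence_years) || any(mean_residence_years < 0) ||
      any(!is.finite(mean_residence_years)))
    stop("mean residence time must be finite and non-negative",
         call. = FALSE)
  1 / (mean_residence_years + 1)
}

#' @rdname timescale_to_probability
#' @param p Transition probability per time step, in `(0, 1]`.
#' @export
probability_to_timescale <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p > 1))
    stop("'p' must lie in (0, 1]", call. = FALSE)
  (1 - p) / p
}

#' Parameter uncertainty box
#'
#' A box of closed subintervals of `[0, 1]` for the parameters that are not
#' pinned down by a case study's timescales. Defaults reflect a moderately
#' farsighted decision maker whose low-pressure reward and acceptability
#' threshold are known only to within broad ranges:
#' `gamma` in `[0.95, 0.99]`, `r_l/r_h` in `[0.3, 0.7]`, `r_min/r_h` in
#' `[0.1, 0.5]`.
#'
#' @param gamma,r_l,r_min Length-2 numeric ranges (lower, upper) in `[0, 1]`.
#' @param delta,rho Optional length-2 ranges overriding the case study's
#'   point values.
#' @return An object of class `uncertainty_box`.
#' @export
uncertainty_box <- function(gamma = c(0.95, 0.99), r_l = c(0.3, 0.7),
                            r_min = c(0.1, 0.5), delta = NULL, rho = NULL) {
  check_range <- function(x, nm) {
    if (is.null(x)) return(NULL)
    if (!is.numeric(x) || length(x) != 2L || x[1] > x[2] ||
        x[1] < 0 || x[2] > 1)
      stop(sprintf("'%s' must be a range (lo, hi) within [0, 1]", nm),
           call. = FALSE)
    x
  }
  structure(list(gamma = check_range(gamma, "gamma"),
                 r_l = check_range(r_l, "r_l"),
                 r_min = check_range(r_min, "r_min"),
                 delta = check_range(delta, "delta"),
                 rho = check_range(rho, "rho")),
            class = "uncertainty_box")
}

#' Real-world case-study presets
#'
#' Loads a case study defined by typical residence timescales and derives
#' the collapse and recovery probabilities per yearly time step via
#' [timescale_to_probability()]. The shipped presets (read from the
#' package's `case_presets.json` configuration file) are:
#' \describe{
#'   \item{climate}{collapse timescale 30--50 years (kept as a range, since
#'     the triggering timescale under business-as-usual scenarios is itself
#'     uncertain); recovery on a multi-millennial timescale, encoded as 5000
#'     years by default, i.e. `rho` close to zero.}
#'   \item{fisheries}{collapse ~20 years, recovery ~50 years.}
#'   \item{farming}{land degradation with collapse ~100 years and soil
#'     recovery ~300 years.}
#' }
#'
#' @param name Preset name, or a custom label when `collapse_years` is
#'   given.
#' @param collapse_years,recovery_years Optional custom timescales (scalar
#'   or length-2 range), overriding the preset.
#' @param presets_file Path to a JSON preset configuration; defaults to the
#'   file shipped with the package.
#' @return An object of class `case_study` with the timescales and the
#'   derived `delta` and `rho` (each a scalar or a length-2 range).
#' @examples
#' case_study("fisheries")
#' @export
case_study <- function(name, collapse_years = NULL, recovery_years = NULL,
                       presets_file = NULL) {
  if (is.null(collapse_years)) {
    if (is.null(presets_file))
      presets_file <- system.file("extdata", "case_presets.json",
                                  package = "tipmdp", mustWork = TRUE)
    presets <- jsonlite::read_json(presets_file, simplifyVector = TRUE)
    if (!name %in% names(presets))
      stop(sprintf("unknown case study '%s'; available: %s", name,
                   paste(names(presets), collapse = ", ")), call. = FALSE)
    collapse_years <- presets[[name]]$collapse_timescale_years
    recovery_years <- presets[[name]]$recovery_timescale_years
  }
  stopifnot(is.numeric(collapse_years), length(collapse_years) %in% 1:2,
            is.numeric(recovery_years), length(recovery_years) %in% 1:2)
  # larger residence timescale -> smaller transition probability, so a
  # (lo, hi) timescale range maps to a reversed probability range
  to_p <- function(ts) sort(timescale_to_probability(ts))
  structure(list(name = name,
                 collapse_timescale_years = collapse_years,
                 recovery_timescale_years = recovery_years,
                 delta = to_p(collapse_years),
                 rho = to_p(recovery_years)),
            class = "case_study")
}

#' @export
print.case_study <- function(x, ...) {
  fmt <- function(v) if (length(v) == 2)
    sprintf("[%g, %g]", v[1], v[2]) else sprintf("%g", v)
  cat(sprintf("Case study '%s'\n", x$name))
  cat(sprintf("  collapse timescale %s years -> delta = %s\n",
              fmt(x$collapse_timescale_years), fmt(signif(x$delta, 4))))
  cat(sprintf("  recovery timescale %s years -> rho   = %s\n",
              fmt(x$recovery_timescale_years), fmt(signif(x$rho, 4))))
  invisible(x)
}

draw_from_range <- function(r, n) {
  if (length(r) == 2L) stats::runif(n, r[1], r[2]) else rep(r, n)
}

#' Regime-membership probabilities under parameter uncertainty
#'
#' Samples the uncertain parameters uniformly and independently from the
#' box (and, for case studies whose timescales are ranges, the collapse or
#' recovery probability from its derived range), classifies both the risky
#' and the cautious policy at every draw, and reports the probability of
#' each paradigm combination per policy, with Monte Carlo standard errors.
#'
#' @param case A [case_study()].
#' @param box An [uncertainty_box()]; its `delta`/`rho` entries, if set,
#'   override the case study's.
#' @param n Number of Monte Carlo draws.
#' @param seed Integer seed (mandatory).
#' @return A data frame with columns `policy`, `code`, `optimal`,
#'   `sustainable`, `safe`, `probability`, `se`; for each policy the four
#'   attainable labels sum to probability one. The sampling configuration is
#'   attached as attribute `"config"`.
#' @examples
#' rp <- regime_probabilities(case_study("farming"), n = 2000, seed = 1)
#' subset(rp, policy == "risky" & probability == max(
#'   rp$probability[rp$policy == "risky"]))
#' @export
regime_probabilities <- function(case, box = uncertainty_box(), n = 1e5,
                                 seed) {
  stopifnot(inherits(case, "case_study"), inherits(box, "uncertainty_box"))
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  delta <- draw_from_range(if (!is.null(box$delta)) box$delta else case$delta, n)
  rho <- draw_from_range(if (!is.null(box$rho)) box$rho else case$rho, n)
  gamma <- draw_from_range(box$gamma, n)
  r_l <- draw_from_range(box$r_l, n)
  r_min <- draw_from_range(box$r_min, n)
  cl <- classify_vec(delta, rho, gamma, r_l, r_min)
  out <- do.call(rbind, lapply(c("risky", "cautious"), function(pol) {
    code <- paradigm_code(cl[[paste0(pol, "_optimal")]],
                          cl[[paste0(pol, "_sustainable")]],
                          pol == "cautious")
    # the four labels attainable by this policy, in canonical order
    lv <- paradigm_codes()[substr(paradigm_codes(), 3, 3) ==
                             (if (pol == "cautious") "F" else "-")]
    prob <- as.vector(table(factor(code, levels = lv))) / n
    d <- decode_paradigm(lv)
    d$policy <- pol
    d$probability <- prob
    d$se <- sqrt(prob * (1 - prob) / n)
    d
  }))
  out <- out[, c("policy", "code", "optimal", "sustainable", "safe",
                 "probability", "se")]
  rownames(out) <- NULL
  attr(out, "config") <- list(case = case$name,
                              delta = unclass(case$delta),
                              rho = unclass(case$rho),
                              box = unclass(box), n = n,
                              seed = as.integer(seed))
  out
}
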