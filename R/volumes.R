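#' Sampling specification for parameter-space volume estimates
#'
#' @param mode `"grid"` (regular lattice including the endpoints 0 and 1 on
#'   every axis) or `"monte_carlo"` (independent uniform draws).
#' @param n Points per axis (grid, >= 2) or total draws (Monte Carlo, >= 1).
#' @param seed Integer seed; mandatory in Monte Carlo mode and recorded in
#'   every report.
#' @return An object of class `sampling_spec`.
#' @export
sampling_spec <- function(mode = c("grid", "monte_carlo"), n, seed = NULL) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  if (mode == "grid" && n < 2L) stop("grid mode needs n >= 2 points per axis",
                                     call. = FALSE)
  if (mode == "monte_carlo") {
    if (n < 1L) stop("monte_carlo mode needs n >= 1 draws", call. = FALSE)
    if (is.null(seed)) stop("monte_carlo mode requires a seed", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(list(mode = mode, n = n, seed = seed), class = "sampling_spec")
}

# Tally half-weighted (point, policy) mass per paradigm code from a
# classification table; returns counts on the 8 canonical codes.
tally_codes <- function(cl) {
  tabulate(paradigm_index(cl$risky_optimal, cl$risky_sustainable, FALSE),
           nbins = 8L) +
    tabulate(paradigm_index(cl$cautious_optimal,
                            rep_len(cl$cautious_sustainable,
                                    length(cl$cautious_optimal)), TRUE),
             nbins = 8L)
}

#' Parameter-space volume of each paradigm combination
#'
#' Estimates, for each of the eight (optimal, sustainable, safe)
#' combinations, the fraction of the five-dimensional unit parameter cube
#' (`delta`, `rho`, `gamma`, `r_l/r_h`, `r_min/r_h`, each uniform on
#' `[0, 1]`, `r_h` fixed at 1) it occupies. At every sampled parameter point
#' both the risky and the cautious policy are classified and each policy
#' contributes half a unit of mass, so the fractions across the eight
#' categories sum to one; all safe categories carry cautious-policy mass
#' only and all unsafe ones risky-policy mass only. Under this weighting the
#' safe-and-sustainable mass equals `P(r_l >= r_min) / 2 = 1/4` exactly in
#' the large-sample limit.
#'
#' Degenerate parameter points (vanishing value denominators at `gamma = 1`)
#' are classified using the documented limiting values, never dropped.
#'
#' @param spec A [sampling_spec()]. Grid mode evaluates the full lattice of
#'   `n^5` points (chunked by collapse-probability slice to bound memory);
#'   Monte Carlo mode draws `n` points.
#' @return An object of class `volume_report`: list with `fractions` (named
#'   by 3-letter code), `standard_error` (Monte Carlo mode; `NULL` for
#'   grid), `n_points`, and the echoed `spec`.
#' @examples
#' category_volumes(sampling_spec("monte_carlo", 10000, seed = 1))
#' @export
category_volumes <- function(spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  codes <- paradigm_codes()
  if (spec$mode == "monte_carlo") {
    set.seed(spec$seed)
    n <- spec$n
    cl <- classify_vec(stats::runif(n), stats::runif(n), stats::runif(n),
                       stats::runif(n), stats::runif(n))
    counts <- tally_codes(cl)
    fractions <- counts / (2 * n)
    # per-point contribution is 0 or 1/2 (a point's two policies never share
    # a category), so Var = f/2 - f^2
    se <- sqrt(pmax(fractions / 2 - fractions^2, 0) / n)
    n_points <- n
  } else {
    axis <- seq(0, 1, length.out = spec$n)
    inner <- expand.grid(rho = axis, gamma = axis, r_l = axis, r_min = axis,
                         KEEP.OUT.ATTRS = FALSE)
    counts <- rep(0, 8L)
    for (d in axis) {
      cl <- classify_vec(d, inner$rho, inner$gamma, inner$r_l, inner$r_min)
      counts <- counts + tally_codes(cl)
    }
    n_points <- spec$n^5
    fractions <- counts / (2 * n_points)
    se <- NULL
  }
  names(fractions) <- codes
  if (!is.null(se)) names(se) <- codes
  structure(list(fractions = fractions, standard_error = se,
                 n_points = n_points, spec = spec),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("Paradigm-combination volumes (%s, %s points%s)\n",
              x$spec$mode, format(x$n_points, big.mark = ","),
              if (!is.null(x$spec$seed))
                paste0(", seed ", x$spec$seed) else ""))
  df <- rank_categories(x)
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %s  %6.2f%%%s\n", df$code[i], 100 * df$fraction[i],
                if (!is.null(x$standard_error))
                  sprintf("  (se %.4f)", x$standard_error[[df$code[i]]])
                else ""))
  invisible(x)
}

#' Rank paradigm combinations by volume
#'
#' @param report A `volume_report` from [category_volumes()].
#' @return A data frame with columns `code`, `optimal`, `sustainable`,
#'   `safe`, `fraction`, sorted by decreasing fraction (ties broken by code).
#' @export
rank_categories <- function(report) {
  stopifnot(inherits(report, "volume_report"))
  df <- decode_paradigm(names(report$fractions))
  df$fraction <- unname(report$fractions)
  df <- df[order(-df$fraction, df$code), ]
  rownames(df) <- NULL
  df
}
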