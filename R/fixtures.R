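#' Witness parameter points for the eight paradigm combinations
#'
#' A fixed set of parameter points (with `r_h = 1`) at which the risky and
#' cautious policies jointly realize all eight (optimal, sustainable, safe)
#' combinations — once with a discounting agent (`gamma < 1`) and once with
#' an absolutely farsighted one (`gamma = 1`), showing that the trade-offs
#' between paradigms do not vanish without discounting. The `expected_code`
#' column records the label each point is certified to produce.
#'
#' @return A data frame with columns `policy`, `delta`, `rho`, `gamma`,
#'   `r_l`, `r_min`, `expected_code`.
#' @examples
#' w <- witness_points()
#' length(unique(w$expected_code))  # all eight labels
#' @export
witness_points <- function() {
  df <- read.csv(text = "policy,delta,rho,gamma,r_l,r_min,expected_code
risky,0.05,0.2,0.9,0.5,0.3,OS-
risky,0.05,0.2,0.9,0.5,0.6,O--
risky,0.3,0.3,0.99,0.9,0.1,-S-
risky,0.5,0.2,0.9,0.5,0.45,---
cautious,0.5,0.2,0.9,0.5,0.3,OSF
cautious,0.5,0.2,0.9,0.5,0.7,O-F
cautious,0.05,0.2,0.9,0.5,0.3,-SF
cautious,0.05,0.2,0.9,0.5,0.7,--F
risky,0.05,0.45,1,0.5,0.3,OS-
risky,0.2,0.4,1,0.5,0.7,O--
risky,0.2,0.4,1,0.9,0.1,-S-
risky,0.2,0.4,1,0.9,0.8,---
cautious,0.5,0.2,1,0.5,0.3,OSF
cautious,0.5,0.2,1,0.5,0.7,O-F
cautious,0.05,0.45,1,0.5,0.3,-SF
cautious,0.05,0.45,1,0.5,0.7,--F
", stringsAsFactors = FALSE)
  df
}

#' Reference parameter settings for the regime maps
#'
#' The fixed parameters used by the two-dimensional classification sweeps:
#' the baseline setting (`rho = 0.2`, `r_l/r_h = 0.5`, `r_min/r_h = 0.3`,
#' under which a safe and just operating space exists since
#' `r_l >= r_min`) and the high-threshold variant (`r_min/r_h = 0.7 > r_l`,
#' under which it does not).
#'
#' @return A named list of named parameter lists.
#' @export
sweep_settings <- function() {
  list(
    baseline = list(rho = 0.2, r_l = 0.5, r_min = 0.3),
    high_threshold = list(rho = 0.2, r_l = 0.5, r_min = 0.7)
  )
}

#' Write machine-readable fixtures
#'
#' Writes the witness parameter points, the regime-map parameter settings,
#' and the case-study presets to a directory as plain CSV/JSON, for use by
#' external tooling or test suites.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    witness = file.path(dir, "witness_points.csv"),
    sweeps = file.path(dir, "sweep_settings.json"),
    cases = file.path(dir, "case_presets.json")
  )
  utils::write.csv(witness_points(), paths[["witness"]], row.names = FALSE)
  jsonlite::write_json(sweep_settings(), paths[["sweeps"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.copy(system.file("extdata", "case_presets.json", package = "tipmdp",
                        mustWork = TRUE),
            paths[["cases"]], overwrite = TRUE)
  invisible(paths)
}
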