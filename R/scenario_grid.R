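# Scenario grids: the factorial simulation setups over which left-truncation
# bias is quantified. One row per setup, columns are the generative parameters
# of the data-generating mechanism (see the methods vignette).

#' Construct a single simulation setup
#'
#' A setup bundles every generative probability and risk ratio of the
#' data-generating mechanism: the prevalence of abnormal placentation, the
#' uniform supports for the per-cohort abruption-onset probability, the
#' multiplicative risk model for spontaneous abortion (SAB), and the
#' multiplicative risk model for the outcome (perinatal mortality or
#' stillbirth) among pregnancies not ending in SAB.
#'
#' @param setup_id Integer label for the setup.
#' @param analysis_family One of `"primary"`, `"sensitivity_mortality"`,
#'   `"sensitivity_stillbirth"`.
#' @param pi_Z Prevalence of abnormal placentation, `Pr(Z = 1)`.
#' @param pX_range_Z1,pX_range_Z0 Length-2 numeric, the `(low, high)` support
#'   of the uniform distribution from which each cohort's abruption-onset
#'   probability is drawn, within the abnormal (`Z = 1`) and normal (`Z = 0`)
#'   placentation strata.
#' @param pC_base Baseline SAB risk `Pr(C = 1 | Z = 0, X = 0)`.
#' @param rr_C_Z,rr_C_X Risk ratios of SAB for abnormal placentation and for
#'   abruption onset.
#' @param rr_C_interaction Multiplicative interaction of `Z` and `X` on SAB
#'   risk (1 = no heterogeneity of risk ratios).
#' @param pOut_base Baseline outcome risk
#'   `Pr(outcome = 1 | M = 0, Z = 0, C = 0)`.
#' @param rr_Out_M,rr_Out_Z Risk ratios of the outcome for a clinical
#'   abruption diagnosis and for abnormal placentation, among pregnancies
#'   surviving past the SAB window.
#' @param rr_Out_interaction Multiplicative interaction of `M` and `Z` on
#'   outcome risk.
#' @param outcome_type `"perinatal_mortality"` (stillbirth or neonatal death)
#'   or `"stillbirth"` (in utero death only).
#'
#' @return A one-row tibble with one column per parameter; range parameters
#'   are split into `_lo`/`_hi` columns so the grid stays flat and
#'   CSV-serialisable.
#' @seealso [build_grid()], [validate_params()]
#' @export
#' @examples
#' scenario_params(rr_C_Z = 2, rr_C_X = 2, rr_Out_Z = 2)
scenario_params <- function(setup_id = 1L,
                            analysis_family = "primary",
                            pi_Z = 0.1,
                            pX_range_Z1 = c(0.005, 0.050),
                            pX_range_Z0 = c(0.001, 0.020),
                            pC_base = 0.05,
                            rr_C_Z = 2,
                            rr_C_X = 2,
                            rr_C_interaction = 1,
                            pOut_base = 0.0082,
                            rr_Out_M = 14.5,
                            rr_Out_Z = 2,
                            rr_Out_interaction = 1,
                            outcome_type = "perinatal_mortality") {
  analysis_family <- match.arg(
    analysis_family,
    c("primary", "sensitivity_mortality", "sensitivity_stillbirth")
  )
  outcome_type <- match.arg(outcome_type, c("perinatal_mortality", "stillbirth"))
  stopifnot(length(pX_range_Z1) == 2L, length(pX_range_Z0) == 2L)
  tibble::tibble(
    setup_id = as.integer(setup_id),
    analysis_family = analysis_family,
    pi_Z = pi_Z,
    pX_lo_Z1 = pX_range_Z1[1], pX_hi_Z1 = pX_range_Z1[2],
    pX_lo_Z0 = pX_range_Z0[1], pX_hi_Z0 = pX_range_Z0[2],
    pC_base = pC_base,
    rr_C_Z = rr_C_Z,
    rr_C_X = rr_C_X,
    rr_C_interaction = rr_C_interaction,
    pOut_base = pOut_base,
    rr_Out_M = rr_Out_M,
    rr_Out_Z = rr_Out_Z,
    rr_Out_interaction = rr_Out_interaction,
    outcome_type = outcome_type
  )
}

param_cols <- c(
  "pi_Z", "pX_lo_Z1", "pX_hi_Z1", "pX_lo_Z0", "pX_hi_Z0", "pC_base",
  "rr_C_Z", "rr_C_X", "rr_C_interaction",
  "pOut_base", "rr_Out_M", "rr_Out_Z", "rr_Out_interaction"
)

#' Validate a simulation setup
#'
#' Both risk models are multiplicative, so the largest fitted value —
#' reached when every indicator is 1 — must still be a probability. A setup
#' whose implied maximal SAB risk `pC_base * rr_C_Z * rr_C_X *
#' rr_C_interaction` or maximal outcome risk `pOut_base * rr_Out_M *
#' rr_Out_Z * rr_Out_interaction` exceeds 1 is well-formed but invalid and is
#' dropped from factorial grids.
#'
#' @param params A one-row tibble as returned by [scenario_params()].
#' @return A list with `valid` (logical), `max_pC` = implied
#'   `Pr(C = 1 | Z = 1, X = 1)` and `max_pOut` = implied
#'   `Pr(outcome = 1 | M = 1, Z = 1, C = 0)`.
#' @details Malformed parameters (negative, non-finite, or probabilities
#'   outside `[0, 1]`, or a degenerate range with `lo > hi`) raise an error;
#'   this is distinct from a well-formed setup that merely implies an event
#'   probability above 1.
#' @export
#' @examples
#' validate_params(scenario_params(rr_C_Z = 6, rr_C_X = 4.5))$valid  # FALSE
validate_params <- function(params) {
  stopifnot(is.data.frame(params), nrow(params) == 1L)
  vals <- unlist(params[param_cols])
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("malformed parameters: all generative parameters must be finite")
  }
  if (any(vals < 0)) {
    stop("malformed parameters: probabilities and risk ratios must be non-negative")
  }
  probs <- unlist(params[c("pi_Z", "pX_lo_Z1", "pX_hi_Z1", "pX_lo_Z0",
                           "pX_hi_Z0", "pC_base", "pOut_base")])
  if (any(probs > 1)) {
    stop("malformed parameters: probability fields must lie in [0, 1]")
  }
  if (params$pX_lo_Z1 > params$pX_hi_Z1 || params$pX_lo_Z0 > params$pX_hi_Z0) {
    stop("malformed parameters: abruption probability range has lo > hi")
  }
  max_pC <- params$pC_base * params$rr_C_Z * params$rr_C_X * params$rr_C_interaction
  max_pOut <- params$pOut_base * params$rr_Out_M * params$rr_Out_Z *
    params$rr_Out_interaction
  list(valid = max_pC <= 1 && max_pOut <= 1, max_pC = max_pC, max_pOut = max_pOut)
}

# One factorial block: cross the SAB and outcome risk ratios, drop setups
# whose implied maximal risk exceeds 1, order deterministically.
factorial_block <- function(rr_C_Z, rr_C_X, rr_Out_Z, pi_Z, pOut_base,
                            rr_Out_M, outcome_type, analysis_family) {
  combos <- expand.grid(rr_Out_Z = rr_Out_Z, rr_C_X = rr_C_X, rr_C_Z = rr_C_Z)
  combos <- combos[order(combos$rr_C_Z, combos$rr_C_X, combos$rr_Out_Z), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    scenario_params(
      analysis_family = analysis_family,
      pi_Z = pi_Z,
      rr_C_Z = combos$rr_C_Z[i],
      rr_C_X = combos$rr_C_X[i],
      rr_Out_Z = combos$rr_Out_Z[i],
      pOut_base = pOut_base,
      rr_Out_M = rr_Out_M,
      outcome_type = outcome_type
    )
  })
  block <- dplyr::bind_rows(rows)
  keep <- vapply(seq_len(nrow(block)),
                 function(i) validate_params(block[i, ])$valid, logical(1))
  block[keep, ]
}

#' Build a scenario grid
#'
#' Constructs the simulation setups of one analysis family (or all 80).
#' The core is the factorial of the SAB risk ratios `rr_C_Z` x `rr_C_X` and
#' the outcome risk ratio `rr_Out_Z`; combinations whose implied maximal SAB
#' risk exceeds 1 are removed, which with the default levels leaves 10 of 12.
#'
#' * `primary` (setups 1-10): `pi_Z = 0.1`, outcome pairing
#'   `(pOut_base = 0.0082, rr_Out_M = 14.5)`, perinatal mortality.
#' * `sensitivity_mortality` (setups 11-40): the same core crossed with the
#'   alternative prevalence `pi_Z = 0.2` and/or the alternative outcome
#'   pairing `(0.0120, 9.9)`.
#' * `sensitivity_stillbirth` (setups 41-80): mirrors setups 1-40 with the
#'   stillbirth outcome pairings `(0.0053, 14.5)` and `(0.0077, 9.9)`.
#'
#' The two outcome parameters move together as a pairing because they keep
#' the abruption-stratum risk essentially constant
#' (`0.0082 * 14.5 ~ 0.0120 * 9.9`); see the methods vignette.
#'
#' @param family `"primary"`, `"sensitivity_mortality"`,
#'   `"sensitivity_stillbirth"`, or `"all"`.
#' @param rr_C_Z,rr_C_X,rr_Out_Z Factor levels of the core factorial;
#'   defaults are the study's levels.
#' @return A tibble of setups, one row each, with `setup_id` assigned in the
#'   deterministic order ascending `rr_C_Z`, then `rr_C_X`, then `rr_Out_Z`
#'   within each block.
#' @export
#' @examples
#' nrow(build_grid("primary"))  # 10
build_grid <- function(family = c("primary", "sensitivity_mortality",
                                  "sensitivity_stillbirth", "all"),
                       rr_C_Z = c(2, 4, 6),
                       rr_C_X = c(2, 4.5),
                       rr_Out_Z = c(2, 4)) {
  family <- match.arg(family)
  blk <- function(pi_Z, pOut_base, rr_Out_M, outcome_type, analysis_family) {
    factorial_block(rr_C_Z, rr_C_X, rr_Out_Z, pi_Z, pOut_base, rr_Out_M,
                    outcome_type, analysis_family)
  }
  primary <- blk(0.1, 0.0082, 14.5, "perinatal_mortality", "primary")
  grids <- switch(
    family,
    primary = primary,
    sensitivity_mortality = dplyr::bind_rows(
      blk(0.2, 0.0082, 14.5, "perinatal_mortality", "sensitivity_mortality"),
      blk(0.1, 0.0120, 9.9, "perinatal_mortality", "sensitivity_mortality"),
      blk(0.2, 0.0120, 9.9, "perinatal_mortality", "sensitivity_mortality")
    ),
    sensitivity_stillbirth = dplyr::bind_rows(
      blk(0.1, 0.0053, 14.5, "stillbirth", "sensitivity_stillbirth"),
      blk(0.2, 0.0053, 14.5, "stillbirth", "sensitivity_stillbirth"),
      blk(0.1, 0.0077, 9.9, "stillbirth", "sensitivity_stillbirth"),
      blk(0.2, 0.0077, 9.9, "stillbirth", "sensitivity_stillbirth")
    ),
    all = dplyr::bind_rows(
      build_grid("primary", rr_C_Z, rr_C_X, rr_Out_Z),
      build_grid("sensitivity_mortality", rr_C_Z, rr_C_X, rr_Out_Z),
      build_grid("sensitivity_stillbirth", rr_C_Z, rr_C_X, rr_Out_Z)
    )
  )
  offset <- switch(family,
    primary = 0L,
    sensitivity_mortality = nrow(primary),
    sensitivity_stillbirth = 4L * nrow(primary),
    all = 0L
  )
  grids$setup_id <- offset + seq_len(nrow(grids))
  grids
}

#' Read or write a scenario grid as a flat CSV
#'
#' The grid is the package's analogue of a simulation design spreadsheet:
#' one row per setup, one column per generative parameter.
#'
#' @param grid A tibble from [build_grid()].
#' @param path File path.
#' @return `write_grid()` returns `path` invisibly; `read_grid()` returns the
#'   grid tibble.
#' @export
write_grid <- function(grid, path) {
  readr::write_csv(grid, path)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      setup_id = readr::col_integer(),
      analysis_family = readr::col_character(),
      outcome_type = readr::col_character(),
      .default = readr::col_double()
    )
  )
}
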