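# The three left-truncation bias estimands, per replicate and stratum:
#   absolute bias of risk, per exposure arm:  risk_observed - risk_unobserved
#   absolute bias of the risk difference:     RD_observed - RD_unobserved
#   relative bias of the risk ratio:          RR_observed / RR_unobserved

#' Compute bias estimands from paired scope estimates
#'
#' Pairs observed-scope and unobserved-scope estimates from the same
#' cohorts and strata and computes the three bias estimands. Undefined
#' inputs (flagged by [estimate_effects()]) propagate as `NA` with
#' `defined = FALSE`.
#'
#' @param observed,unobserved Estimate tibbles from [estimate_effects()]
#'   with the matching scope. Alternatively pass a single tibble containing
#'   both scopes as `observed` and leave `unobserved` `NULL`.
#' @return A tibble with one row per (setup, replicate, stratum):
#'   `risk_bias_exposed`, `risk_bias_unexposed`, `rd_bias`,
#'   `rr_relative_bias`, `defined`.
#' @export
#' @examples
#' set.seed(7)
#' ch <- simulate_cohort(scenario_params(), n_total = 50000)
#' compute_bias(estimate_effects(ch, "both"))
compute_bias <- function(observed, unobserved = NULL) {
  if (is.null(unobserved)) {
    est <- observed
    observed <- est[est$scope == "observed", ]
    unobserved <- est[est$scope == "unobserved", ]
  }
  if (nrow(observed) == 0L || nrow(unobserved) == 0L) {
    stop("compute_bias() needs both an observed- and an unobserved-scope estimate")
  }
  if (!all(observed$scope == "observed") || !all(unobserved$scope == "unobserved")) {
    stop("scope mismatch: pass observed-scope and unobserved-scope estimates")
  }
  keys <- c("setup_id", "replicate_id", "stratum")
  pair <- dplyr::inner_join(
    observed, unobserved,
    by = keys, suffix = c("_obs", "_unobs")
  )
  if (nrow(pair) != nrow(observed)) {
    stop("scope mismatch: observed and unobserved estimates do not pair 1:1")
  }
  tibble::tibble(
    setup_id = pair$setup_id,
    replicate_id = pair$replicate_id,
    stratum = pair$stratum,
    risk_bias_exposed = pair$risk_exposed_obs - pair$risk_exposed_unobs,
    risk_bias_unexposed = pair$risk_unexposed_obs - pair$risk_unexposed_unobs,
    rd_bias = pair$rd_obs - pair$rd_unobs,
    rr_relative_bias = ifelse(!is.na(pair$rr_unobs) & pair$rr_unobs > 0,
                              pair$rr_obs / pair$rr_unobs, NA_real_),
    defined = pair$defined_obs & pair$defined_unobs &
      !is.na(pair$rr_obs) & !is.na(pair$rr_unobs) &
      pair$rr_obs > 0 & pair$rr_unobs > 0
  )
}

#' Summarise estimates or bias results across replicates
#'
#' Long-format summary of any numeric columns: mean, median and the central
#' 95% band across replicates, with explicit accounting of excluded
#' (undefined) replicates. Replicates flagged `defined = FALSE` are excluded
#' from all summaries and counted in `n_excluded`.
#'
#' @param results A tibble from [estimate_effects()] or [compute_bias()]
#'   (or any tibble with numeric outcome columns).
#' @param values Character vector of columns to summarise.
#' @param by Character vector of grouping keys (default: setup and stratum,
#'   plus `scope` when present).
#' @return A tibble with one row per group and quantity: `quantity`,
#'   `n_used`, `mean`, `median`, `pct_2_5`, `pct_97_5`, `n_excluded`.
#' @details Exclusion is per affected quantity: a replicate with an
#'   undefined risk ratio (`NA`) is dropped from the RR summaries but still
#'   contributes its (defined) risks and RD — excluding the whole replicate
#'   would selectively discard low-event cohorts and bias the remaining
#'   means.
#' @export
aggregate_estimates <- function(results,
                                values = intersect(
                                  c("risk_exposed", "risk_unexposed", "rd", "rr",
                                    "risk_bias_exposed", "risk_bias_unexposed",
                                    "rd_bias", "rr_relative_bias"),
                                  names(results)
                                ),
                                by = intersect(c("setup_id", "scope", "stratum"),
                                               names(results))) {
  if (nrow(results) == 0L) {
    warning("empty input: no groups to summarise")
    return(tibble::tibble())
  }
  long <- tidyr::pivot_longer(
    results[c(by, values)],
    dplyr::all_of(values),
    names_to = "quantity", values_to = "value"
  )
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "quantity")))) |>
    dplyr::summarise(
      n_used = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      median = stats::median(.data$value, na.rm = TRUE),
      pct_2_5 = stats::quantile(.data$value, 0.025, na.rm = TRUE,
                                names = FALSE),
      pct_97_5 = stats::quantile(.data$value, 0.975, na.rm = TRUE,
                                 names = FALSE),
      n_excluded = dplyr::n() - .data$n_used,
      .groups = "drop"
    )
}
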