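# Stratified risks, risk differences and risk ratios for the
# abruption-outcome association, in two analysis scopes:
#   unobserved — the full conception cohort (denominator = all conceptions;
#     pregnancies lost to SAB contribute zero outcome events), exposure =
#     abruption onset X;
#   observed — the left-truncated birth cohort (denominator restricted to
#     pregnancies surviving past 20 weeks, C = 0), exposure = the clinical
#     diagnosis M, which equals X on C = 0.
# Numerators are identical across scopes, so truncation can only inflate
# risks.

#' Estimate stratified risks, RD and RR from cell counts
#'
#' Computes, for each cohort and placentation stratum, the outcome risk in
#' the exposed (abruption) and unexposed arms, their difference and ratio,
#' under one or both analysis scopes. Estimates are closed-form cell
#' arithmetic; [fit_saturated_log_binomial()] provides the equivalent
#' maximum-likelihood cross-check.
#'
#' @param counts A cell-count tibble from [simulate_cohort()],
#'   [simulate_study()] or [simulate_grid()] (any number of cohorts).
#' @param scope `"observed"`, `"unobserved"`, or `"both"`.
#' @return A tibble with one row per (setup, replicate, scope, stratum):
#'   `risk_exposed`, `risk_unexposed`, `rd`, `rr`, the numerators
#'   `events_exposed`/`events_unexposed`, the denominators
#'   `denom_exposed`/`denom_unexposed`, and a logical `defined` flag.
#'   Zero-denominator estimates are `NA` with `defined = FALSE`; a zero
#'   unexposed risk leaves `rr` `NA` (flagged) while risks and `rd` remain
#'   usable.
#' @export
#' @examples
#' set.seed(42)
#' ch <- simulate_cohort(scenario_params(), n_total = 50000)
#' estimate_effects(ch, "both")
estimate_effects <- function(counts, scope = c("both", "observed", "unobserved")) {
  scope <- match.arg(scope)
  base <- counts |>
    dplyr::group_by(.data$setup_id, .data$replicate_id, stratum = .data$z,
                    .data$x) |>
    dplyr::summarise(
      events = sum(.data$n[.data$y == 1L]),
      denom_all = sum(.data$n),
      denom_c0 = sum(.data$n[.data$c == 0L]),
      .groups = "drop"
    )
  one_scope <- function(sc) {
    d <- base
    d$denom <- if (sc == "observed") d$denom_c0 else d$denom_all
    wide <- tidyr::pivot_wider(
      d[c("setup_id", "replicate_id", "stratum", "x", "events", "denom")],
      names_from = "x", values_from = c("events", "denom")
    )
    tibble::tibble(
      setup_id = wide$setup_id,
      replicate_id = wide$replicate_id,
      scope = sc,
      stratum = wide$stratum,
      events_exposed = wide$events_1,
      events_unexposed = wide$events_0,
      denom_exposed = wide$denom_1,
      denom_unexposed = wide$denom_0,
      risk_exposed = ifelse(wide$denom_1 > 0, wide$events_1 / wide$denom_1, NA_real_),
      risk_unexposed = ifelse(wide$denom_0 > 0, wide$events_0 / wide$denom_0, NA_real_)
    ) |>
      dplyr::mutate(
        rd = .data$risk_exposed - .data$risk_unexposed,
        rr = ifelse(!is.na(.data$risk_unexposed) & .data$risk_unexposed > 0,
                    .data$risk_exposed / .data$risk_unexposed, NA_real_),
        defined = .data$denom_exposed > 0 & .data$denom_unexposed > 0
      )
  }
  res <- switch(scope,
    observed = one_scope("observed"),
    unobserved = one_scope("unobserved"),
    both = dplyr::bind_rows(one_scope("unobserved"), one_scope("observed"))
  )
  if ("seed" %in% names(counts)) {
    prov <- dplyr::distinct(counts[c("setup_id", "replicate_id", "seed")])
    res <- dplyr::left_join(res, prov, by = c("setup_id", "replicate_id"))
  }
  dplyr::arrange(res, .data$setup_id, .data$replicate_id, .data$scope,
                 .data$stratum)
}

#' Fit the saturated log-binomial model to one cohort
#'
#' Fits `log Pr(outcome) = a0 + a1*exposure + a2*Z + a3*exposure*Z` by
#' maximum likelihood on the four (exposure, stratum) cells of one cohort
#' under the given scope. Because the model is saturated, the fitted risks
#' equal the empirical cell risks, so `exp(a1)` is the stratum-0 risk ratio
#' and `exp(a1 + a3)` the stratum-1 risk ratio; the fit is an equivalence
#' check on [estimate_effects()], not the workhorse.
#'
#' @param counts Cell counts for a single cohort.
#' @param scope `"observed"` or `"unobserved"`.
#' @return A list: `coefficients` (a0..a3), `fitted_risks` (tibble by
#'   stratum and exposure), `converged`, and `estimable` (FALSE when a cell
#'   is empty or has zero events, in which case the MLE lies on the
#'   boundary and coefficients are `NA`).
#' @export
fit_saturated_log_binomial <- function(counts, scope = c("observed", "unobserved")) {
  scope <- match.arg(scope)
  if (length(unique(counts$replicate_id)) != 1L ||
      length(unique(counts$setup_id)) != 1L) {
    stop("fit_saturated_log_binomial() expects counts from a single cohort")
  }
  cells <- counts |>
    dplyr::group_by(.data$z, .data$x) |>
    dplyr::summarise(
      events = sum(.data$n[.data$y == 1L]),
      denom = if (scope == "observed") sum(.data$n[.data$c == 0L]) else sum(.data$n),
      .groups = "drop"
    )
  na_out <- list(
    coefficients = stats::setNames(rep(NA_real_, 4),
                                   c("a0", "a1", "a2", "a3")),
    fitted_risks = NULL, converged = FALSE, estimable = FALSE
  )
  if (any(cells$denom == 0) || any(cells$events == 0)) return(na_out)
  risks <- cells$events / cells$denom
  # exact MLE start from the empirical risks: convergence is immediate
  r <- function(z, x) risks[cells$z == z & cells$x == x]
  start <- c(log(r(0, 0)), log(r(0, 1) / r(0, 0)), log(r(1, 0) / r(0, 0)),
             log(r(1, 1) * r(0, 0) / (r(0, 1) * r(1, 0))))
  fit <- stats::glm(
    cbind(events, denom - events) ~ x * z,
    family = stats::binomial(link = "log"),
    data = cells, start = start
  )
  co <- stats::setNames(stats::coef(fit), c("a0", "a1", "a2", "a3"))
  list(
    coefficients = co,
    fitted_risks = tibble::tibble(
      stratum = cells$z, x = cells$x,
      risk = as.numeric(stats::fitted(fit))
    ),
    converged = fit$converged,
    estimable = TRUE
  )
}
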