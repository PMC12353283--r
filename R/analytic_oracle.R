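# Closed-form expectations of every simulated quantity, derived from the
# data-generating mechanism. Within a placentation stratum, write
#   q(x, z) = 1 - Pr(C = 1 | X = x, Z = z)      (SAB survival fraction)
#   r(x, z) = pOut_base * rr_Out_M^x * rr_Out_Z^z (risk among survivors)
# Then the unobserved (conception-cohort) risk is q * r, the observed
# (left-truncated) risk is r, and the bias estimands collapse to
#   RR_obs / RR_unobs = q(0, z) / q(1, z)
#   RD_obs - RD_unobs = pOut_base * rr_Out_Z^z *
#                        [rr_Out_M * (1 - q(1, z)) - (1 - q(0, z))]
# These expectations use the midpoint of the abruption-probability support,
# which is exact: expected censoring is linear in the drawn probability, and
# within-stratum risks, RD and RR do not involve it at all.

ex_px <- function(params, z) {
  if (z == 1) (params$pX_lo_Z1 + params$pX_hi_Z1) / 2
  else (params$pX_lo_Z0 + params$pX_hi_Z0) / 2
}

q_surv <- function(params, x, z) 1 - p_sab(params, z, x)

#' Expected marginal SAB (censoring) proportion
#'
#' The expected fraction of implanted conceptuses lost to spontaneous
#' abortion before 20 weeks under one setup:
#' `pC_base * sum_z Pr(Z = z) * rr_C_Z^z *
#'  (1 + (rr_C_X * rr_C_interaction^z - 1) * E[pX | z])`.
#'
#' @param params A one-row setup tibble from [scenario_params()].
#' @return Expected marginal `Pr(C = 1)`.
#' @export
#' @examples
#' expected_censoring(scenario_params(rr_C_Z = 2, rr_C_X = 2))  # 0.0557475
expected_censoring <- function(params) {
  v <- validate_params(params)
  if (!v$valid) stop("invalid parameters: implied event probability exceeds 1")
  terms <- vapply(0:1, function(z) {
    pz <- if (z == 1) params$pi_Z else 1 - params$pi_Z
    pz * params$rr_C_Z^z *
      (1 + (params$rr_C_X * params$rr_C_interaction^z - 1) * ex_px(params, z))
  }, numeric(1))
  params$pC_base * sum(terms)
}

#' Expected bias estimands for one stratum
#'
#' Closed-form expected absolute RD bias and relative RR bias in
#' placentation stratum `z` (see the formulas in the file header / methods
#' vignette).
#'
#' @param params A one-row setup tibble.
#' @param z Placentation stratum, 0 or 1 (vectorised).
#' @return A tibble with `stratum`, `rd_bias`, `rr_relative_bias`.
#' @export
#' @examples
#' expected_bias(scenario_params(rr_C_Z = 4, rr_C_X = 4.5), z = 1)
expected_bias <- function(params, z = 0:1) {
  v <- validate_params(params)
  if (!v$valid) stop("invalid parameters: implied event probability exceeds 1")
  q0 <- vapply(z, function(zz) q_surv(params, 0, zz), numeric(1))
  q1 <- vapply(z, function(zz) q_surv(params, 1, zz), numeric(1))
  if (any(q1 == 0)) stop("degenerate setup: no survivors among exposed")
  tibble::tibble(
    stratum = as.integer(z),
    rd_bias = params$pOut_base * params$rr_Out_Z^z *
      (params$rr_Out_M * (1 - q1) - (1 - q0)),
    rr_relative_bias = q0 / q1
  )
}

#' Full table of expectations for one setup
#'
#' Per-stratum expected risks per exposure arm and scope, RD and RR per
#' scope, the bias estimands, the survival terms `q(x, z)`, and the
#' marginal censoring proportion.
#'
#' @param params A one-row setup tibble.
#' @return A two-row tibble (one per stratum).
#' @export
analytic_expectations <- function(params) {
  b <- expected_bias(params)
  z <- b$stratum
  q0 <- vapply(z, function(zz) q_surv(params, 0, zz), numeric(1))
  q1 <- vapply(z, function(zz) q_surv(params, 1, zz), numeric(1))
  r0 <- vapply(z, function(zz) p_outcome(params, zz, m = 0), numeric(1))
  r1 <- vapply(z, function(zz) p_outcome(params, zz, m = 1), numeric(1))
  tibble::tibble(
    setup_id = params$setup_id,
    stratum = z,
    q_unexposed = q0, q_exposed = q1,
    censoring = expected_censoring(params),
    risk_exposed_observed = r1, risk_unexposed_observed = r0,
    risk_exposed_unobserved = q1 * r1, risk_unexposed_unobserved = q0 * r0,
    rd_observed = r1 - r0, rd_unobserved = q1 * r1 - q0 * r0,
    rr_observed = r1 / r0, rr_unobserved = (q1 * r1) / (q0 * r0),
    rd_bias = b$rd_bias,
    rr_relative_bias = b$rr_relative_bias
  )
}

#' Expectations across a scenario grid
#'
#' Per-setup analytic expectations plus across-grid min/max spans per
#' stratum and quantity — the analytic counterpart of the ranges reported
#' across simulation setups.
#'
#' @param grid A scenario grid from [build_grid()].
#' @return A list with `per_setup` (one row per setup and stratum) and
#'   `spans` (one row per stratum and quantity, columns `min` and `max`).
#' @export
#' @examples
#' grid_expectations(build_grid("primary"))$spans
grid_expectations <- function(grid) {
  stopifnot(nrow(grid) >= 1L)
  per_setup <- dplyr::bind_rows(
    lapply(seq_len(nrow(grid)), function(i) analytic_expectations(grid[i, ]))
  )
  spans <- per_setup |>
    tidyr::pivot_longer(
      -c("setup_id", "stratum"),
      names_to = "quantity", values_to = "value"
    ) |>
    dplyr::group_by(.data$stratum, .data$quantity) |>
    dplyr::summarise(min = min(.data$value), max = max(.data$value),
                     .groups = "drop")
  list(per_setup = per_setup, spans = spans)
}
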