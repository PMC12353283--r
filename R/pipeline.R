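# End-to-end orchestration: grid -> simulate -> estimate -> bias ->
# aggregate -> compare with the closed-form expectations. All tabular
# outputs are plain CSV with provenance columns; runs are bit-reproducible
# under a fixed master seed.

# Reporting conventions, stated once and used everywhere: risks and RD-type
# quantities are reported as percentages rounded to the nearest integer,
# fold-type (RR) quantities to one decimal.
round_percent <- function(x) round(100 * x)
round_fold <- function(x) round(x, 1)

#' Run the full simulation pipeline
#'
#' Builds the requested scenario families, simulates replicate cohorts for
#' every setup, estimates stratified effects under both analysis scopes,
#' computes the bias estimands, aggregates across replicates, tabulates the
#' closed-form expectations, and (optionally) juxtaposes simulated spans
#' with the analytic ones. Writes each table as CSV into `out_dir` along
#' with a plain-text log; identical configuration and seed give
#' byte-identical CSVs.
#'
#' @param families Character vector of families to run (any of `"primary"`,
#'   `"sensitivity_mortality"`, `"sensitivity_stillbirth"`).
#' @param n_replicates Replicate cohorts per setup (study default 200).
#' @param n_total Conceptuses per cohort (study default 100,000).
#' @param master_seed Integer master seed.
#' @param out_dir Output directory; created if missing. `NULL` skips all
#'   file output and just returns the tables.
#' @param px_mode Passed to [simulate_study()].
#' @param paper_comparison Add a table juxtaposing simulated across-setup
#'   spans with analytic expectations, in reporting units.
#' @param figures Also write distribution figures (PDF) via
#'   [render_figures()].
#' @return Invisibly, a list of tibbles: `grid`, `estimates`, `bias`,
#'   `aggregates`, `oracle`, and `comparison` (when requested), plus
#'   `paths` of written files.
#' @export
run_pipeline <- function(families = "primary",
                         n_replicates = 200L,
                         n_total = 100000L,
                         master_seed = 1L,
                         out_dir = NULL,
                         px_mode = c("per_cohort", "midpoint"),
                         paper_comparison = TRUE,
                         figures = FALSE) {
  px_mode <- match.arg(px_mode)
  if (n_replicates < 1 || n_total < 1) {
    stop("usage error: n_replicates and n_total must be >= 1")
  }
  bad <- setdiff(families, c("primary", "sensitivity_mortality",
                             "sensitivity_stillbirth"))
  if (length(bad)) stop("usage error: unknown analysis family ", bad[1])

  t0 <- Sys.time()
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(format(...)))
  }

  grid <- dplyr::bind_rows(lapply(unique(families), build_grid))
  est_list <- vector("list", nrow(grid))
  bias_list <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    counts <- simulate_study(grid[i, ], n_replicates, n_total, master_seed,
                             px_mode)
    est <- estimate_effects(counts, "both")
    b <- compute_bias(est)
    est_list[[i]] <- est
    bias_list[[i]] <- b
    say(sprintf("setup %d: %d replicates, %d excluded",
                grid$setup_id[i], n_replicates, sum(!b$defined) %/% 2L))
  }
  estimates <- dplyr::bind_rows(est_list)
  bias <- dplyr::bind_rows(bias_list)
  aggregates <- dplyr::bind_rows(
    aggregate_estimates(estimates),
    aggregate_estimates(bias)
  )
  oracle <- grid_expectations(grid)$per_setup

  comparison <- if (paper_comparison) {
    paper_comparison_table(grid, bias, estimates)
  }

  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(tbl, name) {
      p <- file.path(out_dir, name)
      readr::write_csv(tbl, p)
      paths[[name]] <<- p
    }
    wr(grid, "grid.csv")
    wr(estimates, "estimates.csv")
    wr(bias, "bias.csv")
    wr(aggregates, "aggregates.csv")
    wr(oracle, "oracle.csv")
    if (!is.null(comparison)) wr(comparison, "paper_comparison.csv")
    say(sprintf("run complete in %.1f s", as.numeric(Sys.time() - t0, "secs")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    if (figures) {
      figs <- render_figures(estimates, bias)
      for (nm in names(figs)) {
        ggplot2::ggsave(file.path(out_dir, paste0(nm, ".pdf")), figs[[nm]],
                        width = 8, height = 5)
      }
    }
  }
  invisible(list(grid = grid, estimates = estimates, bias = bias,
                 aggregates = aggregates, oracle = oracle,
                 comparison = comparison, paths = paths))
}

# Across-setup spans of per-setup replicate means, next to analytic spans,
# in reporting units. One row per (family, stratum, quantity).
paper_comparison_table <- function(grid, bias, estimates) {
  fam <- grid[c("setup_id", "analysis_family")]
  per_setup <- bias |>
    dplyr::group_by(.data$setup_id, .data$stratum) |>
    dplyr::summarise(
      rd_bias = mean(.data$rd_bias, na.rm = TRUE),
      rr_relative_bias = mean(.data$rr_relative_bias, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::left_join(fam, by = "setup_id")
  # marginal censoring: 1 - (surviving denominators / all-conception
  # denominators), per replicate, then averaged per setup
  cens <- estimates |>
    dplyr::group_by(.data$setup_id, .data$replicate_id) |>
    dplyr::summarise(
      value = 1 - sum(.data$denom_exposed[.data$scope == "observed"] +
                        .data$denom_unexposed[.data$scope == "observed"]) /
        sum(.data$denom_exposed[.data$scope == "unobserved"] +
              .data$denom_unexposed[.data$scope == "unobserved"]),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$setup_id) |>
    dplyr::summarise(censoring = mean(.data$value), .groups = "drop") |>
    dplyr::left_join(fam, by = "setup_id")
  oracle <- grid_expectations(grid)$per_setup |>
    dplyr::left_join(fam, by = "setup_id")
  sim_spans <- dplyr::bind_rows(
    per_setup |>
      tidyr::pivot_longer(c("rd_bias", "rr_relative_bias"),
                          names_to = "quantity", values_to = "value") |>
      dplyr::group_by(.data$analysis_family, .data$stratum, .data$quantity) |>
      dplyr::summarise(sim_min = min(.data$value), sim_max = max(.data$value),
                       .groups = "drop"),
    cens |>
      dplyr::group_by(.data$analysis_family) |>
      dplyr::summarise(sim_min = min(.data$censoring),
                       sim_max = max(.data$censoring), .groups = "drop") |>
      dplyr::mutate(stratum = NA_integer_, quantity = "censoring")
  )
  ana_spans <- dplyr::bind_rows(
    oracle |>
      tidyr::pivot_longer(c("rd_bias", "rr_relative_bias"),
                          names_to = "quantity", values_to = "value") |>
      dplyr::group_by(.data$analysis_family, .data$stratum, .data$quantity) |>
      dplyr::summarise(analytic_min = min(.data$value),
                       analytic_max = max(.data$value), .groups = "drop"),
    oracle |>
      dplyr::filter(.data$stratum == 0) |>
      dplyr::group_by(.data$analysis_family) |>
      dplyr::summarise(analytic_min = min(.data$censoring),
                       analytic_max = max(.data$censoring), .groups = "drop") |>
      dplyr::mutate(stratum = NA_integer_, quantity = "censoring")
  )
  dplyr::left_join(sim_spans, ana_spans,
                   by = c("analysis_family", "stratum", "quantity")) |>
    dplyr::mutate(
      # reporting conventions: RD bias to integer percent, RR bias to one
      # decimal fold, censoring to one-decimal percent
      reported_min = dplyr::case_when(
        .data$quantity == "rd_bias" ~ round_percent(.data$sim_min),
        .data$quantity == "censoring" ~ round(100 * .data$sim_min, 1),
        TRUE ~ round_fold(.data$sim_min)
      ),
      reported_max = dplyr::case_when(
        .data$quantity == "rd_bias" ~ round_percent(.data$sim_max),
        .data$quantity == "censoring" ~ round(100 * .data$sim_max, 1),
        TRUE ~ round_fold(.data$sim_max)
      ),
      units = ifelse(.data$quantity == "rr_relative_bias", "fold", "percent")
    )
}

#' Distribution figures across setups
#'
#' Strip/interval plots of per-replicate risks, risk differences and risk
#' ratios across setups, observed versus unobserved scope, faceted by
#' placentation stratum; plus the corresponding bias panels.
#'
#' @param estimates Estimate tibble from [estimate_effects()].
#' @param bias Optional bias tibble from [compute_bias()].
#' @return A named list of ggplot objects (`risks`, `rd`, `rr`, and `bias`
#'   when bias results are supplied); empty input returns an empty list
#'   with a warning.
#' @export
render_figures <- function(estimates, bias = NULL) {
  if (is.null(estimates) || nrow(estimates) == 0L) {
    warning("no estimates: no figures rendered")
    return(list())
  }
  est <- dplyr::mutate(
    estimates,
    setup = factor(.data$setup_id),
    stratum_lab = ifelse(.data$stratum == 1, "abnormal placentation",
                         "normal placentation")
  )
  strip <- function(d, yvar, ylab) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$setup, y = .data[[yvar]],
                                    colour = .data$scope)) +
      ggplot2::geom_jitter(width = 0.2, alpha = 0.25, size = 0.5) +
      ggplot2::stat_summary(fun = stats::median, geom = "point", shape = 3,
                            size = 2) +
      ggplot2::facet_wrap(~stratum_lab, scales = "free_y") +
      ggplot2::labs(x = "simulation setup", y = ylab, colour = "scope") +
      ggplot2::theme_minimal()
  }
  long <- tidyr::pivot_longer(est, c("risk_exposed", "risk_unexposed"),
                              names_to = "arm", values_to = "risk")
  figs <- list(
    risks = strip(long, "risk", "outcome risk") +
      ggplot2::aes(shape = .data$arm),
    rd = strip(est, "rd", "risk difference"),
    rr = strip(est, "rr", "risk ratio")
  )
  if (!is.null(bias) && nrow(bias) > 0L) {
    b <- dplyr::mutate(
      bias,
      setup = factor(.data$setup_id),
      stratum_lab = ifelse(.data$stratum == 1, "abnormal placentation",
                           "normal placentation")
    )
    figs$bias <- ggplot2::ggplot(
      b, ggplot2::aes(x = .data$setup, y = .data$rr_relative_bias)
    ) +
      ggplot2::geom_jitter(width = 0.2, alpha = 0.25, size = 0.5) +
      ggplot2::facet_wrap(~stratum_lab, scales = "free_y") +
      ggplot2::labs(x = "simulation setup",
                    y = "relative bias of RR (observed / unobserved)") +
      ggplot2::theme_minimal()
  }
  figs
}
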