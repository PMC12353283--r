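# Cohort simulation by nested binomial sampling. The data-generating
# mechanism is exchangeable within each (placentation, abruption-onset,
# SAB) cell, so sampling cell counts from sequential binomials is
# distributionally identical to drawing each conceptus individually and is
# the package's workhorse representation.

# Conditional probabilities of the two multiplicative risk models.
p_sab <- function(params, z, x) {
  params$pC_base * params$rr_C_Z^z * params$rr_C_X^x *
    params$rr_C_interaction^(x * z)
}

p_outcome <- function(params, z, m) {
  params$pOut_base * params$rr_Out_M^m * params$rr_Out_Z^z *
    params$rr_Out_interaction^(m * z)
}

#' Draw per-cohort abruption-onset probabilities
#'
#' Each simulated cohort receives its own abruption-onset probability per
#' placentation stratum, drawn uniformly from the stratum's support. This
#' gives every replicate a coherent cohort-level abruption rate and induces
#' realistic between-replicate variability.
#'
#' @param params A one-row setup tibble from [scenario_params()].
#' @param n Number of independent draws (cohorts).
#' @return A tibble with columns `pX_Z1` and `pX_Z0`, `n` rows.
#' @export
draw_abruption_probs <- function(params, n = 1L) {
  tibble::tibble(
    pX_Z1 = stats::runif(n, params$pX_lo_Z1, params$pX_hi_Z1),
    pX_Z0 = stats::runif(n, params$pX_lo_Z0, params$pX_hi_Z0)
  )
}

#' Probability of a single cell of the data-generating mechanism
#'
#' The joint probability of one `(z, x, c, y)` configuration:
#' `Pr(Z = z) * Pr(X = x | Z = z) * Pr(C = c | Z = z, X = x) *
#' Pr(outcome = y | ...)`. SAB precludes the outcome, so
#' `Pr(y = 1 | c = 1) = 0`; among survivors the abruption diagnosis equals
#' the onset indicator (`m = x` when `c = 0`), so the outcome model is
#' evaluated at `m = x`.
#'
#' @param params A one-row setup tibble.
#' @param pX_Z1,pX_Z0 The realised abruption-onset probabilities for this
#'   cohort (e.g. from [draw_abruption_probs()]).
#' @param z,x,c,y Binary cell indicators; vectorised.
#' @return Numeric vector of joint cell probabilities.
#' @export
#' @examples
#' p <- scenario_params(rr_C_Z = 4, rr_C_X = 4.5, rr_Out_Z = 4)
#' cell_probability(p, 0.0275, 0.0105, z = 1, x = 1, c = 0, y = 1)
cell_probability <- function(params, pX_Z1, pX_Z0, z, x, c, y) {
  pC <- p_sab(params, z, x)
  pY <- ifelse(c == 1, 0, p_outcome(params, z, m = x))
  if (any(pC < 0 | pC > 1) || any(pY < 0 | pY > 1)) {
    stop("invalid parameters: a conditional event probability falls outside [0, 1]")
  }
  pZ <- ifelse(z == 1, params$pi_Z, 1 - params$pi_Z)
  pX <- ifelse(z == 1,
               ifelse(x == 1, pX_Z1, 1 - pX_Z1),
               ifelse(x == 1, pX_Z0, 1 - pX_Z0))
  pZ * pX * ifelse(c == 1, pC, 1 - pC) * ifelse(y == 1, pY, 1 - pY)
}

#' All sixteen cell probabilities of one cohort
#'
#' @inheritParams cell_probability
#' @return A tibble with columns `z`, `x`, `c`, `y`, `prob`; the 16 `prob`
#'   values sum to 1.
#' @export
cell_probabilities <- function(params, pX_Z1, pX_Z0) {
  cells <- expand.grid(y = 0:1, c = 0:1, x = 0:1, z = 0:1)
  tibble::tibble(
    z = cells$z, x = cells$x, c = cells$c, y = cells$y,
    prob = cell_probability(params, pX_Z1, pX_Z0,
                            cells$z, cells$x, cells$c, cells$y)
  )
}

# Vectorised core: R replicate cohorts of one setup, counts for the 16
# (z, x, c, y) cells. Draw order is fixed (pX pair, then binomials by
# descending z, x) so results are reproducible for a given RNG state.
simulate_counts <- function(params, n_replicates, n_total,
                            px_mode = c("per_cohort", "midpoint")) {
  px_mode <- match.arg(px_mode)
  R <- n_replicates
  if (px_mode == "per_cohort") {
    px <- draw_abruption_probs(params, R)
  } else {
    px <- tibble::tibble(
      pX_Z1 = rep((params$pX_lo_Z1 + params$pX_hi_Z1) / 2, R),
      pX_Z0 = rep((params$pX_lo_Z0 + params$pX_hi_Z0) / 2, R)
    )
  }
  n_z <- list()
  n_z[["1"]] <- stats::rbinom(R, n_total, params$pi_Z)
  n_z[["0"]] <- n_total - n_z[["1"]]

  out <- vector("list", 4L)
  i <- 1L
  for (z in c(1L, 0L)) {
    pX <- if (z == 1L) px$pX_Z1 else px$pX_Z0
    n_x1 <- stats::rbinom(R, n_z[[as.character(z)]], pX)
    for (x in c(1L, 0L)) {
      n_zx <- if (x == 1L) n_x1 else n_z[[as.character(z)]] - n_x1
      n_c1 <- stats::rbinom(R, n_zx, p_sab(params, z, x))
      n_c0 <- n_zx - n_c1
      n_y1 <- stats::rbinom(R, n_c0, p_outcome(params, z, m = x))
      out[[i]] <- tibble::tibble(
        replicate_id = rep(seq_len(R), times = 4L),
        z = z, x = x,
        c = rep(c(1L, 1L, 0L, 0L), each = R),
        y = rep(c(0L, 1L, 0L, 1L), each = R),
        n = c(n_c1, integer(R), n_c0 - n_y1, n_y1)
      )
      i <- i + 1L
    }
  }
  counts <- dplyr::bind_rows(out)
  counts$drawn_pX_Z1 <- px$pX_Z1[counts$replicate_id]
  counts$drawn_pX_Z0 <- px$pX_Z0[counts$replicate_id]
  counts
}

#' Simulate one cohort of implanted conceptuses
#'
#' Conceptuses are allocated to the 16 `(z, x, c, y)` cells by sequential
#' binomial draws: abnormal placentation `Z`, abruption onset `X` within
#' stratum (at the cohort's drawn onset probability), SAB `C` within each
#' `(Z, X)` cell under the multiplicative SAB model, and the outcome within
#' each surviving `(Z, X, C = 0)` cell under the multiplicative outcome
#' model. Cells with `C = 1` receive outcome count 0: SAB precludes
#' stillbirth and neonatal death. The clinical diagnosis `M` is not stored
#' because it is deterministic — missing under SAB, equal to `X` otherwise.
#'
#' Uses the current RNG state; seed beforehand or use [simulate_study()] for
#' a self-seeding replicate set.
#'
#' @param params A one-row setup tibble from [scenario_params()].
#' @param n_total Number of implanted conceptuses (study default 100,000).
#' @param px_mode `"per_cohort"` draws the abruption-onset probability once
#'   per cohort per stratum; `"midpoint"` fixes it at the support midpoint.
#' @return A tibble of 16 rows: `setup_id`, `replicate_id`, `n_total`,
#'   `drawn_pX_Z1`, `drawn_pX_Z0`, the cell indicators `z`, `x`, `c`, `y`,
#'   and the count `n`.
#' @export
#' @examples
#' set.seed(1)
#' ch <- simulate_cohort(scenario_params(), n_total = 1000)
#' sum(ch$n)  # 1000
simulate_cohort <- function(params, n_total = 100000L,
                            px_mode = c("per_cohort", "midpoint")) {
  if (n_total <= 0) stop("empty cohort: n_total must be positive")
  v <- validate_params(params)
  if (!v$valid) stop("invalid parameters: implied event probability exceeds 1")
  counts <- simulate_counts(params, 1L, n_total, px_mode)
  counts$setup_id <- params$setup_id
  counts$n_total <- as.integer(n_total)
  counts[c("setup_id", "replicate_id", "n_total", "drawn_pX_Z1", "drawn_pX_Z0",
           "z", "x", "c", "y", "n")]
}

# Deterministic per-setup seed below 2^31, derived from the master seed.
setup_seed <- function(master_seed, setup_id) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(setup_id) * 16807) %%
               2147483647)
}

#' Simulate a replicate study for one setup
#'
#' Generates `n_replicates` independent cohorts under one setup. The RNG is
#' seeded deterministically from `master_seed` and the setup's `setup_id`,
#' so a master seed reproduces the whole study bit-identically while
#' different setups use disjoint streams.
#'
#' @inheritParams simulate_cohort
#' @param n_replicates Number of replicate cohorts (study default 200).
#' @param master_seed Integer master seed for the study.
#' @return A long tibble of `16 * n_replicates` cell rows with the same
#'   columns as [simulate_cohort()], plus a `seed` provenance column holding
#'   the derived per-setup seed.
#' @export
simulate_study <- function(params, n_replicates = 200L, n_total = 100000L,
                           master_seed = 1L,
                           px_mode = c("per_cohort", "midpoint")) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (n_total <= 0) stop("empty cohort: n_total must be positive")
  v <- validate_params(params)
  if (!v$valid) stop("invalid parameters: implied event probability exceeds 1")
  seed <- setup_seed(master_seed, params$setup_id)
  withr_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(withr_seed)) assign(".Random.seed", withr_seed,
                                           envir = globalenv()))
  set.seed(seed)
  counts <- simulate_counts(params, n_replicates, n_total, px_mode)
  counts$setup_id <- params$setup_id
  counts$n_total <- as.integer(n_total)
  counts$seed <- seed
  dplyr::arrange(
    counts[c("setup_id", "replicate_id", "seed", "n_total",
             "drawn_pX_Z1", "drawn_pX_Z0", "z", "x", "c", "y", "n")],
    .data$replicate_id, dplyr::desc(.data$z), dplyr::desc(.data$x),
    dplyr::desc(.data$c), .data$y
  )
}

#' Simulate every setup of a grid
#'
#' Convenience wrapper running [simulate_study()] over each row of a
#' scenario grid and binding the results.
#'
#' @param grid A scenario grid from [build_grid()].
#' @inheritParams simulate_study
#' @return A long cell-count tibble covering all setups.
#' @export
simulate_grid <- function(grid, n_replicates = 200L, n_total = 100000L,
                          master_seed = 1L,
                          px_mode = c("per_cohort", "midpoint")) {
  px_mode <- match.arg(px_mode)
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    simulate_study(grid[i, ], n_replicates, n_total, master_seed, px_mode)
  }))
}

#' Per-replicate marginal censoring proportion
#'
#' Fraction of each cohort lost to spontaneous abortion before 20 weeks —
#' the conceptuses a birth-cohort design never sees.
#'
#' @param counts A cell-count tibble.
#' @return A tibble with one row per (setup, replicate) and the `censoring`
#'   proportion.
#' @export
marginal_censoring <- function(counts) {
  counts |>
    dplyr::group_by(.data$setup_id, .data$replicate_id) |>
    dplyr::summarise(censoring = sum(.data$n[.data$c == 1L]) / sum(.data$n),
                     .groups = "drop")
}

#' Expand cell counts to individual conceptus records
#'
#' Emits one row per conceptus with columns `z`, `x`, `c`, `m`, `y`, where
#' the diagnosis `m` is reconstructed as `NA` under SAB and `x` otherwise.
#' Intended for small fixtures; the cell-count representation is the
#' workhorse.
#'
#' @param counts A cell-count tibble from [simulate_cohort()].
#' @return A tibble with one row per conceptus.
#' @export
expand_individuals <- function(counts) {
  idx <- rep(seq_len(nrow(counts)), counts$n)
  out <- tibble::tibble(
    z = counts$z[idx], x = counts$x[idx], c = counts$c[idx], y = counts$y[idx]
  )
  out$m <- ifelse(out$c == 1L, NA_integer_, out$x)
  out[c("z", "x", "c", "m", "y")]
}
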