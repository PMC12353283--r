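test_that("risks, RD and RR match hand arithmetic on a toy cohort", {
  est <- estimate_effects(toy_cells(), "both")
  un <- est[est$scope == "unobserved", ]
  ob <- est[est$scope == "observed", ]
  # unexposed arm: 1000 conceptions, 50 SAB, 8 deaths
  expect_equal(un$risk_unexposed, 8 / 1000)
  expect_equal(ob$risk_unexposed, 8 / 950)
  # exposed arm: 100 conceptions, 20 SAB, 10 deaths
  expect_equal(un$risk_exposed, 10 / 100)
  expect_equal(ob$risk_exposed, 10 / 80)
  expect_equal(un$rd, 10 / 100 - 8 / 1000)
  expect_equal(ob$rr, (10 / 80) / (8 / 950))
  expect_true(all(est$defined))
  # left truncation shrinks denominators only: observed risk >= unobserved
  expect_true(all(ob$risk_exposed >= un$risk_exposed))
  expect_true(all(ob$risk_unexposed >= un$risk_unexposed))
})

test_that("without SAB the two scopes coincide", {
  p <- scenario_params(pC_base = 0)
  set.seed(41)
  ch <- simulate_cohort(p, n_total = 20000)
  est <- estimate_effects(ch, "both")
  un <- est[est$scope == "unobserved", ]
  ob <- est[est$scope == "observed", ]
  expect_equal(ob$risk_exposed, un$risk_exposed)
  expect_equal(ob$risk_unexposed, un$risk_unexposed)
  expect_equal(ob$rr, un$rr)
})

test_that("zero denominators are flagged, not silently corrected", {
  cells <- toy_cells()
  cells$n[cells$x == 1L] <- 0L  # no exposed conceptuses at all
  est <- estimate_effects(cells, "both")
  expect_true(all(!est$defined))
  expect_true(all(is.na(est$risk_exposed)))
  # the unexposed arm is still estimated
  expect_equal(est$risk_unexposed[est$scope == "unobserved"], 8 / 1000)
})

test_that("observed RR recovers the generative diagnosis-outcome risk ratio", {
  p <- build_grid("primary")[1, ]
  est <- estimate_effects(
    simulate_study(p, 150, 100000, master_seed = 51), "observed"
  )
  mean_rr0 <- mean(est$rr[est$stratum == 0], na.rm = TRUE)
  # Monte-Carlo + small-sample ratio tolerance around exp(a1) = 14.5
  expect_lt(abs(mean_rr0 - 14.5), 0.7)
})

test_that("the saturated log-binomial fit reproduces closed-form cell risks", {
  p <- build_grid("primary")[7, ]
  cts <- simulate_study(p, 3, 100000, master_seed = 61)
  for (r in 1:3) {
    ch <- cts[cts$replicate_id == r, ]
    est <- estimate_effects(ch, "both")
    for (sc in c("observed", "unobserved")) {
      fit <- fit_saturated_log_binomial(ch, sc)
      expect_true(fit$estimable)
      expect_true(fit$converged)
      e <- est[est$scope == sc, ]
      co <- fit$coefficients
      # saturated-model identities: exp(a0) = stratum-0 unexposed risk,
      # exp(a1) = stratum-0 RR, exp(a1 + a3) = stratum-1 RR
      expect_equal(exp(co[["a0"]]), e$risk_unexposed[e$stratum == 0],
                   tolerance = 1e-8)
      expect_equal(exp(co[["a1"]]), e$rr[e$stratum == 0], tolerance = 1e-8)
      expect_equal(exp(co[["a1"]] + co[["a3"]]), e$rr[e$stratum == 1],
                   tolerance = 1e-8)
      risks <- dplyr::arrange(fit$fitted_risks, stratum, x)
      closed <- c(e$risk_unexposed[e$stratum == 0], e$risk_exposed[e$stratum == 0],
                  e$risk_unexposed[e$stratum == 1], e$risk_exposed[e$stratum == 1])
      expect_equal(risks$risk, closed, tolerance = 1e-8)
    }
  }
  expect_error(fit_saturated_log_binomial(cts), "single cohort")
})

test_that("a cohort with an empty or zero-event cell is inestimable", {
  cells <- toy_cells_two_strata()
  cells$n[cells$z == 1L & cells$x == 1L & cells$y == 1L] <- 0L
  fit <- fit_saturated_log_binomial(cells, "observed")
  expect_false(fit$estimable)
  expect_true(all(is.na(fit$coefficients)))
})

test_that("per-cohort truncation identity: RR ratio equals survival-fraction ratio", {
  p <- build_grid("primary")[4, ]
  cts <- simulate_study(p, 50, 50000, master_seed = 81)
  est <- estimate_effects(cts, "both")
  for (r in unique(est$replicate_id)) {
    ch <- cts[cts$replicate_id == r, ]
    q <- empirical_q(ch)
    e <- est[est$replicate_id == r, ]
    for (s in 0:1) {
      rr_o <- e$rr[e$scope == "observed" & e$stratum == s]
      rr_u <- e$rr[e$scope == "unobserved" & e$stratum == s]
      if (is.na(rr_o) || is.na(rr_u) || rr_u == 0) next
      expect_equal(rr_o / rr_u,
                   q$q[q$z == s & q$x == 0] / q$q[q$z == s & q$x == 1],
                   tolerance = 1e-12)
    }
  }
})
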