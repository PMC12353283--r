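test_that("per-cohort abruption probabilities respect their uniform supports", {
  p <- scenario_params()
  set.seed(11)
  d <- draw_abruption_probs(p, 5000)
  expect_true(all(d$pX_Z1 >= 0.005 & d$pX_Z1 <= 0.050))
  expect_true(all(d$pX_Z0 >= 0.001 & d$pX_Z0 <= 0.020))
  # means converge to the support midpoints (4 MC standard errors)
  se1 <- (0.050 - 0.005) / sqrt(12 * 5000)
  se0 <- (0.020 - 0.001) / sqrt(12 * 5000)
  expect_lt(abs(mean(d$pX_Z1) - 0.0275), 4 * se1)
  expect_lt(abs(mean(d$pX_Z0) - 0.0105), 4 * se0)

  # zero-width support is degenerate
  pz <- scenario_params(pX_range_Z1 = c(0.02, 0.02))
  expect_true(all(draw_abruption_probs(pz, 10)$pX_Z1 == 0.02))
})

test_that("cell probabilities follow the multiplicative risk models and sum to 1", {
  p <- scenario_params(rr_C_Z = 4, rr_C_X = 4.5, rr_Out_Z = 4)
  cp <- cell_probabilities(p, pX_Z1 = 0.0275, pX_Z0 = 0.0105)
  expect_equal(sum(cp$prob), 1)
  # SAB precludes the outcome: every (c = 1, y = 1) cell has probability 0
  expect_true(all(cp$prob[cp$c == 1 & cp$y == 1] == 0))
  # joint cell = Pr(Z) Pr(X|Z) Pr(C|Z,X) Pr(Y|M,Z,C=0), with
  # Pr(C=1|Z=1,X=1) = 0.05*4*4.5 = 0.9 and
  # Pr(Y=1|M=1,Z=1,C=0) = 0.0082*14.5*4 = 0.4756
  expect_equal(
    cell_probability(p, 0.0275, 0.0105, z = 1, x = 1, c = 0, y = 1),
    0.1 * 0.0275 * (1 - 0.9) * 0.4756
  )
  expect_equal(
    cell_probability(p, 0.0275, 0.0105, z = 0, x = 0, c = 1, y = 0),
    0.9 * (1 - 0.0105) * 0.05
  )
  # a setup whose fitted SAB risk exceeds 1 is rejected
  bad <- scenario_params(rr_C_Z = 6, rr_C_X = 4.5)
  expect_error(cell_probability(bad, 0.0275, 0.0105, 1, 1, 0, 0), "invalid")
})

test_that("simulated cohorts conserve conceptuses and forbid impossible cells", {
  p <- scenario_params(rr_C_Z = 4, rr_C_X = 2, rr_Out_Z = 4)
  set.seed(21)
  ch <- simulate_cohort(p, n_total = 20000)
  expect_equal(nrow(ch), 16L)
  expect_equal(sum(ch$n), 20000)
  expect_true(all(ch$n >= 0))
  expect_true(all(ch$n[ch$c == 1 & ch$y == 1] == 0))
  expect_true(ch$drawn_pX_Z1[1] >= 0.005 && ch$drawn_pX_Z1[1] <= 0.050)
  expect_error(simulate_cohort(p, n_total = 0), "empty cohort")
  expect_error(simulate_cohort(scenario_params(rr_C_Z = 6, rr_C_X = 4.5)),
               "invalid")
})

test_that("degenerate probabilities push all mass into the (z=0, x=0) cells", {
  p <- scenario_params(pi_Z = 0, pX_range_Z1 = c(0, 0), pX_range_Z0 = c(0, 0))
  set.seed(5)
  ch <- simulate_cohort(p, n_total = 5000)
  expect_equal(sum(ch$n[ch$z == 0 & ch$x == 0]), 5000)
})

test_that("replicate studies are reproducible and replicates independent", {
  p <- build_grid("primary")[1, ]
  a <- simulate_study(p, n_replicates = 20, n_total = 5000, master_seed = 123)
  b <- simulate_study(p, n_replicates = 20, n_total = 5000, master_seed = 123)
  expect_identical(a, b)
  c2 <- simulate_study(p, n_replicates = 20, n_total = 5000, master_seed = 124)
  expect_false(identical(a$n, c2$n))
  expect_equal(length(unique(a$replicate_id)), 20L)
  expect_true(all(tapply(a$n, a$replicate_id, sum) == 5000))

  # successive replicates draw independent abruption probabilities
  d <- simulate_study(p, n_replicates = 400, n_total = 100, master_seed = 9)
  px <- unique(d[c("replicate_id", "drawn_pX_Z1")])$drawn_pX_Z1
  expect_lt(abs(stats::cor(px[-1], px[-length(px)])), 0.15)
})

test_that("empirical cell frequencies converge to the cell probabilities", {
  p <- build_grid("primary")[8, ]  # the most extreme valid setup
  set.seed(31)
  n <- 1e6
  ch <- simulate_cohort(p, n_total = n, px_mode = "midpoint")
  cp <- cell_probabilities(p, 0.0275, 0.0105)
  m <- dplyr::inner_join(ch, cp, by = c("z", "x", "c", "y"))
  expect_equal(nrow(m), 16L)
  # structural zeros are exact; the rest within 4 binomial SEs
  expect_true(all(m$n[m$prob == 0] == 0))
  live <- m[m$prob > 0, ]
  se <- sqrt(live$prob * (1 - live$prob) / n)
  expect_true(all(abs(live$n / n - live$prob) < 4 * se + 1e-9))
})

test_that("expected censoring is invariant to the abruption-probability draw level", {
  p <- build_grid("primary")[5, ]
  per_cohort <- simulate_study(p, 300, 50000, master_seed = 71,
                               px_mode = "per_cohort")
  midpoint <- simulate_study(p, 300, 50000, master_seed = 72,
                             px_mode = "midpoint")
  c1 <- marginal_censoring(per_cohort)$censoring
  c2 <- marginal_censoring(midpoint)$censoring
  se <- sqrt(stats::var(c1) / 300 + stats::var(c2) / 300)
  expect_lt(abs(mean(c1) - mean(c2)), 4 * se)
  expect_lt(abs(mean(c1) - expected_censoring(p)), 4 * sqrt(var(c1) / 300))
})

test_that("individual-level expansion reconstructs the diagnosis variable", {
  ind <- expand_individuals(toy_cells())
  expect_equal(nrow(ind), 1100L)
  expect_true(all(is.na(ind$m[ind$c == 1])))
  expect_true(all(ind$m[ind$c == 0] == ind$x[ind$c == 0]))
  expect_equal(sum(ind$y), 18L)
})
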