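# Shared fixtures, built in code.

# A hand-sized two-arm cohort in stratum z = 0 with known cell counts:
#   x = 0: 1000 conceptuses, 50 SAB, 8 deaths among the 950 survivors
#   x = 1:  100 conceptuses, 20 SAB, 10 deaths among the 80 survivors
# Closed-form truths used in tests:
#   unobserved risks 8/1000 and 10/100; observed risks 8/950 and 10/80
#   rr_obs / rr_unobs = q(0)/q(1) = 0.95 / 0.80 = 1.1875
toy_cells <- function() {
  tibble::tibble(
    setup_id = 99L, replicate_id = 1L,
    z = 0L,
    x = rep(c(0L, 0L, 0L, 1L, 1L, 1L), 1),
    c = c(1L, 0L, 0L, 1L, 0L, 0L),
    y = c(0L, 1L, 0L, 0L, 1L, 0L),
    n = c(50L, 8L, 942L, 20L, 10L, 70L)
  )
}

# Same cohort with an (uninteresting) z = 1 stratum so the saturated model
# has all four cells.
toy_cells_two_strata <- function() {
  z1 <- tibble::tibble(
    setup_id = 99L, replicate_id = 1L,
    z = 1L,
    x = c(0L, 0L, 0L, 1L, 1L, 1L),
    c = c(1L, 0L, 0L, 1L, 0L, 0L),
    y = c(0L, 1L, 0L, 0L, 1L, 0L),
    n = c(30L, 6L, 264L, 10L, 8L, 22L)
  )
  dplyr::bind_rows(toy_cells(), z1)
}

# Empirical SAB-survival fractions q(x, z) of a single cohort.
empirical_q <- function(counts) {
  counts |>
    dplyr::group_by(z, x) |>
    dplyr::summarise(q = sum(n[c == 0L]) / sum(n), .groups = "drop")
}
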