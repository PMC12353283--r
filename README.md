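# lefttruncsim

Monte-Carlo quantification of left-truncation bias in perinatal cohort
studies, for epidemiologists and biostatisticians who work with
pregnancy cohorts or teach selection bias.

## The problem

Studies of placental abruption and perinatal mortality enrol pregnancies
at ≥ 20 weeks of gestation, because abruption is rarely diagnosable
earlier. Yet abruption onset and its main precursor, abnormal
placentation, arise around implantation, and both sharply raise the risk
of spontaneous abortion (SAB) before 20 weeks. Entry conditional on
surviving the SAB window therefore deletes precisely the pregnancies where
the exposure did the most harm. When the causal question targets **all
conceptions**, the left-truncated "birth cohort" answer is biased relative
to the "conception cohort" answer.

`lefttruncsim` simulates the conception cohort and measures that bias.
Each implanted conceptus carries abnormal placentation `Z`, early
abruption onset `X` (cohort-level probability drawn from a uniform
support per stratum), SAB `C` from the multiplicative risk model

    Pr(C = 1 | Z, X) = pC_base · rr_C_Z^Z · rr_C_X^X,

a deterministic ≥ 20-week diagnosis `M` (missing if `C = 1`, else `X`),
and perinatal mortality `Y` (zero under SAB; among survivors
`Pr(Y = 1 | M, Z) = pOut_base · rr_Out_M^M · rr_Out_Z^Z`). Stratified by
`Z`, each simulated cohort is analysed twice — all conceptions
("unobserved" scope, exposure `X`) and `C = 0` survivors only ("observed"
scope, exposure `M`) — and three bias estimands are formed per replicate:

* absolute risk bias per arm: `risk_obs − risk_unobs`
* absolute RD bias: `RD_obs − RD_unobs`
* relative RR bias: `RR_obs / RR_unobs`

Every simulated quantity has a closed-form expectation: writing
`q(x, z)` for the SAB-survival fraction, the relative RR bias is exactly
`q(0, z) / q(1, z)` and the RD bias is
`pOut_base · rr_Out_Z^z · [rr_Out_M (1 − q(1, z)) − (1 − q(0, z))]`.
These oracles back the test suite.

## Worked example

The most extreme admissible setup (`rr_C_Z = 4`, `rr_C_X = 4.5`,
`rr_Out_Z = 4`) at the study's scale — 200 cohorts of 100,000 implanted
conceptuses:

```r
library(lefttruncsim)
library(dplyr)

p    <- build_grid("primary")[8, ]
cts  <- simulate_study(p, n_replicates = 200, n_total = 100000, master_seed = 42)
bias <- compute_bias(estimate_effects(cts, "both"))
aggregate_estimates(bias) |>
  filter(quantity %in% c("rd_bias", "rr_relative_bias"))
#>   setup_id stratum         quantity n_used   mean median pct_2_5 pct_97_5 n_excluded
#> 1        8       0          rd_bias    200 0.0266 0.0266  0.0192   0.0374          0
#> 2        8       0 rr_relative_bias    200 1.2270 1.2242  1.1828   1.3066          0
#> 3        8       1          rd_bias    200 0.4152 0.4149  0.2378   0.6319          0
#> 4        8       1 rr_relative_bias    199 8.3337 8.0457  5.0283  12.3937          1
```

Read: under normal placentation (stratum 0) truncation overstates the
abruption–mortality risk difference by ~2.7 percentage points and the risk
ratio by ~1.23-fold. Under abnormal placentation the RD is overstated by
~42 percentage points and the RR by roughly eight-fold — the closed-form
values are `expected_bias(p)`: RD bias 0.4215 and RR bias
`q(0,1)/q(1,1) = 0.8/0.1 = 8` (the across-replicate mean of the ratio sits
slightly above 8 because `1/q̂` is convex). One replicate had no exposed
deaths, so its undefined RR ratio is excluded and counted. The full
pipeline — grid, simulation, estimation, bias, aggregation, oracle and
comparison CSVs — is one call:

```r
run_pipeline("primary", n_replicates = 200, n_total = 100000,
             master_seed = 42, out_dir = "out")
```

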