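# Expected values for the printed 189.6 MeV worked-example layer were
# computed from the four-step model formulas by hand:
#   baseline rate = 0.0010 / 0.6 * 2000 = 10/3 MU/s
#   DR=10 floor   = 0.0198 / 10 = 0.00198 MU (segments 1 and 5 elevated)
#   DR=10 rate    = 0.00198 / 0.6 * 2000 = 6.6 MU/s
#   baseline BoT  = 0.0455 / (10/3)  = 0.01365 s
#   DR=10 BoT     = 0.04716 / 6.6    = 0.0071454... s

test_that("baseline dose rate is pinned by the lowest mu/length segment", {
  expect_equal(baseline_dose_rate(table1_layer(), table1_machine()), 10 / 3)
  expect_equal(baseline_dose_rate(energy_layer(100, 0.5, 1.0),
                                  machine_spec()), 1000)
  set.seed(21)
  for (i in 1:5) {
    lay <- rand_layer(200, mixed_lengths = TRUE)
    brute <- Inf
    for (j in seq_len(200))
      brute <- min(brute, lay$segments$mu[j] / lay$segments$length_cm[j] *
                            2000)
    expect_equal(baseline_dose_rate(lay, machine_spec()), brute)
  }
})

test_that("dynamic-range dose rate matches the worked example and formulas", {
  expect_equal(dr_dose_rate(table1_layer(), 10, table1_machine()), 6.6)
  # printed value 6.592 reflects unrounded planning MUs; 4-decimal inputs
  # give 6.6, within 0.2%
  expect_equal(6.6, 6.592, tolerance = 0.01)
  # printed step-2 formula where the floor binds: (mu_max/length)*speed/dr
  expect_equal(dr_dose_rate(energy_layer(100, c(0.001, 1), 1.0), 100,
                            machine_spec()), 20)
  # a floor below every segment MU leaves the baseline rate untouched
  expect_equal(dr_dose_rate(energy_layer(100, c(1, 1), 1.0), 100,
                            machine_spec()), 2000)
  # dr equal to the intrinsic mu_max/mu_min ratio reproduces baseline
  set.seed(22)
  for (i in 1:10) {
    lay <- rand_layer(40)
    ex <- layer_extrema(lay)
    expect_equal(dr_dose_rate(lay, unname(ex["mu_max"] / ex["mu_min"]),
                              machine_spec()),
                 baseline_dose_rate(lay, machine_spec()))
  }
  # unconstrained delegates to baseline
  expect_equal(dr_dose_rate(table1_layer(), Inf, table1_machine()),
               baseline_dose_rate(table1_layer(), table1_machine()))
})

test_that("MU elevation clamps sub-floor segments only", {
  adj <- elevate_mu(table1_layer(), 10)
  expect_equal(as.numeric(adj),
               c(0.00198, 0.0198, 0.0178, 0.0056, 0.00198))
  expect_equal(attr(adj, "n_elevated"), 2L)
  # segments 1 and 5 land on the floor, printed as 0.0020
  expect_lt(max(abs(as.numeric(adj)[c(1, 5)] - 0.0020)), 5e-5)
  # loose dr is the identity
  lay <- table1_layer()
  expect_identical(as.numeric(elevate_mu(lay, 19.8)), lay$segments$mu)
  # dr = 1 clamps everything to mu_max
  expect_equal(as.numeric(elevate_mu(lay, 1)), rep(0.0198, 5))
})

test_that("adjust_layer reproduces the printed per-segment beam-on times", {
  base <- adjust_layer(table1_layer(), Inf, table1_machine())
  expect_equal(base$layer_bot, 0.0138, tolerance = 5e-4 / 0.0138)
  expect_equal(base$layer_bot, 0.01365)
  # printed BoT column, to the table's 1e-4 rounding grain
  expect_lt(max(abs(base$segment_bot -
                    c(0.0004, 0.0060, 0.0054, 0.0017, 0.0003))), 1e-4)
  dr10 <- adjust_layer(table1_layer(), 10, table1_machine())
  expect_equal(dr10$layer_bot, 0.0072, tolerance = 5e-4 / 0.0072)
  expect_lt(max(abs(dr10$segment_bot -
                    c(0.0003, 0.0030, 0.0027, 0.0009, 0.0003))), 1e-4)
  expect_equal(dr10$n_elevated, 2L)
  # reduction ratio lands near the printed "52%"
  expect_equal(dr10$layer_bot / base$layer_bot, 0.52, tolerance = 0.02)
})

test_that("unconstrained adjustment is a strict no-op", {
  set.seed(23)
  lay <- rand_layer(120, mixed_lengths = TRUE)
  a <- adjust_layer(lay, Inf, machine_spec())
  expect_identical(a$adjusted_mu, lay$segments$mu)
  expect_identical(a$dose_rate, baseline_dose_rate(lay, machine_spec()))
  expect_identical(a$layer_bot, sum(lay$segments$mu) / a$dose_rate)
  expect_equal(a$n_elevated, 0L)
})

test_that("all-equal-MU layers deliver at maximum scan speed for any dr", {
  lay <- energy_layer(150, rep(0.02, 37), 0.8)
  for (dr in c(Inf, 200, 10, 1))
    expect_equal(adjust_layer(lay, dr, machine_spec())$layer_bot,
                 37 * 0.8 / 2000)
})

test_that("dose rate and beam-on time are monotone in dr with a path floor", {
  # uniform segment lengths: the regime of the four-step formulas, where
  # elevating the minimum MU always raises the binding mu/length ratio
  set.seed(24)
  grid <- seq(200, 10, by = -10)
  m <- machine_spec()
  for (i in 1:200) {
    lay <- rand_layer(sample(10:80, 1))
    res <- vapply(grid, function(dr) {
      a <- adjust_layer(lay, dr, m)
      c(a$layer_bot, a$dose_rate)
    }, numeric(2))
    expect_true(all(diff(res[1, ]) <= 1e-12))  # bot falls as dr falls
    expect_true(all(diff(res[2, ]) >= -1e-12)) # rate rises as dr falls
    floor_bot <- sum(lay$segments$length_cm) / m$speed_max
    expect_true(all(res[1, ] >= floor_bot - 1e-12))
    # floor attained exactly at dr = 1 (all segments clamp to mu_max and
    # every one is scanned at speed_max)
    expect_equal(adjust_layer(lay, 1, m)$layer_bot, floor_bot)
  }
})

test_that("heterogeneous lengths keep the speed and floor bounds", {
  # elevation can lengthen BoT here (the binding mu/length segment need not
  # be the elevated one), so monotonicity is not asserted -- only the
  # physical bounds
  set.seed(26)
  m <- machine_spec()
  for (i in 1:40) {
    lay <- rand_layer(sample(10:60, 1), mixed_lengths = TRUE)
    for (dr in c(200, 50, 10, 1)) {
      a <- adjust_layer(lay, dr, m)
      speed <- a$dose_rate * lay$segments$length_cm / a$adjusted_mu
      expect_true(all(speed <= m$speed_max * (1 + 1e-9)))
      expect_gte(a$layer_bot,
                 sum(lay$segments$length_cm) / m$speed_max - 1e-12)
    }
  }
})

test_that("adjusted MUs never decrease and scan speed never exceeds the max", {
  set.seed(25)
  m <- machine_spec()
  for (i in 1:50) {
    lay <- rand_layer(60, mixed_lengths = TRUE)
    dr <- sample(c(Inf, 200, 50, 10, 2), 1)
    a <- adjust_layer(lay, dr, m)
    expect_true(all(a$adjusted_mu >= lay$segments$mu - 1e-15))
    expect_gte(sum(a$adjusted_mu), sum(lay$segments$mu))
    if (is.finite(dr))
      expect_true(all(a$adjusted_mu >= max(lay$segments$mu) / dr - 1e-15))
    speed <- a$dose_rate * lay$segments$length_cm / a$adjusted_mu
    expect_true(all(speed <= m$speed_max * (1 + 1e-9)))
    expect_equal(a$layer_bot, sum(a$segment_bot))
  }
})

test_that("a machine dose-rate cap binds when configured", {
  lay <- table1_layer()
  m <- machine_spec(max_dose_rate = 5)
  expect_equal(dr_dose_rate(lay, 10, m), 5)
  expect_equal(baseline_dose_rate(lay, m), 10 / 3)  # below cap, unaffected
  expect_equal(adjust_layer(lay, 10, m)$layer_bot, 0.04716 / 5)
})

test_that("field beam-on time is additive and matches a brute-force loop", {
  lay <- table1_layer()
  fld3 <- treatment_field("f", list(lay, lay, lay))
  m <- table1_machine()
  single <- adjust_layer(lay, 10, m)$layer_bot
  expect_equal(field_bot(fld3, 10, m)$total, 3 * single)
  # unconstrained vs astronomically loose dr coincide
  plan <- generate_plan(plan_gen_spec(n_fields = 1, n_layers = 30,
                                      segments_per_layer = c(20, 60),
                                      seed = 31))
  fld <- plan$fields[[1]]
  expect_equal(field_bot(fld, Inf, m)$total, field_bot(fld, 1e6, m)$total)
  # independent segment-by-segment recomputation
  brute <- 0
  for (l in fld$layers) {
    mu <- l$segments$mu
    floor_mu <- max(mu) / 50
    adj <- ifelse(mu < floor_mu, floor_mu, mu)
    rate <- min(adj / l$segments$length_cm) * m$speed_max
    for (j in seq_along(adj)) brute <- brute + adj[j] / rate
  }
  expect_equal(field_bot(fld, 50, m)$total, brute)
})

test_that("the per-segment adjustment table is consistent with adjust_layer", {
  plan <- generate_plan(plan_gen_spec(n_fields = 2, n_layers = 3,
                                      segments_per_layer = c(4, 8), seed = 8))
  tab <- adjust_plan_table(plan, 20, machine_spec())
  expect_named(tab, c("field", "layer", "energy_mev", "segment", "mu",
                      "mu_adjusted", "dose_rate_mu_s", "bot_s"))
  tot <- field_bot(plan$fields[[1]], 20, machine_spec())$total
  expect_equal(sum(tab$bot_s[tab$field == plan$fields[[1]]$name]), tot)
})
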