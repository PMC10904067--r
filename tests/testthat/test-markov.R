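test_that("initial distribution places prevalence on undiagnosed states", {
  occ <- initial_distribution(fixture_params("rural"))
  expect_equal(sum(occ), 1, tolerance = 1e-15)
  expect_equal(unname(occ["no_dr"]), 1 - 0.256 - 0.016 - 0.035)
  expect_equal(unname(occ["npdr_undx"]), 0.256)
  occ_u <- initial_distribution(fixture_params("urban"))
  expect_equal(unname(occ_u["npdr_undx"]), 0.149)
  # degenerate: zero prevalence puts everything on no-DR
  occ0 <- initial_distribution(degenerate_params())
  expect_identical(unname(occ0["no_dr"]), 1)
  p <- fixture_params("rural")
  for (k in names(p$prevalence)) p$prevalence[[k]][c("base", "hi")] <- 0.4
  expect_error(initial_distribution(p), "sum to < 1")
})

test_that("cycle mortality applies the published risk ratios and caps at 1", {
  mort <- list(life_table = data.frame(age = 50:60, q = 0.004),
               rr_diabetes = c(base = 1.97), rr_svi = c(base = 3.9),
               svi_multiplier_mode = "replace")
  expect_equal(cycle_mortality(50, "npdr", mort), 0.004 * 1.97)
  expect_equal(cycle_mortality(50, "svi", mort), 0.004 * 3.9)
  expect_identical(cycle_mortality(50, "death", mort), 1)
  mort$life_table$q <- 0.9
  expect_identical(cycle_mortality(50, "svi", mort), 1)
  mort$svi_multiplier_mode <- "stack"
  mort$life_table$q <- 0.004
  expect_equal(cycle_mortality(50, "svi", mort), 0.004 * 1.97 * 3.9)
  # beyond the schedule: last entry is carried forward; below it: error
  expect_equal(cycle_mortality(99, "no_dr", mort), 0.004 * 1.97)
  expect_error(cycle_mortality(40, "no_dr", mort), "below the mortality schedule")
})

test_that("transition matrix rows carry the published probabilities and are stochastic", {
  p <- fixture_params("rural")
  p$mortality$life_table <- data.frame(age = 50:100, q = 0)  # isolate disease dynamics
  P <- build_transition_matrix(p, 50)
  expect_equal(P["no_dr", "npdr_undx"], 0.0328)
  expect_equal(P["no_dr", "pdr_undx"], 0.0024)
  expect_equal(P["no_dr", "no_dr"], 1 - 0.0328 - 0.0024)
  expect_equal(P["pdr_tx", "svi_new"], 0.0116)
  expect_equal(P["pdr_undx", "svi_new"], 0.0278)
  expect_identical(P["pdr_tx", "dme_tx"], 0)     # disabled by default
  expect_identical(P["death", "death"], 1)
  expect_identical(P["svi_new", "svi_ong"], 1)   # first SVI year is transient
  # no recovery: everything below the diagonal block structure stays zero
  expect_identical(P["svi_ong", "no_dr"], 0)
  expect_identical(P["dme_undx", "npdr_undx"], 0)
  # degenerate: no transitions and no mortality give the identity, apart
  # from the structural first-SVI-year to ongoing-SVI move
  P0 <- build_transition_matrix(degenerate_params(), 50)
  keep <- setdiff(model_states(), "svi_new")
  expect_equal(unname(P0[keep, keep]), diag(9), tolerance = 0)
  expect_identical(P0["svi_new", "svi_ong"], 1)
  # row-stochastic at every modelled age, both settings
  for (s in c("rural", "urban")) {
    ps <- fixture_params(s)
    for (age in c(50, 60, 75, 90, 100, 120))
      expect_lt(max(abs(rowSums(build_transition_matrix(ps, age)) - 1)), 1e-12)
  }
  # enabling the treated-PDR DME pathway reroutes it to treated DME
  p$model_options$treated_pdr_to_dme <- TRUE
  P2 <- build_transition_matrix(p, 50)
  expect_equal(P2["pdr_tx", "dme_tx"], 0.0290)
})

test_that("cohort accumulators match closed forms in the degenerate model", {
  # constant occupancy, utility 1, no discounting: exactly n_cycles QALYs
  out <- run_cohort(degenerate_params(n_cycles = 10))
  expect_equal(out$result$qalys, 10, tolerance = 1e-12)
  expect_equal(out$result$cost, 0)
  # utility u, discount d: u * sum_{t=1..T} (1+d)^-t (geometric closed form)
  u <- 0.83; d <- 0.035; T <- 25
  out2 <- run_cohort(degenerate_params(n_cycles = T, discount = d, utility = u))
  expect_equal(out2$result$qalys, u * (1 - (1 + d)^-T) / d, tolerance = 1e-12)
})

test_that("occupancy mass is conserved every cycle under every policy", {
  pols <- list(screening_policy("none"), screening_policy("community"),
               screening_policy("telemedicine", 2))
  for (s in c("rural", "urban")) for (pol in pols) {
    tr <- run_cohort(fixture_params(s), pol)$trace
    mass <- rowSums(tr[, model_states()])
    expect_lt(max(abs(mass - 1)), 1e-12)
    expect_true(all(tr[, model_states()] >= 0))
    # discounted cumulatives never decrease
    expect_true(all(diff(tr$cum_disc_cost) >= -1e-12))
    expect_true(all(diff(tr$cum_disc_qaly) >= -1e-12))
  }
})

test_that("screening without treatment effect cannot add health benefit", {
  for (s in c("rural", "urban")) {
    p <- no_treatment_effect_params(s)
    q_none <- run_strategy(p)$qalys
    for (strat in c("community", "telemedicine")) {
      r <- run_strategy(p, strat)
      expect_lte(r$qalys, q_none + 1e-9)
      expect_gt(r$cost, 0)
    }
  }
})

test_that("discounting strictly reduces lifetime totals", {
  p <- fixture_params("rural")
  r_disc <- run_strategy(p)
  p0 <- p
  p0$economics$discount_rate <- 0
  r_undisc <- run_strategy(p0)
  expect_gt(r_undisc$qalys, r_disc$qalys)
  expect_gt(r_undisc$cost, r_disc$cost)
})

test_that("a cohort trace can be exported as a delimited table", {
  out <- run_cohort(fixture_params("rural"), screening_policy("community"))
  path <- tempfile(fileext = ".csv")
  write_trace(out$trace, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 31)
  expect_true(all(model_states() %in% names(back)))
})
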