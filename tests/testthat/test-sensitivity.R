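test_that("distribution fitting matches moments and rejects impossible fits", {
  d <- fit_distribution(0.5, 0.4, 0.6, "beta")
  expect_equal(d$shape1, d$shape2)  # symmetric CI about 0.5
  expect_equal(d$shape1 / (d$shape1 + d$shape2), 0.5)
  d2 <- fit_distribution(0.95, 0.92, 0.99, "beta", "utility_no_dr")
  expect_equal(d2$shape1 / (d2$shape1 + d2$shape2), 0.95, tolerance = 1e-12)
  d3 <- fit_distribution(100, 80, 120, "gamma", "cost")
  expect_equal(d3$shape * d3$scale, 100, tolerance = 1e-12)
  s <- (120 - 80) / (2 * 1.959964)
  expect_equal(d3$shape * d3$scale^2, s^2, tolerance = 1e-12)
  # degenerate interval collapses to a point mass
  expect_identical(fit_distribution(5, 5, 5, "gamma")$family, "fixed")
  expect_identical(draw_distribution(fit_distribution(5, 5, 5, "gamma"), 3),
                   c(5, 5, 5))
  expect_error(fit_distribution(0.5, 0, 2.2, "beta", "wide"), "wide")
  expect_error(fit_distribution(0, 0, 0.1, "beta", "zero"), "\\(0, 1\\)")
  expect_error(fit_distribution(0.6, 0.7, 0.9, "beta"), "lo95 <= base <= hi95")
})

test_that("every fitted parameter distribution reproduces its mean by sampling", {
  reg <- param_registry(fixture_params("rural"))
  set.seed(99)
  n <- 1e5
  for (i in seq_len(nrow(reg))) {
    d <- fit_distribution(reg$base[i], reg$lo[i], reg$hi[i],
                          family = reg$family[i], name = reg$name[i])
    if (d$family == "fixed") next
    x <- draw_distribution(d, n)
    se <- stats::sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - reg$base[i]), 3 * se + 1e-12)
  }
})

test_that("the tornado varies each parameter within support and sorts by span", {
  p <- fixture_params("rural")
  tor <- one_way_dsa(p, "community", "none")
  expect_s3_class(tor, "tornado")
  expect_equal(nrow(tor), nrow(param_registry(p)))
  expect_true(all(diff(tor$span) <= 1e-9))  # sorted descending
  # clipping correctness: no probability leaves [0,1], no cost negative
  probs <- tor$group %in% c("prevalence", "transition", "utility", "test", "compliance")
  expect_true(all(tor$low_value >= 0))
  expect_true(all(tor$high_value[probs] <= 1))
  # the telemedicine test characteristics cannot move a community-vs-none ICUR
  tele_rows <- grepl("tests.telemedicine", tor$parameter)
  expect_true(all(tor$span[tele_rows] < 1e-9))
  # widening a cost's range cannot shrink its span (monotone reruns)
  p50 <- p
  p50$dsa_ranges$cost_program <- 0.50
  tor50 <- one_way_dsa(p50, "community", "none")
  pick <- function(t, nm) t$span[t$parameter == nm]
  nm <- "costs.screening_per_person.community"
  expect_gte(pick(tor50, nm), pick(tor, nm))
})

test_that("the PSA is seed-deterministic and handles degenerate distributions", {
  p <- fixture_params("rural")
  a <- run_psa(p, n_iter = 10, seed = 5)
  b <- run_psa(p, n_iter = 10, seed = 5)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$param_draws, b$param_draws)
  expect_identical(a$ceac, b$ceac)
  c2 <- run_psa(p, n_iter = 10, seed = 6)
  expect_false(identical(a$outcomes$cost, c2$outcomes$cost))
  expect_error(run_psa(p, n_iter = 1), "n_iter must be >= 2")

  # all-fixed distributions: every draw identical, the CI collapses
  pf <- p
  reg <- param_registry(p)
  for (i in seq_len(nrow(reg))) {
    nm <- strsplit(reg$name[i], ".", fixed = TRUE)[[1]]
    leaf <- Reduce(`[[`, nm, pf)
    leaf["lo"] <- leaf["hi"] <- leaf["base"]
    expr <- Reduce(function(acc, k) call("[[", acc, k), nm, quote(pf))
    eval(call("<-", expr, leaf))
  }
  fx <- run_psa(pf, n_iter = 5, seed = 1)
  expect_equal(stats::sd(fx$outcomes$cost[, "community"]), 0)
  for (s in fx$summaries) expect_equal(diff(s$icur_ci), 0, tolerance = 1e-9)
})

test_that("CEAC starts at the sign of the cost difference and rises with positive dQALY", {
  p <- fixture_params("rural")
  # remove the downstream savings so screening strictly costs money
  zero <- c(base = 0, lo = 0, hi = 0)
  p$costs$svi_first_year <- zero
  p$costs$svi_subsequent_year <- zero
  p$costs$followup_maintain <- zero
  psa <- run_psa(p, n_iter = 60, seed = 3)
  for (nm in c("community_vs_none", "telemedicine_vs_none")) {
    s <- psa$summaries[[nm]]
    dc <- psa$outcomes$cost[, s$comparator] - psa$outcomes$cost[, s$reference]
    dq <- psa$outcomes$qaly[, s$comparator] - psa$outcomes$qaly[, s$reference]
    expect_true(all(dc > 0))  # screening spends with no cost offsets left
    ceac <- psa$ceac[psa$ceac$comparison == nm, ]
    expect_identical(ceac$probability[ceac$lambda == 0], 0)  # NMB(0) = -dc < 0
    if (all(dq > 0))  # monotone acceptability in the threshold
      expect_true(all(diff(ceac$probability) >= -1e-12))
  }
})
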