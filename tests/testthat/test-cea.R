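sr <- function(cost, qalys, strategy = "x", setting = "rural", interval = "one-off")
  structure(list(setting = setting, strategy = strategy, interval = interval,
                 cost = cost, qalys = qalys), class = "strategy_result")

test_that("ICURs recomputed from the published incremental columns match the printed ratios", {
  tab <- published_summary()
  rows <- tab[!is.na(tab$icur), ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    ref <- tab[tab$setting == r$setting & tab$strategy == r$reference, ][1, ]
    cmp <- icur(sr(r$cost_per_person, r$qalys_per_person, setting = r$setting),
                sr(ref$cost_per_person, ref$qalys_per_person, setting = r$setting),
                wtp_1x = if (r$setting == "rural") 7000 else 12000)
    # the printed increments carry rounding noise; 0.5% relative tolerance
    expect_equal(r$incr_cost / r$incr_qaly, r$icur, tolerance = 5e-3)
    expect_equal(cmp$icur, r$icur, tolerance = 5e-3)
    expect_match(cmp$verdict, "cost-effective")
  }
})

test_that("dominance and degenerate comparisons are classified, never thrown", {
  cmp <- icur(sr(95, 10.01), sr(100, 10.00), wtp_1x = 7000)
  expect_identical(cmp$dominance, "comparator_dominant")
  expect_true(is.na(cmp$icur))
  expect_match(cmp$verdict, "dominant")
  cmp2 <- icur(sr(100, 10), sr(95, 10.01), wtp_1x = 7000)
  expect_identical(cmp2$dominance, "reference_dominant")
  same <- icur(sr(100, 10), sr(100, 10), wtp_1x = 7000)
  expect_identical(same$dominance, "none")
  expect_true(is.na(same$icur))
  undef <- icur(sr(105, 10), sr(100, 10), wtp_1x = 7000)
  expect_identical(undef$dominance, "undefined")
  expect_identical(undef$verdict, "undefined ICUR")
  expect_error(icur(sr(1, 1, setting = "rural"), sr(1, 1, setting = "urban"), 7000),
               "same setting")
})

test_that("ICUR is cost-scale equivariant and antisymmetric under swapping", {
  a <- sr(228.36, 12.10573); b <- sr(214.07, 12.10231)
  base <- icur(a, b, 7000)$icur
  for (c_scale in c(0.5, 3.7, 100)) {
    scaled <- icur(sr(a$cost * c_scale, a$qalys), sr(b$cost * c_scale, b$qalys), 7000)
    expect_equal(scaled$icur, base * c_scale, tolerance = 1e-12)
  }
  swapped <- icur(b, a, 7000)
  expect_equal(swapped$icur, base, tolerance = 1e-12)  # ratio of negated differences
  expect_identical(icur(sr(95, 10.01), sr(100, 10), 7000)$dominance, "comparator_dominant")
  expect_identical(icur(sr(100, 10), sr(95, 10.01), 7000)$dominance, "reference_dominant")
})

test_that("net monetary benefit is linear in the threshold", {
  expect_equal(net_monetary_benefit(10, 0.002, 7000), 7000 * 0.002 - 10)
  expect_equal(net_monetary_benefit(10, 0.002, c(0, 5000)), c(-10, 0))
})

test_that("interval recommendation walks from the longest interval", {
  wtp <- 21000
  # hand-computed pairwise ICURs: 5yr -> 3yr costs 10 for 0.001 QALY
  # (10000/QALY, accepted), 3yr -> 1yr costs 50 for 0.001 (50000, rejected)
  res <- list(sr(100, 10.000, interval = 5), sr(110, 10.001, interval = 3),
              sr(160, 10.002, interval = 1))
  rec <- interval_recommendation(res, wtp)
  expect_identical(rec$interval, 3)
  expect_identical(rec$accepted, c(TRUE, TRUE, FALSE))
  # every shortening below the threshold: shortest wins
  res2 <- list(sr(100, 10.000, interval = 2), sr(110, 10.001, interval = 1))
  expect_identical(interval_recommendation(res2, wtp)$interval, 1)
  # no shortening acceptable: longest wins
  res3 <- list(sr(100, 10.000, interval = 2), sr(200, 10.001, interval = 1))
  expect_identical(interval_recommendation(res3, wtp)$interval, 2)
  # a one-off head entry counts as the longest
  res4 <- c(list(sr(95, 9.999, interval = "one-off")), res)
  expect_identical(interval_recommendation(res4, wtp)$interval, 3)
  expect_error(interval_recommendation(rev(res), wtp), "decreasing interval")
  expect_error(interval_recommendation(res[1], wtp), "at least two")
})

test_that("comparison tables round-trip through CSV", {
  comps <- list(icur(sr(228, 12.11, "community"), sr(214, 12.10, "none"), 7000))
  path <- tempfile(fileext = ".csv")
  comparison_table(comps, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 1)
  expect_equal(back$delta_cost, 14)
})
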