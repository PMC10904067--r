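test_that("packaged fixtures load, validate cleanly, and carry the published values", {
  for (s in c("rural", "urban")) {
    p <- fixture_params(s)
    expect_s3_class(p, "dr_parameters")
    expect_length(validate_parameters(p), 0)
  }
  rural <- fixture_params("rural")
  urban <- fixture_params("urban")
  expect_equal(unname(rural$prevalence$npdr["base"]), 0.256)
  expect_equal(unname(urban$tests$telemedicine$dme_specificity["base"]), 0.95)
  expect_equal(unname(rural$transitions$treated_pdr_to_svi["base"]), 0.0116)
  expect_equal(urban$economics$wtp_1x, 12000)
  expect_equal(urban$economics$wtp_3x, 36000)
})

test_that("every fixture value matches the flat transcription table", {
  tab <- utils::read.csv(system.file("extdata", "clinical_parameters.csv",
                                     package = "drcea"))
  lookup <- function(p, name) {
    if (grepl("^prevalence_", name)) return(p$prevalence[[sub("prevalence_", "", name)]])
    if (grepl("^utility_", name)) return(p$utilities[[sub("utility_", "", name)]])
    if (grepl("^(community|telemedicine)_", name)) {
      mod <- sub("_.*", "", name)
      return(p$tests[[mod]][[sub("^(community|telemedicine)_", "", name)]])
    }
    if (name == "rr_diabetes") return(p$mortality$rr_diabetes)
    if (name == "rr_svi") return(p$mortality$rr_svi)
    p$transitions[[name]]
  }
  for (i in seq_len(nrow(tab))) {
    settings <- if (tab$setting[i] == "both") c("rural", "urban") else tab$setting[i]
    for (s in settings) {
      val <- lookup(fixture_params(s), tab$parameter[i])
      expect_false(is.null(val), info = tab$parameter[i])
      expect_equal(unname(val["base"]), tab$base[i], info = paste(s, tab$parameter[i]))
      if (!is.na(tab$lo95[i])) {
        expect_equal(unname(val["lo"]), tab$lo95[i], info = tab$parameter[i])
        expect_equal(unname(val["hi"]), tab$hi95[i], info = tab$parameter[i])
      }
    }
  }
})

test_that("validation reports out-of-range, treatment-harm and ordering violations", {
  p <- fixture_params("rural")
  p$prevalence$npdr["base"] <- 1.2
  p$prevalence$npdr["hi"] <- 1.2
  v <- validate_parameters(p)
  expect_true(any(grepl("prevalence.npdr", v)))

  p <- fixture_params("rural")
  p$transitions$treated_pdr_to_svi[c("base", "hi")] <- 0.05
  v <- validate_parameters(p)
  expect_true(any(grepl("treated_pdr_to_svi.*treatment does not harm", v)))

  p <- fixture_params("rural")
  p$utilities$no_dr[c("lo", "base")] <- -0.1
  v <- validate_parameters(p)
  expect_true(any(grepl("utilities.no_dr", v)))

  p <- fixture_params("rural")
  for (k in names(p$prevalence)) p$prevalence[[k]][c("base", "hi")] <- 0.5
  expect_true(any(grepl("sum to < 1", validate_parameters(p))))
})

test_that("loading a config with an out-of-range value fails naming the field", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines("prevalence:\n  npdr: {base: 1.2, lo: 0.1, hi: 1.3}", cfg)
  expect_error(load_parameters(cfg, setting = "rural"), "prevalence.npdr")
})

test_that("a config overrides only what it states; removing a block is an error", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines("transitions:\n  dme_to_svi: {base: 0.04, lo: 0.03, hi: 0.05}", cfg)
  p <- load_parameters(cfg, setting = "urban")
  expect_equal(unname(p$transitions$dme_to_svi["base"]), 0.04)
  # untouched keys keep fixture values
  expect_equal(unname(p$prevalence$npdr["base"]), 0.149)

  cfg2 <- tempfile(fileext = ".yaml")
  writeLines("economics: ~", cfg2)
  expect_error(load_parameters(cfg2, setting = "rural"), "missing key 'economics")
  expect_error(load_parameters(tempfile()), "not found")
})

test_that("write/load round trip reproduces every numeric field bit-identically", {
  p <- perturb_parameters(fixture_params("rural"), relative_sd = 0.05, seed = 11)
  path <- tempfile(fileext = ".yaml")
  write_parameters(p, path)
  p2 <- load_parameters(path, setting = "rural")
  reg <- param_registry(p)
  reg2 <- param_registry(p2)
  expect_identical(reg2$base, reg$base)
  expect_identical(reg2$lo, reg$lo)
  expect_identical(reg2$hi, reg$hi)
  expect_identical(p2$mortality$life_table$q, p$mortality$life_table$q)
  expect_identical(p2$economics$discount_rate, p$economics$discount_rate)
  expect_identical(unname(p2$tests$community$normal_called_normal["base"]),
                   unname(p$tests$community$normal_called_normal["base"]))
})

test_that("the parameter registry is complete and excludes complement entries", {
  reg <- param_registry(fixture_params("rural"))
  # 3 prevalence + 9 transitions + 5 utilities + 2x6 tests + 2 compliance
  # + 3 programme costs + 5 treatment costs
  expect_equal(nrow(reg), 39)
  expect_false(any(grepl("normal_called_normal", reg$name)))
  expect_setequal(unique(reg$family), c("beta", "gamma"))
  p2 <- set_param(fixture_params("rural"), "transitions.dme_to_svi", 0.042)
  expect_equal(unname(p2$transitions$dme_to_svi["base"]), 0.042)
  expect_error(set_param(p2, "transitions.nope", 1), "unknown parameter")
})
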