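# cached fixture loads (parsing YAML once per run keeps the suite fast)
fixture_params <- local({
  cache <- list()
  function(setting = "rural") {
    if (is.null(cache[[setting]]))
      cache[[setting]] <<- load_parameters(setting = setting)
    cache[[setting]]
  }
})

# a degenerate model with closed-form behaviour: one alive state, no
# transitions, no mortality, utility 1, zero recurring costs, no discounting
degenerate_params <- function(n_cycles = 10, discount = 0, utility = 1) {
  p <- fixture_params("rural")
  zero <- c(base = 0, lo = 0, hi = 0)
  for (k in names(p$prevalence)) p$prevalence[[k]] <- zero
  for (k in names(p$transitions)) p$transitions[[k]] <- zero
  for (k in names(p$utilities))
    p$utilities[[k]] <- c(base = utility, lo = utility, hi = utility)
  p$mortality$life_table <- data.frame(age = 50:100, q = 0)
  p$costs$followup_maintain <- zero
  p$costs$svi_first_year <- zero
  p$costs$svi_subsequent_year <- zero
  p$economics$discount_rate <- discount
  p$economics$n_cycles <- as.integer(n_cycles)
  p
}

# treatment stripped of any effect: treated progression equals untreated and
# treated PDR keeps the untreated DME pathway
no_treatment_effect_params <- function(setting = "rural") {
  p <- fixture_params(setting)
  p$transitions$treated_pdr_to_svi <- p$transitions$pdr_to_svi
  p$transitions$treated_dme_to_svi <- p$transitions$dme_to_svi
  p$model_options$treated_pdr_to_dme <- TRUE
  p
}

# a perfect screening test: no misclassification, perfect DME detection
perfect_test <- function() {
  one <- c(base = 1, lo = 1, hi = 1)
  zero <- c(base = 0, lo = 0, hi = 0)
  list(normal_called_npdr = zero, normal_called_normal = one,
       npdr_called_normal = zero, pdr_called_npdr = zero,
       pdr_called_normal = zero, dme_sensitivity = one, dme_specificity = one)
}

published_summary <- function() {
  utils::read.csv(system.file("extdata", "published_summary.csv",
                              package = "drcea"))
}
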