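# A "parameter value" is a named numeric c(base, lo, hi): the point estimate
# and its 95% interval. Point-valued parameters collapse to base = lo = hi.
pv <- function(base, lo = base, hi = base) {
  c(base = as.numeric(base), lo = as.numeric(lo), hi = as.numeric(hi))
}

pv_from_cfg <- function(x, key) {
  if (is.null(x)) stop("configuration error: missing key '", key, "'", call. = FALSE)
  if (is.numeric(x) && length(x) == 1L) return(pv(x))
  if (is.null(x$base)) stop("configuration error: key '", key, "' has no 'base'", call. = FALSE)
  pv(x$base, if (is.null(x$lo)) x$base else x$lo, if (is.null(x$hi)) x$base else x$hi)
}

#' Path to a packaged parameter fixture
#'
#' The package ships complete parameter files for the rural and urban
#' settings, transcribed from the published clinical and costing tables,
#' plus flat delimited mirrors of those tables for auditing.
#'
#' @param setting `"rural"` or `"urban"`.
#' @return path to the packaged YAML parameter file.
#' @export
fixture_path <- function(setting = c("rural", "urban")) {
  setting <- match.arg(setting)
  system.file("extdata", paste0("params_", setting, ".yaml"),
              package = "drcea", mustWork = TRUE)
}

deep_merge <- function(base, override) {
  if (!is.list(base) || !is.list(override)) return(override)
  for (k in names(override)) {
    base[[k]] <- if (!is.null(base[[k]]) && is.list(base[[k]]) && is.list(override[[k]]))
      deep_merge(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Load and validate a model parameter set
#'
#' Reads a structured YAML parameter file into a validated `dr_parameters`
#' object. Keys absent from the file are filled from the packaged fixture
#' for the chosen setting, so a config need only state what it overrides;
#' with `path = NULL` the packaged fixture itself is loaded. Monetary
#' amounts may be given in CNY (`costs: currency: CNY`), in which case they
#' are converted to USD at the configured exchange rate. Derived fields
#' (per-person screening cost from the line items, hospital exam total,
#' 3x willingness-to-pay threshold, the life table from its Gompertz
#' specification) are computed here, and every type invariant is checked;
#' any violation is an error.
#'
#' @param path path to a YAML config, or `NULL` for the packaged fixture.
#' @param setting `"rural"` or `"urban"`; selects the fixture defaults.
#' @return a validated `dr_parameters` object.
#' @seealso [validate_parameters()], [write_parameters()], [fixture_path()]
#' @export
#' @examples
#' p <- load_parameters(setting = "rural")
#' p$prevalence$npdr["base"]
load_parameters <- function(path = NULL, setting = c("rural", "urban")) {
  setting <- match.arg(setting)
  cfg <- yaml::read_yaml(fixture_path(setting))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration error: file not found: ", path)
    cfg <- deep_merge(cfg, yaml::read_yaml(path))
  }
  params <- build_parameters(cfg)
  viol <- validate_parameters(params)
  if (length(viol))
    stop("invalid parameters:\n  - ", paste(viol, collapse = "\n  - "), call. = FALSE)
  params
}

build_parameters <- function(cfg) {
  need <- function(key) {
    x <- cfg[[key]]
    if (is.null(x)) stop("configuration error: missing key '", key, "'", call. = FALSE)
    x
  }
  econ_cfg <- need("economics")
  for (k in c("discount_rate", "n_cycles", "cycle_length", "start_age",
              "persons_screened_per_year", "exchange_rate_cny_per_usd", "wtp_1x"))
    if (is.null(econ_cfg[[k]]))
      stop("configuration error: missing key 'economics.", k, "'", call. = FALSE)

  prev_cfg <- need("prevalence")
  prevalence <- lapply(stats::setNames(nm = c("npdr", "pdr", "dme")), function(k)
    pv_from_cfg(prev_cfg[[k]], paste0("prevalence.", k)))

  tr_names <- c("normal_to_npdr", "normal_to_pdr", "npdr_to_pdr", "npdr_to_dme",
                "pdr_to_dme", "pdr_to_svi", "dme_to_svi",
                "treated_pdr_to_svi", "treated_dme_to_svi")
  tr_cfg <- need("transitions")
  transitions <- lapply(stats::setNames(nm = tr_names), function(k) {
    x <- tr_cfg[[k]]
    # multi-year cumulative entries are converted to an annual probability
    if (!is.null(x$cumulative_years) && x$cumulative_years != 1) {
      t <- x$cumulative_years
      conv <- function(p) prob_from_rate(annual_incidence(p, t), 1)
      pv(conv(x$base), conv(if (is.null(x$lo)) x$base else x$lo),
         conv(if (is.null(x$hi)) x$base else x$hi))
    } else pv_from_cfg(x, paste0("transitions.", k))
  })

  ut_cfg <- need("utilities")
  utilities <- lapply(stats::setNames(nm = c("no_dr", "npdr", "pdr", "dme", "svi")),
                      function(k) pv_from_cfg(ut_cfg[[k]], paste0("utilities.", k)))

  test_names <- c("normal_called_npdr", "normal_called_normal", "npdr_called_normal",
                  "pdr_called_npdr", "pdr_called_normal",
                  "dme_sensitivity", "dme_specificity")
  tests_cfg <- need("tests")
  tests <- lapply(stats::setNames(nm = c("community", "telemedicine")), function(mod) {
    mc <- tests_cfg[[mod]]
    if (is.null(mc)) stop("configuration error: missing key 'tests.", mod, "'", call. = FALSE)
    lapply(stats::setNames(nm = test_names), function(k)
      pv_from_cfg(mc[[k]], paste0("tests.", mod, ".", k)))
  })

  costs_cfg <- need("costs")
  fx <- econ_cfg$exchange_rate_cny_per_usd
  usd <- if (identical(costs_cfg$currency, "CNY"))
    function(x) cny_to_usd(x, fx) else identity

  conv_items <- function(items) lapply(items, function(it) {
    if (!is.null(it$unit_cost)) it$unit_cost <- usd(it$unit_cost)
    if (!is.null(it$annual_cost)) it$annual_cost <- usd(it$annual_cost)
    it
  })
  scr_items <- lapply(costs_cfg$screening_items, conv_items)
  n_scr <- econ_cfg$persons_screened_per_year
  r <- econ_cfg$discount_rate
  rng <- if (is.null(cfg$dsa_ranges)) list() else cfg$dsa_ranges
  rng <- utils::modifyList(list(probability = 0.10, utility = 0.10, test = 0.10,
                                compliance = 0.10, cost_program = 0.20,
                                cost_treatment = 0.50), rng)
  band <- function(x, f) pv(x, x * (1 - f), x * (1 + f))

  # an explicit per-person or exam-total value overrides the line-item
  # derivation (and detaches validation from the items)
  spp <- lapply(stats::setNames(nm = c("community", "telemedicine")), function(mod) {
    ov <- costs_cfg$screening_per_person[[mod]]
    if (!is.null(ov)) return(pv_from_cfg(ov, paste0("costs.screening_per_person.", mod)))
    its <- scr_items[[mod]]
    if (is.null(its)) stop("configuration error: missing key 'costs.screening_items.",
                           mod, "'", call. = FALSE)
    band(per_person_screening_cost(its, n_scr, r = r)$per_person, rng$cost_program)
  })

  exam_items <- lapply(costs_cfg$hospital_exam_items, function(it) {
    it$cost <- usd(it$cost); it
  })
  exam_explicit <- costs_cfg$hospital_exam_total
  exam_total <- if (!is.null(exam_explicit))
    pv_from_cfg(exam_explicit, "costs.hospital_exam_total")
  else band(sum(vapply(exam_items, function(it) it$cost, numeric(1))),
            rng$cost_program)

  treat <- function(key) {
    x <- costs_cfg[[key]]
    if (is.null(x)) stop("configuration error: missing key 'costs.", key, "'", call. = FALSE)
    if (is.list(x) && !is.null(x$lo)) {
      p <- pv_from_cfg(x, paste0("costs.", key)); pv(usd(p["base"]), usd(p["lo"]), usd(p["hi"]))
    } else band(usd(if (is.list(x)) x$base else x), rng$cost_treatment)
  }
  costs <- list(
    screening_items = scr_items,
    screening_per_person = spp,
    hospital_exam_items = exam_items,
    hospital_exam_total = exam_total,
    photocoagulation = treat("photocoagulation"),
    anti_vegf = treat("anti_vegf"),
    followup_maintain = treat("followup_maintain"),
    svi_first_year = treat("svi_first_year"),
    svi_subsequent_year = treat("svi_subsequent_year"),
    items_authoritative = is.null(exam_explicit)
  )

  mort_cfg <- need("mortality")
  lt <- if (!is.null(mort_cfg$life_table$table)) {
    tab <- mort_cfg$life_table$table
    data.frame(age = vapply(tab, function(x) x$age, numeric(1)),
               q = vapply(tab, function(x) x$q, numeric(1)))
  } else {
    g <- mort_cfg$life_table$gompertz
    if (is.null(g)) stop("configuration error: missing key 'mortality.life_table'", call. = FALSE)
    make_life_table(a = g$a, b = g$b,
                    age_from = mort_cfg$life_table$age_from %||% 50,
                    age_to = mort_cfg$life_table$age_to %||% 100)
  }
  mortality <- list(
    life_table = lt,
    rr_diabetes = pv_from_cfg(mort_cfg$rr_diabetes, "mortality.rr_diabetes"),
    rr_svi = pv_from_cfg(mort_cfg$rr_svi, "mortality.rr_svi"),
    svi_multiplier_mode = mort_cfg$svi_multiplier_mode %||% "replace"
  )

  comp_cfg <- need("compliance")
  compliance <- list(
    uptake = pv_from_cfg(comp_cfg$uptake, "compliance.uptake"),
    referral_acceptance = pv_from_cfg(comp_cfg$referral_acceptance,
                                      "compliance.referral_acceptance")
  )

  economics <- list(
    discount_rate = econ_cfg$discount_rate,
    n_cycles = as.integer(econ_cfg$n_cycles),
    cycle_length = econ_cfg$cycle_length,
    start_age = econ_cfg$start_age,
    persons_screened_per_year = n_scr,
    exchange_rate_cny_per_usd = fx,
    wtp_1x = econ_cfg$wtp_1x,
    wtp_3x = 3 * econ_cfg$wtp_1x
  )

  structure(list(
    setting = cfg$setting %||% "rural",
    prevalence = prevalence,
    transitions = transitions,
    utilities = utilities,
    tests = tests,
    costs = costs,
    mortality = mortality,
    compliance = compliance,
    economics = economics,
    dsa_ranges = rng,
    model_options = utils::modifyList(list(treated_pdr_to_dme = FALSE),
                                      cfg$model_options %||% list())
  ), class = "dr_parameters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a parameter set
#'
#' Checks every type invariant: probability and utility bounds, prevalence
#' summing below 1, per-origin outgoing transition mass, treatment benefit
#' (treated progression no worse than untreated), utility ordering across
#' disease severity, screening-test row mass, nonnegative costs, the
#' hospital exam total matching its line items, a nondecreasing mortality
#' schedule, and economic settings. A reporting operation: it never throws.
#'
#' @param params a `dr_parameters` object.
#' @return character vector of violations (empty when valid), each naming
#'   the field, its value and the rule broken.
#' @export
validate_parameters <- function(params) {
  v <- character(0)
  bad <- function(field, value, rule)
    sprintf("%s = %s violates: %s", field, paste(signif(value, 6), collapse = ","), rule)

  chk_pv <- function(x, field, lo_b = 0, hi_b = 1) {
    out <- character(0)
    if (any(!is.finite(x))) return(bad(field, x, "finite value required"))
    if (x["base"] < x["lo"] || x["base"] > x["hi"])
      out <- c(out, bad(field, x, "base must lie in [lo, hi]"))
    if (x["lo"] < lo_b || x["hi"] > hi_b)
      out <- c(out, bad(field, x, sprintf("values must lie in [%g, %g]", lo_b, hi_b)))
    out
  }
  b <- function(x) unname(x["base"])

  for (k in names(params$prevalence))
    v <- c(v, chk_pv(params$prevalence[[k]], paste0("prevalence.", k)))
  psum <- sum(vapply(params$prevalence, b, numeric(1)))
  if (psum >= 1) v <- c(v, bad("prevalence", psum, "prevalence must sum to < 1"))

  for (k in names(params$transitions))
    v <- c(v, chk_pv(params$transitions[[k]], paste0("transitions.", k)))
  tr <- lapply(params$transitions, b)
  outgoing <- list(no_dr = tr$normal_to_npdr + tr$normal_to_pdr,
                   npdr = tr$npdr_to_pdr + tr$npdr_to_dme,
                   pdr = tr$pdr_to_dme + tr$pdr_to_svi,
                   dme = tr$dme_to_svi)
  for (s in names(outgoing)) if (outgoing[[s]] > 1)
    v <- c(v, bad(paste0("transitions[", s, "]"), outgoing[[s]],
                  "outgoing disease probabilities must sum to <= 1"))
  if (tr$treated_pdr_to_svi > tr$pdr_to_svi)
    v <- c(v, bad("transitions.treated_pdr_to_svi",
                  c(tr$treated_pdr_to_svi, tr$pdr_to_svi),
                  "treated progression must not exceed untreated (treatment does not harm)"))
  if (tr$treated_dme_to_svi > tr$dme_to_svi)
    v <- c(v, bad("transitions.treated_dme_to_svi",
                  c(tr$treated_dme_to_svi, tr$dme_to_svi),
                  "treated progression must not exceed untreated (treatment does not harm)"))

  for (k in names(params$utilities))
    v <- c(v, chk_pv(params$utilities[[k]], paste0("utilities.", k)))
  u <- lapply(params$utilities, b)
  if (!(u$no_dr >= u$npdr && u$npdr >= u$pdr && u$npdr >= u$dme &&
        u$pdr >= u$svi && u$dme >= u$svi))
    v <- c(v, bad("utilities", unlist(u),
                  "utilities must be nonincreasing with disease severity"))

  for (mod in names(params$tests)) {
    te <- params$tests[[mod]]
    for (k in names(te))
      v <- c(v, chk_pv(te[[k]], paste0("tests.", mod, ".", k)))
    if (b(te$normal_called_npdr) + b(te$normal_called_normal) > 1 + 1e-9)
      v <- c(v, bad(paste0("tests.", mod, ".normal_called_*"),
                    b(te$normal_called_npdr) + b(te$normal_called_normal),
                    "called-NPDR and called-normal fractions must sum to <= 1"))
    if (b(te$pdr_called_npdr) + b(te$pdr_called_normal) > 1 + 1e-9)
      v <- c(v, bad(paste0("tests.", mod, ".pdr_called_*"),
                    b(te$pdr_called_npdr) + b(te$pdr_called_normal),
                    "PDR misclassification fractions must sum to <= 1"))
  }

  cost_fields <- c("hospital_exam_total", "photocoagulation", "anti_vegf",
                   "followup_maintain", "svi_first_year", "svi_subsequent_year")
  for (k in cost_fields)
    v <- c(v, chk_pv(params$costs[[k]], paste0("costs.", k), 0, Inf))
  for (mod in names(params$costs$screening_per_person))
    v <- c(v, chk_pv(params$costs$screening_per_person[[mod]],
                     paste0("costs.screening_per_person.", mod), 0, Inf))
  if (isTRUE(params$costs$items_authoritative)) {
    isum <- sum(vapply(params$costs$hospital_exam_items,
                       function(it) it$cost, numeric(1)))
    if (abs(isum - b(params$costs$hospital_exam_total)) > 1e-6)
      v <- c(v, bad("costs.hospital_exam_total",
                    c(b(params$costs$hospital_exam_total), isum),
                    "exam total must equal the sum of its line items"))
  }

  lt <- params$mortality$life_table
  if (any(lt$q < 0) || any(lt$q > 1))
    v <- c(v, bad("mortality.life_table.q", range(lt$q), "q(age) must lie in [0, 1]"))
  if (is.unsorted(lt$q))
    v <- c(v, bad("mortality.life_table.q", NA_real_,
                  "q(age) must be nondecreasing over the modelled ages"))
  if (b(params$mortality$rr_diabetes) <= 0 || b(params$mortality$rr_svi) <= 0)
    v <- c(v, bad("mortality.rr", c(b(params$mortality$rr_diabetes),
                                    b(params$mortality$rr_svi)),
                  "mortality multipliers must be positive"))

  ec <- params$economics
  if (ec$discount_rate < 0)
    v <- c(v, bad("economics.discount_rate", ec$discount_rate, "must be >= 0"))
  if (ec$n_cycles < 1)
    v <- c(v, bad("economics.n_cycles", ec$n_cycles, "must be >= 1"))
  if (abs(ec$wtp_3x - 3 * ec$wtp_1x) > 1e-9)
    v <- c(v, bad("economics.wtp_3x", c(ec$wtp_3x, ec$wtp_1x), "wtp_3x must be 3 x wtp_1x"))
  v <- c(v, chk_pv(params$compliance$uptake, "compliance.uptake"))
  v <- c(v, chk_pv(params$compliance$referral_acceptance, "compliance.referral_acceptance"))
  v
}

#' Write a parameter set back to YAML
#'
#' Serializes a `dr_parameters` object to the same schema [load_parameters()]
#' reads, with full floating-point precision so that a write/load round trip
#' reproduces every numeric field bit-identically. The life table is written
#' out explicitly (age, q), not as its generating law.
#'
#' @param params a `dr_parameters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  num <- function(x) structure(format(unname(x), digits = 17, trim = TRUE,
                                      scientific = FALSE), class = "verbatim")
  pv_out <- function(x) list(base = num(x["base"]), lo = num(x["lo"]), hi = num(x["hi"]))
  items_out <- function(items) lapply(items, function(it) {
    out <- list(item = it$item, kind = it$kind)
    if (!is.null(it$units)) out$units <- it$units
    if (!is.null(it$unit_cost)) out$unit_cost <- num(it$unit_cost)
    if (!is.null(it$life_years)) out$life_years <- it$life_years
    if (!is.null(it$annual_cost)) out$annual_cost <- num(it$annual_cost)
    out
  })
  cfg <- list(
    setting = params$setting,
    prevalence = lapply(params$prevalence, pv_out),
    transitions = lapply(params$transitions, pv_out),
    utilities = lapply(params$utilities, pv_out),
    tests = lapply(params$tests, function(te) lapply(te, pv_out)),
    costs = list(
      currency = "USD",
      screening_items = lapply(params$costs$screening_items, items_out),
      hospital_exam_items = lapply(params$costs$hospital_exam_items, function(it)
        list(item = it$item, cost = num(it$cost))),
      screening_per_person = lapply(params$costs$screening_per_person, pv_out),
      hospital_exam_total = pv_out(params$costs$hospital_exam_total),
      photocoagulation = pv_out(params$costs$photocoagulation),
      anti_vegf = pv_out(params$costs$anti_vegf),
      followup_maintain = pv_out(params$costs$followup_maintain),
      svi_first_year = pv_out(params$costs$svi_first_year),
      svi_subsequent_year = pv_out(params$costs$svi_subsequent_year)
    ),
    mortality = list(
      rr_diabetes = pv_out(params$mortality$rr_diabetes),
      rr_svi = pv_out(params$mortality$rr_svi),
      svi_multiplier_mode = params$mortality$svi_multiplier_mode,
      life_table = list(table = lapply(seq_len(nrow(params$mortality$life_table)),
        function(i) list(age = params$mortality$life_table$age[i],
                         q = num(params$mortality$life_table$q[i]))))
    ),
    compliance = list(uptake = pv_out(params$compliance$uptake),
                      referral_acceptance = pv_out(params$compliance$referral_acceptance)),
    economics = list(
      discount_rate = num(params$economics$discount_rate),
      n_cycles = params$economics$n_cycles,
      cycle_length = params$economics$cycle_length,
      start_age = params$economics$start_age,
      persons_screened_per_year = params$economics$persons_screened_per_year,
      exchange_rate_cny_per_usd = num(params$economics$exchange_rate_cny_per_usd),
      wtp_1x = num(params$economics$wtp_1x)
    ),
    dsa_ranges = params$dsa_ranges,
    model_options = params$model_options
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.dr_parameters <- function(x, ...) {
  cat("<dr_parameters> setting:", x$setting, "\n")
  cat("  prevalence (base): NPDR", x$prevalence$npdr["base"],
      " PDR", x$prevalence$pdr["base"], " DME", x$prevalence$dme["base"], "\n")
  cat("  cycles:", x$economics$n_cycles, " start age:", x$economics$start_age,
      " discount:", x$economics$discount_rate, "\n")
  cat("  WTP thresholds: 1x =", x$economics$wtp_1x, " 3x =", x$economics$wtp_3x, "USD/QALY\n")
  cat("  screening $/person: community",
      round(x$costs$screening_per_person$community["base"], 2),
      " telemedicine", round(x$costs$screening_per_person$telemedicine["base"], 2), "\n")
  nv <- length(validate_parameters(x))
  cat("  validation:", if (nv == 0) "OK" else paste(nv, "violation(s)"), "\n")
  invisible(x)
}

# ---- parameter registry: flat view of the uncertain parameters ----------

#' Enumerate the uncertain model parameters
#'
#' Flattens a parameter set into one row per uncertain scalar: dotted name,
#' group (prevalence, transition, utility, test, compliance, cost_program,
#' cost_treatment), base value, 95% bounds, the sampling family used in
#' probabilistic sensitivity analysis (beta for probabilities and utilities,
#' gamma for costs) and the one-way DSA relative range. Complement-type test
#' entries (the called-normal fractions) are excluded: they are recomputed
#' from their drawn counterparts so that classification rows stay stochastic.
#'
#' @param params a `dr_parameters` object.
#' @return data.frame with columns `name`, `group`, `base`, `lo`, `hi`,
#'   `family`, `dsa_range`.
#' @export
param_registry <- function(params) {
  rows <- list()
  add <- function(name, x, group, family, range_key) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, group = group, base = unname(x["base"]),
      lo = unname(x["lo"]), hi = unname(x["hi"]), family = family,
      dsa_range = params$dsa_ranges[[range_key]], stringsAsFactors = FALSE)
  }
  for (k in names(params$prevalence))
    add(paste0("prevalence.", k), params$prevalence[[k]], "prevalence", "beta", "probability")
  for (k in names(params$transitions))
    add(paste0("transitions.", k), params$transitions[[k]], "transition", "beta", "probability")
  for (k in names(params$utilities))
    add(paste0("utilities.", k), params$utilities[[k]], "utility", "beta", "utility")
  for (mod in names(params$tests))
    for (k in setdiff(names(params$tests[[mod]]), "normal_called_normal"))
      add(paste0("tests.", mod, ".", k), params$tests[[mod]][[k]], "test", "beta", "test")
  add("compliance.uptake", params$compliance$uptake, "compliance", "beta", "compliance")
  add("compliance.referral_acceptance", params$compliance$referral_acceptance,
      "compliance", "beta", "compliance")
  for (mod in names(params$costs$screening_per_person))
    add(paste0("costs.screening_per_person.", mod),
        params$costs$screening_per_person[[mod]], "cost_program", "gamma", "cost_program")
  add("costs.hospital_exam_total", params$costs$hospital_exam_total,
      "cost_program", "gamma", "cost_program")
  for (k in c("photocoagulation", "anti_vegf", "followup_maintain",
              "svi_first_year", "svi_subsequent_year"))
    add(paste0("costs.", k), params$costs[[k]], "cost_treatment", "gamma", "cost_treatment")
  do.call(rbind, rows)
}

#' Set one parameter's base value by dotted name
#'
#' Used by the sensitivity machinery to perturb a single parameter, e.g.
#' `"transitions.treated_pdr_to_svi"` or `"costs.screening_per_person.community"`.
#' Touching a derived cost (per-person screening cost, exam total) detaches
#' it from its line items, which then no longer constrain validation.
#'
#' @param params a `dr_parameters` object.
#' @param name dotted parameter name as listed by [param_registry()].
#' @param value new base value.
#' @return modified `dr_parameters` object (bounds are left untouched).
#' @export
set_param <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  ref <- params
  node <- function(p, idx) Reduce(function(acc, k) acc[[k]], idx, p)
  leaf <- node(ref, parts)
  if (is.null(leaf)) stop("unknown parameter: ", name)
  leaf["base"] <- value
  leaf["lo"] <- min(leaf["lo"], value)
  leaf["hi"] <- max(leaf["hi"], value)
  expr <- Reduce(function(acc, k) call("[[", acc, k), parts, quote(params))
  eval(call("<-", expr, leaf))
  if (parts[1] == "costs") params$costs$items_authoritative <- FALSE
  params
}

get_param <- function(params, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  unname(Reduce(function(acc, k) acc[[k]], parts, params)["base"])
}

# Repair a perturbed parameter set so every invariant holds again: clamp
# probabilities and utilities to their supports, cap treated progression at
# the untreated value, rescale outgoing transition mass and prevalence to
# sum below 1. Used by the DSA (bounds are clipped, never aborted) and by
# the synthetic perturbation generator.
clip_parameters <- function(params) {
  clamp <- function(x, lo = 0, hi = 1) {
    x["base"] <- min(max(x["base"], lo), hi)
    x["lo"] <- max(lo, min(x["lo"], x["base"]))
    x["hi"] <- min(hi, max(x["hi"], x["base"]))
    x
  }
  for (k in names(params$prevalence))
    params$prevalence[[k]] <- clamp(params$prevalence[[k]])
  psum <- sum(vapply(params$prevalence, function(x) x["base"], numeric(1)))
  if (psum >= 1)
    for (k in names(params$prevalence))
      params$prevalence[[k]]["base"] <- params$prevalence[[k]]["base"] / psum * 0.999
  for (k in names(params$transitions))
    params$transitions[[k]] <- clamp(params$transitions[[k]])
  tr <- params$transitions
  pairs <- list(c("normal_to_npdr", "normal_to_pdr"), c("npdr_to_pdr", "npdr_to_dme"),
                c("pdr_to_dme", "pdr_to_svi"))
  for (pr in pairs) {
    s <- tr[[pr[1]]]["base"] + tr[[pr[2]]]["base"]
    if (s > 1) for (k in pr) params$transitions[[k]]["base"] <-
        params$transitions[[k]]["base"] / s
  }
  params$transitions$treated_pdr_to_svi["base"] <-
    min(params$transitions$treated_pdr_to_svi["base"],
        params$transitions$pdr_to_svi["base"])
  params$transitions$treated_dme_to_svi["base"] <-
    min(params$transitions$treated_dme_to_svi["base"],
        params$transitions$dme_to_svi["base"])
  for (k in names(params$utilities))
    params$utilities[[k]] <- clamp(params$utilities[[k]])
  u <- params$utilities
  params$utilities$npdr["base"] <- min(u$npdr["base"], u$no_dr["base"])
  params$utilities$pdr["base"] <- min(u$pdr["base"], params$utilities$npdr["base"])
  params$utilities$dme["base"] <- min(u$dme["base"], params$utilities$npdr["base"])
  params$utilities$svi["base"] <- min(u$svi["base"], params$utilities$pdr["base"],
                                      params$utilities$dme["base"])
  for (mod in names(params$tests)) {
    for (k in names(params$tests[[mod]]))
      params$tests[[mod]][[k]] <- clamp(params$tests[[mod]][[k]])
    te <- params$tests[[mod]]
    params$tests[[mod]]$normal_called_normal["base"] <-
      1 - te$normal_called_npdr["base"]
    s <- te$pdr_called_npdr["base"] + te$pdr_called_normal["base"]
    if (s > 1) {
      params$tests[[mod]]$pdr_called_npdr["base"] <- te$pdr_called_npdr["base"] / s
      params$tests[[mod]]$pdr_called_normal["base"] <- te$pdr_called_normal["base"] / s
    }
  }
  for (k in c("hospital_exam_total", "photocoagulation", "anti_vegf",
              "followup_maintain", "svi_first_year", "svi_subsequent_year"))
    params$costs[[k]]["base"] <- max(params$costs[[k]]["base"], 0)
  for (mod in names(params$costs$screening_per_person))
    params$costs$screening_per_person[[mod]]["base"] <-
      max(params$costs$screening_per_person[[mod]]["base"], 0)
  params$compliance$uptake <- clamp(params$compliance$uptake)
  params$compliance$referral_acceptance <- clamp(params$compliance$referral_acceptance)
  params$costs$items_authoritative <- FALSE
  # repairs above may have moved a base outside its stated interval; widen
  fix <- function(x) {
    x["lo"] <- min(x["lo"], x["base"]); x["hi"] <- max(x["hi"], x["base"]); x
  }
  for (k in names(params$prevalence)) params$prevalence[[k]] <- fix(params$prevalence[[k]])
  for (k in names(params$transitions)) params$transitions[[k]] <- fix(params$transitions[[k]])
  for (k in names(params$utilities)) params$utilities[[k]] <- fix(params$utilities[[k]])
  for (mod in names(params$tests))
    for (k in names(params$tests[[mod]]))
      params$tests[[mod]][[k]] <- fix(params$tests[[mod]][[k]])
  params
}
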