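# shared plumbing for the report commands: output dir, manifest, JSON dump
start_run <- function(out_dir, seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  list(out_dir = out_dir, seed = seed, outputs = character(0),
       started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

finish_run <- function(man, config = NULL) {
  manifest <- list(
    package = "drcea",
    version = as.character(utils::packageVersion("drcea")),
    timestamp = man$started,
    config = config,
    seed = man$seed,
    outputs = man$outputs
  )
  path <- file.path(man$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

emit <- function(man, name, writer) {
  path <- file.path(man$out_dir, name)
  writer(path)
  man$outputs <- c(man$outputs, name)
  man
}

#' Base-case cost-utility report
#'
#' Runs each requested strategy through the cohort engine and writes a
#' summary table in the shape of the published results table: per-person
#' cost and QALYs per strategy, incremental columns and ICUR (or dominance)
#' for each screening strategy against no screening plus telemedicine
#' against community, as CSV and JSON, with a run manifest.
#'
#' @param params a validated `dr_parameters` object (or `NULL` to load the
#'   packaged fixture for `setting`).
#' @param setting `"rural"` or `"urban"`, used when `params` is `NULL`.
#' @param strategies strategies to run.
#' @param interval screening interval.
#' @param out_dir output directory (created if needed); `NULL` suppresses
#'   file output.
#' @param config optional path of the config the parameters came from
#'   (recorded in the manifest).
#' @return list with `results` (strategy results), `comparisons`
#'   (`cea_comparison`s) and `table` (the summary data.frame).
#' @export
report_base_case <- function(params = NULL, setting = "rural",
                             strategies = c("none", "community", "telemedicine"),
                             interval = "one-off", out_dir = NULL,
                             config = NULL) {
  if (is.null(params)) params <- load_parameters(setting = setting)
  res <- lapply(stats::setNames(nm = strategies), function(s)
    run_strategy(params, s, interval))
  comps <- list()
  if ("none" %in% strategies)
    for (s in setdiff(strategies, "none"))
      comps[[paste0(s, "_vs_none")]] <-
        icur(res[[s]], res[["none"]], params$economics$wtp_1x)
  if (all(c("community", "telemedicine") %in% strategies))
    comps[["telemedicine_vs_community"]] <-
      icur(res[["telemedicine"]], res[["community"]], params$economics$wtp_1x)

  tab <- do.call(rbind, lapply(strategies, function(s) {
    cmp <- comps[[paste0(s, "_vs_none")]]
    data.frame(setting = params$setting, strategy = s,
               interval = as.character(interval),
               cost_per_person = round(res[[s]]$cost, 2),
               qalys_per_person = round(res[[s]]$qalys, 5),
               incr_cost = if (is.null(cmp)) NA else round(cmp$delta_cost, 2),
               incr_qaly = if (is.null(cmp)) NA else round(cmp$delta_qaly, 5),
               icur = if (is.null(cmp)) NA else round(cmp$icur, 2),
               verdict = if (is.null(cmp)) NA_character_ else cmp$verdict,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    man <- start_run(out_dir)
    man <- emit(man, "base_case.csv", function(p)
      utils::write.csv(tab, p, row.names = FALSE))
    man <- emit(man, "comparisons.csv", function(p) comparison_table(comps, p))
    man <- emit(man, "base_case.json", function(p)
      jsonlite::write_json(tab, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    finish_run(man, config)
  }
  list(results = res, comparisons = comps, table = tab)
}

#' Screening-interval comparison report
#'
#' Runs one strategy at the one-off schedule and every interval from
#' `k_max` down to 1 year, and applies the interval-recommendation walk at
#' the 3x GDP threshold.
#'
#' @inheritParams report_base_case
#' @param strategy the screening strategy to evaluate.
#' @param k_max largest repeat interval in years.
#' @return list with `results`, `recommendation` and `table`.
#' @export
report_intervals <- function(params = NULL, setting = "rural",
                             strategy = "telemedicine", k_max = 5,
                             out_dir = NULL, config = NULL) {
  if (is.null(params)) params <- load_parameters(setting = setting)
  if (k_max < 1) stop("k_max must be >= 1")
  ivals <- c(list("one-off"), as.list(rev(seq_len(k_max))))
  res <- lapply(ivals, function(iv) run_strategy(params, strategy, iv))
  rec <- interval_recommendation(res, wtp = params$economics$wtp_3x)
  tab <- do.call(rbind, lapply(seq_along(res), function(i) data.frame(
    setting = params$setting, strategy = strategy,
    interval = as.character(res[[i]]$interval),
    cost_per_person = round(res[[i]]$cost, 2),
    qalys_per_person = round(res[[i]]$qalys, 5),
    accepted = rec$accepted[i], stringsAsFactors = FALSE)))
  tab$recommended <- tab$interval == as.character(rec$interval)
  if (!is.null(out_dir)) {
    man <- start_run(out_dir)
    man <- emit(man, "intervals.csv", function(p)
      utils::write.csv(tab, p, row.names = FALSE))
    man <- emit(man, "intervals.json", function(p)
      jsonlite::write_json(list(table = tab, recommended = as.character(rec$interval)),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    finish_run(man, config)
  }
  list(results = res, recommendation = rec, table = tab)
}

#' Sensitivity-analysis report
#'
#' `mode = "dsa"` writes the sorted tornado table for the requested
#' comparison; `mode = "psa"` writes the PSA draw table, ICUR CIs,
#' preference probabilities and CEAC points. The manifest records the seed
#' whenever stochastic work ran.
#'
#' @inheritParams report_base_case
#' @param mode `"dsa"` or `"psa"`.
#' @param comparator,reference strategies compared.
#' @param n_iter PSA iterations (>= 2).
#' @param seed PSA seed.
#' @return the `tornado` table (dsa) or `psa_result` (psa).
#' @export
report_sensitivity <- function(params = NULL, setting = "rural",
                               mode = c("dsa", "psa"),
                               comparator = "telemedicine", reference = "none",
                               interval = "one-off",
                               n_iter = 1000, seed = 1, out_dir = NULL,
                               config = NULL) {
  mode <- match.arg(mode)
  if (is.null(params)) params <- load_parameters(setting = setting)
  if (mode == "dsa") {
    tor <- one_way_dsa(params, comparator, reference, interval)
    if (!is.null(out_dir)) {
      man <- start_run(out_dir)
      man <- emit(man, "tornado.csv", function(p)
        utils::write.csv(as.data.frame(tor), p, row.names = FALSE))
      finish_run(man, config)
    }
    return(tor)
  }
  psa <- run_psa(params, interval = interval, n_iter = n_iter, seed = seed)
  if (!is.null(out_dir)) {
    man <- start_run(out_dir, seed = seed)
    draws <- data.frame(iteration = seq_len(psa$n_iter), psa$param_draws,
                        cost = psa$outcomes$cost, qaly = psa$outcomes$qaly)
    man <- emit(man, "psa_draws.csv", function(p)
      utils::write.csv(draws, p, row.names = FALSE))
    man <- emit(man, "ceac.csv", function(p)
      utils::write.csv(psa$ceac, p, row.names = FALSE))
    summ <- lapply(psa$summaries, function(s)
      s[c("comparator", "reference", "mean_delta_cost", "mean_delta_qaly",
          "icur_ci", "excluded_fraction", "p_dominant",
          "p_preferred_1x", "p_preferred_3x")])
    man <- emit(man, "psa_summary.json", function(p)
      jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    finish_run(man, config)
  }
  psa
}
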