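#' Incremental cost-utility comparison
#'
#' Compares a strategy (the comparator) against a reference: the ICUR is
#' the incremental cost divided by the incremental QALYs. When the
#' comparator costs less and gains QALYs it dominates (no ratio is
#' meaningful); when it costs more and loses QALYs it is dominated; when
#' the QALY difference is below tolerance the ICUR is flagged undefined
#' rather than raising an error. Verdicts follow the WHO convention:
#' "significantly cost-effective" below 1x per-capita GDP and
#' "cost-effective" below 3x (only for comparisons that gain QALYs).
#'
#' @param comparator,reference `strategy_result` objects (or any list with
#'   `cost` and `qalys`), from the same setting.
#' @param wtp_1x willingness-to-pay threshold at 1x per-capita GDP
#'   (USD/QALY); `wtp_3x` defaults to three times it.
#' @param wtp_3x threshold at 3x per-capita GDP.
#' @param tolerance QALY difference below which the ratio is not formed.
#' @return a `cea_comparison`: `delta_cost`, `delta_qaly`, `icur` (NA when
#'   dominant/dominated/undefined), `dominance` (`"none"`,
#'   `"comparator_dominant"`, `"reference_dominant"`, `"undefined"`),
#'   `verdict`, and `nmb_1x`/`nmb_3x` net monetary benefits.
#' @export
#' @examples
#' a <- list(cost = 228.36, qalys = 12.10573, setting = "rural",
#'           strategy = "community", interval = "one-off")
#' b <- list(cost = 214.07, qalys = 12.10231, setting = "rural",
#'           strategy = "none", interval = "one-off")
#' icur(a, b, wtp_1x = 7000)$icur
icur <- function(comparator, reference, wtp_1x, wtp_3x = 3 * wtp_1x,
                 tolerance = 1e-9) {
  if (!is.null(comparator$setting) && !is.null(reference$setting) &&
      !identical(comparator$setting, reference$setting))
    stop("ICUR compares strategies from the same setting; got ",
         comparator$setting, " vs ", reference$setting)
  dc <- comparator$cost - reference$cost
  dq <- comparator$qalys - reference$qalys
  ratio <- NA_real_
  dominance <- "none"
  if (abs(dq) <= tolerance) {
    dominance <- if (abs(dc) > tolerance) "undefined" else "none"
  } else if (dc < 0 && dq > 0) {
    dominance <- "comparator_dominant"
  } else if (dc > 0 && dq < 0) {
    dominance <- "reference_dominant"
  } else {
    ratio <- dc / dq
  }
  verdict <- if (dominance == "comparator_dominant") {
    "significantly cost-effective (dominant)"
  } else if (dominance == "reference_dominant") {
    "not cost-effective (dominated)"
  } else if (dominance == "undefined") {
    "undefined ICUR"
  } else if (is.na(ratio)) {
    "equivalent"
  } else if (dq > 0 && ratio < wtp_1x) {
    "significantly cost-effective"
  } else if (dq > 0 && ratio < wtp_3x) {
    "cost-effective"
  } else {
    "not cost-effective"
  }
  structure(list(
    comparator = comparator, reference = reference,
    delta_cost = dc, delta_qaly = dq, icur = ratio, dominance = dominance,
    verdict = verdict, wtp_1x = wtp_1x, wtp_3x = wtp_3x,
    nmb_1x = wtp_1x * dq - dc, nmb_3x = wtp_3x * dq - dc
  ), class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  lbl <- function(r) if (is.null(r$strategy)) "?" else
    paste0(r$strategy, if (!identical(r$interval, "one-off"))
      paste0("@", r$interval, "yr") else "")
  cat(sprintf("<cea_comparison> %s vs %s: dCost $%.2f, dQALY %.5f, %s\n",
              lbl(x$comparator), lbl(x$reference), x$delta_cost, x$delta_qaly,
              if (!is.na(x$icur)) sprintf("ICUR $%.2f/QALY (%s)", x$icur, x$verdict)
              else x$verdict))
  invisible(x)
}

#' Net monetary benefit
#'
#' NMB(lambda) = lambda x delta QALY - delta cost for a comparison; used to
#' build cost-effectiveness acceptability curves.
#'
#' @param delta_cost,delta_qaly incremental cost (USD) and QALYs.
#' @param lambda willingness-to-pay (USD/QALY), scalar or vector.
#' @return numeric vector of NMB values.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, lambda) {
  lambda * delta_qaly - delta_cost
}

#' Recommend a screening interval
#'
#' Walks the strategies from the longest screening interval to the
#' shortest; each shortening is accepted when its pairwise ICUR against the
#' last accepted interval is below the willingness-to-pay threshold (or it
#' dominates); the shortest accepted interval is recommended. Shorter
#' intervals are expected to cost more and yield more QALYs.
#'
#' @param results list of `strategy_result`s for the same setting and
#'   strategy, ordered by strictly decreasing interval (a leading
#'   `"one-off"` entry is treated as the longest).
#' @param wtp threshold in USD/QALY (typically 3x per-capita GDP).
#' @return list with `interval` (the recommendation), `accepted` (logical
#'   per input), and `comparisons` (the pairwise `cea_comparison`s).
#' @export
interval_recommendation <- function(results, wtp) {
  if (length(results) < 2) stop("need at least two strategy results")
  ivals <- vapply(results, function(r)
    if (identical(r$interval, "one-off")) Inf else as.numeric(r$interval),
    numeric(1))
  if (any(diff(ivals) >= 0))
    stop("validation error: results must be ordered by strictly decreasing interval")
  accepted <- logical(length(results))
  accepted[1] <- TRUE
  last <- 1L
  comps <- list()
  for (i in seq_along(results)[-1]) {
    cmp <- icur(results[[i]], results[[last]], wtp_1x = wtp, wtp_3x = wtp)
    comps[[length(comps) + 1L]] <- cmp
    ok <- cmp$dominance == "comparator_dominant" ||
      (!is.na(cmp$icur) && cmp$delta_qaly > 0 && cmp$icur < wtp)
    if (ok) { accepted[i] <- TRUE; last <- i }
  }
  list(interval = results[[max(which(accepted))]]$interval,
       accepted = accepted, comparisons = comps)
}

#' Export comparisons as a delimited table
#'
#' @param comparisons list of `cea_comparison` objects.
#' @param path optional CSV path; when `NULL` the data.frame is returned only.
#' @return data.frame (one row per comparison), invisibly when written.
#' @export
comparison_table <- function(comparisons, path = NULL) {
  row <- function(x) data.frame(
    setting = x$comparator$setting %||% NA_character_,
    comparator = x$comparator$strategy %||% NA_character_,
    comparator_interval = as.character(x$comparator$interval %||% NA),
    reference = x$reference$strategy %||% NA_character_,
    delta_cost = x$delta_cost, delta_qaly = x$delta_qaly,
    icur = x$icur, dominance = x$dominance, verdict = x$verdict,
    stringsAsFactors = FALSE)
  df <- do.call(rbind, lapply(comparisons, row))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
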