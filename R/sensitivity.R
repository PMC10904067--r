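#' Fit a sampling distribution to a parameter's point estimate and CI
#'
#' Method-of-moments fit with mean equal to the base value and standard
#' deviation (hi - lo) / (2 x 1.959964), reading the interval as a normal
#' 95% CI. Probabilities and utilities use a beta distribution
#' (alpha = m (m(1-m)/v - 1), beta = (1-m)(m(1-m)/v - 1)); costs use a
#' gamma (shape = m^2/v, scale = v/m). A degenerate interval (v = 0) gives
#' a point mass ("fixed").
#'
#' @param base point estimate (the distribution mean).
#' @param lo95,hi95 95% interval bounds, lo95 <= base <= hi95.
#' @param family `"beta"`, `"gamma"` or `"fixed"`.
#' @param name parameter name, used in error messages.
#' @return a `parameter_distribution` list: `name`, `base`, `lo95`, `hi95`,
#'   `family`, and the fitted shape parameters.
#' @export
#' @examples
#' fit_distribution(0.95, 0.92, 0.99, "beta", "utility_no_dr")
fit_distribution <- function(base, lo95, hi95, family = c("beta", "gamma", "fixed"),
                             name = "parameter") {
  family <- match.arg(family)
  if (lo95 > base || base > hi95)
    stop("fit error for '", name, "': need lo95 <= base <= hi95")
  m <- base
  s <- (hi95 - lo95) / (2 * 1.959964)
  v <- s^2
  if (v == 0) family <- "fixed"
  fit <- switch(family,
    fixed = list(),
    beta = {
      if (m <= 0 || m >= 1)
        stop("fit error for '", name, "': beta mean must lie in (0, 1), got ", m)
      if (v >= m * (1 - m))
        stop("fit error for '", name, "': variance ", signif(v, 4),
             " >= m(1-m) = ", signif(m * (1 - m), 4), "; beta fit impossible")
      k <- m * (1 - m) / v - 1
      list(shape1 = m * k, shape2 = (1 - m) * k)
    },
    gamma = {
      if (m <= 0)
        stop("fit error for '", name, "': gamma mean must be positive, got ", m)
      list(shape = m^2 / v, scale = v / m)
    })
  structure(c(list(name = name, base = base, lo95 = lo95, hi95 = hi95,
                   family = family), fit),
            class = "parameter_distribution")
}

#' @export
print.parameter_distribution <- function(x, ...) {
  cat("<parameter_distribution>", x$name, x$family,
      switch(x$family,
             beta = sprintf("(a=%.3g, b=%.3g)", x$shape1, x$shape2),
             gamma = sprintf("(shape=%.3g, scale=%.3g)", x$shape, x$scale),
             fixed = sprintf("(= %g)", x$base)), "\n")
  invisible(x)
}

#' Draw from a fitted parameter distribution
#'
#' @param dist a `parameter_distribution` from [fit_distribution()].
#' @param n number of draws.
#' @return numeric vector of draws (constant for `"fixed"`).
#' @export
draw_distribution <- function(dist, n = 1) {
  switch(dist$family,
    fixed = rep(dist$base, n),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale))
}

# ratio dc/dq whenever the QALY difference is resolvable; sign retained so
# that dominating (negative) ratios are visible in tornado/PSA summaries
raw_icur <- function(comp_res, ref_res, tolerance = 1e-9) {
  dq <- comp_res$qalys - ref_res$qalys
  if (abs(dq) <= tolerance) return(NA_real_)
  (comp_res$cost - ref_res$cost) / dq
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each uncertain parameter one at a time to the low and high end of
#' its DSA range (relative ranges per group: by default 10% for
#' probabilities, utilities, test accuracy and compliance; 20% for
#' programme costs; 50% for treatment and SVI costs), clips the perturbed
#' value to its valid support, reruns both strategies, and records the
#' ICUR of the comparison at each bound. Entries are sorted by descending
#' span.
#'
#' @param params a validated `dr_parameters` object.
#' @param comparator,reference strategy names for the compared policies.
#' @param interval screening interval for both policies.
#' @return a `tornado` data.frame: `parameter`, `group`, `low_value`,
#'   `high_value`, `icur_low`, `icur_high`, `span`, plus the base-case ICUR
#'   as attribute `base_icur`.
#' @export
one_way_dsa <- function(params, comparator = "telemedicine", reference = "none",
                        interval = "one-off") {
  pol_c <- screening_policy(comparator, interval)
  pol_r <- if (reference == "none") screening_policy("none")
           else screening_policy(reference, interval)
  base_icur <- raw_icur(run_cohort(params, pol_c)$result,
                        run_cohort(params, pol_r)$result)
  reg <- param_registry(params)
  rerun <- function(name, value) {
    p2 <- clip_parameters(set_param(params, name, value))
    raw_icur(run_cohort(p2, pol_c)$result, run_cohort(p2, pol_r)$result)
  }
  rows <- lapply(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    lo_v <- r$base * (1 - r$dsa_range)
    hi_v <- r$base * (1 + r$dsa_range)
    if (r$family == "beta") hi_v <- min(hi_v, 1)
    lo_v <- max(lo_v, 0)
    data.frame(parameter = r$name, group = r$group,
               low_value = lo_v, high_value = hi_v,
               icur_low = rerun(r$name, lo_v), icur_high = rerun(r$name, hi_v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$span <- abs(out$icur_high - out$icur_low)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "base_icur") <- base_icur
  class(out) <- c("tornado", "data.frame")
  out
}

# assemble one drawn parameter set; complements recomputed so that
# classification rows stay stochastic
apply_draws <- function(params, reg, draws) {
  for (i in seq_len(nrow(reg)))
    params <- set_param(params, reg$name[i], draws[i])
  for (mod in names(params$tests)) {
    ncn <- 1 - unname(params$tests[[mod]]$normal_called_npdr["base"])
    x <- params$tests[[mod]]$normal_called_normal
    x["base"] <- ncn; x["lo"] <- min(x["lo"], ncn); x["hi"] <- max(x["hi"], ncn)
    params$tests[[mod]]$normal_called_normal <- x
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter independently from its fitted beta or
#' gamma distribution, reruns all strategies per iteration, and summarises:
#' percentile 95% CIs of the ICUR draws (2.5/97.5 percentiles over draws
#' with a resolvable QALY difference; the excluded fraction is reported),
#' cost-effectiveness acceptability curves (the fraction of iterations with
#' positive net monetary benefit at each willingness-to-pay value), and for
#' the telemedicine-vs-community comparison the fraction of iterations in
#' which telemedicine strictly dominates and the fraction in which it is
#' preferred at the 1x and 3x GDP thresholds. A drawn set violating the
#' parameter invariants is redrawn (the count is reported). Fully
#' reproducible given `seed`.
#'
#' @param params a validated `dr_parameters` object.
#' @param strategies strategy names to run each iteration.
#' @param interval screening interval applied to the screening strategies.
#' @param comparisons list of `c(comparator, reference)` strategy pairs.
#' @param n_iter number of iterations, >= 2 (default 1000).
#' @param seed integer RNG seed.
#' @param lambda_grid willingness-to-pay grid for the CEAC (USD/QALY);
#'   default 0 to 3x GDP in 40 steps.
#' @return a `psa_result`: `outcomes` (iteration x strategy cost/QALY
#'   draws), `param_draws`, `summaries` (per comparison: ICUR CI, excluded
#'   fraction, preference probabilities), `ceac` (long data.frame), counts
#'   of redraws, and the call settings.
#' @export
run_psa <- function(params, strategies = c("none", "community", "telemedicine"),
                    interval = "one-off",
                    comparisons = list(c("community", "none"),
                                       c("telemedicine", "none"),
                                       c("telemedicine", "community")),
                    n_iter = 1000, seed = 1,
                    lambda_grid = NULL) {
  if (n_iter < 2) stop("validation error: n_iter must be >= 2")
  comparisons <- Filter(function(cp) all(cp %in% strategies), comparisons)
  set.seed(seed)
  reg <- param_registry(params)
  dists <- lapply(seq_len(nrow(reg)), function(i)
    fit_distribution(reg$base[i], reg$lo[i], reg$hi[i],
                     family = reg$family[i], name = reg$name[i]))
  if (is.null(lambda_grid))
    lambda_grid <- seq(0, params$economics$wtp_3x, length.out = 41)

  pols <- lapply(stats::setNames(nm = strategies), function(s)
    if (s == "none") screening_policy("none") else screening_policy(s, interval))

  n_par <- nrow(reg)
  param_draws <- matrix(NA_real_, n_iter, n_par, dimnames = list(NULL, reg$name))
  cost <- qaly <- matrix(NA_real_, n_iter, length(strategies),
                         dimnames = list(NULL, strategies))
  n_redraw <- 0L
  for (it in seq_len(n_iter)) {
    repeat {
      dr <- vapply(dists, draw_distribution, numeric(1))
      p_it <- apply_draws(params, reg, dr)
      if (length(validate_parameters(p_it)) == 0) break
      n_redraw <- n_redraw + 1L
      if (n_redraw > 100L * n_iter) stop("too many invalid parameter draws")
    }
    param_draws[it, ] <- dr
    for (s in strategies) {
      r <- run_cohort(p_it, pols[[s]])$result
      cost[it, s] <- r$cost
      qaly[it, s] <- r$qalys
    }
  }

  tol <- 1e-9
  summaries <- lapply(comparisons, function(cp) {
    dc <- cost[, cp[1]] - cost[, cp[2]]
    dq <- qaly[, cp[1]] - qaly[, cp[2]]
    ok <- abs(dq) > tol
    ic <- ifelse(ok, dc / dq, NA_real_)
    ci <- stats::quantile(ic[ok], c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    list(comparator = cp[1], reference = cp[2],
         mean_delta_cost = mean(dc), mean_delta_qaly = mean(dq),
         icur_draws = ic, icur_ci = ci,
         excluded_fraction = mean(!ok),
         p_dominant = mean(dc < 0 & dq > 0),
         p_preferred_1x = mean(net_monetary_benefit(dc, dq, params$economics$wtp_1x) > 0),
         p_preferred_3x = mean(net_monetary_benefit(dc, dq, params$economics$wtp_3x) > 0))
  })
  names(summaries) <- vapply(comparisons, paste, character(1), collapse = "_vs_")

  ceac <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    dc <- cost[, s$comparator] - cost[, s$reference]
    dq <- qaly[, s$comparator] - qaly[, s$reference]
    data.frame(comparison = nm, lambda = lambda_grid,
               probability = vapply(lambda_grid, function(l)
                 mean(net_monetary_benefit(dc, dq, l) > 0), numeric(1)))
  }))

  structure(list(outcomes = list(cost = cost, qaly = qaly),
                 param_draws = param_draws, summaries = summaries, ceac = ceac,
                 n_iter = n_iter, seed = seed, n_redraw = n_redraw,
                 interval = interval, setting = params$setting),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$setting, "setting,", x$n_iter, "iterations (seed",
      paste0(x$seed, ")"), "\n")
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %s: mean ICUR basis dC $%.2f / dQ %.5f; 95%% CI [%.0f, %.0f]; P(pref @1xGDP) %.1f%%\n",
                nm, s$mean_delta_cost, s$mean_delta_qaly,
                s$icur_ci[1], s$icur_ci[2], 100 * s$p_preferred_1x))
  }
  if (x$n_redraw > 0) cat("  redraws due to invalid parameter sets:", x$n_redraw, "\n")
  invisible(x)
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x a `psa_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.psa_result <- function(x, ...) {
  wide <- stats::reshape(x$ceac, idvar = "lambda", timevar = "comparison",
                         direction = "wide")
  graphics::matplot(wide$lambda, wide[, -1, drop = FALSE], type = "l", lty = 1,
                    xlab = "Willingness to pay (USD/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("bottomright", legend = sub("probability\\.", "", names(wide)[-1]),
                   lty = 1, col = seq_len(ncol(wide) - 1), cex = 0.8)
  invisible(x)
}
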