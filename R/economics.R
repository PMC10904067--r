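#' Capital-cost annualization factor
#'
#' Annuity divisor converting the replacement cost of a capital item into an
#' equivalent annual cost over its useful life: \eqn{((1+r)^n - 1) / (r (1+r)^n)},
#' the present value of an n-year unit annuity at discount rate r. At r = 0
#' the continuity limit n is returned.
#'
#' Two rounding modes are provided. `"exact"` returns the full-precision
#' factor. `"printed"` quantizes the factor to two decimals by truncation,
#' giving 4.51 at the default costing assumptions (r = 0.035, n = 5); the
#' published line-item tables this package ships were computed with that
#' two-decimal factor, so `"printed"` reproduces them to the cent.
#'
#' @param r discount (interest) rate per year, >= 0.
#' @param n useful life of the capital item in years, >= 1.
#' @param rounding `"exact"` or `"printed"` (two-decimal truncated factor).
#' @return annualization factor in years.
#' @export
#' @examples
#' annualization_factor(0.035, 5)            # 4.515052...
#' annualization_factor(0.035, 5, "printed")   # 4.51
annualization_factor <- function(r, n, rounding = c("exact", "printed")) {
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(r), is.numeric(n), length(r) == 1L, length(n) == 1L)
  if (r < 0) stop("annualization_factor: discount rate r must be >= 0, got ", r)
  if (n < 1) stop("annualization_factor: useful life n must be >= 1, got ", n)
  # expm1/log1p keep the annuity form accurate as r -> 0
  f <- if (r == 0) n else {
    nl <- n * log1p(r)
    expm1(nl) / (r * exp(nl))
  }
  if (rounding == "printed") f <- trunc(f * 100) / 100
  f
}

#' Annualize the cost of a capital item
#'
#' Divides the replacement cost by the [annualization_factor()]. With
#' `rounding = "printed"` (the default) the factor is the two-decimal value
#' used in the published cost tables, so e.g. a $24,000 camera over 5 years
#' at 3.5% gives $5,321.51 per year.
#'
#' @param replacement_cost purchase price of the capital item, >= 0.
#' @param r discount rate per year (default 0.035).
#' @param n useful life in years (default 5).
#' @param rounding passed to [annualization_factor()]; default `"printed"`.
#' @return equivalent annual cost.
#' @export
annualize_capital <- function(replacement_cost, r = 0.035, n = 5,
                              rounding = c("printed", "exact")) {
  rounding <- match.arg(rounding)
  if (any(replacement_cost < 0))
    stop("annualize_capital: replacement_cost must be >= 0")
  replacement_cost / annualization_factor(r, n, rounding)
}

#' Per-person cost of a screening programme
#'
#' Sums annualized capital costs and annual recurring costs over the
#' programme's line items and divides by the number of people screened per
#' year. Capital items carry `unit_cost` (total purchase price for the line,
#' i.e. units x price each) and `life_years`; recurring items carry
#' `annual_cost`.
#'
#' @param items list of line items; each a list with `item`, `kind`
#'   (`"capital"` or `"recurring"`), and either `unit_cost` + `life_years`
#'   (capital) or `annual_cost` (recurring).
#' @param n_screened number of people screened per year, > 0.
#' @param r discount rate for annualization (default 0.035).
#' @param rounding annualization rounding mode, default `"printed"`.
#' @return list with `annual_total` (programme cost per year), `per_person`,
#'   and `annualized` (named vector of each line's annual cost).
#' @export
per_person_screening_cost <- function(items, n_screened, r = 0.035,
                                      rounding = c("printed", "exact")) {
  rounding <- match.arg(rounding)
  if (n_screened <= 0)
    stop("per_person_screening_cost: n_screened must be > 0, got ", n_screened)
  ann <- vapply(items, function(it) {
    kind <- match.arg(it$kind, c("capital", "recurring"))
    if (kind == "capital") {
      life <- if (is.null(it$life_years)) 5 else it$life_years
      annualize_capital(it$unit_cost, r = r, n = life, rounding = rounding)
    } else {
      it$annual_cost
    }
  }, numeric(1))
  names(ann) <- vapply(items, function(it) it$item, character(1))
  total <- sum(ann)
  list(annual_total = total, per_person = total / n_screened, annualized = ann)
}

#' Convert between cumulative incidence and annual rate
#'
#' `annual_incidence()` converts a cumulative incidence proportion p over an
#' interval of t years into a constant annual rate r = -ln(1 - p)/t;
#' `prob_from_rate()` is its inverse, 1 - exp(-r t). The pair are exact
#' mutual inverses under the constant-rate (exponential) assumption.
#'
#' @param p cumulative incidence in \code{[0, 1)}.
#' @param t interval length in years, > 0.
#' @param r rate per year, >= 0.
#' @return a rate per year, or a probability.
#' @export
#' @examples
#' annual_incidence(1 - exp(-0.15), t = 3)   # 0.05
annual_incidence <- function(p, t = 1) {
  if (any(p < 0) || any(p >= 1))
    stop("annual_incidence: cumulative incidence p must be in [0, 1)")
  if (any(t <= 0)) stop("annual_incidence: interval t must be > 0")
  -log(1 - p) / t
}

#' @rdname annual_incidence
#' @export
prob_from_rate <- function(r, t = 1) {
  if (any(r < 0)) stop("prob_from_rate: rate r must be >= 0")
  1 - exp(-r * t)
}

#' Convert Chinese yuan to US dollars
#'
#' Linear conversion at the 2020 People's Bank of China reference rate of
#' 6.9762 yuan per dollar (overridable).
#'
#' @param amount amount in CNY.
#' @param rate exchange rate in CNY per USD.
#' @return amount in USD.
#' @export
cny_to_usd <- function(amount, rate = 6.9762) {
  stopifnot(is.finite(rate), rate > 0)
  amount / rate
}
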