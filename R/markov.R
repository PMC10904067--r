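#' Initial cohort distribution
#'
#' Places the setting's NPDR/PDR/DME prevalence on the corresponding
#' undiagnosed states and the remainder on no-DR; the cohort enters the
#' model never screened, so every member starts undiagnosed.
#'
#' @param params a validated `dr_parameters` object.
#' @return named occupancy vector over [model_states()] summing to 1.
#' @export
#' @examples
#' sum(initial_distribution(load_parameters(setting = "rural")))
initial_distribution <- function(params) {
  p <- vapply(params$prevalence, function(x) unname(x["base"]), numeric(1))
  if (sum(p) >= 1)
    stop("validation error: prevalence must sum to < 1, got ", sum(p))
  occ <- stats::setNames(numeric(length(model_states())), model_states())
  occ["npdr_undx"] <- p[["npdr"]]
  occ["pdr_undx"] <- p[["pdr"]]
  occ["dme_undx"] <- p[["dme"]]
  occ["no_dr"] <- 1 - sum(p)
  occ
}

#' Annual death probability by age and health state
#'
#' Background (all-cause) mortality q(age) from the parameter set's life
#' table, inflated by the diabetes risk ratio for all alive states, except
#' that severe visual impairment uses its own (higher) risk ratio — by
#' default replacing, not stacking with, the diabetes multiplier
#' (`mortality$svi_multiplier_mode = "stack"` selects the product). The
#' inflated probability is capped at 1. Ages beyond the life table use its
#' last entry; ages below its start are an error.
#'
#' @param age age in years at the start of the cycle.
#' @param health clinical health state (one of [health_states()]).
#' @param mort the `mortality` component of a `dr_parameters` object.
#' @return death probability for the cycle.
#' @export
cycle_mortality <- function(age, health, mort) {
  if (health == "death") return(1)
  lt <- mort$life_table
  if (age < min(lt$age))
    stop("age ", age, " below the mortality schedule (starts at ", min(lt$age), ")")
  q <- if (age > max(lt$age)) lt$q[nrow(lt)] else lt$q[match(floor(age), lt$age)]
  if (is.na(q)) stop("age ", age, " not covered by the mortality schedule")
  rr <- if (health == "svi") {
    if (identical(mort$svi_multiplier_mode, "stack"))
      unname(mort$rr_svi["base"]) * unname(mort$rr_diabetes["base"])
    else unname(mort$rr_svi["base"])
  } else unname(mort$rr_diabetes["base"])
  min(1, q * rr)
}

#' Build the one-cycle transition matrix
#'
#' Row-stochastic matrix over the ten model states for one annual cycle at
#' a given age. Mortality applies first (competing-risk convention);
#' surviving mass is allocated to the allowed forward disease transitions:
#' no DR to NPDR/PDR; NPDR to PDR/DME; PDR to DME/SVI; DME to SVI; treated
#' states progress to SVI at their (lower) treated rates; NPDR under annual
#' follow-up is detected on progression, so it moves directly into the
#' treated states; residual mass stays put. First-year SVI survivors move
#' to the subsequent-year SVI state; death is absorbing. By default treated
#' PDR does not progress to DME (`model_options$treated_pdr_to_dme`
#' re-enables that path, into treated DME).
#'
#' @param params a validated `dr_parameters` object.
#' @param age age in years at the start of the cycle.
#' @return `transition_matrix`: a 10 x 10 row-stochastic matrix.
#' @export
build_transition_matrix <- function(params, age) {
  st <- model_states()
  n <- length(st)
  P <- matrix(0, n, n, dimnames = list(st, st))
  tr <- lapply(params$transitions, function(x) unname(x["base"]))
  hp <- state_health()
  for (s in st) {
    if (s == "death") { P[s, "death"] <- 1; next }
    pd <- cycle_mortality(age, hp[[s]], params$mortality)
    P[s, "death"] <- pd
    surv <- 1 - pd
    out <- switch(s,
      no_dr = c(npdr_undx = tr$normal_to_npdr, pdr_undx = tr$normal_to_pdr),
      npdr_undx = c(pdr_undx = tr$npdr_to_pdr, dme_undx = tr$npdr_to_dme),
      npdr_fu = c(pdr_tx = tr$npdr_to_pdr, dme_tx = tr$npdr_to_dme),
      pdr_undx = c(dme_undx = tr$pdr_to_dme, svi_new = tr$pdr_to_svi),
      pdr_tx = if (isTRUE(params$model_options$treated_pdr_to_dme))
        c(dme_tx = tr$pdr_to_dme, svi_new = tr$treated_pdr_to_svi)
      else c(svi_new = tr$treated_pdr_to_svi),
      dme_undx = c(svi_new = tr$dme_to_svi),
      dme_tx = c(svi_new = tr$treated_dme_to_svi),
      svi_new = c(svi_ong = 1),
      svi_ong = NULL)
    stay <- s
    if (!is.null(out)) {
      P[s, names(out)] <- surv * out
      stay_mass <- surv * (1 - sum(out))
    } else stay_mass <- surv
    if (s == "svi_new") stay_mass <- 0  # all survivors become ongoing SVI
    P[s, stay] <- P[s, stay] + stay_mass
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12))
    stop("internal consistency error: transition rows must sum to 1 (max dev ",
         max(abs(rs - 1)), ")")
  structure(P, class = c("transition_matrix", "matrix", "array"))
}

# one-off costs charged on specific transitions (treatment initiation when
# annual follow-up detects progression)
transition_cost_matrix <- function(params) {
  st <- model_states()
  C <- matrix(0, length(st), length(st), dimnames = list(st, st))
  C["npdr_fu", "pdr_tx"] <- unname(params$costs$photocoagulation["base"])
  C["npdr_fu", "dme_tx"] <- unname(params$costs$anti_vegf["base"])
  if (isTRUE(params$model_options$treated_pdr_to_dme))
    C["pdr_tx", "dme_tx"] <- unname(params$costs$anti_vegf["base"])
  C
}

#' Run the deterministic cohort model
#'
#' Propagates a unit cohort through `n_cycles` annual cycles from the start
#' age. At each cycle-start boundary where the policy's schedule fires, the
#' screening event is applied (management flags move, one-off screening,
#' exam and treatment costs are charged, discounted at the boundary); then
#' the age-specific transition matrix advances the cohort. Utilities and
#' recurring costs (annual follow-up, SVI care) accrue with half-cycle
#' correction — the trapezoidal mean of the cycle-start and cycle-end state
#' valuations — discounted at (1 + r)^-k for cycle k; treatment costs
#' triggered by within-cycle progression under follow-up are charged at the
#' cycle-end factor, undampened.
#'
#' @param params a validated `dr_parameters` object.
#' @param policy a [screening_policy()]; default none.
#' @return list with `trace` (a `cohort_trace` data.frame: cycle, age, one
#'   column per model state, cycle cost and QALY contributions, cumulative
#'   discounted totals) and `result` (a `strategy_result`: per-person
#'   discounted cost and QALYs).
#' @export
#' @examples
#' run_cohort(load_parameters(setting = "rural"))$result
run_cohort <- function(params, policy = screening_policy("none")) {
  ec <- params$economics
  d <- ec$discount_rate
  n_cyc <- ec$n_cycles
  u <- state_utilities(params)
  rc <- state_recurring_costs(params)
  tc <- transition_cost_matrix(params)
  has_tc <- any(tc != 0)

  occ <- initial_distribution(params)
  st <- model_states()
  trace <- matrix(NA_real_, n_cyc + 1L, length(st), dimnames = list(NULL, st))
  cyc_cost <- cyc_qaly <- numeric(n_cyc + 1L)
  cost_total <- qaly_total <- 0
  cum_cost <- cum_qaly <- numeric(n_cyc + 1L)

  for (k in seq_len(n_cyc)) {
    b <- k - 1L  # cycle-start boundary
    if (screen_due(policy, b)) {
      ev <- apply_screening_event(occ, policy, params)
      occ <- ev$occupancy
      cost_total <- cost_total + ev$cost * (1 + d)^(-b)
      cyc_cost[k] <- cyc_cost[k] + ev$cost
    }
    if (k == 1L) trace[1L, ] <- occ
    age <- ec$start_age + b
    P <- build_transition_matrix(params, age)
    occ_new <- drop(occ %*% P)
    disc <- (1 + d)^(-k)
    if (has_tc) {
      flow_cost <- sum((occ * P) * tc)
      cost_total <- cost_total + flow_cost * disc
      cyc_cost[k + 1L] <- cyc_cost[k + 1L] + flow_cost
    }
    q_k <- 0.5 * (sum(u * occ) + sum(u * occ_new))
    c_k <- 0.5 * (sum(rc * occ) + sum(rc * occ_new))
    qaly_total <- qaly_total + q_k * disc
    cost_total <- cost_total + c_k * disc
    cyc_qaly[k + 1L] <- cyc_qaly[k + 1L] + q_k
    cyc_cost[k + 1L] <- cyc_cost[k + 1L] + c_k
    occ <- occ_new
    trace[k + 1L, ] <- occ
    cum_cost[k + 1L] <- cost_total
    cum_qaly[k + 1L] <- qaly_total
  }
  cum_cost[1L] <- cyc_cost[1L]  # boundary-0 screening cost (undiscounted)
  tr <- data.frame(cycle = 0:n_cyc, age = ec$start_age + 0:n_cyc, trace,
                   cycle_cost = cyc_cost, cycle_qaly = cyc_qaly,
                   cum_disc_cost = cum_cost, cum_disc_qaly = cum_qaly)
  class(tr) <- c("cohort_trace", "data.frame")
  res <- structure(list(setting = params$setting, strategy = policy$strategy,
                        interval = policy$interval,
                        cost = cost_total, qalys = qaly_total),
                   class = "strategy_result")
  list(trace = tr, result = res)
}

#' Run one strategy and return its per-person result
#'
#' Thin wrapper over [run_cohort()] returning only the `strategy_result`.
#'
#' @inheritParams run_cohort
#' @param strategy,interval forwarded to [screening_policy()].
#' @param ... further arguments to [screening_policy()].
#' @return a `strategy_result`.
#' @export
run_strategy <- function(params, strategy = "none", interval = "one-off", ...) {
  run_cohort(params, screening_policy(strategy, interval, ...))$result
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s / %s / %s: cost $%.2f, %.5f QALYs per person\n",
              x$setting, x$strategy,
              if (identical(x$interval, "one-off")) "one-off"
              else paste0("every ", x$interval, " yr"),
              x$cost, x$qalys))
  invisible(x)
}

#' Export a cohort trace as a delimited table
#'
#' @param trace a `cohort_trace` (from [run_cohort()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
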