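#' Synthetic Gompertz life table
#'
#' Deterministic age-specific annual mortality schedule
#' q(age) = min(1, a e^{b (age - ref_age)}): a stand-in with the right
#' shape for an adult background-mortality schedule, not a transcription
#' of any national life table. The defaults (a = 0.004, b = 0.085) give
#' q(50) = 0.004 rising to about 0.022 at age 70.
#'
#' @param a baseline annual hazard at the reference age, > 0.
#' @param b log-hazard slope per year of age, >= 0.
#' @param age_from,age_to modelled age range (inclusive).
#' @param ref_age age at which q = a (defaults to `age_from`).
#' @return data.frame with columns `age` and `q`.
#' @export
#' @examples
#' lt <- make_life_table()
#' lt$q[lt$age == 70]  # ~0.0219
make_life_table <- function(a = 0.004, b = 0.085, age_from = 50, age_to = 100,
                            ref_age = age_from) {
  if (!is.finite(a) || a <= 0) stop("life table: baseline hazard a must be > 0")
  if (!is.finite(b) || b < 0) stop("life table: slope b must be >= 0")
  if (age_to < age_from) stop("life table: age_to must be >= age_from")
  age <- seq(age_from, age_to)
  data.frame(age = age, q = pmin(1, a * exp(b * (age - ref_age))))
}

#' Randomly perturbed but internally consistent parameter sets
#'
#' Multiplies every uncertain parameter by an independent lognormal factor
#' (unit mean, relative standard deviation `relative_sd`), then repairs the
#' result so that all invariants hold again: probabilities are clamped to
#' \code{[0, 1]}, treated progression is capped at untreated, complement
#' test entries are recomputed, outgoing transition mass and prevalence are
#' rescaled below 1, and utility ordering is restored. Seed-deterministic.
#' Intended for property-style testing of the model machinery.
#'
#' @param params a validated `dr_parameters` object.
#' @param relative_sd relative standard deviation of the noise, >= 0.
#' @param seed integer RNG seed.
#' @return a valid `dr_parameters` object.
#' @export
perturb_parameters <- function(params, relative_sd = 0.1, seed = 1) {
  if (relative_sd < 0) stop("relative_sd must be >= 0")
  if (relative_sd == 0) return(params)
  set.seed(seed)
  reg <- param_registry(params)
  sdlog <- sqrt(log(1 + relative_sd^2))
  fac <- stats::rlnorm(nrow(reg), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  for (i in seq_len(nrow(reg)))
    params <- set_param(params, reg$name[i], reg$base[i] * fac[i])
  clip_parameters(params)
}

#' Individual-level microsimulation (validation oracle)
#'
#' Simulates each cohort member's random trajectory cycle by cycle with the
#' same event ordering, cost and utility valuation, discounting and
#' half-cycle convention as the deterministic cohort engine — but with its
#' own independently written transition and screening sampling (it does not
#' call the cohort engine's transition-matrix code), so agreement between
#' the two is a genuine cross-check of the transition algebra. Monte-Carlo
#' means converge to the cohort model's expectations.
#'
#' @param params a validated `dr_parameters` object.
#' @param policy a [screening_policy()].
#' @param n_individuals number of simulated individuals, >= 1.
#' @param seed integer RNG seed.
#' @return a `microsim_result`: `mean_cost`, `mean_qaly`, `se_cost`,
#'   `se_qaly`, `n`, plus the per-individual totals.
#' @export
microsimulate <- function(params, policy = screening_policy("none"),
                          n_individuals = 1e4, seed = 1) {
  stopifnot(n_individuals >= 1)
  set.seed(seed)
  n <- as.integer(n_individuals)
  ec <- params$economics
  d <- ec$discount_rate
  n_cyc <- ec$n_cycles
  st <- model_states()
  i_of <- stats::setNames(seq_along(st), st)
  DEATH <- i_of[["death"]]
  u <- state_utilities(params)
  rc <- state_recurring_costs(params)
  tr <- lapply(params$transitions, function(x) unname(x["base"]))
  lt <- params$mortality$life_table
  rr_dm <- unname(params$mortality$rr_diabetes["base"])
  rr_svi <- if (identical(params$mortality$svi_multiplier_mode, "stack"))
    unname(params$mortality$rr_svi["base"]) * rr_dm
  else unname(params$mortality$rr_svi["base"])
  rr_by_state <- ifelse(st %in% c("svi_new", "svi_ong"), rr_svi, rr_dm)

  # initial states from the prevalence distribution
  occ0 <- initial_distribution(params)
  state <- sample.int(length(st), n, replace = TRUE, prob = occ0)

  cost <- qaly <- numeric(n)
  screening <- policy$strategy != "none"
  if (screening) {
    comp <- policy_compliance(policy, params)
    te <- lapply(params$tests[[policy$strategy]], function(x) unname(x["base"]))
    scr_cost <- unname(params$costs$screening_per_person[[policy$strategy]]["base"])
    exam_cost <- unname(params$costs$hospital_exam_total["base"])
    photo <- unname(params$costs$photocoagulation["base"])
    avegf <- unname(params$costs$anti_vegf["base"])
  }
  photo_fu <- unname(params$costs$photocoagulation["base"])
  avegf_fu <- unname(params$costs$anti_vegf["base"])
  tx_dme_allowed <- isTRUE(params$model_options$treated_pdr_to_dme)

  for (k in seq_len(n_cyc)) {
    b <- k - 1L
    disc_b <- (1 + d)^(-b)
    disc_k <- (1 + d)^(-k)
    if (screening && screen_due(policy, b)) {
      att <- state %in% i_of[screenable_states()] &
        stats::runif(n) < comp$uptake
      cost[att] <- cost[att] + scr_cost * disc_b
      dme_flag <- stats::runif(n) < (1 - te$dme_specificity)  # false-positive DME call
      grade_pos <- rep(FALSE, n)
      idx <- att & state == i_of[["no_dr"]]
      grade_pos[idx] <- stats::runif(sum(idx)) < te$normal_called_npdr
      idx <- att & state == i_of[["npdr_undx"]]
      grade_pos[idx] <- stats::runif(sum(idx)) >= te$npdr_called_normal
      idx <- att & state == i_of[["pdr_undx"]]
      grade_pos[idx] <- stats::runif(sum(idx)) >= te$pdr_called_normal
      referred <- att & (grade_pos | dme_flag)
      idx <- att & state == i_of[["dme_undx"]]
      referred[idx] <- stats::runif(sum(idx)) < te$dme_sensitivity
      accepted <- referred & stats::runif(n) < comp$referral
      cost[accepted] <- cost[accepted] + exam_cost * disc_b
      conf <- accepted & state == i_of[["npdr_undx"]]
      state[conf] <- i_of[["npdr_fu"]]
      conf <- accepted & state == i_of[["pdr_undx"]]
      cost[conf] <- cost[conf] + photo * disc_b
      state[conf] <- i_of[["pdr_tx"]]
      conf <- accepted & state == i_of[["dme_undx"]]
      cost[conf] <- cost[conf] + avegf * disc_b
      state[conf] <- i_of[["dme_tx"]]
    }
    age <- ec$start_age + b
    q_age <- if (age > max(lt$age)) lt$q[nrow(lt)] else lt$q[match(floor(age), lt$age)]
    prev <- state
    alive <- state != DEATH
    dies <- alive & stats::runif(n) < pmin(1, q_age * rr_by_state[state])
    v <- stats::runif(n)  # disease-transition draw for survivors
    ns <- state
    pick2 <- function(s, p1, to1, p2 = NULL, to2 = NULL) {
      idx <- alive & !dies & state == i_of[[s]]
      ns[idx & v < p1] <<- i_of[[to1]]
      if (!is.null(p2)) ns[idx & v >= p1 & v < p1 + p2] <<- i_of[[to2]]
    }
    pick2("no_dr", tr$normal_to_npdr, "npdr_undx", tr$normal_to_pdr, "pdr_undx")
    pick2("npdr_undx", tr$npdr_to_pdr, "pdr_undx", tr$npdr_to_dme, "dme_undx")
    pick2("npdr_fu", tr$npdr_to_pdr, "pdr_tx", tr$npdr_to_dme, "dme_tx")
    pick2("pdr_undx", tr$pdr_to_dme, "dme_undx", tr$pdr_to_svi, "svi_new")
    if (tx_dme_allowed)
      pick2("pdr_tx", tr$pdr_to_dme, "dme_tx", tr$treated_pdr_to_svi, "svi_new")
    else pick2("pdr_tx", tr$treated_pdr_to_svi, "svi_new")
    pick2("dme_undx", tr$dme_to_svi, "svi_new")
    pick2("dme_tx", tr$treated_dme_to_svi, "svi_new")
    idx <- alive & !dies & state == i_of[["svi_new"]]
    ns[idx] <- i_of[["svi_ong"]]
    ns[dies] <- DEATH
    # treatment initiated when annual follow-up detects progression
    flow <- prev == i_of[["npdr_fu"]] & ns == i_of[["pdr_tx"]]
    cost[flow] <- cost[flow] + photo_fu * disc_k
    flow <- prev == i_of[["npdr_fu"]] & ns == i_of[["dme_tx"]]
    cost[flow] <- cost[flow] + avegf_fu * disc_k
    if (tx_dme_allowed) {
      flow <- prev == i_of[["pdr_tx"]] & ns == i_of[["dme_tx"]]
      cost[flow] <- cost[flow] + avegf_fu * disc_k
    }
    qaly <- qaly + 0.5 * (u[prev] + u[ns]) * disc_k
    cost <- cost + 0.5 * (rc[prev] + rc[ns]) * disc_k
    state <- ns
  }
  structure(list(
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n), se_qaly = stats::sd(qaly) / sqrt(n),
    n = n, cost = cost, qaly = qaly,
    strategy = policy$strategy, interval = policy$interval,
    setting = params$setting, seed = seed
  ), class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> %s / %s, n = %d (seed %d)\n", x$setting,
              x$strategy, x$n, x$seed))
  cat(sprintf("  cost  $%.2f (SE %.3f)\n  QALYs %.5f (SE %.5f)\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}
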