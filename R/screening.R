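#' Define a screening policy
#'
#' A policy combines a screening strategy (no screening, community-based
#' photography, or telemedicine reading), a schedule (a one-off screen at
#' model start, or a repeat screen every `interval` years), and compliance
#' (the probability of attending a screening round, and of accepting the
#' hospital referral when called positive). Compliance defaults come from
#' the parameter set's synthetic assumptions unless overridden here.
#'
#' @param strategy `"none"`, `"community"` or `"telemedicine"`.
#' @param interval `"one-off"` or an integer number of years (1..5 typical).
#' @param uptake optional override of screening attendance probability.
#' @param referral_acceptance optional override of referral acceptance.
#' @return a `screening_policy` object.
#' @export
#' @examples
#' screening_policy("telemedicine", interval = 2)
screening_policy <- function(strategy = c("none", "community", "telemedicine"),
                             interval = "one-off",
                             uptake = NULL, referral_acceptance = NULL) {
  strategy <- match.arg(strategy)
  if (!identical(interval, "one-off")) {
    interval <- as.numeric(interval)
    if (!is.finite(interval) || interval < 1 || interval != round(interval))
      stop("screening interval must be 'one-off' or a whole number of years >= 1")
  }
  structure(list(strategy = strategy, interval = interval,
                 uptake = uptake, referral_acceptance = referral_acceptance),
            class = "screening_policy")
}

#' @export
print.screening_policy <- function(x, ...) {
  cat("<screening_policy>", x$strategy,
      if (identical(x$interval, "one-off")) "(one-off)" else
        paste0("(every ", x$interval, " yr)"), "\n")
  invisible(x)
}

#' Does a policy screen at a given cycle?
#'
#' One-off policies screen only at cycle 0 (model entry); an every-k-years
#' policy screens at cycles 0, k, 2k, ...
#'
#' @param policy a [screening_policy()].
#' @param cycle cycle index, >= 0.
#' @return logical.
#' @export
screen_due <- function(policy, cycle) {
  stopifnot(cycle >= 0)
  if (policy$strategy == "none") return(FALSE)
  if (identical(policy$interval, "one-off")) return(cycle == 0)
  cycle %% policy$interval == 0
}

#' Classification behaviour of a screening test
#'
#' Expands the test characteristics into per-true-state conditional
#' distributions. DR-grade calling: a true-normal eye is called NPDR with
#' the stated false-positive rate and normal otherwise; a true-NPDR eye is
#' called normal with the stated miss rate and NPDR otherwise; a true-PDR
#' eye is called NPDR or normal with the stated rates and PDR otherwise.
#' DME detection is layered on top: true DME is flagged positive with the
#' test's sensitivity, and any non-DME state is flagged DME-positive with
#' one minus its specificity (independently of the grade call). A person is
#' referred to hospital if called NPDR or PDR, or flagged DME-positive.
#'
#' @param test one modality's test characteristics, e.g.
#'   `params$tests$community`.
#' @return a `classification_matrix`: list with `grade` (matrix of
#'   P(called normal/npdr/pdr | true state) rows no_dr/npdr/pdr),
#'   `dme_positive` (named vector of P(DME flag | true state)), and
#'   `referral` (named vector of P(referred | true state) over the four
#'   screenable health states).
#' @export
classification_matrix <- function(test) {
  b <- function(k) unname(test[[k]]["base"])
  grade <- rbind(
    no_dr = c(normal = 1 - b("normal_called_npdr"),
              npdr = b("normal_called_npdr"), pdr = 0),
    npdr = c(normal = b("npdr_called_normal"),
             npdr = 1 - b("npdr_called_normal"), pdr = 0),
    pdr = c(normal = b("pdr_called_normal"), npdr = b("pdr_called_npdr"),
            pdr = 1 - b("pdr_called_npdr") - b("pdr_called_normal"))
  )
  if (any(grade < -1e-12) || any(abs(rowSums(grade) - 1) > 1e-12))
    stop("classification rows must be probabilities summing to 1")
  grade[grade < 0] <- 0
  dme_pos <- c(no_dr = 1 - b("dme_specificity"), npdr = 1 - b("dme_specificity"),
               pdr = 1 - b("dme_specificity"), dme = b("dme_sensitivity"))
  # referred if grade call is npdr/pdr OR the DME flag fires (independent)
  referral <- c(
    no_dr = 1 - grade["no_dr", "normal"] * (1 - dme_pos["no_dr"]),
    npdr = 1 - grade["npdr", "normal"] * (1 - dme_pos["npdr"]),
    pdr = 1 - grade["pdr", "normal"] * (1 - dme_pos["pdr"]),
    dme = dme_pos[["dme"]]
  )
  names(referral) <- c("no_dr", "npdr", "pdr", "dme")
  structure(list(grade = grade, dme_positive = dme_pos, referral = referral),
            class = "classification_matrix")
}

policy_compliance <- function(policy, params) {
  list(uptake = policy$uptake %||% unname(params$compliance$uptake["base"]),
       referral = policy$referral_acceptance %||%
         unname(params$compliance$referral_acceptance["base"]))
}

#' Apply one screening round to a cohort
#'
#' For the attending fraction of each undiagnosed alive state: the
#' programme's per-person screening cost is charged; those called positive
#' (DR grade or DME flag) who accept referral undergo a full hospital
#' ophthalmologic examination (assumed perfectly accurate, exam cost
#' charged). Confirmed NPDR enters annual follow-up; confirmed PDR receives
#' photocoagulation and moves to the treated-PDR state; confirmed DME
#' receives anti-VEGF therapy and moves to the treated-DME state; true
#' normals called positive incur the exam cost only; false negatives stay
#' undiagnosed. Health states never change — only management flags — so
#' total occupancy mass is conserved exactly.
#'
#' @param occupancy named occupancy vector over [model_states()].
#' @param policy a [screening_policy()] with strategy != "none".
#' @param params a validated `dr_parameters` object.
#' @return list with `occupancy` (updated) and `cost` (event cost per
#'   cohort member, USD, undiscounted).
#' @export
apply_screening_event <- function(occupancy, policy, params) {
  stopifnot(policy$strategy != "none")
  comp <- policy_compliance(policy, params)
  cm <- classification_matrix(params$tests[[policy$strategy]])
  scr_cost <- unname(params$costs$screening_per_person[[policy$strategy]]["base"])
  exam_cost <- unname(params$costs$hospital_exam_total["base"])

  occ <- occupancy
  cost <- 0
  attending_mass <- 0
  ref <- cm$referral
  move <- function(from, to, frac) {
    m <- occupancy[[from]] * frac
    occ[[from]] <<- occ[[from]] - m
    occ[[to]] <<- occ[[to]] + m
    m
  }
  # true normal: referral leads to exam only (hospital rules out DR)
  attending_mass <- attending_mass + occupancy[["no_dr"]] * comp$uptake
  cost <- cost + occupancy[["no_dr"]] * comp$uptake * ref[["no_dr"]] *
    comp$referral * exam_cost
  # true NPDR: confirmed cases enter annual follow-up
  attending_mass <- attending_mass + occupancy[["npdr_undx"]] * comp$uptake
  m <- move("npdr_undx", "npdr_fu", comp$uptake * ref[["npdr"]] * comp$referral)
  cost <- cost + m * exam_cost
  # true PDR: confirmed cases are treated with photocoagulation
  attending_mass <- attending_mass + occupancy[["pdr_undx"]] * comp$uptake
  m <- move("pdr_undx", "pdr_tx", comp$uptake * ref[["pdr"]] * comp$referral)
  cost <- cost + m * (exam_cost + unname(params$costs$photocoagulation["base"]))
  # true DME: confirmed cases receive anti-VEGF
  attending_mass <- attending_mass + occupancy[["dme_undx"]] * comp$uptake
  m <- move("dme_undx", "dme_tx", comp$uptake * ref[["dme"]] * comp$referral)
  cost <- cost + m * (exam_cost + unname(params$costs$anti_vegf["base"]))

  cost <- cost + attending_mass * scr_cost
  list(occupancy = occ, cost = cost)
}
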