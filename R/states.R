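#' Model state space
#'
#' The cohort model tracks the product of clinical health state and
#' management status. Six clinical states (no DR, NPDR, PDR, DME, severe
#' visual impairment, death) combine with management flags (undiagnosed;
#' NPDR under annual follow-up; treated PDR; treated DME) into ten model
#' states. Severe visual impairment (SVI) is split into a first-year and a
#' subsequent-year state so that the higher first-year care cost can be
#' charged exactly once; death is a single absorbing state.
#'
#' @return `model_states()` returns the character vector of the ten model
#'   state labels, in canonical order.
#' @export
#' @examples
#' model_states()
model_states <- function() {
  c("no_dr", "npdr_undx", "npdr_fu", "pdr_undx", "pdr_tx",
    "dme_undx", "dme_tx", "svi_new", "svi_ong", "death")
}

#' @rdname model_states
#' @return `health_states()` returns the six clinical health-state labels.
#' @export
health_states <- function() {
  c("no_dr", "npdr", "pdr", "dme", "svi", "death")
}

#' @rdname model_states
#' @return `management_flags()` returns the four management-flag labels.
#' @export
management_flags <- function() {
  c("undiagnosed", "diagnosed_followup", "treated_pdr", "treated_dme")
}

# clinical health state underlying each model state
state_health <- function() {
  c(no_dr = "no_dr", npdr_undx = "npdr", npdr_fu = "npdr",
    pdr_undx = "pdr", pdr_tx = "pdr", dme_undx = "dme", dme_tx = "dme",
    svi_new = "svi", svi_ong = "svi", death = "death")
}

# model states eligible for a screening invitation: alive and not yet
# known to the health system
screenable_states <- function() {
  c("no_dr", "npdr_undx", "pdr_undx", "dme_undx")
}

#' Per-state QALY weights and annual recurring costs
#'
#' Maps a validated parameter set onto the ten model states: the utility
#' weight of each state (by its clinical health state; death is 0) and the
#' annual recurring cost attached to state membership (annual follow-up
#' observation for diagnosed NPDR; first-year and subsequent-year care cost
#' for severe visual impairment).
#'
#' @param params a validated [dr_parameters] object.
#' @return named numeric vector over [model_states()].
#' @export
state_utilities <- function(params) {
  u <- params$utilities
  vapply(model_states(), function(s) {
    h <- state_health()[[s]]
    if (h == "death") 0 else unname(u[[h]]["base"])
  }, numeric(1))
}

#' @rdname state_utilities
#' @export
state_recurring_costs <- function(params) {
  co <- params$costs
  out <- stats::setNames(numeric(length(model_states())), model_states())
  out["npdr_fu"] <- co$followup_maintain["base"]
  out["svi_new"] <- co$svi_first_year["base"]
  out["svi_ong"] <- co$svi_subsequent_year["base"]
  out
}
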