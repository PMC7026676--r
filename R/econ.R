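#' Present-value discount factor
#'
#' Annual-compounding discounting: a cost incurred `t` years from model
#' start is multiplied by `(1 + rate)^(-t)`. Costs are discounted in
#' this model; life-years and QALYs are reported undiscounted.
#'
#' @param t Time in years (>= 0); may be a vector.
#' @param rate Discount rate per year, in \[0, 1).
#' @return Discount factor(s) in (0, 1\].
#' @examples
#' discount_factor(10, 0.03)  # 0.744094
#' @export
discount_factor <- function(t, rate) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)", call. = FALSE)
  (1 + rate)^(-t)
}

#' Accrue one model cycle for one patient
#'
#' The per-cycle accounting rule used by both engines, exposed for
#' audit. Membership in a state at the start of a cycle accrues that
#' cycle's amounts (no half-cycle correction):
#' \itemize{
#'   \item cost: the strategy's per-cycle follow-up cost (remission and
#'     salvage states) or metastatic management cost (metastatic state),
#'     plus one-time costs of any events occurring this cycle
#'     (adverse-event onsets by name, `"salvage_pr"`, `"salvage_rt"`,
#'     or `"procedure"`), discounted at `t = cycle_index * cycle_length`
#'     years;
#'   \item life-years: half a year (one cycle) if alive, else 0;
#'   \item QALYs: cycle length times the state utility minus the summed
#'     active utility decrements, floored at 0.
#' }
#' Death states accrue nothing.
#'
#' @param state A health-state label (see [health_states()]).
#' @param events Character vector of event names occurring this cycle.
#' @param deck A `cea_deck`.
#' @param strategy `"AM"`, `"PR"`, or `"RT"`.
#' @param cycle_index Zero-based cycle index.
#' @param active_decrement Sum of utility decrements active this cycle.
#' @return One-row data frame: `cycle`, `cost_nominal`,
#'   `cost_discounted`, `life_years`, `qalys`.
#' @export
accrue_cycle <- function(state, events = character(0), deck, strategy,
                         cycle_index, active_decrement = 0) {
  state <- match.arg(state, health_states())
  strategy <- match.arg(strategy, strategies())
  s <- deck$strategies[[strategy]]
  cl <- deck$econ$cycle_length
  t <- cycle_index * cl
  if (state %in% absorbing_states()) {
    return(data.frame(cycle = cycle_index, cost_nominal = 0,
                      cost_discounted = 0, life_years = 0, qalys = 0))
  }
  cost <- if (state == "METASTATIC") s$costs$metastatic_per_cycle
          else s$costs$followup_per_cycle
  for (ev in events) {
    cost <- cost + switch(ev,
      salvage_pr = s$costs$salvage_pr,
      salvage_rt = s$costs$salvage_rt,
      procedure = s$costs$procedure,
      {
        e <- s$adverse_events[[ev]]
        if (is.null(e)) {
          e <- .expanded_events(s)[[ev]]
          if (is.null(e)) stop("unknown event type: ", ev, call. = FALSE)
        }
        e$cost
      })
  }
  u <- switch(state,
              REMISSION = s$utilities$remission,
              LOCAL_PROG_SALVAGE_PR = s$utilities$salvage_pr,
              LOCAL_PROG_SALVAGE_RT = s$utilities$salvage_rt,
              METASTATIC = s$utilities$metastatic)
  data.frame(cycle = cycle_index,
             cost_nominal = cost,
             cost_discounted = cost * discount_factor(t, deck$econ$discount_rate),
             life_years = cl,
             qalys = cl * max(0, u - active_decrement))
}
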