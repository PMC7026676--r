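# Expand a strategy's adverse-event catalogue into a flat event list.
# The surgical-complication block (probability split 2:1 minor:major) is
# expanded into two independent events with probabilities
# prob * minor_weight and prob * major_weight.
.expanded_events <- function(s) {
  ev <- s$adverse_events
  if (!is.null(s$surgical)) {
    sg <- s$surgical
    ev$surgical_minor <- list(prob = sg$prob * sg$minor_weight,
                              cost = sg$minor$cost,
                              decrement = sg$minor$decrement,
                              window_cycles = sg$window_cycles,
                              duration_cycles = sg$minor$duration_cycles)
    ev$surgical_major <- list(prob = sg$prob * sg$major_weight,
                              cost = sg$major$cost,
                              decrement = sg$major$decrement,
                              window_cycles = sg$window_cycles,
                              duration_cycles = sg$major$duration_cycles)
  }
  ev
}

# Per-cycle conversion probability under active monitoring: the annual
# treatment-conversion rate (13% in year 1, 5% thereafter by default)
# converted to the cycle length.
.conversion_prob <- function(deck, strategy, cycle_index) {
  tr <- deck$strategies[[strategy]]$transitions
  cl <- deck$econ$cycle_length
  cycles_per_year <- max(1, round(1 / cl))
  annual <- if (cycle_index < cycles_per_year) tr$conversion_annual_year1
            else tr$conversion_annual_later
  annual_to_cycle_prob(annual, cl)
}

#' Build the one-cycle transition matrix
#'
#' Assembles the six-by-six row-stochastic transition matrix for one
#' strategy at one cycle. Rows and columns follow [health_states()]
#' order. From remission, exits are treatment conversion (active
#' monitoring only, time-varying, split between the two salvage states)
#' plus local progression (same split), metastasis, and other-cause
#' death; from the salvage states, metastasis and other-cause death;
#' from the metastatic state, prostate-cancer death and other-cause
#' death. The death rows are unit vectors (absorbing).
#'
#' @param deck A `cea_deck`.
#' @param strategy `"AM"`, `"PR"`, or `"RT"`.
#' @param cycle_index Zero-based cycle index, below the deck horizon.
#' @return A 6 x 6 numeric matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(deck, strategy, cycle_index) {
  strategy <- match.arg(strategy, strategies())
  if (cycle_index < 0 || cycle_index >= deck$econ$horizon)
    stop("cycle_index must lie in [0, horizon)", call. = FALSE)
  tr <- deck$strategies[[strategy]]$transitions
  st <- health_states()
  P <- matrix(0, 6, 6, dimnames = list(st, st))
  conv <- .conversion_prob(deck, strategy, cycle_index)
  to_treat <- conv + tr$local_progression
  split <- tr$salvage_split_pr
  exit_rem <- to_treat + tr$metastasis + tr$death_other
  if (exit_rem > 1 + 1e-12)
    stop(sprintf("exit probabilities from REMISSION sum to %.4f > 1 (%s, cycle %d)",
                 exit_rem, strategy, cycle_index), call. = FALSE)
  P["REMISSION", ] <- c(1 - exit_rem, to_treat * split, to_treat * (1 - split),
                        tr$metastasis, tr$death_other, 0)
  exit_salv <- tr$metastasis + tr$death_other
  if (exit_salv > 1 + 1e-12)
    stop(sprintf("exit probabilities from the salvage states sum to %.4f > 1 (%s, cycle %d)",
                 exit_salv, strategy, cycle_index), call. = FALSE)
  for (ss in c("LOCAL_PROG_SALVAGE_PR", "LOCAL_PROG_SALVAGE_RT"))
    P[ss, c(ss, "METASTATIC", "DEATH_OTHER")] <-
      c(1 - exit_salv, tr$metastasis, tr$death_other)
  exit_met <- tr$death_pc + tr$death_other
  if (exit_met > 1 + 1e-12)
    stop(sprintf("exit probabilities from METASTATIC sum to %.4f > 1 (%s, cycle %d)",
                 exit_met, strategy, cycle_index), call. = FALSE)
  P["METASTATIC", c("METASTATIC", "DEATH_PC", "DEATH_OTHER")] <-
    c(1 - exit_met, tr$death_pc, tr$death_other)
  P["DEATH_OTHER", "DEATH_OTHER"] <- 1
  P["DEATH_PC", "DEATH_PC"] <- 1
  P
}

# shared result constructor
.run_result <- function(strategy, mode, n, seed, mean_cost, sd_cost,
                        mean_ly, sd_ly, mean_qaly, sd_qaly, trajectory,
                        ledger, per_patient = NULL, events = NULL) {
  out <- list(strategy = strategy, mode = mode, n = n, seed = seed,
              mean_cost = mean_cost, sd_cost = sd_cost,
              mean_ly = mean_ly, sd_ly = sd_ly,
              mean_qaly = mean_qaly, sd_qaly = sd_qaly,
              trajectory = trajectory, ledger = ledger,
              per_patient = per_patient, events = events)
  class(out) <- "cea_run"
  out
}

# Expected per-cycle adverse-event quantities for the cohort engine.
# Events occur at most once per patient, with per-cycle probability p
# during the onset window; the first-onset probability at cycle j is
# p * (1 - p)^j. A chronic decrement (duration Inf) stays active from
# onset; finite durations expire. Event draws are independent of the
# transition process, so expectations factor through alive-occupancy.
.ae_expectations <- function(s, horizon) {
  ev <- .expanded_events(s)
  onset <- matrix(0, horizon, max(1, length(ev)))  # first-onset prob by cycle
  active <- matrix(0, horizon, max(1, length(ev))) # P(decrement active)
  cost <- numeric(length(ev)); dec <- numeric(length(ev))
  for (i in seq_along(ev)) {
    e <- ev[[i]]
    w <- min(e$window_cycles, horizon)
    if (w > 0) onset[seq_len(w), i] <- e$prob * (1 - e$prob)^(seq_len(w) - 1)
    for (j in seq_len(horizon)) {
      k_lo <- if (is.finite(e$duration_cycles)) max(1, j - e$duration_cycles + 1)
              else 1
      ks <- seq(k_lo, j)
      active[j, i] <- sum(onset[ks[ks <= w], i])
    }
    cost[i] <- e$cost; dec[i] <- e$decrement
  }
  list(names = names(ev), onset = onset, active = active,
       cost = cost, decrement = dec)
}

#' Deterministic cohort expectation run
#'
#' Evolves the full state distribution by repeated vector–matrix
#' products from an all-remission start, accruing discounted cost and
#' undiscounted life-years and QALYs each cycle under the accounting
#' rules of [accrue_cycle()]. This is the analytic expectation of the
#' microsimulation and serves as its oracle: [microsim_run()] means
#' converge to these values as the number of patients grows.
#'
#' One-time costs are booked at the time they occur: the procedure at
#' t = 0, salvage treatment at the transition into a salvage state,
#' adverse-event costs at onset. Utility decrements from adverse events
#' are applied in expectation to the alive occupancy.
#'
#' @param deck A `cea_deck`.
#' @param strategy `"AM"`, `"PR"`, or `"RT"`.
#' @param horizon Number of cycles to run (default: deck horizon).
#' @return A `cea_run` with means, per-cycle occupancy `trajectory`
#'   (rows = cycles, columns = states), and an `AccrualLedger`-style
#'   per-cycle `ledger`. SD fields are `NA` (cohort mode is exact).
#' @export
cohort_run <- function(deck, strategy, horizon = deck$econ$horizon) {
  strategy <- match.arg(strategy, strategies())
  stopifnot(horizon >= 1, horizon <= deck$econ$horizon)
  s <- deck$strategies[[strategy]]
  cl <- deck$econ$cycle_length
  rate <- deck$econ$discount_rate
  u_state <- c(s$utilities$remission, s$utilities$salvage_pr,
               s$utilities$salvage_rt, s$utilities$metastatic, 0, 0)
  percycle_cost <- c(rep(s$costs$followup_per_cycle, 3),
                     s$costs$metastatic_per_cycle, 0, 0)
  ae <- .ae_expectations(s, horizon)
  o <- c(1, 0, 0, 0, 0, 0)
  traj <- matrix(0, horizon, 6,
                 dimnames = list(NULL, health_states()))
  led <- data.frame(cycle = 0:(horizon - 1), cost_nominal = 0,
                    cost_discounted = 0, life_years = 0, qalys = 0)
  for (j in seq_len(horizon)) {        # j is 1-based; cycle index is j - 1
    traj[j, ] <- o
    alive <- sum(o[1:4])
    t <- (j - 1) * cl
    df <- discount_factor(t, rate)
    cost <- sum(o * percycle_cost)
    if (j == 1) cost <- cost + s$costs$procedure
    if (length(ae$cost))
      cost <- cost + alive * sum(ae$onset[j, ] * ae$cost)
    led$cost_nominal[j] <- led$cost_nominal[j] + cost
    led$cost_discounted[j] <- led$cost_discounted[j] + cost * df
    led$life_years[j] <- alive * cl
    dec <- if (length(ae$decrement)) sum(ae$active[j, ] * ae$decrement) else 0
    led$qalys[j] <- cl * (sum(o * u_state) - alive * dec)
    if (j < horizon) {
      P <- build_transition_matrix(deck, strategy, j - 1)
      o_next <- as.vector(o %*% P)
      inflow_pr <- o[1] * P[1, 2]
      inflow_rt <- o[1] * P[1, 3]
      salv_cost <- inflow_pr * s$costs$salvage_pr +
                   inflow_rt * s$costs$salvage_rt
      led$cost_nominal[j + 1] <- salv_cost
      led$cost_discounted[j + 1] <- salv_cost * discount_factor(j * cl, rate)
      o <- o_next
    }
  }
  .run_result(strategy, "cohort", NA_integer_, NA_integer_,
              mean_cost = sum(led$cost_discounted), sd_cost = NA_real_,
              mean_ly = sum(led$life_years), sd_ly = NA_real_,
              mean_qaly = sum(led$qalys), sd_qaly = NA_real_,
              trajectory = traj, ledger = led)
}

#' Patient-level Monte Carlo microsimulation
#'
#' Simulates `n_patients` independent trajectories through the model by
#' inverse-CDF draws against each cycle's transition-matrix row, with
#' adverse events drawn per patient while alive during each event's
#' onset window (at most one onset per event type per patient). All
#' randomness comes from the explicit `seed`; each patient consumes a
#' dedicated pre-drawn block of uniforms, so results are invariant to
#' patient execution order and identical calls are bit-identical.
#'
#' @param deck A `cea_deck`.
#' @param strategy `"AM"`, `"PR"`, or `"RT"`.
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer seed (required; no implicit entropy).
#' @param horizon Number of cycles (default: deck horizon).
#' @param keep_trajectories If `TRUE`, also return the per-patient state
#'   matrix and an event log (cycle-stamped adverse events and salvage
#'   treatments). Intended for small `n_patients`.
#' @return A `cea_run` with per-patient means and SDs of discounted
#'   cost, undiscounted life-years and QALYs, and the occupancy
#'   trajectory (fractions per cycle).
#' @export
microsim_run <- function(deck, strategy, n_patients, seed,
                         horizon = deck$econ$horizon,
                         keep_trajectories = FALSE) {
  strategy <- match.arg(strategy, strategies())
  stopifnot(n_patients >= 1, horizon >= 1, horizon <= deck$econ$horizon)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  s <- deck$strategies[[strategy]]
  cl <- deck$econ$cycle_length
  rate <- deck$econ$discount_rate
  ev <- .expanded_events(s)
  n_ae <- length(ev)
  ae_prob <- vapply(ev, `[[`, 0, "prob")
  ae_cost <- vapply(ev, `[[`, 0, "cost")
  ae_dec <- vapply(ev, `[[`, 0, "decrement")
  ae_win <- vapply(ev, `[[`, 0, "window_cycles")
  ae_dur <- vapply(ev, `[[`, 0, "duration_cycles")
  u_state <- c(s$utilities$remission, s$utilities$salvage_pr,
               s$utilities$salvage_rt, s$utilities$metastatic, 0, 0)
  percycle_cost <- c(rep(s$costs$followup_per_cycle, 3),
                     s$costs$metastatic_per_cycle, 0, 0)
  # one pre-drawn block per patient: per cycle one transition uniform
  # plus one uniform per adverse-event type
  per_cycle_u <- 1L + n_ae
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  U <- matrix(stats::runif(n_patients * horizon * per_cycle_u),
              nrow = n_patients, byrow = TRUE)
  state <- rep(1L, n_patients)
  onset <- matrix(NA_integer_, n_patients, max(1, n_ae))
  cost_d <- rep(s$costs$procedure * 1.0, n_patients)   # procedure at t = 0
  cost_n <- rep(s$costs$procedure * 1.0, n_patients)
  ly <- numeric(n_patients)
  qaly <- numeric(n_patients)
  traj <- matrix(0, horizon, 6, dimnames = list(NULL, health_states()))
  states_mat <- if (keep_trajectories)
    matrix(NA_integer_, n_patients, horizon) else NULL
  log_cycle <- integer(0); log_patient <- integer(0); log_event <- character(0)
  for (j in seq_len(horizon)) {
    cyc <- j - 1L
    t <- cyc * cl
    df <- discount_factor(t, rate)
    alive <- state <= 4L
    base_col <- (j - 1L) * per_cycle_u
    # adverse-event onsets this cycle
    if (n_ae > 0) for (e in seq_len(n_ae)) {
      if (cyc < ae_win[e]) {
        hit <- alive & is.na(onset[, e]) &
          U[, base_col + 1L + e] < ae_prob[e]
        if (any(hit)) {
          onset[hit, e] <- cyc
          cost_n[hit] <- cost_n[hit] + ae_cost[e]
          cost_d[hit] <- cost_d[hit] + ae_cost[e] * df
          if (keep_trajectories) {
            idx <- which(hit)
            log_cycle <- c(log_cycle, rep(cyc, length(idx)))
            log_patient <- c(log_patient, idx)
            log_event <- c(log_event, rep(names(ev)[e], length(idx)))
          }
        }
      }
    }
    # accrual at cycle start
    traj[j, ] <- tabulate(state, 6) / n_patients
    if (keep_trajectories) states_mat[, j] <- state
    cc <- percycle_cost[state]
    cost_n <- cost_n + cc
    cost_d <- cost_d + cc * df
    ly <- ly + cl * alive
    if (n_ae > 0) {
      active <- !is.na(onset) &
        (cyc < sweep(onset, 2, ae_dur, `+`))
      dec_sum <- as.vector(active %*% ae_dec)
    } else dec_sum <- 0
    qaly <- qaly + ifelse(alive, cl * pmax(0, u_state[state] - dec_sum), 0)
    # transition to next cycle
    if (j < horizon) {
      P <- build_transition_matrix(deck, strategy, cyc)
      cumP <- t(apply(P, 1, cumsum))
      u_tr <- U[, base_col + 1L]
      new_state <- state
      for (ss in unique(state[alive])) {
        idx <- which(state == ss)
        new_state[idx] <- .bincode(pmin(u_tr[idx], 1 - 1e-15),
                                   c(0, cumP[ss, ]), include.lowest = TRUE)
      }
      df_next <- discount_factor(j * cl, rate)
      for (sv in c(2L, 3L)) {
        entered <- new_state == sv & state == 1L
        if (any(entered)) {
          scost <- if (sv == 2L) s$costs$salvage_pr else s$costs$salvage_rt
          cost_n[entered] <- cost_n[entered] + scost
          cost_d[entered] <- cost_d[entered] + scost * df_next
          if (keep_trajectories) {
            idx <- which(entered)
            log_cycle <- c(log_cycle, rep(j, length(idx)))
            log_patient <- c(log_patient, idx)
            log_event <- c(log_event,
                           rep(if (sv == 2L) "salvage_pr" else "salvage_rt",
                               length(idx)))
          }
        }
      }
      state <- new_state
    }
  }
  per_patient <- if (keep_trajectories)
    data.frame(patient = seq_len(n_patients), cost = cost_d,
               life_years = ly, qalys = qaly) else NULL
  events <- if (keep_trajectories)
    data.frame(cycle = log_cycle, patient = log_patient,
               event = log_event)[order(log_cycle, log_patient), ] else NULL
  res <- .run_result(strategy, "microsim", as.integer(n_patients),
                     as.integer(seed),
                     mean_cost = mean(cost_d), sd_cost = stats::sd(cost_d),
                     mean_ly = mean(ly), sd_ly = stats::sd(ly),
                     mean_qaly = mean(qaly), sd_qaly = stats::sd(qaly),
                     trajectory = traj, ledger = NULL,
                     per_patient = per_patient, events = events)
  if (keep_trajectories) res$states <- states_mat
  res
}

#' Run all three strategies
#'
#' @param deck A `cea_deck`.
#' @param mode `"cohort"` (deterministic expectation) or `"microsim"`.
#' @param n_patients,seed Microsimulation size and seed (ignored in
#'   cohort mode).
#' @param horizon Cycles to run (default: deck horizon).
#' @return Named list of `cea_run`, one per strategy.
#' @export
run_all <- function(deck, mode = c("cohort", "microsim"),
                    n_patients = 1000, seed = NULL,
                    horizon = deck$econ$horizon) {
  mode <- match.arg(mode)
  out <- lapply(strategies(), function(s) {
    if (mode == "cohort") cohort_run(deck, s, horizon)
    else microsim_run(deck, s, n_patients, seed, horizon)
  })
  stats::setNames(out, strategies())
}

#' Tabulate run results in base-case-report shape
#'
#' @param runs Named list of `cea_run` (from [run_all()]).
#' @return Data frame with one row per strategy: mean and SD of
#'   discounted cost, undiscounted life-years, undiscounted QALYs.
#' @export
run_table <- function(runs) {
  data.frame(
    strategy = vapply(runs, `[[`, "", "strategy"),
    mean_cost = vapply(runs, `[[`, 0, "mean_cost"),
    sd_cost = vapply(runs, `[[`, 0, "sd_cost"),
    mean_ly = vapply(runs, `[[`, 0, "mean_ly"),
    sd_ly = vapply(runs, `[[`, 0, "sd_ly"),
    mean_qaly = vapply(runs, `[[`, 0, "mean_qaly"),
    sd_qaly = vapply(runs, `[[`, 0, "sd_qaly"),
    row.names = NULL)
}

#' @export
print.cea_run <- function(x, ...) {
  cat(sprintf("<cea_run> %s, %s mode%s\n", x$strategy, x$mode,
              if (x$mode == "microsim")
                sprintf(" (n = %d, seed = %d)", x$n, x$seed) else ""))
  cat(sprintf("  discounted cost  $%0.0f%s\n", x$mean_cost,
              if (!is.na(x$sd_cost)) sprintf(" (SD %0.0f)", x$sd_cost) else ""))
  cat(sprintf("  life-years       %0.3f\n", x$mean_ly))
  cat(sprintf("  QALYs            %0.3f\n", x$mean_qaly))
  invisible(x)
}
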