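#' Health states of the model
#'
#' The model evolves each patient through six mutually exclusive health
#' states: remission (progression-free), local progression treated with
#' salvage prostatectomy, local progression treated with salvage
#' radiotherapy, metastatic disease, death from other causes, and death
#' from prostate cancer. The two death states are absorbing.
#'
#' @return Character vector of the six state labels, in model order.
#' @export
health_states <- function() {
  c("REMISSION", "LOCAL_PROG_SALVAGE_PR", "LOCAL_PROG_SALVAGE_RT",
    "METASTATIC", "DEATH_OTHER", "DEATH_PC")
}

#' @rdname health_states
#' @return For `absorbing_states()`, the labels of the absorbing states.
#' @export
absorbing_states <- function() c("DEATH_OTHER", "DEATH_PC")

#' Management strategies compared by the model
#'
#' @return Character vector `c("AM", "PR", "RT")`: active monitoring,
#'   radical prostatectomy, and external-beam radiotherapy with
#'   neoadjuvant hormone therapy.
#' @export
strategies <- function() c("AM", "PR", "RT")

# internal numeric indices used by the engine
.STATE_IDX <- stats::setNames(1:6, c("REMISSION", "LOCAL_PROG_SALVAGE_PR",
                                     "LOCAL_PROG_SALVAGE_RT", "METASTATIC",
                                     "DEATH_OTHER", "DEATH_PC"))

#' Convert an annual probability to a per-cycle probability
#'
#' Uses the constant-hazard complement rule: a probability `p` per year
#' becomes `1 - (1 - p)^t` over `t` years. Composing two half-year
#' cycles recovers the annual probability exactly.
#'
#' @param p_annual Probability per year, in \[0, 1\].
#' @param cycle_length Cycle length in years (> 0).
#' @return Per-cycle probability.
#' @examples
#' annual_to_cycle_prob(0.13, 0.5)  # 0.0672621
#' @export
annual_to_cycle_prob <- function(p_annual, cycle_length) {
  if (any(p_annual < 0 | p_annual > 1))
    stop("p_annual must lie in [0, 1]", call. = FALSE)
  if (any(cycle_length <= 0))
    stop("cycle_length must be positive", call. = FALSE)
  1 - (1 - p_annual)^cycle_length
}

#' Excess count of patients with a treatment-related adverse effect
#'
#' Computes `round((max_pct - baseline_pct) * n_treated)`: the number of
#' treated patients whose adverse effect is attributable to treatment,
#' i.e. the maximum reported prevalence minus the baseline prevalence,
#' scaled by the number treated.
#'
#' @param max_pct Maximum fraction of patients reporting the effect.
#' @param baseline_pct Fraction reporting the effect at baseline.
#' @param n_treated Number of patients treated (>= 0).
#' @return Non-negative integer count.
#' @export
excess_ae_count <- function(max_pct, baseline_pct, n_treated) {
  if (baseline_pct < 0 || max_pct > 1 || baseline_pct > max_pct)
    stop("require 0 <= baseline_pct <= max_pct <= 1", call. = FALSE)
  if (n_treated < 0) stop("n_treated must be >= 0", call. = FALSE)
  as.integer(round((max_pct - baseline_pct) * n_treated))
}

# ---------------------------------------------------------------------------
# Deck construction

.default_wtp_grid <- function() c(0, 10000, 20000, 50000, 70000, 100000,
                                  150000, 200000)

# Adverse-event entry constructor. `duration_cycles = Inf` marks a chronic
# event whose utility decrement persists from onset to death/horizon.
.ae <- function(prob, cost, decrement, window_cycles = 2,
                duration_cycles = 1) {
  list(prob = prob, cost = cost, decrement = decrement,
       window_cycles = window_cycles, duration_cycles = duration_cycles)
}

.default_strategy <- function(strategy) {
  trans <- list(
    conversion_annual_year1 = 0,
    conversion_annual_later = 0,
    salvage_split_pr = 0.5,
    local_progression = 0.005,
    metastasis = 0.006,
    death_pc = annual_to_cycle_prob(0.30, 0.5),
    death_other = annual_to_cycle_prob(0.007, 0.5))
  costs <- list(
    procedure = 0,
    followup_per_cycle = 150,
    salvage_pr = 12000,
    salvage_rt = 18000,
    metastatic_per_cycle = 4000)
  utils_ <- list(
    remission = 0.80,
    salvage_pr = 0.75,
    salvage_rt = 0.73,
    metastatic = 0.45)
  if (strategy == "AM") {
    trans$conversion_annual_year1 <- 0.13
    trans$conversion_annual_later <- 0.05
    trans$local_progression <- 0
    costs$followup_per_cycle <- 450
    aes <- list(
      urinary_symptoms   = .ae(0.025,  500, 0.05),
      incontinence       = .ae(0.005, 2500, 0.06, duration_cycles = Inf),
      sexual_dysfunction = .ae(0.026, 1200, 0.05, duration_cycles = Inf))
    surgical <- NULL
  } else if (strategy == "PR") {
    costs$procedure <- 13500
    aes <- list(
      urinary_symptoms   = .ae(0.075,  500, 0.05),
      incontinence       = .ae(0.22,  2500, 0.06, duration_cycles = Inf),
      sexual_dysfunction = .ae(0.27,  1200, 0.05, duration_cycles = Inf))
    # overall complication risk is split 2:1 minor:major
    surgical <- list(
      prob = 0.10,
      minor_weight = 2 / 3,
      major_weight = 1 / 3,
      window_cycles = 2,
      minor = list(cost = 1200, decrement = 0.03, duration_cycles = 1),
      major = list(cost = 7000, decrement = 0.10, duration_cycles = 2))
  } else { # RT
    costs$procedure <- 25000
    aes <- list(
      urinary_symptoms   = .ae(0.046,  500, 0.05),
      incontinence       = .ae(0.003, 2500, 0.06, duration_cycles = Inf),
      sexual_dysfunction = .ae(0.205, 1200, 0.05, duration_cycles = Inf),
      gi_short           = .ae(0.025,  800, 0.04),
      gi_long            = .ae(0.036, 2000, 0.04, duration_cycles = Inf))
    surgical <- NULL
  }
  out <- list(transitions = trans, costs = costs, utilities = utils_,
              adverse_events = aes)
  if (!is.null(surgical)) out$surgical <- surgical
  out
}

#' Build the template parameter deck
#'
#' Returns the full model parameterization with every published constant
#' fixed at its source value (complication probabilities, the 13%/5%
#' annual conversion rates under active monitoring, the 2:1
#' minor:major surgical-complication split, 3% discounting, 6-month
#' cycles over 10 years) and plausible placeholder values for the
#' unpublished inputs (procedure and follow-up costs, state utilities,
#' metastasis and mortality hazards). The placeholders are what
#' [calibrate()] adjusts; the shipped `deck_default.yaml` is this
#' template after calibration to the published 10-year aggregates.
#'
#' @return A `cea_deck` object.
#' @seealso [load_deck()], [validate_deck()], [calibrate()]
#' @export
deck_template <- function() {
  deck <- list(
    deck_version = 1L,
    econ = list(
      cycle_length = 0.5,
      horizon = 20L,
      discount_rate = 0.03,
      wtp_grid = .default_wtp_grid()),
    cohort_size = 545L,
    psa = list(iterations = 10000L, patients = 1000L),
    strategies = list(
      AM = .default_strategy("AM"),
      PR = .default_strategy("PR"),
      RT = .default_strategy("RT")))
  class(deck) <- "cea_deck"
  deck
}

#' The calibrated default deck shipped with the package
#'
#' Loads `deck_default.yaml` from the package's `extdata`: the template
#' deck with its free parameters calibrated so that the 10-year cohort
#' run reproduces the published per-strategy mean discounted costs,
#' undiscounted life-years and QALYs (see [default_targets()]).
#'
#' @return A validated `cea_deck`.
#' @export
deck_default <- function() {
  load_deck(system.file("extdata", "deck_default.yaml",
                        package = "prostcea", mustWork = TRUE))
}

#' A hand-checkable miniature deck
#'
#' A deliberately degenerate deck used in examples and tests: two
#' cycles, no discounting, no adverse events, no costs beyond a flat
#' follow-up charge, and a single exit hazard of 0.1 per cycle from
#' remission to other-cause death with remission utility 0.8. Its
#' life-year and QALY totals (0.95 and 0.76 over one year) can be
#' enumerated by hand.
#'
#' @return A validated `cea_deck`.
#' @export
deck_toy <- function() {
  load_deck(system.file("extdata", "deck_toy.yaml",
                        package = "prostcea", mustWork = TRUE))
}

# ---------------------------------------------------------------------------
# Schema handling: unknown-key rejection, defaults, canonical ordering

# Canonical key order for every level of the deck. Used both to reject
# unknown keys on load and to serialize deterministically on save.
.deck_schema <- function() {
  ae <- c("prob", "cost", "decrement", "window_cycles", "duration_cycles")
  strat <- list(
    transitions = c("conversion_annual_year1", "conversion_annual_later",
                    "salvage_split_pr", "local_progression", "metastasis",
                    "death_pc", "death_other"),
    costs = c("procedure", "followup_per_cycle", "salvage_pr", "salvage_rt",
              "metastatic_per_cycle"),
    utilities = c("remission", "salvage_pr", "salvage_rt", "metastatic"),
    adverse_events = ae,   # per-event keys; event names are free
    surgical = list(
      .keys = c("prob", "minor_weight", "major_weight", "window_cycles",
                "minor", "major"),
      minor = c("cost", "decrement", "duration_cycles"),
      major = c("cost", "decrement", "duration_cycles")))
  list(
    .keys = c("deck_version", "econ", "cohort_size", "psa", "strategies"),
    econ = c("cycle_length", "horizon", "discount_rate", "wtp_grid"),
    psa = c("iterations", "patients"),
    strategy = strat)
}

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key%s in %s: %s", if (length(bad) > 1) "s" else "",
                 where, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.check_strategy_keys <- function(s, label) {
  sch <- .deck_schema()$strategy
  .check_keys(s, c("transitions", "costs", "utilities", "adverse_events",
                   "surgical"), label)
  .check_keys(s$transitions, sch$transitions, paste0(label, "$transitions"))
  .check_keys(s$costs, sch$costs, paste0(label, "$costs"))
  .check_keys(s$utilities, sch$utilities, paste0(label, "$utilities"))
  for (nm in names(s$adverse_events))
    .check_keys(s$adverse_events[[nm]], sch$adverse_events,
                paste0(label, "$adverse_events$", nm))
  if (!is.null(s$surgical)) {
    .check_keys(s$surgical, sch$surgical$.keys, paste0(label, "$surgical"))
    .check_keys(s$surgical$minor, sch$surgical$minor,
                paste0(label, "$surgical$minor"))
    .check_keys(s$surgical$major, sch$surgical$major,
                paste0(label, "$surgical$major"))
  }
}

#' Load a parameter deck from a YAML file
#'
#' Parses and validates a deck file. Unknown keys are rejected with an
#' error naming the offending key; missing optional sections
#' (`wtp_grid`, `psa`, `cohort_size`) are filled with documented
#' defaults; any invariant violation reported by [validate_deck()]
#' aborts the load.
#'
#' @param path Path to a deck YAML file.
#' @return A validated `cea_deck`.
#' @export
load_deck <- function(path) {
  if (!file.exists(path)) stop("deck file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  sch <- .deck_schema()
  .check_keys(raw, sch$.keys, "deck")
  if (is.null(raw$econ)) stop("deck is missing the econ section", call. = FALSE)
  .check_keys(raw$econ, sch$econ, "econ")
  if (is.null(raw$econ$wtp_grid)) raw$econ$wtp_grid <- .default_wtp_grid()
  if (is.null(raw$cohort_size)) raw$cohort_size <- 545L
  if (is.null(raw$psa)) raw$psa <- list(iterations = 10000L, patients = 1000L)
  .check_keys(raw$psa, sch$psa, "psa")
  if (is.null(raw$deck_version)) raw$deck_version <- 1L
  if (is.null(raw$strategies)) stop("deck has no strategies", call. = FALSE)
  .check_keys(raw$strategies, strategies(), "strategies")
  for (s in names(raw$strategies))
    .check_strategy_keys(raw$strategies[[s]], paste0("strategies$", s))
  deck <- raw[sch$.keys]
  deck$econ <- raw$econ[sch$econ]
  deck$psa <- raw$psa[sch$psa]
  class(deck) <- "cea_deck"
  viol <- validate_deck(deck)
  if (length(viol))
    stop("invalid deck:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  deck
}

#' Save a parameter deck to canonical YAML
#'
#' Writes the deck with a fixed key order and fixed numeric precision,
#' so that save–load–save round-trips are byte-stable.
#'
#' @param deck A `cea_deck`.
#' @param path Output file path.
#' @param header Optional character vector of comment lines written at
#'   the top of the file (each prefixed with `#`).
#' @return `path`, invisibly.
#' @export
save_deck <- function(deck, path, header = NULL) {
  stopifnot(inherits(deck, "cea_deck"))
  sch <- .deck_schema()
  ord <- deck[sch$.keys]
  ord$econ <- deck$econ[sch$econ]
  ord$psa <- deck$psa[sch$psa]
  ord$strategies <- lapply(deck$strategies[strategies()], function(s) {
    out <- list(
      transitions = s$transitions[sch$strategy$transitions],
      costs = s$costs[sch$strategy$costs],
      utilities = s$utilities[sch$strategy$utilities],
      adverse_events = lapply(s$adverse_events[sort(names(s$adverse_events))],
                              function(e) e[sch$strategy$adverse_events]))
    if (!is.null(s$surgical)) {
      sg <- s$surgical[sch$strategy$surgical$.keys]
      sg$minor <- s$surgical$minor[sch$strategy$surgical$minor]
      sg$major <- s$surgical$major[sch$strategy$surgical$major]
      out$surgical <- sg
    }
    out
  })
  txt <- yaml::as.yaml(unclass(ord), precision = 12L)
  if (!is.null(header)) txt <- paste0(paste0("# ", header, collapse = "\n"),
                                      "\n", txt)
  writeLines(txt, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Validation

.is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x <= 1

#' Validate a parameter deck
#'
#' Checks every structural invariant of the deck and returns a character
#' vector of violations (empty when the deck is valid). Each violation
#' names the component, field, and broken rule. Checks include:
#' probabilities in \[0, 1\]; per-state exit probabilities summing to at
#' most 1 at every cycle; non-negative costs; a zero up-front procedure
#' cost for active monitoring; utilities in \[0, 1\]; the minor:major
#' surgical split normalizing to 1; and economic settings (positive
#' cycle length, horizon of at least one cycle, discount rate in
#' \[0, 1), a strictly increasing non-negative willingness-to-pay grid).
#'
#' @param deck A `cea_deck` (or deck-shaped list).
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_deck <- function(deck) {
  v <- character(0)
  add <- function(...) v <<- c(v, sprintf(...))
  ec <- deck$econ
  if (!is.numeric(ec$cycle_length) || ec$cycle_length <= 0)
    add("EconSettings: cycle_length must be > 0")
  if (!is.numeric(ec$horizon) || ec$horizon < 1 ||
      ec$horizon != round(ec$horizon))
    add("EconSettings: horizon must be an integer cycle count >= 1")
  if (!is.numeric(ec$discount_rate) || ec$discount_rate < 0 ||
      ec$discount_rate >= 1)
    add("EconSettings: discount_rate must lie in [0, 1)")
  wg <- ec$wtp_grid
  if (!is.numeric(wg) || any(wg < 0) || any(diff(wg) <= 0))
    add("EconSettings: wtp_grid must be non-negative and strictly increasing")
  if (!is.numeric(deck$cohort_size) || deck$cohort_size < 1)
    add("ParameterDeck: cohort_size must be >= 1")
  if (!is.numeric(deck$psa$iterations) || deck$psa$iterations < 1 ||
      !is.numeric(deck$psa$patients) || deck$psa$patients < 1)
    add("ParameterDeck: psa iterations and patients must be >= 1")
  missing_s <- setdiff(strategies(), names(deck$strategies))
  if (length(missing_s)) {
    add("Strategy: missing strategies %s", paste(missing_s, collapse = ", "))
    return(v)
  }
  for (snm in strategies()) {
    s <- deck$strategies[[snm]]
    tr <- s$transitions
    for (f in c("conversion_annual_year1", "conversion_annual_later",
                "salvage_split_pr", "local_progression", "metastasis",
                "death_pc", "death_other"))
      if (!.is_prob(tr[[f]]))
        add("TransitionSpec[%s]: %s must be a probability in [0, 1]", snm, f)
    if (snm != "AM" &&
        (isTRUE(tr$conversion_annual_year1 > 0) ||
         isTRUE(tr$conversion_annual_later > 0)))
      add("TransitionSpec[%s]: conversion probabilities apply to AM only", snm)
    for (f in names(s$costs))
      if (!is.numeric(s$costs[[f]]) || is.na(s$costs[[f]]) || s$costs[[f]] < 0)
        add("CostDeck[%s]: %s must be a cost >= 0", snm, f)
    if (snm == "AM" && isTRUE(s$costs$procedure != 0))
      add("CostDeck[AM]: procedure cost must be 0 (monitoring has no up-front procedure)")
    for (f in names(s$utilities))
      if (!.is_prob(s$utilities[[f]]))
        add("UtilityDeck[%s]: %s must lie in [0, 1]", snm, f)
    for (anm in names(s$adverse_events)) {
      e <- s$adverse_events[[anm]]
      if (!.is_prob(e$prob))
        add("AECatalog[%s]: %s prob must lie in [0, 1]", snm, anm)
      if (!is.numeric(e$cost) || e$cost < 0)
        add("AECatalog[%s]: %s cost must be >= 0", snm, anm)
      if (!is.numeric(e$decrement) || e$decrement < 0 || e$decrement > 1)
        add("AECatalog[%s]: %s decrement must lie in [0, 1]", snm, anm)
      if (!is.numeric(e$window_cycles) || e$window_cycles < 0)
        add("AECatalog[%s]: %s window_cycles must be >= 0", snm, anm)
      if (!is.numeric(e$duration_cycles) || e$duration_cycles < 1)
        add("AECatalog[%s]: %s duration_cycles must be >= 1", snm, anm)
    }
    if (!is.null(s$surgical)) {
      sg <- s$surgical
      if (!.is_prob(sg$prob))
        add("AECatalog[%s]: surgical prob must lie in [0, 1]", snm)
      if (!is.numeric(sg$minor_weight) || !is.numeric(sg$major_weight) ||
          sg$minor_weight < 0 || sg$major_weight < 0 ||
          abs(sg$minor_weight + sg$major_weight - 1) > 1e-9)
        add("AECatalog[%s]: surgical minor/major weights must be non-negative and sum to 1", snm)
    }
    # per-cycle exit-mass check (conversion is time-varying, so check both
    # the year-1 and the steady-state cycle)
    if (all(vapply(tr, .is_prob, TRUE))) {
      for (cyc in c(0L, 4L)) {
        conv <- annual_to_cycle_prob(
          if (cyc < 2) tr$conversion_annual_year1 else tr$conversion_annual_later,
          deck$econ$cycle_length)
        exit_rem <- conv + tr$local_progression + tr$metastasis + tr$death_other
        if (exit_rem > 1)
          add("TransitionSpec[%s]: exit probabilities from REMISSION sum to %.3f > 1 at cycle %d",
              snm, exit_rem, cyc)
      }
      if (tr$metastasis + tr$death_other > 1)
        add("TransitionSpec[%s]: exit probabilities from the salvage states exceed 1", snm)
      if (tr$death_pc + tr$death_other > 1)
        add("TransitionSpec[%s]: exit probabilities from METASTATIC exceed 1", snm)
    }
  }
  v
}

# ---------------------------------------------------------------------------
# Deck path access (used by sensitivity analysis and calibration)

#' Get or set a scalar deck entry by path
#'
#' Paths are dot-separated, e.g. `"strategies.PR.costs.procedure"` or
#' `"strategies.AM.adverse_events.incontinence.prob"`.
#'
#' @param deck A `cea_deck`.
#' @param path Dot-separated path string.
#' @param value Replacement value (for `deck_set`).
#' @return `deck_get` returns the value; `deck_set` returns the
#'   modified deck (the input deck is untouched).
#' @export
deck_get <- function(deck, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  x <- deck
  for (k in keys) {
    x <- x[[k]]
    if (is.null(x)) stop("no deck entry at path: ", path, call. = FALSE)
  }
  x
}

#' @rdname deck_get
#' @export
deck_set <- function(deck, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  deck[[keys]] <- value
  deck
}

#' Enumerate scalar parameter paths of a deck
#'
#' Lists the dot-separated paths of every numeric scalar under the
#' strategy blocks (transition probabilities, costs, utilities,
#' adverse-event probabilities/costs/decrements, surgical split). This
#' is the default parameter set swept by [tornado()].
#'
#' @param deck A `cea_deck`.
#' @return Character vector of paths.
#' @export
deck_scalar_paths <- function(deck) {
  out <- character(0)
  for (snm in names(deck$strategies)) {
    s <- deck$strategies[[snm]]
    base <- paste0("strategies.", snm, ".")
    for (f in names(s$transitions))
      out <- c(out, paste0(base, "transitions.", f))
    for (f in names(s$costs))
      out <- c(out, paste0(base, "costs.", f))
    for (f in names(s$utilities))
      out <- c(out, paste0(base, "utilities.", f))
    for (anm in names(s$adverse_events))
      for (f in c("prob", "cost", "decrement"))
        out <- c(out, paste0(base, "adverse_events.", anm, ".", f))
    if (!is.null(s$surgical))
      out <- c(out, paste0(base, "surgical.prob"),
               paste0(base, "surgical.minor.cost"),
               paste0(base, "surgical.major.cost"))
  }
  out
}

# TRUE if the path holds a quantity bounded to [0, 1]
.is_prob_path <- function(path) {
  grepl("\\.(transitions|utilities)\\.", path) ||
    grepl("\\.(prob|decrement|minor_weight|major_weight|salvage_split_pr)$",
          path)
}

#' @export
print.cea_deck <- function(x, ...) {
  cat("<cea_deck> ", length(x$strategies), " strategies, ",
      x$econ$horizon, " cycles of ", x$econ$cycle_length,
      " y, discount ", x$econ$discount_rate * 100, "%/y\n", sep = "")
  for (snm in names(x$strategies)) {
    s <- x$strategies[[snm]]
    cat(sprintf("  %-2s procedure $%-8.0f follow-up $%-6.0f/cycle  u(rem) %.3f\n",
                snm, s$costs$procedure, s$costs$followup_per_cycle,
                s$utilities$remission))
  }
  invisible(x)
}
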