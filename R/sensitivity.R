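# Pairwise ICER between two strategies on a deck (cohort mode),
# effect measured in undiscounted QALYs, cost discounted.
.pair_icer <- function(deck, comparison, horizon = deck$econ$horizon) {
  hi <- cohort_run(deck, comparison[1], horizon)
  lo <- cohort_run(deck, comparison[2], horizon)
  icer(lo$mean_cost, lo$mean_qaly, hi$mean_cost, hi$mean_qaly)
}

#' One-way sensitivity of an ICER to one parameter
#'
#' Scales a single deck entry by a low and a high multiplier, reruns
#' the deterministic cohort model, and reports the pairwise ICER at
#' each extreme together with the swing (absolute difference). Scaled
#' probabilities and utilities that leave \[0, 1\] are clamped with a
#' warning. The base deck is never modified.
#'
#' @param deck A `cea_deck`.
#' @param parameter Dot-separated deck path (see [deck_get()]).
#' @param multipliers Length-2 numeric `(low, high)`, both > 0.
#' @param comparison Character pair `c(high, low)`: ICER of
#'   `comparison[1]` versus `comparison[2]`. Default PR versus AM.
#' @return One-row data frame: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `swing`.
#' @export
one_way <- function(deck, parameter, multipliers = c(0.5, 2),
                    comparison = c("PR", "AM")) {
  stopifnot(length(multipliers) == 2, all(multipliers > 0))
  base_val <- deck_get(deck, parameter)
  stopifnot(is.numeric(base_val), length(base_val) == 1)
  run_at <- function(m) {
    val <- base_val * m
    if (.is_prob_path(parameter) && (val > 1 || val < 0)) {
      warning(sprintf("scaled value %.4f for %s clamped to [0, 1]",
                      val, parameter), call. = FALSE)
      val <- min(1, max(0, val))
    }
    .pair_icer(deck_set(deck, parameter, val), comparison)
  }
  lo <- run_at(multipliers[1])
  hi <- run_at(multipliers[2])
  data.frame(parameter = parameter,
             low = multipliers[1], high = multipliers[2],
             icer_low = lo, icer_high = hi, swing = abs(hi - lo))
}

#' Tornado analysis over every deck scalar
#'
#' Runs [one_way()] for each parameter path (default: every scalar
#' under the strategy blocks, see [deck_scalar_paths()]) and returns
#' rows sorted by descending swing — the data behind a tornado diagram.
#'
#' @inheritParams one_way
#' @param parameters Character vector of deck paths.
#' @return Data frame of `one_way` rows, sorted by descending `swing`.
#' @export
tornado <- function(deck, parameters = deck_scalar_paths(deck),
                    multipliers = c(0.5, 2), comparison = c("PR", "AM")) {
  if (!length(parameters))
    return(data.frame(parameter = character(0), low = numeric(0),
                      high = numeric(0), icer_low = numeric(0),
                      icer_high = numeric(0), swing = numeric(0)))
  rows <- lapply(parameters, function(p)
    one_way(deck, p, multipliers, comparison))
  out <- do.call(rbind, rows)
  out[order(-out$swing), , drop = FALSE]
}

#' Horizon sweep of the cost-effectiveness table
#'
#' Truncates the cohort run at each requested horizon and rebuilds the
#' frontier there, mirroring a follow-up-years sensitivity analysis:
#' cumulative discounted cost against cumulative undiscounted QALYs per
#' strategy.
#'
#' @param deck A `cea_deck`.
#' @param horizons_years Numeric vector of horizons in years, each a
#'   positive multiple of the cycle length and at most the deck
#'   horizon.
#' @param wtp Willingness-to-pay for the NMB column.
#' @return Named list of `cea_table`, one per horizon (names like
#'   `"2y"`).
#' @export
horizon_sweep <- function(deck, horizons_years = c(2, 4, 6, 8, 10),
                          wtp = 50000) {
  cl <- deck$econ$cycle_length
  cycles <- horizons_years / cl
  if (any(horizons_years <= 0) ||
      any(abs(cycles - round(cycles)) > 1e-9) ||
      any(round(cycles) > deck$econ$horizon))
    stop("each horizon must be a positive multiple of the cycle length within the deck horizon",
         call. = FALSE)
  out <- lapply(round(cycles), function(h) {
    runs <- run_all(deck, "cohort", horizon = h)
    tab <- data.frame(strategy = names(runs),
                      cost = vapply(runs, `[[`, 0, "mean_cost"),
                      effect = vapply(runs, `[[`, 0, "mean_qaly"))
    frontier(tab, wtp)
  })
  stats::setNames(out, paste0(horizons_years, "y"))
}

# ---------------------------------------------------------------------------
# Probabilistic sensitivity analysis

#' Default uncertainty distributions for a deck
#'
#' One distribution per uncertain scalar, following the standard
#' health-economics convention: beta for probabilities and utilities,
#' gamma for costs, each parameterized by method of moments around the
#' deck's central value with a relative standard deviation
#' (default 20% of the central value). Structural zeros (e.g. the
#' absent up-front procedure cost under active monitoring) are kept
#' fixed. The `crn_name` column names the parameter without its
#' strategy prefix; [psa()] draws one quantile per `crn_name` per
#' iteration, shared across strategies (common random numbers).
#'
#' @param deck A `cea_deck`.
#' @param rel_sd Relative standard deviation (SD / central value).
#' @return Data frame of class `dist_spec`: `path`, `family`,
#'   `central`, `sd`, `crn_name`.
#' @export
default_distributions <- function(deck, rel_sd = 0.2) {
  paths <- character(0)
  for (snm in strategies()) {
    base <- paste0("strategies.", snm, ".")
    tr <- names(deck$strategies[[snm]]$transitions)
    tr <- setdiff(tr, "salvage_split_pr")
    paths <- c(paths, paste0(base, "transitions.", tr),
               paste0(base, "costs.",
                      names(deck$strategies[[snm]]$costs)),
               paste0(base, "utilities.",
                      names(deck$strategies[[snm]]$utilities)))
  }
  central <- vapply(paths, function(p) deck_get(deck, p), 0)
  keep <- central > 0
  paths <- paths[keep]; central <- central[keep]
  family <- ifelse(vapply(paths, .is_prob_path, TRUE), "beta", "gamma")
  spec <- data.frame(path = paths, family = family, central = central,
                     sd = rel_sd * central,
                     crn_name = sub("^strategies\\.[A-Z]+\\.", "", paths),
                     row.names = NULL)
  bad <- spec$family == "beta" & spec$sd^2 >= spec$central * (1 - spec$central)
  if (any(bad))
    stop("beta method-of-moments undefined for: ",
         paste(spec$path[bad], collapse = ", "), call. = FALSE)
  class(spec) <- c("dist_spec", "data.frame")
  spec
}

# quantile of the method-of-moments distribution for one spec row
.q_dist <- function(u, family, m, s) {
  if (s == 0) return(m)
  if (family == "beta") {
    nu <- m * (1 - m) / s^2 - 1
    stats::qbeta(u, m * nu, (1 - m) * nu)
  } else {
    shape <- (m / s)^2
    stats::qgamma(u, shape = shape, rate = shape / m)
  }
}

.validate_dists <- function(dists) {
  stopifnot(is.data.frame(dists),
            all(c("path", "family", "central", "sd", "crn_name")
                %in% names(dists)))
  if (any(!dists$family %in% c("beta", "gamma")))
    stop("distribution family must be beta or gamma", call. = FALSE)
  if (any(dists$sd < 0) || any(!is.finite(dists$central)))
    stop("invalid distribution parameters", call. = FALSE)
  bad <- dists$family == "beta" &
    (dists$central <= 0 | dists$central >= 1 |
       dists$sd^2 >= dists$central * (1 - dists$central))
  if (any(bad))
    stop("beta parameters infeasible for: ",
         paste(dists$path[bad], collapse = ", "), call. = FALSE)
  invisible(dists)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iterations` deck realizations from the uncertainty
#' distributions and evaluates all three strategies on each realization
#' with common random numbers: within an iteration the same quantile is
#' applied to the corresponding parameter of every strategy, so
#' incremental comparisons are not diluted by independent sampling
#' noise. Cohort mode (the default) evaluates each realization exactly;
#' microsim mode simulates `n_patients` per strategy per iteration.
#'
#' @param deck A `cea_deck`.
#' @param dists A `dist_spec` (default [default_distributions()]).
#' @param n_iterations Number of parameter draws.
#' @param n_patients Patients per iteration (microsim mode only).
#' @param seed Integer seed (required).
#' @param mode `"cohort"` or `"microsim"`.
#' @return A `psa_draws` object: `draws` (long data frame `iteration`,
#'   `strategy`, `cost`, `effect` (QALYs), `ly`), the parameter draw
#'   matrix `params` (iterations x parameters), `seed`,
#'   `n_iterations`.
#' @export
psa <- function(deck, dists = default_distributions(deck),
                n_iterations = 1000, n_patients = deck$psa$patients,
                seed, mode = c("cohort", "microsim")) {
  mode <- match.arg(mode)
  stopifnot(n_iterations >= 1, n_patients >= 1)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  .validate_dists(dists)
  crn <- sort(unique(dists$crn_name))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  Uq <- matrix(stats::runif(n_iterations * length(crn)),
               nrow = n_iterations, dimnames = list(NULL, crn))
  params <- matrix(NA_real_, n_iterations, nrow(dists),
                   dimnames = list(NULL, dists$path))
  draws <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    d <- deck
    for (r in seq_len(nrow(dists))) {
      val <- .q_dist(Uq[it, dists$crn_name[r]], dists$family[r],
                     dists$central[r], dists$sd[r])
      params[it, r] <- val
      d <- deck_set(d, dists$path[r], val)
    }
    viol <- validate_deck(d)
    if (length(viol))
      stop("PSA draw ", it, " produced an invalid deck:\n  ",
           paste(viol, collapse = "\n  "), call. = FALSE)
    runs <- if (mode == "cohort") run_all(d, "cohort")
            else run_all(d, "microsim", n_patients = n_patients,
                         seed = as.integer((seed + it) %% .Machine$integer.max))
    draws[[it]] <- data.frame(
      iteration = it,
      strategy = names(runs),
      cost = vapply(runs, `[[`, 0, "mean_cost"),
      effect = vapply(runs, `[[`, 0, "mean_qaly"),
      ly = vapply(runs, `[[`, 0, "mean_ly"),
      row.names = NULL)
  }
  out <- list(draws = do.call(rbind, draws), params = params,
              seed = as.integer(seed), n_iterations = as.integer(n_iterations),
              mode = mode)
  class(out) <- "psa_draws"
  out
}

#' @export
print.psa_draws <- function(x, ...) {
  cat(sprintf("<psa_draws> %d iterations (%s mode, seed %d), %d parameters\n",
              x$n_iterations, x$mode, x$seed, ncol(x$params)))
  invisible(x)
}
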