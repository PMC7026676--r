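# Reporters mirroring the published tables: each command writes CSV +
# JSON artifacts plus a manifest recording the deck hash and seeds, so
# any run can be reproduced bit-identically from its manifest.

.write_manifest <- function(out_dir, command, deck_path, seed = NULL,
                            extra = list()) {
  man <- c(list(command = command,
                deck = deck_path,
                deck_md5 = unname(tools::md5sum(deck_path)),
                seed = seed,
                horizon = NULL,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                package_version = as.character(utils::packageVersion("prostcea"))),
           extra)
  jsonlite::write_json(man[!vapply(man, is.null, TRUE)],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

.prep_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", out_dir,
                        call. = FALSE)
  file.remove(probe)
  invisible(out_dir)
}

#' Run the base-case model and write a report
#'
#' Runs all three strategies (deterministic cohort expectation or
#' seeded microsimulation) and writes `run_results.csv` (strategy by
#' mean/SD of discounted cost, life-years, QALYs; dollars rounded to
#' integers), `run_results.json` (full precision), and
#' `manifest.json`.
#'
#' @param deck_path Path to a deck YAML file.
#' @param mode `"cohort"` or `"microsim"`.
#' @param n Patients per strategy (microsim mode).
#' @param seed Integer seed (microsim mode).
#' @param out_dir Output directory (created if needed).
#' @return The run table, invisibly.
#' @export
cmd_run <- function(deck_path, mode = c("cohort", "microsim"),
                    n = 1000, seed = NULL, out_dir) {
  mode <- match.arg(mode)
  .prep_out_dir(out_dir)
  deck <- load_deck(deck_path)
  runs <- run_all(deck, mode, n_patients = n, seed = seed)
  tab <- run_table(runs)
  csv <- tab
  for (cc in c("mean_cost", "sd_cost")) csv[[cc]] <- round(csv[[cc]])
  utils::write.csv(csv, file.path(out_dir, "run_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(tab, file.path(out_dir, "run_results.json"),
                       dataframe = "rows", digits = NA, na = "null")
  .write_manifest(out_dir, "run", deck_path, seed,
                  list(mode = mode, n = if (mode == "microsim") n))
  invisible(tab)
}

#' Cost-effectiveness analysis report
#'
#' Builds the dominance frontier with ICERs, net monetary benefit at
#' the given threshold, and average C/E ratios, and writes
#' `cea_table.csv` in the published column order (cost, incremental
#' cost, effectiveness, incremental effectiveness, ICER, NMB, C/E).
#' With a single strategy a degenerate one-row table is written with a
#' note rather than failing.
#'
#' @param results A run table (data frame with `strategy`, `mean_cost`,
#'   `mean_qaly`; e.g. from [cmd_run()] or [run_table()]), or a data
#'   frame with `strategy`, `cost`, `effect` columns.
#' @param wtp Willingness-to-pay threshold for NMB.
#' @param out_dir Output directory.
#' @param deck_path Optional deck path recorded in the manifest.
#' @return The `cea_table`, invisibly.
#' @export
cmd_cea <- function(results, wtp = 50000, out_dir, deck_path = NULL) {
  .prep_out_dir(out_dir)
  pts <- if (all(c("cost", "effect") %in% names(results))) {
    results[, c("strategy", "cost", "effect")]
  } else {
    data.frame(strategy = results$strategy, cost = results$mean_cost,
               effect = results$mean_qaly)
  }
  tab <- frontier(pts, wtp)
  csv <- data.frame(strategy = tab$strategy,
                    cost = round(tab$cost),
                    incremental_cost = round(tab$inc_cost),
                    effectiveness = tab$effect,
                    incremental_effectiveness = tab$inc_effect,
                    icer = round(tab$icer, 2),
                    nmb = round(tab$nmb),
                    ce = round(tab$ce_ratio, 2),
                    dominance = tab$dominance)
  utils::write.csv(csv, file.path(out_dir, "cea_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.data.frame(tab),
                       file.path(out_dir, "cea_table.json"),
                       dataframe = "rows", digits = NA, na = "null")
  if (nrow(tab) < 2)
    writeLines("note: single strategy; no incremental comparison possible",
               file.path(out_dir, "cea_note.txt"))
  if (!is.null(deck_path))
    .write_manifest(out_dir, "cea", deck_path, NULL, list(wtp = wtp))
  invisible(tab)
}

#' Horizon sweep report
#'
#' Writes `sweep_table.csv`: one CEA-table block per follow-up horizon.
#'
#' @param deck_path Path to a deck YAML file.
#' @param horizons_years Horizons in years.
#' @param wtp Willingness-to-pay threshold.
#' @param out_dir Output directory.
#' @return The sweep (list of `cea_table`), invisibly.
#' @export
cmd_sweep <- function(deck_path, horizons_years = c(2, 4, 6, 8, 10),
                      wtp = 50000, out_dir) {
  .prep_out_dir(out_dir)
  deck <- load_deck(deck_path)
  sw <- horizon_sweep(deck, horizons_years, wtp)
  rows <- do.call(rbind, lapply(seq_along(sw), function(i) {
    tab <- as.data.frame(sw[[i]])
    cbind(years = horizons_years[i], tab)
  }))
  utils::write.csv(rows, file.path(out_dir, "sweep_table.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "sweep", deck_path, NULL,
                  list(horizons_years = horizons_years, wtp = wtp))
  invisible(sw)
}

#' Tornado report
#'
#' Writes `tornado.csv`: parameter, low/high ICER, swing, sorted by
#' descending swing. An empty parameter list writes an empty table.
#'
#' @param deck_path Path to a deck YAML file.
#' @param parameters Deck paths to vary (default: all strategy scalars).
#' @param multipliers Length-2 low/high multipliers.
#' @param comparison Strategy pair `c(high, low)`.
#' @param out_dir Output directory.
#' @return The tornado table, invisibly.
#' @export
cmd_tornado <- function(deck_path, parameters = NULL,
                        multipliers = c(0.5, 2),
                        comparison = c("PR", "AM"), out_dir) {
  .prep_out_dir(out_dir)
  deck <- load_deck(deck_path)
  if (is.null(parameters)) parameters <- deck_scalar_paths(deck)
  tab <- tornado(deck, parameters, multipliers, comparison)
  utils::write.csv(tab, file.path(out_dir, "tornado.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "tornado", deck_path, NULL,
                  list(multipliers = multipliers, comparison = comparison))
  invisible(tab)
}

#' Probabilistic sensitivity analysis report
#'
#' Writes `psa_draws.csv` (iteration, strategy, cost, effect,
#' life-years) and `manifest.json`.
#'
#' @param deck_path Path to a deck YAML file.
#' @param n_iterations Number of PSA iterations.
#' @param seed Integer seed.
#' @param rel_sd Relative SD of the default uncertainty distributions.
#' @param out_dir Output directory.
#' @return The `psa_draws`, invisibly.
#' @export
cmd_psa <- function(deck_path, n_iterations = 1000, seed, rel_sd = 0.2,
                    out_dir) {
  .prep_out_dir(out_dir)
  deck <- load_deck(deck_path)
  dr <- psa(deck, default_distributions(deck, rel_sd),
            n_iterations = n_iterations, seed = seed)
  utils::write.csv(dr$draws, file.path(out_dir, "psa_draws.csv"),
                   row.names = FALSE)
  .write_manifest(out_dir, "psa", deck_path, seed,
                  list(n_iterations = n_iterations, rel_sd = rel_sd))
  invisible(dr)
}

#' Acceptability-curve report
#'
#' Runs a PSA and writes `ceac.csv` in long format (threshold,
#' strategy, probability of being cost-effective).
#'
#' @inheritParams cmd_psa
#' @param wtp_grid Thresholds (default: the deck's grid).
#' @return The CEAC data frame, invisibly.
#' @export
cmd_ceac <- function(deck_path, n_iterations = 1000, seed, rel_sd = 0.2,
                     wtp_grid = NULL, out_dir) {
  .prep_out_dir(out_dir)
  deck <- load_deck(deck_path)
  if (is.null(wtp_grid)) wtp_grid <- deck$econ$wtp_grid
  dr <- psa(deck, default_distributions(deck, rel_sd),
            n_iterations = n_iterations, seed = seed)
  cc <- ceac(dr, wtp_grid)
  utils::write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  .write_manifest(out_dir, "ceac", deck_path, seed,
                  list(n_iterations = n_iterations, rel_sd = rel_sd,
                       wtp_grid = wtp_grid))
  invisible(cc)
}

#' Calibration report
#'
#' Calibrates a template deck to aggregate targets, writes the fitted
#' deck (`deck_calibrated.yaml`), a JSON report of relative errors and
#' convergence (`calibration.json`), and a manifest.
#'
#' @param deck_path Path to the template deck YAML.
#' @param targets Targets data frame (default [default_targets()]).
#' @param tolerance Relative tolerance.
#' @param out_dir Output directory.
#' @return The `calibration_result`, invisibly.
#' @export
cmd_calibrate <- function(deck_path, targets = default_targets(),
                          tolerance = 0.01, out_dir) {
  .prep_out_dir(out_dir)
  deck <- load_deck(deck_path)
  res <- calibrate(deck, targets, tolerance)
  save_deck(res$deck, file.path(out_dir, "deck_calibrated.yaml"))
  jsonlite::write_json(
    list(converged = res$converged, iterations = res$iterations,
         rel_errors = as.list(res$rel_errors),
         targets = res$targets, tolerance = tolerance),
    file.path(out_dir, "calibration.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .write_manifest(out_dir, "calibrate", deck_path, NULL,
                  list(tolerance = tolerance))
  invisible(res)
}
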