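deck_path <- function() system.file("extdata", "deck_default.yaml",
                                    package = "prostcea")

test_that("cmd_run writes the base-case report with a manifest", {
  out <- withr::local_tempdir()
  tab <- cmd_run(deck_path(), mode = "cohort", out_dir = out)
  expect_true(all(file.exists(file.path(out, c("run_results.csv",
                                               "run_results.json",
                                               "manifest.json")))))
  csv <- read.csv(file.path(out, "run_results.csv"))
  expect_equal(csv$strategy, c("AM", "PR", "RT"))
  expect_equal(csv$mean_cost, c(15654, 18791, 30378), tolerance = 1e-4)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$deck_md5, unname(tools::md5sum(deck_path())))
  expect_equal(man$command, "run")
})

test_that("seeded microsim reports are bit-identical across reruns", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cmd_run(deck_path(), mode = "microsim", n = 10, seed = 7, out_dir = out1)
  cmd_run(deck_path(), mode = "microsim", n = 10, seed = 7, out_dir = out2)
  expect_identical(readLines(file.path(out1, "run_results.csv")),
                   readLines(file.path(out2, "run_results.csv")))
  expect_identical(readLines(file.path(out1, "run_results.json")),
                   readLines(file.path(out2, "run_results.json")))
})

test_that("cmd_cea on injected base-case means reproduces the ICER chain", {
  out <- withr::local_tempdir()
  tg <- default_targets()
  tab <- cmd_cea(data.frame(strategy = tg$strategy, cost = tg$cost,
                            effect = tg$qaly), wtp = 50000, out_dir = out)
  expect_equal(tab$icer[tab$strategy == "PR"], 3137 / 0.48)
  csv <- read.csv(file.path(out, "cea_table.csv"))
  expect_equal(names(csv)[1:8],
               c("strategy", "cost", "incremental_cost", "effectiveness",
                 "incremental_effectiveness", "icer", "nmb", "ce"))
  expect_equal(csv$icer[csv$strategy == "PR"], round(3137 / 0.48, 2))
})

test_that("degenerate CEA inputs are flagged, not fatal", {
  out <- withr::local_tempdir()
  tab <- cmd_cea(data.frame(strategy = c("A", "B"), cost = c(10, 10),
                            effect = c(1, 1)), out_dir = out)
  expect_true(all(is.na(tab$icer)))
  one <- cmd_cea(data.frame(strategy = "A", cost = 10, effect = 1),
                 out_dir = out)
  expect_equal(nrow(one), 1)
  expect_true(file.exists(file.path(out, "cea_note.txt")))
})

test_that("cmd_sweep and cmd_tornado write their tables", {
  out <- withr::local_tempdir()
  cmd_sweep(deck_path(), c(2, 10), out_dir = out)
  sw <- read.csv(file.path(out, "sweep_table.csv"))
  expect_setequal(unique(sw$years), c(2, 10))
  cmd_tornado(deck_path(), parameters = "strategies.PR.costs.procedure",
              out_dir = out)
  tr <- read.csv(file.path(out, "tornado.csv"))
  expect_equal(nrow(tr), 1)
  empty <- cmd_tornado(deck_path(), parameters = character(0), out_dir = out)
  expect_equal(nrow(empty), 0)
})

test_that("cmd_psa and cmd_ceac produce seeded artifacts", {
  out <- withr::local_tempdir()
  cmd_psa(deck_path(), n_iterations = 4, seed = 3, out_dir = out)
  dr <- read.csv(file.path(out, "psa_draws.csv"))
  expect_equal(nrow(dr), 12)
  cmd_ceac(deck_path(), n_iterations = 4, seed = 3,
           wtp_grid = c(0, 50000), out_dir = out)
  cc <- read.csv(file.path(out, "ceac.csv"))
  agg <- aggregate(probability ~ wtp, cc, sum)
  expect_equal(agg$probability, rep(1, 2))
})

test_that("cmd_calibrate on self-targets is a zero-adjustment run", {
  out <- withr::local_tempdir()
  runs <- run_all(load_deck(deck_path()), "cohort")
  tg <- data.frame(strategy = names(runs),
                   cost = vapply(runs, `[[`, 0, "mean_cost"),
                   ly = vapply(runs, `[[`, 0, "mean_ly"),
                   qaly = vapply(runs, `[[`, 0, "mean_qaly"))
  res <- cmd_calibrate(deck_path(), targets = tg, out_dir = out)
  expect_true(res$converged)
  expect_true(file.exists(file.path(out, "deck_calibrated.yaml")))
  rep <- jsonlite::read_json(file.path(out, "calibration.json"))
  expect_true(rep$converged)
})
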