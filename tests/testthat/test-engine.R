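test_that("transition matrices are row-stochastic with absorbing deaths", {
  deck <- cached_default_deck()
  for (s in strategies()) for (cyc in c(0, 1, 5, 19)) {
    P <- build_transition_matrix(deck, s, cyc)
    expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(P["DEATH_PC", ], c(0, 0, 0, 0, 0, 1), ignore_attr = TRUE)
    expect_equal(P["DEATH_OTHER", ], c(0, 0, 0, 0, 1, 0), ignore_attr = TRUE)
    expect_true(all(P >= 0))
  }
})

test_that("a single-exit deck produces the expected remission row", {
  deck <- simple_deck(death_other = 0.1)
  P <- build_transition_matrix(deck, "AM", 0)
  expect_equal(P["REMISSION", ], c(0.9, 0, 0, 0, 0.1, 0), ignore_attr = TRUE)
})

test_that("AM conversion probability is time-varying (13% year 1, 5% after)", {
  deck <- cached_default_deck()
  P0 <- build_transition_matrix(deck, "AM", 0)
  P4 <- build_transition_matrix(deck, "AM", 4)
  conv0 <- sum(P0["REMISSION", c("LOCAL_PROG_SALVAGE_PR",
                                 "LOCAL_PROG_SALVAGE_RT")])
  conv4 <- sum(P4["REMISSION", c("LOCAL_PROG_SALVAGE_PR",
                                 "LOCAL_PROG_SALVAGE_RT")])
  expect_equal(conv0, 1 - sqrt(0.87), tolerance = 1e-12)
  expect_equal(conv4, 1 - sqrt(0.95), tolerance = 1e-12)
  # the two salvage routes split 50/50 by default
  expect_equal(P0["REMISSION", "LOCAL_PROG_SALVAGE_PR"],
               P0["REMISSION", "LOCAL_PROG_SALVAGE_RT"])
})

test_that("assembly errors name the state when exit mass exceeds one", {
  deck <- deck_set(simple_deck(), "strategies.AM.transitions.metastasis", 0.95)
  expect_error(build_transition_matrix(deck, "AM", 0), "REMISSION")
})

test_that("the toy cohort matches the hand-enumerated ledger", {
  run <- cohort_run(deck_toy(), "AM")
  # occupancy 1.0 then 0.9; accruals 0.5 + 0.45 LY and 0.4 + 0.36 QALY
  expect_equal(run$mean_ly, 0.95)
  expect_equal(run$mean_qaly, 0.76)
  expect_equal(run$ledger$life_years, c(0.5, 0.45))
  expect_equal(run$ledger$qalys, c(0.4, 0.36))
  # deterministic: identical on repeated calls
  expect_equal(run$mean_cost, cohort_run(deck_toy(), "AM")$mean_cost)
})

test_that("an immortal cohort at full utility accrues the whole horizon", {
  deck <- simple_deck(death_other = 0, utility = 1, horizon = 20L)
  run <- cohort_run(deck, "PR")
  expect_equal(run$mean_ly, 10)
  expect_equal(run$mean_qaly, 10)
})

test_that("occupancy is conserved and mortality is monotone every cycle", {
  deck <- cached_default_deck()
  for (s in strategies()) {
    traj <- cohort_run(deck, s)$trajectory
    expect_equal(rowSums(traj), rep(1, nrow(traj)), tolerance = 1e-12)
    dead <- traj[, "DEATH_OTHER"] + traj[, "DEATH_PC"]
    expect_true(all(diff(dead) >= -1e-15))
  }
})

test_that("cohort cost and life-years are non-decreasing in the horizon", {
  deck <- cached_default_deck()
  runs <- lapply(c(4, 8, 12, 16, 20), function(h) cohort_run(deck, "RT", h))
  costs <- vapply(runs, `[[`, 0, "mean_cost")
  lys <- vapply(runs, `[[`, 0, "mean_ly")
  expect_true(all(diff(costs) > 0))
  expect_true(all(diff(lys) > 0))
})

test_that("degenerate microsimulation keeps every patient in remission", {
  deck <- simple_deck(death_other = 0, utility = 1, horizon = 20L,
                      followup = 50)
  run <- microsim_run(deck, "AM", n_patients = 3, seed = 5,
                      keep_trajectories = TRUE)
  expect_true(all(run$states == 1L))
  expect_equal(run$sd_cost, 0)
  expect_equal(run$sd_ly, 0)
  expect_equal(run$sd_qaly, 0)
  expect_equal(run$mean_ly, 10)
})

test_that("identical seeded calls give identical results and event logs", {
  deck <- cached_default_deck()
  a <- microsim_run(deck, "PR", 200, seed = 7, keep_trajectories = TRUE)
  b <- microsim_run(deck, "PR", 200, seed = 7, keep_trajectories = TRUE)
  expect_identical(a$events, b$events)
  expect_identical(a$per_patient, b$per_patient)
  expect_identical(a$mean_cost, b$mean_cost)
  c <- microsim_run(deck, "PR", 200, seed = 8)
  expect_false(identical(a$mean_cost, c$mean_cost))
})

test_that("microsimulation means converge to the cohort expectation", {
  deck <- deck_toy()
  co <- cohort_run(deck, "AM")
  ms <- microsim_run(deck, "AM", n_patients = 20000, seed = 1)
  expect_lt(abs(ms$mean_ly - co$mean_ly), 3 * ms$sd_ly / sqrt(20000))
  expect_lt(abs(ms$mean_qaly - co$mean_qaly), 3 * ms$sd_qaly / sqrt(20000))
})

test_that("patient accounting respects QALY <= LY <= horizon", {
  deck <- cached_default_deck()
  run <- microsim_run(deck, "AM", 500, seed = 3, keep_trajectories = TRUE)
  pp <- run$per_patient
  expect_true(all(pp$qalys <= pp$life_years + 1e-12))
  expect_true(all(pp$life_years <= 10 + 1e-12))
  # no resurrection: once dead, stays in the same absorbing state
  st <- run$states
  for (i in seq_len(nrow(st))) {
    dead_at <- which(st[i, ] >= 5L)
    if (length(dead_at))
      expect_true(all(st[i, dead_at[1]:ncol(st)] == st[i, dead_at[1]]))
  }
})

test_that("run tables collect per-strategy means in report shape", {
  runs <- run_all(deck_toy(), "cohort")
  tab <- run_table(runs)
  expect_equal(tab$strategy, c("AM", "PR", "RT"))
  expect_equal(tab$mean_ly, rep(0.95, 3))
  expect_true(all(is.na(tab$sd_cost)))
})
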