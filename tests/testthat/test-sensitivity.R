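test_that("one-way analysis with unit multipliers is a no-op", {
  deck <- cached_default_deck()
  base <- prostcea:::.pair_icer(deck, c("PR", "AM"))
  row <- one_way(deck, "strategies.PR.costs.procedure", c(1, 1))
  expect_equal(row$icer_low, base)
  expect_equal(row$icer_high, base)
  expect_equal(row$swing, 0)
})

test_that("varying an RT cost leaves the PR-vs-AM comparison untouched", {
  deck <- cached_default_deck()
  base <- prostcea:::.pair_icer(deck, c("PR", "AM"))
  row <- one_way(deck, "strategies.RT.costs.procedure", c(0.5, 2),
                 comparison = c("PR", "AM"))
  expect_equal(row$icer_low, base)
  expect_equal(row$swing, 0)
  row_rt <- one_way(deck, "strategies.RT.costs.procedure", c(0.5, 2),
                    comparison = c("RT", "PR"))
  expect_gt(row_rt$swing, 0)
})

test_that("scaling every cost by two exactly doubles the ICER", {
  deck <- cached_default_deck()
  base <- prostcea:::.pair_icer(deck, c("RT", "PR"))
  doubled <- deck
  for (p in grep("(costs\\.|\\.cost$)", deck_scalar_paths(deck), value = TRUE))
    doubled <- deck_set(doubled, p, 2 * deck_get(deck, p))
  expect_equal(prostcea:::.pair_icer(doubled, c("RT", "PR")), 2 * base,
               tolerance = 1e-12)
})

test_that("probabilities scaled beyond one are clamped with a warning", {
  deck <- cached_default_deck()
  expect_warning(
    one_way(deck, "strategies.PR.adverse_events.incontinence.prob",
            c(0.5, 8)),
    "clamped")
})

test_that("the tornado covers the requested scalars sorted by swing", {
  deck <- cached_default_deck()
  pars <- c("strategies.PR.costs.procedure",
            "strategies.AM.costs.followup_per_cycle",
            "strategies.PR.utilities.salvage_pr")
  # doubling a utility near 0.75 exceeds 1 and is clamped with a warning
  tab <- suppressWarnings(tornado(deck, pars))
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$swing) <= 0))
  empty <- tornado(deck, character(0))
  expect_equal(nrow(empty), 0)
})

test_that("the horizon sweep at full horizon reproduces the base run", {
  deck <- cached_default_deck()
  sw <- horizon_sweep(deck, 10)
  runs <- run_all(deck, "cohort")
  tab <- frontier(data.frame(strategy = names(runs),
                             cost = vapply(runs, `[[`, 0, "mean_cost"),
                             effect = vapply(runs, `[[`, 0, "mean_qaly")))
  expect_identical(sw[["10y"]]$cost, tab$cost)
  expect_identical(sw[["10y"]]$icer, tab$icer)
  expect_error(horizon_sweep(deck, 3.7), "multiple")
})

test_that("shorter horizons accumulate no more cost than longer ones", {
  sw <- horizon_sweep(cached_default_deck(), c(2, 4, 6, 8, 10))
  for (s in strategies()) {
    costs <- vapply(sw, function(tb) tb$cost[tb$strategy == s], 0)
    expect_true(all(diff(costs) > 0))
  }
})

test_that("default distributions are beta/gamma with feasible moments", {
  deck <- cached_default_deck()
  spec <- default_distributions(deck)
  expect_true(all(spec$family %in% c("beta", "gamma")))
  expect_true(all(spec$central > 0))
  probs <- grepl("transitions|utilities", spec$path)
  expect_true(all(spec$family[probs] == "beta"))
  expect_true(all(spec$family[grepl("costs", spec$path)] == "gamma"))
  # AM has no up-front procedure, so no distribution for it
  expect_false("strategies.AM.costs.procedure" %in% spec$path)
})

test_that("method-of-moments draws recover the central values", {
  spec <- default_distributions(cached_default_deck())
  set.seed(123)
  u <- runif(10000)
  for (r in sample(nrow(spec), 6)) {
    x <- prostcea:::.q_dist(u, spec$family[r], spec$central[r], spec$sd[r])
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - spec$central[r]), 3 * se)
  }
})

test_that("PSA is reproducible and zero dispersion recovers the base case", {
  deck <- deck_toy()
  spec <- default_distributions(deck)
  a <- psa(deck, spec, n_iterations = 5, seed = 11)
  b <- psa(deck, spec, n_iterations = 5, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$params, b$params)
  spec0 <- spec
  spec0$sd <- 0
  z <- psa(deck, spec0, n_iterations = 3, seed = 2)
  base <- cohort_run(deck, "AM")
  am <- z$draws[z$draws$strategy == "AM", ]
  expect_equal(am$cost, rep(base$mean_cost, 3))
  expect_equal(am$effect, rep(base$mean_qaly, 3))
})

test_that("common random numbers share quantiles across strategies", {
  deck <- cached_default_deck()
  spec <- default_distributions(deck)
  dr <- psa(deck, spec, n_iterations = 4, seed = 9)
  # the same iteration's metastasis draws are perfectly rank-correlated:
  # identical quantile applied to each strategy's distribution
  cols <- paste0("strategies.", strategies(), ".transitions.metastasis")
  qm <- dr$params[, cols]
  expect_equal(order(qm[, 1]), order(qm[, 2]))
  expect_equal(order(qm[, 1]), order(qm[, 3]))
})

test_that("the acceptability curve matches the published direction", {
  deck <- cached_default_deck()
  dr <- psa(deck, n_iterations = 300, seed = 17)
  cc <- ceac(dr, c(0, 50000, 100000))
  p <- function(w, s) cc$probability[cc$wtp == w & cc$strategy == s]
  # cheapest strategy wins at zero willingness to pay
  expect_equal(which.max(sapply(strategies(), p, w = 0)), c(AM = 1))
  # prostatectomy is the modal cost-effective choice at $50,000/QALY
  expect_equal(which.max(sapply(strategies(), p, w = 50000)), c(PR = 2))
  # radiotherapy becomes the modal choice at $100,000/QALY
  expect_equal(which.max(sapply(strategies(), p, w = 100000)), c(RT = 3))
  # and its acceptability rises with the threshold
  expect_gt(p(100000, "RT"), p(50000, "RT"))
})
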