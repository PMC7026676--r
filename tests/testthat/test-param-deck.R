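test_that("annual-to-cycle conversion follows the constant-hazard rule", {
  expect_equal(annual_to_cycle_prob(0, 0.5), 0)
  expect_equal(annual_to_cycle_prob(1, 0.5), 1)
  expect_equal(annual_to_cycle_prob(0.13, 0.5), 1 - sqrt(0.87))
  expect_equal(annual_to_cycle_prob(0.05, 0.5), 1 - sqrt(0.95))
  # monotone in the annual probability
  p <- annual_to_cycle_prob(seq(0, 1, by = 0.05), 0.5)
  expect_true(all(diff(p) > 0))
  expect_error(annual_to_cycle_prob(1.2, 0.5), "0, 1")
  expect_error(annual_to_cycle_prob(0.5, 0), "positive")
})

test_that("composing two half-year cycles recovers the annual probability", {
  for (p in c(0.01, 0.13, 0.5, 0.9)) {
    pc <- annual_to_cycle_prob(p, 0.5)
    expect_equal(1 - (1 - pc)^2, p, tolerance = 1e-12)
  }
})

test_that("excess adverse-event counts round the attributable fraction", {
  expect_identical(excess_ae_count(0.22, 0.22, 545), 0L)
  expect_identical(excess_ae_count(0.27, 0.10, 200), 34L)
  expect_identical(excess_ae_count(0.22, 0.0, 100), 22L)
  expect_error(excess_ae_count(0.10, 0.22, 100), "baseline")
})

test_that("the shipped default deck carries the published constants", {
  deck <- cached_default_deck()
  expect_equal(deck_get(deck, "strategies.PR.adverse_events.incontinence.prob"),
               0.22)
  expect_equal(deck_get(deck, "strategies.PR.adverse_events.urinary_symptoms.prob"),
               0.075)
  expect_equal(deck_get(deck, "strategies.PR.adverse_events.sexual_dysfunction.prob"),
               0.27)
  expect_equal(deck_get(deck, "strategies.AM.adverse_events.urinary_symptoms.prob"),
               0.025)
  expect_equal(deck_get(deck, "strategies.RT.adverse_events.sexual_dysfunction.prob"),
               0.205)
  expect_equal(deck_get(deck, "strategies.RT.adverse_events.gi_short.prob"), 0.025)
  expect_equal(deck_get(deck, "strategies.RT.adverse_events.gi_long.prob"), 0.036)
  expect_equal(deck_get(deck, "strategies.AM.transitions.conversion_annual_year1"),
               0.13)
  expect_equal(deck_get(deck, "strategies.AM.transitions.conversion_annual_later"),
               0.05)
  expect_equal(deck_get(deck, "strategies.PR.surgical.minor_weight"), 2 / 3,
               tolerance = 1e-9)
  expect_equal(deck$econ$discount_rate, 0.03)
  expect_equal(deck$econ$horizon, 20L)
  expect_equal(deck$cohort_size, 545L)
  expect_true(50000 %in% deck$econ$wtp_grid)
})

test_that("loading rejects unknown keys and invariant violations", {
  deck <- deck_toy()
  p <- withr::local_tempfile(fileext = ".yaml")
  save_deck(deck, p)
  txt <- readLines(p)
  writeLines(c(txt, "not_a_key: 1"), p)
  expect_error(load_deck(p), "unknown key.*not_a_key")

  deck_bad <- deck
  deck_bad$econ$discount_rate <- -0.1
  p2 <- withr::local_tempfile(fileext = ".yaml")
  save_deck(deck_bad, p2)
  expect_error(load_deck(p2), "discount_rate")
})

test_that("save/load round-trip is the identity on canonical decks", {
  for (deck in list(deck_toy(), cached_default_deck())) {
    p1 <- withr::local_tempfile(fileext = ".yaml")
    p2 <- withr::local_tempfile(fileext = ".yaml")
    save_deck(deck, p1)
    d2 <- load_deck(p1)
    save_deck(d2, p2)
    expect_identical(readLines(p1), readLines(p2))
    expect_equal(unclass(d2)[c("econ", "strategies")],
                 unclass(load_deck(p2))[c("econ", "strategies")])
  }
})

test_that("validate_deck names the violated component and rule", {
  deck <- deck_template()
  expect_length(validate_deck(deck), 0)

  bad <- deck_set(deck, "strategies.PR.utilities.remission", 1.2)
  v <- validate_deck(bad)
  expect_length(v, 1)
  expect_match(v, "UtilityDeck\\[PR\\]")

  bad2 <- deck_set(deck, "strategies.AM.transitions.metastasis", 0.7)
  bad2 <- deck_set(bad2, "strategies.AM.transitions.local_progression", 0.7)
  v2 <- validate_deck(bad2)
  expect_true(any(grepl("TransitionSpec\\[AM\\].*REMISSION", v2)))

  bad3 <- deck_set(deck, "strategies.AM.costs.procedure", 500)
  expect_true(any(grepl("CostDeck\\[AM\\]", validate_deck(bad3))))
})

test_that("a deck passing validation builds matrices at every cycle", {
  deck <- cached_default_deck()
  expect_length(validate_deck(deck), 0)
  for (s in strategies())
    for (cyc in seq_len(deck$econ$horizon) - 1)
      expect_no_error(build_transition_matrix(deck, s, cyc))
})

test_that("deck paths read and write scalars without touching the input", {
  deck <- deck_template()
  v0 <- deck_get(deck, "strategies.RT.costs.procedure")
  d2 <- deck_set(deck, "strategies.RT.costs.procedure", 999)
  expect_equal(deck_get(d2, "strategies.RT.costs.procedure"), 999)
  expect_equal(deck_get(deck, "strategies.RT.costs.procedure"), v0)
  expect_error(deck_get(deck, "strategies.RT.costs.nope"), "no deck entry")
})
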