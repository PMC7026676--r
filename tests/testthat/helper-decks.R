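# Fixtures built in code.

# A minimal deck with a single exit hazard from remission, no adverse
# events and flat follow-up costs; parameters are overridable.
simple_deck <- function(death_other = 0.1, utility = 0.8, horizon = 2L,
                        discount = 0, followup = 100) {
  deck <- deck_template()
  deck$econ$horizon <- as.integer(horizon)
  deck$econ$discount_rate <- discount
  for (s in strategies()) {
    st <- deck$strategies[[s]]
    st$transitions <- list(conversion_annual_year1 = 0,
                           conversion_annual_later = 0,
                           salvage_split_pr = 0.5,
                           local_progression = 0,
                           metastasis = 0,
                           death_pc = 0,
                           death_other = death_other)
    st$costs <- list(procedure = 0, followup_per_cycle = followup,
                     salvage_pr = 0, salvage_rt = 0,
                     metastatic_per_cycle = 0)
    st$utilities <- list(remission = utility, salvage_pr = 0.5,
                         salvage_rt = 0.5, metastatic = 0.5)
    st$adverse_events <- list()
    st$surgical <- NULL
    deck$strategies[[s]] <- st
  }
  deck
}

# cached calibrated default deck (loaded once per test run)
cached_default_deck <- local({
  deck <- NULL
  function() {
    if (is.null(deck)) deck <<- deck_default()
    deck
  }
})
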