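# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Standard five-source campaign: 400 sites, measurement noise cv 0.1,
# inter-source correlation 0.2, fixed seed.
std_campaign <- function() {
  .cached("std_campaign", generate_monitoring_campaign(
    default_source_profiles(), campaign_config(seed = 42)))
}

std_model <- function() {
  .cached("std_model", suppressMessages(fit_apca(std_campaign()$table)))
}

# Loading pattern of the generating five-source structure, used as the
# reference for congruence matching (dominant tracers per source).
target_pattern <- function() {
  polls <- c("NO2", "BC", "Cu", "Fe", "Kw", "Ni", "Si", "V", "Zn")
  tg <- matrix(0, 9, 5, dimnames = list(polls, c(
    "traffic", "oil", "soil", "biomass_agriculture", "industry")))
  tg[c("NO2", "BC", "Cu", "Fe"), "traffic"] <- c(0.97, 0.88, 0.86, 0.71)
  tg[c("Ni", "V"), "oil"] <- c(0.91, 0.95)
  tg[c("Si", "Fe"), "soil"] <- c(0.89, 0.46)
  tg["Kw", "biomass_agriculture"] <- 0.99
  tg["Zn", "industry"] <- 0.93
  tg
}

# Small cohort for fast health-model unit tests.
small_cohort <- function() {
  .cached("small_cohort", generate_cohort(
    default_source_profiles(),
    cohort_config(n_participants = 4000, seed = 11)))
}

source_cols <- function() paste0("true_", default_source_profiles()$sources)
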