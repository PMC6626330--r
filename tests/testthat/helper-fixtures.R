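# Shared fixtures. Simulations are cached so several test files can reuse the
# same generated panels within one test run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (!exists(key, envir = .sim_cache))
    assign(key, simulate_claims(config), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# The default study conditions: 20,000 members over four years.
default_sim <- function() cached_sim("default4", generator_config(seed = 20110))

# One-year 50,000-member panel for recovery checks.
big_sim <- function() {
  cached_sim("big1", generator_config(n_members = 50000, years = 2011, seed = 50110))
}

# Two-year panel with the code-severity cost coupling switched on, for
# code-level breakdown studies (severity raises unexplained cost, so the
# high-severity share climbs across the residual spectrum).
breakdown_sim <- function() {
  cached_sim("breakdown2",
             generator_config(n_members = 20000, years = 2013:2014,
                              seed = 1333, severity_cost_shift = 0.4))
}

fit_year <- function(sim, year) {
  cohort <- suppressMessages(
    build_cohort(sim$members, sim$claims, synthetic_ccs_map(), year))
  design <- suppressMessages(build_design_matrix(cohort))
  fit <- fit_linear(design)
  list(cohort = cohort, design = design, fit = fit,
       residuals = tibble::tibble(member_id = fit$member_id, year = year,
                                  residual = fit$residuals))
}

.fit_cache <- new.env(parent = emptyenv())
cached_fit <- function(key, sim, year) {
  if (!exists(key, envir = .fit_cache))
    assign(key, fit_year(sim, year), envir = .fit_cache)
  get(key, envir = .fit_cache)
}

# Hand-built five-member panel exercising every inclusion rule.
toy_tables <- function() {
  members <- tibble::tibble(
    member_id = c("A", "B", "C", "D", "E", "F"),
    year = 2011L,
    age = c(17L, 60L, 30L, 45L, 25L, 61L),
    sex = c("F", "F", "M", "F", "M", "M"),
    race = c("White", "Black", "White", "Hispanic", "White", "Black"),
    disabled = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    county = c("C1", "C1", "C2", "C2", "C1", "C2"),
    plan = c("FFS", "MCO_A", "FFS", "MCO_A", "FFS", "FFS"),
    months_enrolled = c(12L, 12L, 5L, 12L, 10L, 12L),
    pregnant = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  claims <- tibble::tibble(
    member_id = c("A", "C", "C", "D", "E", "F"),
    year = 2011L,
    setting = c("professional", "inpatient", "professional",
                "emergency", "pharmacy", "professional"),
    principal_dx = c("4019", "4011", "5856", "2962", "4019", "3040"),
    paid_amount = c(100, 600, 150, 200, 50, 80))
  list(members = members, claims = claims)
}

# Design-matrix object built directly from raw components (for model tests
# that do not need the cohort machinery).
raw_design <- function(y, X, ids = sprintf("M%03d", seq_along(y)), year = 2011L) {
  structure(list(y = y, X = X, member_id = ids, year = year,
                 dropped = character(0)),
            class = "design_matrix")
}
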