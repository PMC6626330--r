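#' Configuration for the synthetic claims generator
#'
#' Builds the parameter set that drives [generate_members()], [generate_claims()]
#' and [generate_ppe()]. The generator emulates the statistical structure a
#' residual-based high-utilizer analysis assumes in a state Medicaid panel:
#' per-member per-month (PMPM) expenditures that are log-normal on the log10
#' scale and driven linearly by condition and demographic covariates; a small
#' planted subpopulation carrying a positive latent excess-utilization effect
#' that persists across years as an AR(1) process; claim-level cost variation
#' both *within* a designated diagnosis code (cost spread increasing with the
#' latent excess) and *between* codes of a designated category (the
#' high-severity code becoming more likely with the latent excess); and
#' preventable-event counts whose Poisson rate increases with the latent
#' excess.
#'
#' @param n_members Number of distinct members in the panel.
#' @param years Calendar years covered; every member appears in every year.
#' @param seed Integer seed. Members, claims and preventable-event records are
#'   drawn from seeded streams derived from this value in documented order
#'   (`seed`, `seed + 1`, `seed + 2`), so each stage regenerates reproducibly.
#' @param prevalence Named probabilities of chronic condition categories,
#'   assigned once per member and kept across years.
#' @param beta Named vector of true log10-scale effects; see
#'   [default_effects()]. `age` is per year of age, centered at 39.
#' @param interactions List of `list(a =, b =, beta =)` condition-pair
#'   interaction effects (both conditions present adds `beta` to the log10
#'   mean); these are what a purely additive linear model cannot capture.
#'   The default generating model is additive (no interactions).
#' @param sigma_noise SD of the iid log10-scale noise (> 0).
#' @param excess_fraction Share of members planted as over-utilizers, in
#'   \[0, 1\].
#' @param excess_shift Mean of the planted latent excess on the log10 scale.
#'   The default is three times `sigma_noise`.
#' @param excess_sd SD of the planted latent excess around `excess_shift`
#'   (kept small so the planted component is a tight shifted bump).
#' @param persistence_rho AR(1) correlation of the latent excess between
#'   consecutive years, in \[0, 1). Planted/non-planted membership is fixed
#'   across years; only the planted members' latent value evolves.
#' @param ppe_coupling Non-negative log-link coefficient from latent excess to
#'   the preventable-event Poisson rates. The default (2.0) makes planted
#'   members' event rates roughly 4-5 times the baseline, the order of
#'   contrast preventable-readmission tables show between high-residual and
#'   other patients.
#' @param ppr_base_rate,ppv_base_rate Baseline yearly rates of potentially
#'   preventable readmissions (PPR) and ED visits (PPV) for members with zero
#'   latent excess.
#' @param ppr_event_cost,ppv_event_cost Named vectors `c(meanlog =, sdlog =)`
#'   of the log-normal per-event cost draws.
#' @param wcv_category Category whose claim-level cost spread grows with the
#'   latent excess ("within-code variance" mechanism).
#' @param wcv_coupling Strength of that growth (multiplier on the claim-weight
#'   log-SD per unit latent excess).
#' @param mix_category Category whose high-severity code becomes more likely
#'   with the latent excess ("mixture shift" mechanism).
#' @param mix_coupling Logit-scale coefficient of the latent excess in the
#'   high-severity code assignment probability.
#' @param mix_base_p Baseline probability of the high-severity code.
#' @param severity_cost_shift Log10-scale cost increment for member-years
#'   carrying the high-severity code. Because severity is invisible to the
#'   risk-adjustment covariates (which only see the category), this pushes
#'   high-severity members up the residual spectrum — the mechanism behind a
#'   code-mixture gradient across residual groups. Off (0) by default, so the
#'   baseline generating model stays exactly `beta.x + latent + noise`;
#'   breakdown studies switch it on explicitly.
#' @param excess_setting `NULL` (default) applies the latent excess to the
#'   member's total cost; naming a setting (e.g. `"inpatient"`) instead
#'   scales only that setting's claim amounts by `10^latent_excess`,
#'   producing setting-specific planted excess for stratified-model checks.
#' @param claim_weight_sdlog Log-SD of the log-normal claim weights used to
#'   split a member's annual total across claim lines.
#' @param setting_probs Named claim-setting probabilities over
#'   `inpatient`, `emergency`, `professional`, `pharmacy`, `other`.
#'
#' @return A list of class `"generator_config"`.
#' @seealso [simulate_claims()] for the one-call wrapper.
#' @export
generator_config <- function(n_members = 20000,
                             years = 2011:2014,
                             seed = 20110,
                             prevalence = c(HTN = 0.25, CKD = 0.08, MEN = 0.30,
                                            SUD = 0.20, DIA = 0.15, AST = 0.10,
                                            CHF = 0.05, CAN = 0.03),
                             beta = default_effects(),
                             interactions = list(),
                             sigma_noise = 0.25,
                             excess_fraction = 0.05,
                             excess_shift = 3 * sigma_noise,
                             excess_sd = 0.04,
                             persistence_rho = 0.5,
                             ppe_coupling = 2.0,
                             ppr_base_rate = 0.15,
                             ppv_base_rate = 1.5,
                             ppr_event_cost = c(meanlog = log(6000), sdlog = 0.5),
                             ppv_event_cost = c(meanlog = log(700), sdlog = 0.5),
                             wcv_category = "HTN",
                             wcv_coupling = 1.0,
                             mix_category = "CKD",
                             mix_coupling = 2.0,
                             mix_base_p = 0.15,
                             severity_cost_shift = 0,
                             excess_setting = NULL,
                             claim_weight_sdlog = 0.75,
                             setting_probs = c(inpatient = 0.08, emergency = 0.15,
                                               professional = 0.45, pharmacy = 0.25,
                                               other = 0.07)) {
  cfg <- list(n_members = as.integer(n_members), years = as.integer(years),
              seed = as.integer(seed), prevalence = prevalence, beta = beta,
              interactions = interactions, sigma_noise = sigma_noise,
              excess_fraction = excess_fraction, excess_shift = excess_shift,
              excess_sd = excess_sd, persistence_rho = persistence_rho,
              ppe_coupling = ppe_coupling,
              ppr_base_rate = ppr_base_rate, ppv_base_rate = ppv_base_rate,
              ppr_event_cost = ppr_event_cost, ppv_event_cost = ppv_event_cost,
              wcv_category = wcv_category, wcv_coupling = wcv_coupling,
              mix_category = mix_category, mix_coupling = mix_coupling,
              mix_base_p = mix_base_p,
              severity_cost_shift = severity_cost_shift,
              excess_setting = excess_setting,
              claim_weight_sdlog = claim_weight_sdlog,
              setting_probs = setting_probs)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Default true log10-scale effects of the synthetic generator
#'
#' Named effects used as the generating truth: `intercept` (log10 PMPM of the
#' reference member, 2.0 i.e. $100/month), per-year `age` slope (centered at
#' age 39), demographic offsets, plan offsets, and one `cond_*` entry per
#' condition category. Magnitudes are chosen so the covariates explain roughly
#' 55-60% of log10-PMPM variance, the share a risk-adjustment regression on
#' claims data typically reaches on the log scale.
#'
#' @return Named numeric vector.
#' @export
default_effects <- function() {
  c(intercept = 2.0, age = 0.004, female = -0.05, disabled = 0.20,
    race_Black = 0.02, race_Hispanic = 0.03, race_AmIndian = 0.00,
    race_Asian = -0.02, race_Other = 0.01,
    plan_MCO_A = 0.03, plan_MCO_B = -0.02,
    cond_HTN = 0.30, cond_CKD = 0.50, cond_MEN = 0.25, cond_SUD = 0.20,
    cond_DIA = 0.30, cond_AST = 0.20, cond_CHF = 0.45, cond_CAN = 0.60,
    cond_GEN = 0.00)
}

validate_generator_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n_members), cfg$n_members >= 1,
            length(cfg$years) >= 1, !anyNA(cfg$years))
  if (!all(is.finite(cfg$prevalence)) ||
      any(cfg$prevalence < 0 | cfg$prevalence > 1))
    stop("prevalence must be probabilities in [0, 1]")
  if (!is.finite(cfg$sigma_noise) || cfg$sigma_noise <= 0)
    stop("sigma_noise must be a positive real")
  if (cfg$excess_fraction < 0 || cfg$excess_fraction > 1)
    stop("excess_fraction must lie in [0, 1]")
  if (!is.finite(cfg$persistence_rho) || abs(cfg$persistence_rho) >= 1)
    stop("persistence_rho must satisfy |rho| < 1")
  if (cfg$ppe_coupling < 0) stop("ppe_coupling must be non-negative")
  if (!all(is.finite(unlist(cfg$beta)))) stop("beta effects must be finite")
  if (!is.null(cfg$excess_setting) &&
      !cfg$excess_setting %in% names(cfg$setting_probs))
    stop("excess_setting must be one of the claim settings")
  invisible(cfg)
}

#' Synthetic diagnosis-to-category mapping
#'
#' A small stand-in for a clinical grouper (such as the AHRQ Clinical
#' Classification Software, which maps ICD-9-CM codes into ~283 categories):
#' each synthetic category owns a handful of ICD-9-CM-style codes. Essential
#' hypertension (prefix 401) and chronic kidney disease (prefix 585) carry the
#' real code families used in code-level breakdowns: 4019/4011 and
#' 5851..5856 (5856 = end-stage renal disease, the high-severity code).
#'
#' @return A tibble with columns `code` and `category`.
#' @export
synthetic_ccs_map <- function() {
  tibble::tribble(
    ~code,    ~category,
    "4019",   "HTN",
    "4011",   "HTN",
    "5851",   "CKD",
    "5852",   "CKD",
    "5853",   "CKD",
    "5854",   "CKD",
    "5855",   "CKD",
    "5856",   "CKD",
    "2962",   "MEN",
    "3004",   "MEN",
    "3040",   "SUD",
    "3051",   "SUD",
    "25000",  "DIA",
    "25002",  "DIA",
    "49390",  "AST",
    "49392",  "AST",
    "4280",   "CHF",
    "42822",  "CHF",
    "1749",   "CAN",
    "1629",   "CAN",
    "V700",   "GEN",
    "V7231",  "GEN")
}

ckd_low_codes <- c("5851", "5852", "5853", "5854", "5855")
ckd_high_code <- "5856"

#' Generate the synthetic member panel
#'
#' Draws `n_members` members observed in every configured year. Demographics
#' are fixed at entry (age increments by calendar year), enrollment months and
#' pregnancy status are redrawn yearly, chronic condition categories are
#' assigned once per member, and a fraction `excess_fraction` of members is
#' planted with a positive latent excess-utilization effect that follows a
#' stationary AR(1) across years (mean `excess_shift`, SD `excess_sd`,
#' lag-one correlation `persistence_rho`). Non-planted members have latent
#' excess exactly 0 in every year.
#'
#' The latent truth is returned in a separate sidecar table and never appears
#' in the analysis-facing `members` table.
#'
#' @param config A [generator_config()].
#' @return An object of class `"member_panel"`: a list with
#'   * `members` — tibble with `member_id`, `year`, `age`, `sex`, `race`,
#'     `disabled`, `county`, `plan`, `months_enrolled`, `pregnant`;
#'   * `truth` — tibble with `member_id`, `year`, `planted`, `latent_excess`,
#'     `conditions` (";"-joined category ids).
#' @export
generate_members <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_members
  years <- sort(config$years)
  ny <- length(years)

  id <- sprintf("M%07d", seq_len(n))
  age0 <- sample(16:60, n, replace = TRUE)
  sex <- ifelse(runif(n) < 0.66, "F", "M")
  race <- sample(c("White", "Black", "Hispanic", "AmIndian", "Asian", "Other"),
                 n, replace = TRUE,
                 prob = c(0.26, 0.215, 0.375, 0.002, 0.016, 0.132))
  disabled <- runif(n) < 0.45
  county <- sample(sprintf("C%02d", 1:8), n, replace = TRUE)
  plan <- sample(c("FFS", "MCO_A", "MCO_B"), n, replace = TRUE,
                 prob = c(0.30, 0.40, 0.30))

  cats <- names(config$prevalence)
  cond <- matrix(runif(n * length(cats)) <
                   rep(config$prevalence, each = n), nrow = n,
                 dimnames = list(NULL, cats))
  cond_str <- apply(cond, 1L, function(z) paste(c(cats[z], "GEN"), collapse = ";"))

  planted <- runif(n) < config$excess_fraction
  m <- config$excess_shift; tau <- config$excess_sd; rho <- config$persistence_rho
  latent <- matrix(0, nrow = n, ncol = ny)
  latent[planted, 1L] <- m + tau * rnorm(sum(planted))
  if (ny > 1) for (t in 2:ny) {
    innov <- tau * sqrt(1 - rho^2) * rnorm(sum(planted))
    latent[planted, t] <- m + rho * (latent[planted, t - 1L] - m) + innov
  }

  months <- matrix(ifelse(runif(n * ny) < 0.8, 12L,
                          sample(1:11, n * ny, replace = TRUE)), nrow = n)
  preg <- matrix(runif(n * ny) < 0.04, nrow = n) & (sex == "F") & (age0 < 45)

  members <- tibble(
    member_id = rep(id, ny),
    year = rep(years, each = n),
    age = rep(age0, ny) + rep(years - years[1L], each = n),
    sex = rep(sex, ny),
    race = rep(race, ny),
    disabled = rep(disabled, ny),
    county = rep(county, ny),
    plan = rep(plan, ny),
    months_enrolled = as.integer(as.vector(months)),
    pregnant = as.vector(preg))
  truth <- tibble(
    member_id = rep(id, ny),
    year = rep(years, each = n),
    planted = rep(planted, ny),
    latent_excess = as.vector(latent),
    conditions = rep(cond_str, ny))
  structure(list(members = members, truth = truth), class = "member_panel")
}

#' @export
print.member_panel <- function(x, ...) {
  cat("Synthetic member panel:",
      length(unique(x$members$member_id)), "members x",
      length(unique(x$members$year)), "years\n")
  invisible(x)
}

# True log10-PMPM linear predictor (excluding latent excess and noise) for
# each member-year row, given the member table and its condition strings.
linear_predictor <- function(members, conditions, config) {
  b <- config$beta
  pick <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  lp <- rep(b[["intercept"]], nrow(members)) +
    b[["age"]] * (members$age - 39) +
    pick("female") * (members$sex == "F") +
    pick("disabled") * members$disabled
  for (r in c("Black", "Hispanic", "AmIndian", "Asian", "Other"))
    lp <- lp + pick(paste0("race_", r)) * (members$race == r)
  for (p in c("MCO_A", "MCO_B"))
    lp <- lp + pick(paste0("plan_", p)) * (members$plan == p)
  cond_list <- strsplit(conditions, ";", fixed = TRUE)
  for (cat in names(config$prevalence)) {
    has <- vapply(cond_list, function(z) cat %in% z, logical(1))
    lp <- lp + pick(paste0("cond_", cat)) * has
  }
  for (ia in config$interactions) {
    has_a <- vapply(cond_list, function(z) ia$a %in% z, logical(1))
    has_b <- vapply(cond_list, function(z) ia$b %in% z, logical(1))
    lp <- lp + ia$beta * (has_a & has_b)
  }
  lp
}

#' Generate synthetic claim lines
#'
#' For each member-year, draws the annual total expenditure from the
#' generating model `log10(PMPM) = beta.x + latent_excess + noise` (noise SD
#' `sigma_noise`), then splits it across claim lines. Each of the member's
#' condition categories (plus a general-care category) contributes one or more
#' claims; claim settings are sampled independently from `setting_probs` and
#' paid amounts are log-normal shares of the annual total, so claim-line
#' amounts sum to the member's annual total by construction.
#'
#' Two planted variation mechanisms mirror what code-level breakdowns of real
#' claims exhibit: for `wcv_category`, the log-SD of the claim weights grows
#' with the latent excess (within-code cost variance); for `mix_category`, the
#' probability that the member carries the high-severity code (end-stage renal
#' disease, 5856) rather than an earlier-stage code increases with the latent
#' excess on the logit scale (code-mixture shift). Diagnosis codes are
#' assigned at the member-year level within each category.
#'
#' @param panel A `"member_panel"` from [generate_members()].
#' @param config The same [generator_config()].
#' @return Tibble of claim lines: `member_id`, `year`, `setting`,
#'   `principal_dx`, `paid_amount`.
#' @export
generate_claims <- function(panel, config) {
  stopifnot(inherits(panel, "member_panel"))
  members <- panel$members
  if (nrow(members) == 0L) stop("empty member list")
  set.seed(config$seed + 1L)

  mt <- inner_join(members, panel$truth, by = c("member_id", "year"))

  cond_list <- strsplit(mt$conditions, ";", fixed = TRUE)
  ncat <- lengths(cond_list)
  ridx <- rep(seq_len(nrow(mt)), ncat)
  mc <- tibble(row = ridx,
               member_id = mt$member_id[ridx],
               year = mt$year[ridx],
               latent = mt$latent_excess[ridx],
               category = unlist(cond_list))
  mc$n_claims <- 1L + rpois(nrow(mc), 1)
  mc$code <- assign_codes(mc$category, mc$latent, config)

  has_high <- logical(nrow(mt))
  has_high[unique(mc$row[mc$code == ckd_high_code])] <- TRUE
  mu <- linear_predictor(mt, mt$conditions, config) +
    config$severity_cost_shift * has_high +
    (if (is.null(config$excess_setting)) mt$latent_excess else 0) +
    rnorm(nrow(mt), 0, config$sigma_noise)
  total <- mt$months_enrolled * 10^mu

  cidx <- rep(seq_len(nrow(mc)), mc$n_claims)
  claims <- tibble(row = mc$row[cidx],
                   member_id = mc$member_id[cidx],
                   year = mc$year[cidx],
                   category = mc$category[cidx],
                   principal_dx = mc$code[cidx],
                   latent = mc$latent[cidx])
  claims$setting <- sample(names(config$setting_probs), nrow(claims),
                           replace = TRUE, prob = config$setting_probs)
  sdlog <- config$claim_weight_sdlog *
    ifelse(claims$category == config$wcv_category,
           1 + config$wcv_coupling * pmax(claims$latent, 0), 1)
  w <- exp(rnorm(nrow(claims), 0, sdlog))
  wsum <- tapply(w, claims$row, sum)[as.character(claims$row)]
  claims$paid_amount <- total[claims$row] * w / as.numeric(wsum)
  if (!is.null(config$excess_setting)) {
    sel <- claims$setting == config$excess_setting
    claims$paid_amount[sel] <- claims$paid_amount[sel] * 10^claims$latent[sel]
  }
  claims %>%
    select("member_id", "year", "setting", "principal_dx", "paid_amount") %>%
    arrange(.data$member_id, .data$year)
}

# Member-level diagnosis code assignment within each category. CKD severity
# is mixture-shifted by the latent excess; HTN is mostly the unspecified code.
assign_codes <- function(category, latent, config) {
  map <- synthetic_ccs_map()
  code <- character(length(category))
  for (cat in unique(category)) {
    i <- which(category == cat)
    if (cat == config$mix_category) {
      p_high <- stats::plogis(stats::qlogis(config$mix_base_p) +
                                config$mix_coupling * latent[i])
      high <- runif(length(i)) < p_high
      code[i] <- ifelse(high, ckd_high_code,
                        sample(ckd_low_codes, length(i), replace = TRUE))
    } else if (cat == config$wcv_category) {
      code[i] <- ifelse(runif(length(i)) < 0.8, "4019", "4011")
    } else {
      pool <- map$code[map$category == cat]
      code[i] <- pool[sample.int(length(pool), length(i), replace = TRUE)]
    }
  }
  code
}

#' Generate synthetic potentially-preventable-event records
#'
#' Draws per member-year counts of potentially preventable readmissions (PPR)
#' and preventable ED visits (PPV) from Poisson distributions with log-link
#' rates increasing in the latent excess:
#' `rate = base_rate * exp(ppe_coupling * latent_excess)`. Event expenditures
#' are `count` times a log-normal per-event cost draw, and exactly 0 whenever
#' the count is 0. This emulates the output of a preventable-event grouping
#' tool without reimplementing one.
#'
#' @param panel A `"member_panel"`.
#' @param config The same [generator_config()].
#' @return Tibble: `member_id`, `year`, `ppr_count`, `ppr_expenditure`,
#'   `ppv_count`, `ppv_expenditure`.
#' @export
generate_ppe <- function(panel, config) {
  stopifnot(inherits(panel, "member_panel"))
  if (config$ppe_coupling < 0) stop("ppe_coupling must be non-negative")
  set.seed(config$seed + 2L)
  tr <- panel$truth
  lam_r <- config$ppr_base_rate * exp(config$ppe_coupling * tr$latent_excess)
  lam_v <- config$ppv_base_rate * exp(config$ppe_coupling * tr$latent_excess)
  ppr <- rpois(nrow(tr), lam_r)
  ppv <- rpois(nrow(tr), lam_v)
  ppr_exp <- ifelse(ppr > 0, ppr * rlnorm(nrow(tr), config$ppr_event_cost[["meanlog"]],
                                          config$ppr_event_cost[["sdlog"]]), 0)
  ppv_exp <- ifelse(ppv > 0, ppv * rlnorm(nrow(tr), config$ppv_event_cost[["meanlog"]],
                                          config$ppv_event_cost[["sdlog"]]), 0)
  tibble(member_id = tr$member_id, year = tr$year,
         ppr_count = ppr, ppr_expenditure = ppr_exp,
         ppv_count = ppv, ppv_expenditure = ppv_exp)
}

#' Simulate a full synthetic claims dataset
#'
#' One-call wrapper running [generate_members()], [generate_claims()] and
#' [generate_ppe()] under a single configuration.
#'
#' @param config A [generator_config()].
#' @return List with `members`, `claims`, `ppe`, and the `truth` sidecar.
#' @examples
#' sim <- simulate_claims(generator_config(n_members = 200, years = 2011:2012))
#' head(sim$claims)
#' @export
simulate_claims <- function(config = generator_config()) {
  panel <- generate_members(config)
  claims <- generate_claims(panel, config)
  ppe <- generate_ppe(panel, config)
  list(members = panel$members, claims = claims, ppe = ppe, truth = panel$truth)
}
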