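test_that("setting strata keep only members with nonzero setting spend", {
  toy <- toy_tables()
  st <- stratify_cohort(toy$members, toy$claims, "inpatient", 2011)
  expect_identical(st$member_id, "C")
  expect_equal(st$setting_pmpm, 600 / 5)
  # E has pharmacy spend only -> absent from both strata
  expect_false("E" %in%
                 stratify_cohort(toy$members, toy$claims, "emergency", 2011)$member_id)
  expect_error(stratify_cohort(toy$members, toy$claims, "dental", 2011))
})

test_that("stratum totals match a filter-and-sum oracle", {
  sim <- cached_sim("small2", generator_config(n_members = 2000,
                                               years = 2011:2012, seed = 23))
  st <- stratify_cohort(sim$members, sim$claims, "emergency", 2011)
  ids <- apply_inclusion(sim$members, sim$claims, 2011)
  cl <- sim$claims[sim$claims$year == 2011 & sim$claims$setting == "emergency" &
                     sim$claims$member_id %in% ids, ]
  oracle <- tapply(cl$paid_amount, cl$member_id, sum)
  expect_setequal(st$member_id, names(oracle))
  expect_equal(as.numeric(oracle[st$member_id]), st$setting_total,
               tolerance = 1e-12)
  # a member with both inpatient and ED spend appears in both strata
  st2 <- stratify_cohort(sim$members, sim$claims, "inpatient", 2011)
  both <- intersect(st$member_id, st2$member_id)
  expect_gt(length(both), 0)
})

test_that("stratified residuals equal overall residuals when the setting is everything", {
  sim <- cached_sim("small2", generator_config(n_members = 2000,
                                               years = 2011:2012, seed = 23))
  claims_all_inpt <- dplyr::mutate(sim$claims, setting = "inpatient")
  sf <- suppressWarnings(fit_stratified(sim$members, claims_all_inpt,
                                        synthetic_ccs_map(), "inpatient", 2011))
  overall <- cached_fit("small2_2011", sim, 2011)
  expect_equal(sf$fit$residuals[match(overall$fit$member_id, sf$fit$member_id)],
               overall$fit$residuals, tolerance = 1e-10)
  expect_gte(sf$flagged_fraction, 0.01 - 1e-9)
  expect_lte(sf$flagged_fraction, 0.07 + 1e-9)
})

test_that("stratified residuals recover planted setting-specific excess", {
  # shift calibrated to three times the stratified model's residual SD
  cfg <- generator_config(n_members = 50000, years = 2011, seed = 71,
                          excess_setting = "inpatient", excess_shift = 1.27,
                          excess_sd = 0.04)
  sim <- simulate_claims(cfg)
  sf <- suppressMessages(fit_stratified(sim$members, sim$claims,
                                        synthetic_ccs_map(), "inpatient", 2011))
  tr <- sim$truth[match(sf$residuals$member_id, sim$truth$member_id), ]
  # the tail-threshold flags stay inside the configured band
  expect_gte(sf$flagged_fraction, 0.01)
  expect_lte(sf$flagged_fraction, 0.07)
  # a top-5% cut on the stratified residuals recovers the planted members
  top5 <- flag_high_utilizers(
    sf$residuals[, c("member_id", "year", "residual")], "top_fraction", 0.05)
  sens <- sum(top5$high_utilizer & tr$planted) / sum(tr$planted)
  expect_gte(sens, 0.75)
})

test_that("Mann-Whitney comparison matches exact enumeration and null behavior", {
  flags <- tibble::tibble(member_id = letters[1:6], year = 2011,
                          residual = c(3, 2.5, 2, -1, -2, -3),
                          high_utilizer = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ppe <- tibble::tibble(member_id = letters[1:6], year = 2011,
                        ppr_count = c(4L, 5L, 6L, 1L, 2L, 3L),
                        ppr_expenditure = c(400, 500, 600, 100, 200, 300),
                        ppv_count = 0L, ppv_expenditure = 0)
  cmp <- compare_ppe(flags, ppe, 2011)
  row <- cmp[cmp$measure == "ppr_count", ]
  # complete separation of two groups of three: U = 9, exact p = 2/choose(6,3)
  expect_equal(row$statistic, 9)
  expect_equal(row$p_value, 0.1, tolerance = 1e-12)
  expect_equal(row$mean_high - row$mean_other, 3)
  # identical groups: mean difference zero
  ppe2 <- dplyr::mutate(ppe, ppr_count = 2L, ppr_expenditure = 10)
  cmp2 <- compare_ppe(flags, ppe2, 2011)
  expect_equal(cmp2$mean_high[cmp2$measure == "ppr_count"],
               cmp2$mean_other[cmp2$measure == "ppr_count"])
})

test_that("residual-PPE correlation has the configured limiting behavior", {
  cfg0 <- generator_config(n_members = 50000, years = 2011, seed = 72,
                           ppe_coupling = 0)
  sim0 <- simulate_claims(cfg0)
  f <- fit_year(sim0, 2011)
  rc <- ppe_residual_correlation(f$residuals, sim0$ppe, sim0$members, "ppr", 0)
  expect_lt(abs(rc$r), 0.02)
  # Pearson r is invariant to scaling all PPE expenditures by 10
  ppe10 <- dplyr::mutate(sim0$ppe, ppr_expenditure = ppr_expenditure * 10)
  rc10 <- ppe_residual_correlation(f$residuals, ppe10, sim0$members, "ppr", 0)
  expect_equal(rc$r, rc10$r, tolerance = 1e-12)
})

test_that("index-year PPE association exceeds the next-year association", {
  # the latent fluctuation (excess_sd comparable to the shift) is what makes
  # the association fade between years; see the temporal decay tests
  cfg <- generator_config(n_members = 20000, years = 2011:2012, seed = 73,
                          excess_sd = 0.35)
  sim <- simulate_claims(cfg)
  sf <- suppressWarnings(suppressMessages(
    fit_stratified(sim$members, sim$claims, synthetic_ccs_map(),
                   "inpatient", 2011)))
  r0 <- ppe_residual_correlation(sf$residuals, sim$ppe, sim$members, "ppr", 0)
  r1 <- ppe_residual_correlation(sf$residuals, sim$ppe, sim$members, "ppr", 1)
  expect_gt(r0$r, r1$r)
  expect_gt(r1$r, 0)
})
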