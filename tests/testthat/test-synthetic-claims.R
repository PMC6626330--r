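test_that("generator is deterministic and honors degenerate mixtures", {
  cfg <- generator_config(n_members = 300, years = 2011:2012, seed = 99)
  s1 <- simulate_claims(cfg)
  s2 <- simulate_claims(cfg)
  expect_identical(s1$members, s2$members)
  expect_identical(s1$claims, s2$claims)
  expect_identical(s1$ppe, s2$ppe)
  expect_identical(s1$truth, s2$truth)

  cfg0 <- generator_config(n_members = 300, years = 2011:2012, seed = 99,
                           excess_fraction = 0)
  p0 <- generate_members(cfg0)
  expect_true(all(p0$truth$latent_excess == 0))
  expect_false(any(p0$truth$planted))
})

test_that("configuration validation rejects out-of-range values", {
  expect_error(generator_config(sigma_noise = 0), "sigma_noise")
  expect_error(generator_config(excess_fraction = 1.2), "excess_fraction")
  expect_error(generator_config(persistence_rho = 1), "persistence_rho")
  expect_error(generator_config(prevalence = c(HTN = 1.5)), "prevalence")
  expect_error(generator_config(ppe_coupling = -1), "ppe_coupling")
  expect_error(generator_config(excess_setting = "dental"), "excess_setting")
})

test_that("latent excess follows the configured AR(1) across years", {
  cfg <- generator_config(n_members = 50000, years = 2011:2014, seed = 314,
                          persistence_rho = 0.5)
  p <- generate_members(cfg)
  tr <- p$truth[p$truth$planted, ]
  wide <- split(tr, tr$year)
  # pooled lag-one correlation over the three adjacent year pairs
  lag1 <- do.call(rbind, lapply(1:3, function(i) {
    a <- wide[[i]]; b <- wide[[i + 1]]
    cbind(a$latent_excess, b$latent_excess[match(a$member_id, b$member_id)])
  }))
  expect_lt(abs(cor(lag1[, 1], lag1[, 2]) - 0.5), 0.02)
})

test_that("claims reproduce the configured cost model in the noiseless limit", {
  cfg <- generator_config(
    n_members = 150, years = 2011, seed = 7,
    beta = c(intercept = 2, age = 0),
    excess_fraction = 0, sigma_noise = 1e-9, wcv_coupling = 0)
  sim <- simulate_claims(cfg)
  tot <- tapply(sim$claims$paid_amount, sim$claims$member_id, sum)
  months <- sim$members$months_enrolled[match(names(tot), sim$members$member_id)]
  expect_true(all(abs(log10(tot / months) - 2) < 1e-6))
})

test_that("high-severity code assignment decouples when the mixture coupling is zero", {
  cfg <- generator_config(n_members = 50000, years = 2011, seed = 27,
                          mix_coupling = 0)
  sim <- simulate_claims(cfg)
  ckd <- unique(sim$claims$member_id[startsWith(sim$claims$principal_dx, "585")])
  has_high <- ckd %in% sim$claims$member_id[sim$claims$principal_dx == "5856"]
  latent <- sim$truth$latent_excess[match(ckd, sim$truth$member_id)]
  expect_lt(abs(cor(latent, as.numeric(has_high))), 0.02)
})

test_that("mean log10 PMPM of non-planted members matches the analytic expectation", {
  cfg <- generator_config(n_members = 20000, years = 2011, seed = 11,
                          interactions = list(list(a = "CKD", b = "DIA",
                                                   beta = 0.30)))
  sim <- simulate_claims(cfg)
  tr <- sim$truth
  # independent linear-predictor oracle written out longhand from the config
  b <- cfg$beta
  m <- sim$members
  conds <- strsplit(tr$conditions[match(m$member_id, tr$member_id)], ";")
  lp <- b[["intercept"]] + b[["age"]] * (m$age - 39) +
    b[["female"]] * (m$sex == "F") + b[["disabled"]] * m$disabled +
    ifelse(m$race == "Black", b[["race_Black"]],
    ifelse(m$race == "Hispanic", b[["race_Hispanic"]],
    ifelse(m$race == "AmIndian", b[["race_AmIndian"]],
    ifelse(m$race == "Asian", b[["race_Asian"]],
    ifelse(m$race == "Other", b[["race_Other"]], 0))))) +
    ifelse(m$plan == "MCO_A", b[["plan_MCO_A"]],
           ifelse(m$plan == "MCO_B", b[["plan_MCO_B"]], 0))
  for (cc in names(cfg$prevalence))
    lp <- lp + b[[paste0("cond_", cc)]] *
      vapply(conds, function(z) cc %in% z, logical(1))
  has_ckd <- vapply(conds, function(z) "CKD" %in% z, logical(1))
  has_dia <- vapply(conds, function(z) "DIA" %in% z, logical(1))
  lp <- lp + 0.30 * (has_ckd & has_dia)

  tot <- tapply(sim$claims$paid_amount, sim$claims$member_id, sum)
  obs <- log10(tot[m$member_id] / m$months_enrolled)
  keep <- !tr$planted[match(m$member_id, tr$member_id)]
  se <- cfg$sigma_noise / sqrt(sum(keep))
  expect_lt(abs(mean(obs[keep]) - mean(lp[keep])), 3 * se)
})

test_that("claim totals are conserved and the truth stays in the sidecar", {
  sim <- cached_sim("small2", generator_config(n_members = 2000, years = 2011:2012,
                                               seed = 23))
  expect_true(all(sim$claims$paid_amount >= 0))
  expect_false(any(c("latent_excess", "planted") %in%
                     c(names(sim$members), names(sim$claims), names(sim$ppe))))
  co <- suppressMessages(
    build_cohort(sim$members, sim$claims, synthetic_ccs_map(), 2011))
  oracle <- tapply(sim$claims$paid_amount[sim$claims$year == 2011],
                   sim$claims$member_id[sim$claims$year == 2011], sum)
  expect_identical(as.numeric(oracle[co$member_id]), co$total_expenditure)
  # every claim's code maps to exactly one category
  map <- synthetic_ccs_map()
  expect_true(all(sim$claims$principal_dx %in% map$code))
  expect_identical(anyDuplicated(map$code), 0L)
})

test_that("generating noise is normal at the nominal rate when nothing is planted", {
  reps <- 120
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    cfg <- generator_config(n_members = 150, years = 2011, seed = 7000 + i,
                            excess_fraction = 0, wcv_coupling = 0)
    sim <- simulate_claims(cfg)
    tr <- sim$truth
    lp <- residhu:::linear_predictor(sim$members, tr$conditions, cfg)
    tot <- tapply(sim$claims$paid_amount, sim$claims$member_id, sum)
    z <- (log10(tot[sim$members$member_id] / sim$members$months_enrolled) - lp) /
      cfg$sigma_noise
    pvals[i] <- stats::shapiro.test(z)$p.value
  }
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.105)
})

test_that("preventable events couple to the latent excess as configured", {
  sim0 <- simulate_claims(generator_config(n_members = 50000, years = 2011,
                                           seed = 61, ppe_coupling = 0))
  latent <- sim0$truth$latent_excess
  expect_lt(abs(cor(latent, sim0$ppe$ppr_count)), 0.02)
  expect_true(all(sim0$ppe$ppr_expenditure[sim0$ppe$ppr_count == 0] == 0))
  expect_true(all(sim0$ppe$ppv_expenditure[sim0$ppe$ppv_count == 0] == 0))

  cfg1 <- generator_config(n_members = 50000, years = 2011, seed = 62,
                           ppe_coupling = 1.0)
  sim1 <- simulate_claims(cfg1)
  tr <- sim1$truth
  obs_ratio <- mean(sim1$ppe$ppr_count[tr$planted]) /
    mean(sim1$ppe$ppr_count[!tr$planted])
  # Poisson log-link: planted rate = base * E[exp(latent)], latent ~ N(m, tau^2)
  exp_ratio <- exp(cfg1$excess_shift + cfg1$excess_sd^2 / 2)
  expect_lt(abs(obs_ratio - exp_ratio) / exp_ratio, 0.10)
})
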