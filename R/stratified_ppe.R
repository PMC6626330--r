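#' Restrict the cohort to one service setting
#'
#' Members of the year's included population with nonzero expenditure in the
#' setting, with PMPM recomputed from that setting's claims only.
#'
#' @param members,claims Input tables.
#' @param setting `"inpatient"` or `"emergency"`.
#' @param year Index year.
#' @return Tibble with `member_id`, `setting_total`, `months_enrolled`,
#'   `setting_pmpm`.
#' @export
stratify_cohort <- function(members, claims, setting, year) {
  setting <- match.arg(setting, c("inpatient", "emergency"))
  ids <- apply_inclusion(members, claims, year)
  cl <- claims %>%
    filter(.data$year == !!year, .data$setting == !!setting,
           .data$member_id %in% ids) %>%
    group_by(.data$member_id) %>%
    summarise(setting_total = sum(.data$paid_amount), .groups = "drop") %>%
    filter(.data$setting_total > 0)
  months <- members %>%
    filter(.data$year == !!year) %>%
    select("member_id", "months_enrolled")
  cl %>%
    inner_join(months, by = "member_id") %>%
    mutate(setting_pmpm = .data$setting_total / .data$months_enrolled)
}

#' Fit the setting-stratified risk-adjustment model
#'
#' Re-runs the linear risk adjustment with the dependent variable restricted
#' to one service setting: the cohort is limited to members with nonzero
#' expenditure in the setting, the response is log10 setting-specific PMPM,
#' and the independent variables are unchanged. Residual-tail flags are
#' derived with the same consistent-deviation rule as the overall model.
#'
#' @param members,claims Input tables.
#' @param mapping Diagnosis mapping, e.g. [synthetic_ccs_map()].
#' @param setting `"inpatient"` or `"emergency"`.
#' @param year Index year.
#' @param delta,min_frac,max_frac Tail-detection settings
#'   (see [detect_tail_threshold()]).
#' @param weights Comorbidity weight map.
#' @return List of class `"stratified_fit"`: `setting`, `year`, `fit`
#'   (a `linear_fit`), `residuals` (a [flag_high_utilizers()] tibble),
#'   `threshold`, `flagged_fraction`.
#' @export
fit_stratified <- function(members, claims, mapping, setting, year,
                           delta = 0.1, min_frac = 0.01, max_frac = 0.07,
                           weights = charlson_weights()) {
  setting <- match.arg(setting, c("inpatient", "emergency"))
  stratum <- stratify_cohort(members, claims, setting, year)
  cohort <- build_cohort(members, claims, mapping, year, weights) %>%
    inner_join(stratum[, c("member_id", "setting_pmpm")], by = "member_id") %>%
    mutate(pmpm = .data$setting_pmpm, log10_pmpm = log10_pmpm(.data$setting_pmpm))
  if (nrow(cohort) < 50L) stop("stratum too small for a stable OLS fit")
  design <- build_design_matrix(cohort)
  fit <- fit_linear(design)
  qq <- qq_data(fit$residuals)
  thr <- detect_tail_threshold(qq, delta = delta, min_frac = min_frac,
                               max_frac = max_frac)
  res <- tibble(member_id = fit$member_id, year = year, residual = fit$residuals)
  flags <- flag_high_utilizers(res, mode = "threshold", parameter = thr$threshold)
  structure(list(setting = setting, year = year, fit = fit, residuals = flags,
                 threshold = thr$threshold,
                 flagged_fraction = mean(flags$high_utilizer)),
            class = "stratified_fit")
}

#' @export
print.stratified_fit <- function(x, ...) {
  cat(sprintf("Stratified fit (%s, %d): n = %d, R-squared %.4f, flagged %.2f%%\n",
              x$setting, x$year, x$fit$n, x$fit$r_squared,
              100 * x$flagged_fraction))
  invisible(x)
}

ppe_measures <- c("ppr_count", "ppr_expenditure", "ppv_count", "ppv_expenditure")

#' Compare preventable-event measures between high utilizers and others
#'
#' Group means and two-sided Mann-Whitney U tests for each preventable-event
#' measure (PPR/PPV counts and expenditures), in the index year and — when
#' available — the following year. Next-year statistics condition on presence
#' in the next year's records (pairwise deletion).
#'
#' @param flags A [flag_high_utilizers()] tibble for the index year.
#' @param ppe Preventable-event table
#'   (`member_id`, `year`, `ppr_count`, `ppr_expenditure`, `ppv_count`,
#'   `ppv_expenditure`).
#' @param index_year Index year.
#' @param next_year Optional following year (omit for the final study year).
#' @return Tibble: `measure`, `year_type` ("index"/"next"), `year`,
#'   `mean_high`, `mean_other`, `statistic` (U), `p_value`.
#' @export
compare_ppe <- function(flags, ppe, index_year, next_year = NULL) {
  one_year <- function(yr, type) {
    df <- inner_join(flags[, c("member_id", "high_utilizer")],
                     ppe[ppe$year == yr, ], by = "member_id")
    if (!any(df$high_utilizer) || !any(!df$high_utilizer))
      stop("a comparison group is empty in year ", yr)
    bind_rows(lapply(ppe_measures, function(msr) {
      x <- df[[msr]][df$high_utilizer]
      y <- df[[msr]][!df$high_utilizer]
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
      tibble(measure = msr, year_type = type, year = yr,
             mean_high = mean(x), mean_other = mean(y),
             statistic = unname(wt$statistic), p_value = wt$p.value)
    }))
  }
  out <- one_year(index_year, "index")
  if (!is.null(next_year)) out <- bind_rows(out, one_year(next_year, "next"))
  out
}

#' Correlation between residuals and log10 preventable-event expenditures
#'
#' Pearson correlation between the stratified-model residuals of the index
#' year and log10 per-member per-month preventable-event expenditures of the
#' index year (`year_offset = 0`) or the following year (`year_offset = 1`).
#' Members with zero event expenditure are excluded (the log is undefined
#' there); counts-based comparisons in [compare_ppe()] retain them.
#'
#' @param residuals Tibble with `member_id`, `year`, `residual` (one year).
#' @param ppe Preventable-event table.
#' @param members Member table (for months enrolled in the event year).
#' @param measure `"ppr"` or `"ppv"`.
#' @param year_offset 0 for index year, 1 for next year.
#' @return List with `r`, `n`, `year`.
#' @export
ppe_residual_correlation <- function(residuals, ppe, members,
                                     measure = c("ppr", "ppv"),
                                     year_offset = 0) {
  measure <- match.arg(measure)
  yr <- unique(residuals$year) + year_offset
  col <- paste0(measure, "_expenditure")
  ev <- ppe[ppe$year == yr & ppe[[col]] > 0, c("member_id", col)]
  months <- members[members$year == yr, c("member_id", "months_enrolled")]
  df <- residuals %>%
    inner_join(ev, by = "member_id") %>%
    inner_join(months, by = "member_id")
  if (nrow(df) < 3L) stop("fewer than 3 members with nonzero ", measure,
                          " expenditure in year ", yr)
  list(r = cor(df$residual, log10(df[[col]] / df$months_enrolled)),
       n = nrow(df), year = yr)
}
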