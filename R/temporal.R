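#' Rank percentiles of residuals within one year
#'
#' Percentile = average rank of the signed residual divided by `n`; tied
#' residuals receive the mean of their rank range. Signed residuals are
#' ranked (an `absolute = TRUE` switch ranks `|residual|` instead, for
#' sensitivity analyses), because downstream persistence summaries treat high
#' percentiles as over-utilization.
#'
#' @param residuals Tibble with `member_id`, `residual` for one year.
#' @param absolute Rank absolute residuals instead of signed ones.
#' @return Tibble with `member_id`, `percentile` in (0, 1\].
#' @export
rank_percentiles <- function(residuals, absolute = FALSE) {
  if (nrow(residuals) == 0L) stop("empty residual table")
  r <- if (absolute) abs(residuals$residual) else residuals$residual
  tibble(member_id = residuals$member_id,
         percentile = rank(r, ties.method = "average") / length(r))
}

#' Pearson correlation of rank percentiles between two years
#'
#' Computed over members present in both years (pairwise deletion; members
#' absent from either year are dropped, not imputed).
#'
#' @param pct_a,pct_b [rank_percentiles()] tibbles for the two years.
#' @param year_a,year_b Optional year labels carried into the output.
#' @return Tibble with `year_a`, `year_b`, `pearson_r`, `n_members_in_both`.
#' @export
year_pair_correlation <- function(pct_a, pct_b, year_a = NA, year_b = NA) {
  both <- inner_join(pct_a, pct_b, by = "member_id", suffix = c("_a", "_b"))
  if (nrow(both) < 3L) stop("fewer than 3 members present in both years")
  if (var(both$percentile_a) == 0 || var(both$percentile_b) == 0)
    stop("zero variance in a percentile vector")
  tibble(year_a = year_a, year_b = year_b,
         pearson_r = cor(both$percentile_a, both$percentile_b),
         n_members_in_both = nrow(both))
}

#' Pairwise rank-percentile correlation matrix across years
#'
#' Convenience wrapper producing all year pairs (a < b) from a named list of
#' per-year residual tables.
#'
#' @param residuals_by_year Named list (names = years) of residual tibbles.
#' @param absolute Passed to [rank_percentiles()].
#' @return Tibble with one row per year pair.
#' @export
residual_persistence <- function(residuals_by_year, absolute = FALSE) {
  yrs <- names(residuals_by_year)
  pcts <- lapply(residuals_by_year, rank_percentiles, absolute = absolute)
  out <- list()
  for (i in seq_along(yrs)) for (j in seq_along(yrs)) if (i < j)
    out[[length(out) + 1L]] <- year_pair_correlation(
      pcts[[i]], pcts[[j]], as.integer(yrs[i]), as.integer(yrs[j]))
  bind_rows(out)
}

#' Mean next-year rank percentile of index-year high utilizers
#'
#' How high do the members flagged in the index year rank in a later year?
#' Under no persistence the flagged group's mean later-year percentile is
#' 0.5; persistent excess utilization pushes it toward 1.
#'
#' @param flags [flag_high_utilizers()] tibble for the index year.
#' @param pct_later [rank_percentiles()] tibble for the later year.
#' @return List: `flagged_mean`, `others_mean`, `n_flagged`, `n_others`
#'   (counts of members present in the later year).
#' @export
mean_followup_percentile <- function(flags, pct_later) {
  both <- inner_join(flags[, c("member_id", "high_utilizer")], pct_later,
                     by = "member_id")
  if (!any(both$high_utilizer))
    stop("no flagged member persists to the later year")
  list(flagged_mean = mean(both$percentile[both$high_utilizer]),
       others_mean = mean(both$percentile[!both$high_utilizer]),
       n_flagged = sum(both$high_utilizer),
       n_others = sum(!both$high_utilizer))
}
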