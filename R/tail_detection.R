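#' Detect the residual threshold where the right tail consistently deviates
#'
#' Operationalizes reading the Q-Q plot: the flagged region starts at the
#' smallest standardized residual from which *every* larger order statistic
#' exceeds its theoretical normal quantile by more than `delta`. The implied
#' flagged fraction is clipped into `[min_frac, max_frac]` (defaults 1% and
#' 7%, the range a residual-tail rule typically selects on claims data). If
#' no point deviates consistently — e.g. residuals are effectively normal or
#' `delta` is too large — the `max_frac` quantile is returned as a fallback
#' with a warning.
#'
#' The scan stops short of the most extreme `tail_trim` fraction of order
#' statistics: at the very top, sample quantiles are dominated by
#' extreme-value fluctuation (and are systematically shrunk by the sample-SD
#' standardization), so they carry no information about where the departure
#' starts. The flagged region still extends through those extremes.
#'
#' @param qq A [qq_data()] tibble (sorted ascending, standardized).
#' @param delta Consistency tolerance in SD units.
#' @param min_frac,max_frac Bounds on the flagged fraction,
#'   `0 < min_frac < max_frac < 0.5`.
#' @param tail_trim Fraction of the largest order statistics excluded from
#'   the consistency scan (but always included in the flagged region).
#' @return List: `threshold` (raw residual scale), `threshold_std`,
#'   `n_flagged`, `fraction`, `fallback` (logical).
#' @export
detect_tail_threshold <- function(qq, delta = 0.1, min_frac = 0.01, max_frac = 0.07,
                                  tail_trim = 0.005) {
  stopifnot(min_frac > 0, min_frac < max_frac, max_frac < 0.5)
  n <- attr(qq, "n")
  m <- min(max(1L, as.integer(ceiling(tail_trim * n))), n - 2L)
  top <- n - m
  dev <- qq$observed - qq$theoretical
  exceeds <- dev[seq_len(top)] > delta
  run <- if (!exceeds[top]) 0L else if (all(exceeds)) top else top - max(which(!exceeds))
  if (run > 0L) run <- run + m
  fallback <- run == 0L
  if (fallback)
    warning("no consistent right-tail deviation beyond delta = ", delta,
            "; falling back to the max_frac quantile")
  k <- if (fallback) floor(max_frac * n) else run
  k <- max(min(k, floor(max_frac * n)), ceiling(min_frac * n))
  k <- min(k, n - 1L)
  thr_std <- qq$observed[n - k]
  list(threshold = attr(qq, "center") + attr(qq, "scale") * thr_std,
       threshold_std = thr_std,
       n_flagged = k, fraction = k / n, fallback = fallback)
}

#' Size of the top-k high-utilizer cut
#'
#' `floor(fraction * n)`, the convention under which a 5% cut of the yearly
#' cohorts reproduces published top-5% population counts exactly.
#'
#' @param n_population Positive cohort size.
#' @param fraction Fraction in (0, 1).
#' @return Integer count.
#' @export
top_k_count <- function(n_population, fraction) {
  if (any(n_population <= 0)) stop("n_population must be positive")
  if (any(fraction <= 0 | fraction >= 1)) stop("fraction must lie in (0, 1)")
  as.integer(floor(fraction * n_population + 1e-9))
}

#' Flag high utilizers from a residual table
#'
#' Threshold mode flags members with residual strictly above the supplied
#' (raw-scale) threshold; top-fraction mode flags the `floor(fraction * n)`
#' largest residuals, with ties broken deterministically by
#' (residual descending, member_id ascending). Rank percentiles use average
#' ranks divided by `n`.
#'
#' @param residuals Tibble with `member_id`, `year`, `residual`.
#' @param mode `"threshold"` or `"top_fraction"`.
#' @param parameter The raw-scale threshold, or the fraction in (0, 0.5).
#' @return Tibble with `member_id`, `year`, `residual`, `rank_percentile`,
#'   `high_utilizer`.
#' @export
flag_high_utilizers <- function(residuals, mode = c("top_fraction", "threshold"),
                                parameter) {
  mode <- match.arg(mode)
  n <- nrow(residuals)
  if (n == 0L) stop("empty residual table")
  pct <- rank(residuals$residual, ties.method = "average") / n
  high <- logical(n)
  if (mode == "threshold") {
    high <- residuals$residual > parameter
  } else {
    if (parameter <= 0 || parameter >= 0.5) stop("fraction must lie in (0, 0.5)")
    k <- top_k_count(n, parameter)
    ord <- order(-residuals$residual, residuals$member_id)
    high[ord[seq_len(k)]] <- TRUE
  }
  tibble(member_id = residuals$member_id, year = residuals$year,
         residual = residuals$residual, rank_percentile = pct,
         high_utilizer = high)
}

#' Overlap between two flagged populations
#'
#' @param flags_a,flags_b Character vectors of flagged member ids (or
#'   [flag_high_utilizers()] tibbles, from which flagged ids are taken).
#' @return List with `n_intersection` and `pct_of_a` (percent of A, one
#'   decimal).
#' @export
overlap_flags <- function(flags_a, flags_b) {
  ids <- function(x) if (is.data.frame(x)) x$member_id[x$high_utilizer] else x
  a <- ids(flags_a); b <- ids(flags_b)
  if (length(a) == 0L) stop("empty reference flag set")
  ni <- length(intersect(a, b))
  list(n_intersection = ni, pct_of_a = round(100 * ni / length(a), 1))
}

#' Characterize high utilizers versus other patients
#'
#' Group-wise demographics, comorbidity burden and utilization for the
#' flagged versus unflagged members of a cohort: counts, mean age, percent
#' female, percent per race, percent disabled, mean comorbidity index,
#' percent with mental illness and substance use, mean expenditures (total,
#' professional, institutional, pharmacy) and mean ED/inpatient visit counts.
#'
#' @param cohort A [build_cohort()] tibble.
#' @param flags A [flag_high_utilizers()] tibble for the same year.
#' @return Tibble with columns `statistic`, `high_utilizers`, `others`.
#' @export
characterize_groups <- function(cohort, flags) {
  df <- inner_join(cohort, flags[, c("member_id", "high_utilizer")], by = "member_id")
  races <- sort(unique(cohort$race))
  one_group <- function(g) {
    if (nrow(g) == 0L) return(NULL)
    v <- c(n = nrow(g),
           mean_age = mean(g$age),
           pct_female = 100 * mean(g$sex == "F"))
    for (r in races) v[paste0("pct_race_", r)] <- 100 * mean(g$race == r)
    c(v,
      pct_disabled = 100 * mean(g$disabled),
      mean_charlson = mean(g$charlson),
      pct_mental_illness = 100 * mean(g$mental_illness),
      pct_substance_use = 100 * mean(g$substance_use),
      mean_total_expenditure = mean(g$total_expenditure),
      mean_professional_expenditure = mean(g$professional_expenditure),
      mean_institutional_expenditure = mean(g$institutional_expenditure),
      mean_pharmacy_expenditure = mean(g$pharmacy_expenditure),
      mean_ed_visits = mean(g$ed_visits),
      mean_inpatient_visits = mean(g$inpatient_visits))
  }
  hi <- one_group(df[df$high_utilizer, ])
  ot <- one_group(df[!df$high_utilizer, ])
  if (is.null(hi) || is.null(ot)) {
    warning("one comparison group is empty; its column is NA")
    template <- if (is.null(hi)) ot else hi
    nas <- setNames(rep(NA_real_, length(template)), names(template))
    if (is.null(hi)) hi <- nas else ot <- nas
  }
  tibble(statistic = names(hi), high_utilizers = unname(hi), others = unname(ot))
}
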