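#' Apply the study inclusion criteria for one year
#'
#' Keeps adult members (18-60 years old at the index year), excludes pregnant
#' members, and requires nonzero total expenditure in the year.
#'
#' @param members Member table (one row per member-year).
#' @param claims Claim-line table.
#' @param year Index year.
#' @return Character vector of included `member_id`s.
#' @export
apply_inclusion <- function(members, claims, year) {
  if (!year %in% members$year) stop("year ", year, " absent from member table")
  my <- members[members$year == year, ]
  paid <- claims %>%
    filter(.data$year == !!year) %>%
    group_by(.data$member_id) %>%
    summarise(total = sum(.data$paid_amount), .groups = "drop")
  my <- left_join(my, paid, by = "member_id")
  my$total[is.na(my$total)] <- 0
  my$member_id[my$age >= 18 & my$age <= 60 & !my$pregnant & my$total > 0]
}

#' Per-member per-month expenditure
#'
#' @param total_expenditure Total paid amount over the year.
#' @param months_enrolled Integer months of enrollment, 1-12.
#' @return `total_expenditure / months_enrolled`.
#' @export
compute_pmpm <- function(total_expenditure, months_enrolled) {
  if (any(months_enrolled <= 0)) stop("months_enrolled must be >= 1")
  total_expenditure / months_enrolled
}

#' Base-10 log transform of PMPM
#'
#' The dependent variable of the risk-adjustment models. Zero or negative
#' PMPM is a cohort-rule violation (such members must already have been
#' excluded by the nonzero-expenditure rule), so it errors rather than
#' returning `-Inf`.
#'
#' @param pmpm Positive per-member per-month expenditure.
#' @return `log10(pmpm)`.
#' @export
log10_pmpm <- function(pmpm) {
  if (any(pmpm <= 0)) stop("pmpm must be positive; zero-cost members are excluded upstream")
  log10(pmpm)
}

#' Group member diagnoses into clinical categories
#'
#' Maps each claim's principal diagnosis code through a two-column mapping
#' table (`code`, `category`) and returns each member's set of categories as
#' the union over the member-year's claims. Codes absent from the mapping are
#' routed to an `"UNCLASSIFIED"` catch-all (with a warning) rather than
#' dropped.
#'
#' @param claims Claim-line table (already restricted to the year of interest
#'   if desired).
#' @param mapping Tibble with columns `code` and `category`.
#' @return Tibble with `member_id` and `categories` (list-column of character
#'   category ids).
#' @export
group_diagnoses <- function(claims, mapping) {
  cat <- mapping$category[match(claims$principal_dx, mapping$code)]
  if (anyNA(cat)) {
    warning(sum(is.na(cat)), " claim(s) with unmapped diagnosis codes routed to UNCLASSIFIED")
    cat[is.na(cat)] <- "UNCLASSIFIED"
  }
  tibble(member_id = claims$member_id, category = cat) %>%
    distinct() %>%
    group_by(.data$member_id) %>%
    summarise(categories = list(sort(.data$category)), .groups = "drop")
}

#' Synthetic Charlson-style comorbidity weights
#'
#' Weight map over the synthetic condition categories, in the spirit of the
#' Charlson Comorbidity Index (chronic conditions weighted by severity and
#' summed). Categories not in the map contribute 0.
#'
#' @return Named numeric vector.
#' @export
charlson_weights <- function() {
  c(CKD = 2, CAN = 2, CHF = 1, DIA = 1, HTN = 0, AST = 1, MEN = 0, SUD = 0)
}

#' Charlson-style comorbidity index
#'
#' Sum of weights over the *distinct* categories present in the weight map;
#' duplicated categories count once and unknown categories contribute 0.
#'
#' @param categories Character vector (or list of vectors) of category ids.
#' @param weights Named weight map, e.g. [charlson_weights()].
#' @return Non-negative numeric score (vectorized over a list input).
#' @export
charlson_index <- function(categories, weights = charlson_weights()) {
  score1 <- function(cats) {
    cats <- unique(cats)
    sum(weights[cats[cats %in% names(weights)]])
  }
  if (is.list(categories)) vapply(categories, score1, numeric(1)) else score1(categories)
}

#' Build the analysis cohort table for one year
#'
#' Applies inclusion, computes total/setting-specific expenditures, PMPM and
#' log10 PMPM, groups diagnoses into categories, and attaches utilization
#' summaries (ED and inpatient claim counts) and the comorbidity index.
#'
#' @param members,claims Generator-style input tables.
#' @param mapping Diagnosis-to-category mapping, e.g. [synthetic_ccs_map()].
#' @param year Index year.
#' @param weights Comorbidity weight map.
#' @return Tibble with one row per included member: demographics,
#'   `months_enrolled`, `total_expenditure`, expenditures by setting
#'   (`professional_expenditure`, `institutional_expenditure`,
#'   `pharmacy_expenditure`), `ed_visits`, `inpatient_visits`, `pmpm`,
#'   `log10_pmpm`, `categories` (list-column), `charlson`, `mental_illness`,
#'   `substance_use`.
#' @export
build_cohort <- function(members, claims, mapping, year,
                         weights = charlson_weights()) {
  ids <- apply_inclusion(members, claims, year)
  my <- members %>% filter(.data$year == !!year, .data$member_id %in% ids)
  cy <- claims %>% filter(.data$year == !!year, .data$member_id %in% ids)

  totals <- cy %>%
    group_by(.data$member_id) %>%
    summarise(
      total_expenditure = sum(.data$paid_amount),
      professional_expenditure = sum(.data$paid_amount[.data$setting == "professional"]),
      institutional_expenditure = sum(.data$paid_amount[.data$setting %in%
                                                          c("inpatient", "other")]),
      pharmacy_expenditure = sum(.data$paid_amount[.data$setting == "pharmacy"]),
      ed_visits = sum(.data$setting == "emergency"),
      inpatient_visits = sum(.data$setting == "inpatient"),
      .groups = "drop")
  cats <- group_diagnoses(cy, mapping)

  cohort <- my %>%
    inner_join(totals, by = "member_id") %>%
    left_join(cats, by = "member_id")
  empty <- vapply(cohort$categories, is.null, logical(1))
  cohort$categories[empty] <- list(character(0))
  cohort <- cohort %>%
    mutate(
      pmpm = compute_pmpm(.data$total_expenditure, .data$months_enrolled),
      log10_pmpm = log10_pmpm(.data$pmpm),
      charlson = charlson_index(.data$categories, weights),
      mental_illness = vapply(.data$categories, function(z) "MEN" %in% z, logical(1)),
      substance_use = vapply(.data$categories, function(z) "SUD" %in% z, logical(1)))
  cohort
}

#' Build the one-hot design matrix
#'
#' Encodes the risk-adjustment covariates: an intercept, one indicator per
#' disease category (each category is its own binary variable, so no
#' reference level is involved), numeric age, and one-hot blocks for sex,
#' race, county and plan with one reference level dropped per block.
#' Zero-variance columns (a level or category absent from the cohort) are
#' dropped with a message so the matrix has no all-zero columns.
#'
#' @param cohort Tibble from [build_cohort()].
#' @param categoricals Character vector of categorical demographic columns to
#'   one-hot encode.
#' @return Object of class `"design_matrix"`: list with response `y`
#'   (log10 PMPM), matrix `X` (intercept included), `member_id`, `year`, and
#'   `dropped` (names of removed constant columns).
#' @export
build_design_matrix <- function(cohort,
                                categoricals = c("sex", "race", "county", "plan")) {
  if (nrow(cohort) < 2L) stop("cohort must contain at least two members")
  df <- cohort
  for (v in categoricals) df[[v]] <- factor(df[[v]])
  constant <- categoricals[vapply(categoricals,
                                  function(v) nlevels(df[[v]]) < 2, logical(1))]
  if (length(constant))
    message("dropping single-level categoricals: ", paste(constant, collapse = ", "))
  form <- stats::as.formula(paste(
    "~ age +", paste(c(setdiff(categoricals, constant), "disabled"),
                     collapse = " + ")))
  X <- stats::model.matrix(form, data = df)
  colnames(X)[1L] <- "intercept"

  all_cats <- sort(unique(unlist(df$categories)))
  if (length(all_cats)) {
    C <- vapply(all_cats,
                function(cc) vapply(df$categories, function(z) as.numeric(cc %in% z),
                                    numeric(1)),
                numeric(nrow(df)))
    colnames(C) <- paste0("cond_", all_cats)
    X <- cbind(X, C)
  }

  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, function(col) var(col) > 0))
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    message("dropping constant design columns: ", paste(dropped, collapse = ", "))
  X <- X[, keep, drop = FALSE]

  y <- df$log10_pmpm
  if (!all(is.finite(y))) stop("non-finite response in cohort")
  structure(list(y = y, X = X, member_id = df$member_id,
                 year = unique(df$year), dropped = dropped),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("Design matrix:", nrow(x$X), "members x", ncol(x$X), "columns",
      "(year", paste(x$year, collapse = ","), ")\n")
  invisible(x)
}
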