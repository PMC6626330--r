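#' Members of a disease cohort
#'
#' Members with at least one claim in the index year whose principal
#' diagnosis code falls in the category (a code-prefix rule such as `"401"`
#' for essential hypertension or `"585"` for chronic kidney disease, or an
#' explicit code set).
#'
#' @param claims Claim-line table.
#' @param category Prefix string (length 1) or character vector of codes.
#' @param year Index year.
#' @return Character vector of member ids.
#' @export
disease_cohort <- function(claims, category, year) {
  cl <- claims[claims$year == year & dx_in_category(claims$principal_dx, category), ]
  unique(cl$member_id)
}

dx_in_category <- function(dx, category) {
  if (length(category) == 0L) stop("empty category")
  if (length(category) == 1L) startsWith(dx, category) else dx %in% category
}

#' Attribute claim costs to individual diagnosis codes
#'
#' For each claim whose principal diagnosis falls in the category, the claim's
#' expenditure is attributed to that code; per-member per-code totals are
#' annualized to PMPM by the member's months enrolled. Codes outside the
#' category contribute nothing.
#'
#' @param claims Claim-line table.
#' @param members Member table (for `months_enrolled`).
#' @param category Prefix string or code set (see [disease_cohort()]).
#' @param year Year whose claims are attributed.
#' @return Tibble with `member_id`, `code`, `pmpm`.
#' @export
attribute_claim_costs <- function(claims, members, category, year) {
  cl <- claims[claims$year == year & dx_in_category(claims$principal_dx, category), ]
  months <- members[members$year == year, c("member_id", "months_enrolled")]
  cl %>%
    group_by(.data$member_id, code = .data$principal_dx) %>%
    summarise(total = sum(.data$paid_amount), .groups = "drop") %>%
    inner_join(months, by = "member_id") %>%
    mutate(pmpm = .data$total / .data$months_enrolled) %>%
    select("member_id", "code", "pmpm")
}

#' Assign members to residual-ordered groups
#'
#' Members are sorted by residual from high to low (ties broken by member id)
#' and chunked into consecutive groups of `group_size`; group 0 holds the
#' highest residuals and the last group may be smaller.
#'
#' @param residuals Tibble with `member_id`, `residual`.
#' @param group_size Positive integer (5000 reproduces full-scale practice;
#'   smaller values suit smaller cohorts).
#' @return Tibble with `member_id`, `residual`, `group_index` (0-based).
#' @export
group_by_residual <- function(residuals, group_size = 5000) {
  if (group_size <= 0) stop("group_size must be positive")
  ord <- order(-residuals$residual, residuals$member_id)
  tibble(member_id = residuals$member_id[ord],
         residual = residuals$residual[ord],
         group_index = as.integer((seq_along(ord) - 1L) %/% group_size))
}

#' Code-level breakdown of category spending across the residual spectrum
#'
#' For each (residual group, diagnosis code) cell: the number of patients
#' with any expenditure on the code, and the group-mean per-member per-month
#' expenditure for the code (members of the group without that code
#' contribute zero, so per-group code means sum exactly to the group's mean
#' category PMPM). Groups formed on index-year residuals can be combined
#' with another year's attributed costs to track the same members forward.
#'
#' @param groups A [group_by_residual()] tibble.
#' @param per_code_costs An [attribute_claim_costs()] tibble.
#' @return List with `cells` (tibble `group_index`, `code`, `n_patients`,
#'   `mean_pmpm`) and `totals` (tibble `group_index`, `n_members`,
#'   `mean_category_pmpm`).
#' @export
breakdown_table <- function(groups, per_code_costs) {
  sizes <- groups %>% count(.data$group_index, name = "n_members")
  joined <- inner_join(per_code_costs,
                       groups[, c("member_id", "group_index")], by = "member_id")
  cells <- joined %>%
    group_by(.data$group_index, .data$code) %>%
    summarise(n_patients = dplyr::n_distinct(.data$member_id[.data$pmpm > 0]),
              sum_pmpm = sum(.data$pmpm), .groups = "drop") %>%
    inner_join(sizes, by = "group_index") %>%
    mutate(mean_pmpm = .data$sum_pmpm / .data$n_members) %>%
    select("group_index", "code", "n_patients", "mean_pmpm") %>%
    arrange(.data$group_index, .data$code)
  totals <- cells %>%
    group_by(.data$group_index) %>%
    summarise(mean_category_pmpm = sum(.data$mean_pmpm), .groups = "drop") %>%
    right_join(sizes, by = "group_index") %>%
    mutate(mean_category_pmpm = ifelse(is.na(.data$mean_category_pmpm), 0,
                                       .data$mean_category_pmpm)) %>%
    select("group_index", "n_members", "mean_category_pmpm") %>%
    arrange(.data$group_index)
  list(cells = cells, totals = totals)
}
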