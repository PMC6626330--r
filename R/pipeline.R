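#' Read a pipeline run configuration from YAML
#'
#' @param path Path to a YAML document with the fields accepted by
#'   [run_all()].
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

validate_run_config <- function(config) {
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required")
  has_gen <- !is.null(config$generator)
  has_paths <- !is.null(config$paths$members) && !is.null(config$paths$claims)
  if (!has_gen && !has_paths)
    stop("config must supply either a 'generator' block or 'paths$members' and 'paths$claims'")
  if (has_paths) for (p in unlist(config$paths))
    if (!file.exists(p)) stop("input file not found: ", p)
  invisible(config)
}

write_table <- function(df, dir, name) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.list(df[[j]]))
    df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
  path <- file.path(dir, paste0(name, ".csv"))
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full high-utilizer analysis pipeline
#'
#' Orchestrates simulate (or load) -> prepare -> fit -> identify -> temporal
#' -> breakdown -> stratify -> report, writing every stage's outputs under
#' one run directory together with a reproducible manifest (configuration
#' hash, seed, stage outputs). A failing stage aborts with the stage named.
#'
#' Configuration fields (all optional unless noted):
#' * `out_dir` (required) — run directory.
#' * `generator` — arguments for [generator_config()]; alternatively
#'   `paths$members`, `paths$claims`, `paths$ppe` name CSV inputs.
#' * `seed` — global seed, fanned out to per-stage substreams.
#' * `model` — `gbm` (logical, default TRUE) and [gbm_params()] overrides.
#' * `tail` — `mode` ("threshold"/"top_fraction"), `delta`, `min_frac`,
#'   `max_frac`, `top_fraction`.
#' * `breakdown` — `category` (code prefix, default "401"), `group_size`,
#'   `index_year`.
#' * `stratified` — `settings` (default inpatient + emergency).
#'
#' @param config A named list or a YAML path.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(seed = seed, stages = list())
  artifacts <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # -- simulate ---------------------------------------------------------------
  mapping <- synthetic_ccs_map()
  dat <- stage("simulate", {
    if (!is.null(config$generator)) {
      gen_args <- config$generator
      if (is.null(gen_args$seed)) gen_args$seed <- seed
      gcfg <- do.call(generator_config, gen_args)
      manifest$generator_seed <- gcfg$seed
      d <- simulate_claims(gcfg)
      artifacts <- c(artifacts,
                     write_table(d$members, out, "members"),
                     write_table(d$claims, out, "claims"),
                     write_table(d$ppe, out, "ppe"),
                     write_table(d$truth, out, "truth_sidecar"))
      d
    } else {
      list(members = as_tibble(utils::read.csv(config$paths$members)),
           claims = as_tibble(utils::read.csv(config$paths$claims)),
           ppe = if (!is.null(config$paths$ppe))
             as_tibble(utils::read.csv(config$paths$ppe)) else NULL)
    }
  })
  years <- if (!is.null(config$years)) as.integer(config$years) else
    sort(unique(dat$members$year))

  # -- prepare ----------------------------------------------------------------
  cohorts <- stage("prepare", {
    cs <- lapply(years, function(y) build_cohort(dat$members, dat$claims, mapping, y))
    names(cs) <- years
    artifacts <- c(artifacts, write_table(bind_rows(cs), out, "cohort"))
    cs
  })

  # -- fit --------------------------------------------------------------------
  tail_cfg <- config$tail
  if (is.null(tail_cfg$mode)) tail_cfg$mode <- "top_fraction"
  if (is.null(tail_cfg$delta)) tail_cfg$delta <- 0.1
  if (is.null(tail_cfg$min_frac)) tail_cfg$min_frac <- 0.01
  if (is.null(tail_cfg$max_frac)) tail_cfg$max_frac <- 0.07
  if (is.null(tail_cfg$top_fraction)) tail_cfg$top_fraction <- 0.05
  use_gbm <- is.null(config$model$gbm) || isTRUE(config$model$gbm)

  fits <- stage("fit", {
    gp_args <- config$model[setdiff(names(config$model), "gbm")]
    gp <- do.call(gbm_params, if (length(gp_args)) gp_args else list())
    fs <- lapply(seq_along(years), function(i) {
      design <- build_design_matrix(cohorts[[i]])
      lin <- fit_linear(design)
      gbm <- if (use_gbm) fit_gbm(design, gp, split_seed = seed + 100L + i) else NULL
      list(design = design, linear = lin, gbm = gbm)
    })
    names(fs) <- years
    summary <- lapply(fs, function(f) {
      s <- list(n = f$linear$n, r_squared_linear = f$linear$r_squared,
                f_test_p = f$linear$f_test_p, bp_p = f$linear$bp_p)
      if (!is.null(f$gbm))
        s <- c(s, list(r_squared_gbm_train = f$gbm$r_squared_train,
                       r_squared_gbm_test = f$gbm$r_squared_test,
                       r_squared_gbm_overall = f$gbm$r_squared_overall,
                       gbm_best_params = f$gbm$best_params))
      s
    })
    jsonlite::write_json(summary, file.path(out, "fit_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, file.path(out, "fit_summary.json"))
    residual_tables <- lapply(seq_along(years), function(i)
      tibble(member_id = fs[[i]]$linear$member_id, year = years[i],
             residual = fs[[i]]$linear$residuals))
    names(residual_tables) <- years
    artifacts <- c(artifacts, write_table(bind_rows(residual_tables), out, "residuals"))
    qq <- qq_data(fs[[length(fs)]]$linear$residuals)
    artifacts <- c(artifacts, write_table(qq, out, "qq_pairs"))
    list(fits = fs, residual_tables = residual_tables)
  })

  # -- identify ---------------------------------------------------------------
  flags_by_year <- stage("identify", {
    fl <- lapply(seq_along(years), function(i) {
      res <- fits$residual_tables[[i]]
      if (tail_cfg$mode == "threshold") {
        qq <- qq_data(res$residual)
        thr <- detect_tail_threshold(qq, tail_cfg$delta, tail_cfg$min_frac,
                                     tail_cfg$max_frac)
        flag_high_utilizers(res, "threshold", thr$threshold)
      } else {
        flag_high_utilizers(res, "top_fraction", tail_cfg$top_fraction)
      }
    })
    names(fl) <- years
    artifacts <- c(artifacts, write_table(bind_rows(fl), out, "flags"))
    if (use_gbm) {
      ov <- lapply(seq_along(years), function(i) {
        gres <- tibble(member_id = fits$fits[[i]]$gbm$member_id, year = years[i],
                       residual = fits$fits[[i]]$gbm$residuals)
        gfl <- flag_high_utilizers(gres, "top_fraction", tail_cfg$top_fraction)
        o <- overlap_flags(fl[[i]], gfl)
        list(year = years[i], n_intersection = o$n_intersection,
             overlap_pct = o$pct_of_a)
      })
      jsonlite::write_json(ov, file.path(out, "overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, file.path(out, "overlap.json"))
    }
    chr <- characterize_groups(cohorts[[length(years)]], fl[[length(years)]])
    artifacts <- c(artifacts, write_table(chr, out, "characterization"))
    fl
  })

  # -- temporal ---------------------------------------------------------------
  stage("temporal", {
    if (length(years) >= 2L) {
      persist <- residual_persistence(fits$residual_tables)
      followup <- bind_rows(lapply(seq_len(length(years) - 1L), function(i) {
        fu <- mean_followup_percentile(
          flags_by_year[[i]], rank_percentiles(fits$residual_tables[[i + 1L]]))
        tibble(index_year = years[i], next_year = years[i + 1L],
               flagged_mean = fu$flagged_mean, others_mean = fu$others_mean)
      }))
      artifacts <- c(artifacts, write_table(persist, out, "temporal_correlations"),
                     write_table(followup, out, "followup_percentiles"))
    }
    NULL
  })

  # -- breakdown --------------------------------------------------------------
  stage("breakdown", {
    bd_cfg <- config$breakdown
    category <- if (is.null(bd_cfg$category)) "401" else bd_cfg$category
    idx_year <- if (is.null(bd_cfg$index_year))
      years[max(1L, length(years) - 1L)] else bd_cfg$index_year
    grp_size <- if (is.null(bd_cfg$group_size))
      max(50L, nrow(cohorts[[as.character(idx_year)]]) %/% 10L) else bd_cfg$group_size
    dc <- disease_cohort(dat$claims, category, idx_year)
    res <- fits$residual_tables[[as.character(idx_year)]]
    res <- res[res$member_id %in% dc, ]
    groups <- group_by_residual(res, grp_size)
    cost_years <- intersect(c(idx_year, idx_year + 1L), years)
    bd <- bind_rows(lapply(cost_years, function(cy) {
      pc <- attribute_claim_costs(dat$claims, dat$members, category, cy)
      tab <- breakdown_table(groups, pc)
      mutate(tab$cells, cost_year = cy)
    }))
    artifacts <- c(artifacts, write_table(bd, out, "breakdown"))
    NULL
  })

  # -- stratify ---------------------------------------------------------------
  stage("stratify", {
    settings <- if (is.null(config$stratified$settings))
      c("inpatient", "emergency") else config$stratified$settings
    idx_year <- years[1L]
    nxt <- if (length(years) >= 2L) years[2L] else NULL
    strat_rows <- list(); ppe_rows <- list()
    for (s in settings) {
      sf <- fit_stratified(dat$members, dat$claims, mapping, s, idx_year,
                           delta = tail_cfg$delta, min_frac = tail_cfg$min_frac,
                           max_frac = tail_cfg$max_frac)
      strat_rows[[s]] <- tibble(setting = s, year = idx_year, n = sf$fit$n,
                                r_squared = sf$fit$r_squared,
                                flagged_fraction = sf$flagged_fraction)
      if (!is.null(dat$ppe)) {
        cmp <- compare_ppe(sf$residuals, dat$ppe, idx_year, nxt)
        msr <- if (s == "inpatient") "ppr" else "ppv"
        corr <- ppe_residual_correlation(sf$residuals, dat$ppe, dat$members,
                                         msr, year_offset = 0)
        ppe_rows[[s]] <- mutate(cmp, setting = s,
                                residual_ppe_correlation = corr$r)
      }
    }
    artifacts <- c(artifacts, write_table(bind_rows(strat_rows), out, "stratified"))
    if (length(ppe_rows))
      artifacts <- c(artifacts, write_table(bind_rows(ppe_rows), out, "ppe_comparison"))
    NULL
  })

  # -- report -----------------------------------------------------------------
  stage("report", {
    manifest$config_hash <- rlang::hash(config)
    manifest$years <- years
    manifest$artifacts <- sort(unique(basename(
      list.files(out, pattern = "\\.(csv|json)$"))))
    manifest$package_version <- as.character(utils::packageVersion("residhu"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    NULL
  })
  invisible(manifest)
}
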