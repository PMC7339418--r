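#' Validate in-memory survey records
#'
#' Applies the eligibility and consistency rules to a table of survey
#' attempts: minimum age 16 (under-age rows are rejected, not fatal),
#' positive durations, valid categorical codes, and an incompleteness
#' reason present exactly when the status is `incomplete`.  Incomplete
#' attempts may lack demographics.  Duplicate record ids are a hard error.
#'
#' @param records Data frame with columns `record_id`, `date`, `site_id`,
#'   `gender`, `age`, `ses`, `status` (`complete`/`incomplete`),
#'   `incomplete_reason`, `duration` (minutes), `residence`, `income_band`,
#'   `language_at_home`, `education_year10`.
#' @return The validated records tibble, with a `rejects` attribute (a
#'   tibble `record_id`, `reason`) listing dropped rows.
#' @export
validate_records <- function(records) {
  records <- as_tibble(records)
  defaults <- list(
    record_id = NA_character_, date = as.Date(NA), site_id = NA_character_,
    gender = NA_character_, age = NA_real_, ses = NA_character_,
    status = NA_character_, incomplete_reason = NA_character_,
    duration = NA_real_, residence = NA_character_, income_band = NA_character_,
    language_at_home = NA, education_year10 = NA
  )
  for (nm in setdiff(names(defaults), names(records))) {
    records[[nm]] <- defaults[[nm]]
  }
  if (anyDuplicated(records$record_id)) {
    stop("duplicate record id(s): ",
         paste(unique(records$record_id[duplicated(records$record_id)]), collapse = ", "),
         call. = FALSE)
  }
  reject_reason <- rep(NA_character_, nrow(records))
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- FALSE
    reject_reason[is.na(reject_reason) & cond] <<- reason
  }
  flag(records$age < 16, "eligibility")
  flag(!records$status %in% c("complete", "incomplete"), "invalid_status")
  flag(!is.na(records$gender) & !records$gender %in% gender_levels, "invalid_gender")
  flag(!is.na(records$ses) & !records$ses %in% ses_levels, "invalid_ses")
  flag(!is.na(records$residence) & !records$residence %in% residence_levels,
       "invalid_residence")
  flag(!is.na(records$duration) & records$duration <= 0, "nonpositive_duration")
  flag(records$status == "incomplete" & is.na(records$incomplete_reason),
       "missing_incomplete_reason")
  flag(records$status == "complete" & !is.na(records$incomplete_reason),
       "reason_on_complete")
  flag(!is.na(records$incomplete_reason) &
         !records$incomplete_reason %in% incomplete_reason_levels,
       "invalid_incomplete_reason")
  # a complete, analysable record needs its stratum demographics
  flag(records$status == "complete" &
         (is.na(records$gender) | is.na(records$age) | is.na(records$ses)),
       "missing_demographics")

  rejects <- tibble(record_id = records$record_id[!is.na(reject_reason)],
                    reason = reject_reason[!is.na(reject_reason)])
  kept <- records[is.na(reject_reason), ]
  if (nrow(rejects) > 0) {
    message(nrow(rejects), " record(s) rejected (",
            paste(sprintf("%s: %d", names(table(rejects$reason)), table(rejects$reason)),
                  collapse = ", "), ")")
  }
  attr(kept, "rejects") <- rejects
  kept
}

#' Ingest survey records from CSV
#'
#' Reads one row per survey attempt and validates it with
#' [validate_records()]; malformed or ineligible rows are collected into
#' the `rejects` attribute (and optionally written to a rejects CSV)
#' rather than aborting the ingest.
#'
#' @param path Records CSV path.
#' @param rejects_path Optional path to write rejected rows to.
#' @return Validated records tibble with a `rejects` attribute.
#' @export
ingest_records <- function(path, rejects_path = NULL) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  records <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                             col_types = readr::cols(
                               record_id = readr::col_character(),
                               date = readr::col_date(),
                               site_id = readr::col_character(),
                               gender = readr::col_character(),
                               age = readr::col_double(),
                               ses = readr::col_character(),
                               status = readr::col_character(),
                               incomplete_reason = readr::col_character(),
                               duration = readr::col_double(),
                               residence = readr::col_character(),
                               income_band = readr::col_character(),
                               language_at_home = readr::col_logical(),
                               education_year10 = readr::col_logical()
                             ))
  kept <- validate_records(records)
  if (!is.null(rejects_path)) {
    readr::write_csv(attr(kept, "rejects"), rejects_path, progress = FALSE)
  }
  kept
}

#' Summarise survey commencements and attrition
#'
#' Counts commenced survey attempts, incompletes by reason (participant
#' left for time reasons, technical problems, discomfort with content,
#' other) and the final analysable sample size, which always satisfies
#' `final_n = commenced - sum(incomplete_by_reason)`.
#'
#' @param records Validated survey records.
#' @return An object of class `completion_summary`.
#' @export
completion_summary <- function(records) {
  records <- as_tibble(records)
  commenced <- nrow(records)
  inc <- records[records$status == "incomplete", ]
  by_reason <- table(factor(inc$incomplete_reason, levels = incomplete_reason_levels))
  by_reason <- by_reason[by_reason > 0]
  structure(
    list(
      commenced = commenced,
      incomplete_by_reason = stats::setNames(as.integer(by_reason), names(by_reason)),
      final_n = commenced - nrow(inc)
    ),
    class = "completion_summary"
  )
}

#' @export
print.completion_summary <- function(x, ...) {
  cat("<completion_summary> commenced ", x$commenced, "; incomplete ",
      sum(x$incomplete_by_reason), "; final n = ", x$final_n, "\n", sep = "")
  if (length(x$incomplete_by_reason) > 0) {
    cat("  reasons:", paste(sprintf("%s = %d", names(x$incomplete_by_reason),
                                    x$incomplete_by_reason), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Recruitment progress against strata targets
#'
#' Counts completed surveys on or before a review date towards each
#' stratum's target (ages are binned into the frame's bands; bands are
#' closed on the left, so a participant aged exactly 25 counts in 25-44).
#' Over-recruited strata are flagged; `remaining = max(0, target -
#' recruited)`.  Records whose stratum lies outside the frame are counted
#' under a catch-all bucket and flagged rather than lost.
#'
#' @param records Validated survey records.
#' @param targets A `strata_targets` object.
#' @param as_of Review date; defaults to the latest record date.
#' @return An object of class `progress_report`: tibble with per-stratum
#'   `recruited`, `target`, `remaining`, `over_flag`, plus attributes
#'   `as_of`, `overall_fraction` and `catch_all` (out-of-frame count).
#' @export
progress_report <- function(records, targets, as_of = NULL) {
  stopifnot(inherits(targets, "strata_targets"))
  records <- as_tibble(records)
  completes <- records[records$status == "complete", ]
  if (is.null(as_of)) as_of <- suppressWarnings(max(completes$date))
  completes <- completes[!is.na(completes$date) & completes$date <= as_of, ]
  completes$age_band <- as.character(bin_age(completes$age))
  tgt <- dplyr::mutate(targets$targets,
                       dplyr::across(c("gender", "age_band", "ses"), as.character))
  counts <- dplyr::count(completes, .data$gender, .data$age_band, .data$ses,
                         name = "recruited")
  rep_tab <- dplyr::left_join(tgt[, c("gender", "age_band", "ses", "target")],
                              counts, by = c("gender", "age_band", "ses"))
  rep_tab$recruited[is.na(rep_tab$recruited)] <- 0L
  in_frame <- dplyr::semi_join(counts, tgt, by = c("gender", "age_band", "ses"))
  catch_all <- sum(counts$recruited) - sum(in_frame$recruited)
  if (catch_all > 0) {
    warning(catch_all, " complete record(s) fall outside the target frame (catch-all bucket)",
            call. = FALSE)
  }
  rep_tab$remaining <- pmax(0L, rep_tab$target - rep_tab$recruited)
  rep_tab$over_flag <- rep_tab$recruited > rep_tab$target
  structure(rep_tab,
            class = c("progress_report", class(rep_tab)),
            as_of = as_of,
            catch_all = as.integer(catch_all),
            overall_fraction = sum(pmin(rep_tab$recruited, rep_tab$target)) /
              max(1L, sum(rep_tab$target)))
}

#' Survey duration statistics
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and maximum
#' of survey duration in minutes over all attempts that carry a duration
#' (complete or incomplete).  Values are kept at full precision; the print
#' method rounds to 2 decimals.
#'
#' @param records Validated survey records.
#' @return An object of class `duration_stats` (list `n`, `mean`, `sd`,
#'   `min`, `max`); with no durations present, `n = 0` plus a warning.
#' @export
duration_stats <- function(records) {
  d <- as_tibble(records)$duration
  d <- d[!is.na(d)]
  if (length(d) == 0) {
    warning("no durations recorded", call. = FALSE)
    return(structure(list(n = 0L, mean = NA_real_, sd = NA_real_,
                          min = NA_real_, max = NA_real_),
                     class = "duration_stats"))
  }
  structure(
    list(n = length(d), mean = mean(d),
         sd = if (length(d) > 1) stats::sd(d) else NA_real_,
         min = min(d), max = max(d)),
    class = "duration_stats"
  )
}

#' @export
print.duration_stats <- function(x, ...) {
  cat(sprintf("<duration_stats> n = %d; mean = %.2f min (SD = %.2f); min = %.2f; max = %.2f\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Tally a categorical variable with percentages
#'
#' Counts and percentages (one decimal, recomputed from counts) of a
#' categorical vector — the workhorse behind recruitment-source and
#' residence breakdowns.
#'
#' @param x Character or factor vector (NAs dropped).
#' @param levels Optional level order; defaults to decreasing frequency.
#' @param digits Decimals for the percentage column.
#' @return Tibble `category`, `n`, `pct`.
#' @export
category_summary <- function(x, levels = NULL, digits = 1) {
  x <- x[!is.na(x)]
  tab <- table(if (is.null(levels)) factor(x) else factor(x, levels = levels))
  if (is.null(levels)) tab <- sort(tab, decreasing = TRUE)
  tibble(
    category = names(tab),
    n = as.integer(tab),
    pct = round(100 * as.integer(tab) / max(1L, length(x)), digits)
  )
}

#' Default grouping of site types into reporting categories
#'
#' Service types are grouped into the broader categories used in field
#' reports (e.g. unemployment and public-housing services together;
#' mental-health with alcohol-and-other-drug services; public events with
#' public spaces).
#'
#' @return Tibble `type`, `group`.
#' @export
site_type_groups <- function() {
  tibble(
    type = c("public_space", "public_event", "indigenous_health_service",
             "community_group", "indigenous_adult_education",
             "unemployment_service", "public_housing_service",
             "homelessness_service", "mental_health_service", "aod_service",
             "childcare", "cultural_group", "hobby_group"),
    group = c("Public space", "Public space", "Indigenous health service",
              "Community groups", "Indigenous community colleges",
              "Unemployment and housing services", "Unemployment and housing services",
              "Homelessness services", "Mental health and AOD services",
              "Mental health and AOD services", "Childcare services",
              "Cultural groups", "Cultural groups")
  )
}

#' Recruitment-source breakdown of completed surveys
#'
#' Where the analysable sample was recruited: completed records are mapped
#' through the registry to their site's reporting category and tallied
#' with percentages.
#'
#' @param records Validated survey records.
#' @param registry A `site_registry`.
#' @param groups Type-to-category map; see [site_type_groups()].
#' @return Tibble `category`, `n`, `pct`.
#' @export
site_category_summary <- function(records, registry, groups = site_type_groups()) {
  stopifnot(inherits(registry, "site_registry"))
  completes <- as_tibble(records)[as_tibble(records)$status == "complete", ]
  type <- registry$sites$type[match(completes$site_id, registry$sites$site_id)]
  grp <- groups$group[match(as.character(type), groups$type)]
  category_summary(grp)
}

#' Residence breakdown of completed surveys
#'
#' Where participants reported living: town or city, a discrete Indigenous
#' community, local parkland or scrub (outdoors), or other.
#'
#' @param records Validated survey records.
#' @return Tibble `category`, `n`, `pct`.
#' @export
residence_summary <- function(records) {
  completes <- as_tibble(records)[as_tibble(records)$status == "complete", ]
  category_summary(completes$residence, levels = residence_levels)
}

#' Heuristic duplicate-participation report
#'
#' Participant names are deliberately not recorded in anonymous field
#' surveys, so true re-participation cannot be detected.  This report
#' flags groups of completed records sharing (site, date, gender, age,
#' SES) as *possible* duplicates.  It is a heuristic screen only: distinct
#' individuals with identical demographics surveyed at the same site on
#' the same day are indistinguishable from repeats.
#'
#' @param records Validated survey records.
#' @return Tibble of suspect groups with `n_records`.
#' @export
possible_duplicates <- function(records) {
  completes <- as_tibble(records)[as_tibble(records)$status == "complete", ]
  grp <- dplyr::count(completes, .data$site_id, .data$date, .data$gender,
                      .data$age, .data$ses, name = "n_records")
  grp[grp$n_records > 1, ]
}
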