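#' Construct a census profile
#'
#' A census profile is the reference standard for the whole pipeline: the
#' proportion of the eligible population (aged 16+) in each sampling-frame
#' stratum (age band x gender x socioeconomic status), plus optional
#' marginal distributions (weekly income bands, Indigenous language spoken
#' at home, completion of Year 10) used for representativeness checks.
#'
#' Proportions may be given as fractions or as percentages; the scale is
#' auto-detected from the sum (near 1 vs near 100).  In strict mode (the
#' default) the proportions must sum to 1 within `tolerance` after
#' rescaling; with `normalize = TRUE` they are rescaled to sum to 1.
#'
#' The `general` SES category is the residual: the census mass of people in
#' none of the four named categories (e.g. part-time workers, retirees).
#'
#' @param strata Data frame with columns `gender` (`female`/`male`),
#'   `age_band` (`16-24`, `25-44`, `45-64`, `65+`; en-dash accepted),
#'   `ses` (`full_time_worker`, `student`, `unemployed`, `homeless`,
#'   `general`) and `proportion`.
#' @param population_size Optional count of eligible individuals.
#' @param income_distribution Optional named numeric vector of proportions
#'   per weekly income band, in ascending band order; fractions or
#'   percentages, must sum to 1 (or 100) within tolerance.
#' @param language_at_home Optional proportion (or percentage) speaking an
#'   Indigenous language at home.
#' @param education_year10 Optional proportion (or percentage) who completed
#'   Year 10.
#' @param normalize If `TRUE`, rescale strata proportions to sum to 1
#'   instead of erroring on a deficit/excess.
#' @param tolerance Tolerance for the sum-to-one invariant.
#' @return An object of class `census_profile`.
#' @export
#' @examples
#' census_profile(data.frame(
#'   gender = c("female", "male"), age_band = "16-24",
#'   ses = "general", proportion = c(0.5, 0.5)
#' ))
census_profile <- function(strata, population_size = NULL,
                           income_distribution = NULL,
                           language_at_home = NULL,
                           education_year10 = NULL,
                           normalize = FALSE, tolerance = 1e-6) {
  strata <- as_tibble(strata)
  required <- c("gender", "age_band", "ses", "proportion")
  missing_cols <- setdiff(required, names(strata))
  if (length(missing_cols) > 0) {
    stop("strata table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(strata) == 0) stop("strata table is empty", call. = FALSE)
  if (anyNA(strata$proportion)) {
    bad <- strata[is.na(strata$proportion), ]
    stop("missing proportion for stratum ",
         stratum_key(bad$gender[1], bad$age_band[1], bad$ses[1]), call. = FALSE)
  }
  strata$gender <- check_levels(strata$gender, gender_levels, "gender")
  strata$age_band <- normalize_age_band(strata$age_band)
  strata$ses <- check_levels(strata$ses, ses_levels, "SES")
  key <- stratum_key(strata$gender, strata$age_band, strata$ses)
  if (anyDuplicated(key)) {
    stop("duplicate stratum row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (any(strata$proportion < 0)) stop("negative stratum proportion", call. = FALSE)

  p <- as.numeric(strata$proportion)
  s <- sum(p)
  if (s > 2) p <- p / 100  # percentage scale
  s <- sum(p)
  if (normalize) {
    if (s <= 0) stop("proportions sum to zero; cannot normalize", call. = FALSE)
    p <- p / s
  } else if (abs(s - 1) > tolerance) {
    stop(sprintf(
      "strata proportions sum to %.6f (residual %+.6f); supply the residual 'general' stratum or use normalize = TRUE",
      s, 1 - s
    ), call. = FALSE)
  }
  strata$proportion <- p
  strata <- arrange_strata(strata)

  inc <- income_distribution
  if (is.list(inc)) inc <- unlist(inc)  # e.g. parsed from a JSON object
  if (!is.null(inc)) {
    if (is.null(names(inc)) || any(!nzchar(names(inc)))) {
      stop("income_distribution must be a named vector (ascending band order)",
           call. = FALSE)
    }
    if (sum(inc) > 2) inc <- inc / 100
    if (abs(sum(inc) - 1) > 1e-4) {
      stop(sprintf("income_distribution sums to %.4f, not 1", sum(inc)), call. = FALSE)
    }
  }
  scalar_prop <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (x > 1) x <- x / 100
    if (x < 0 || x > 1) stop(what, " must lie in [0, 1]", call. = FALSE)
    x
  }

  structure(
    list(
      strata = strata,
      population_size = population_size,
      income_distribution = inc,
      language_at_home = scalar_prop(language_at_home, "language_at_home"),
      education_year10 = scalar_prop(education_year10, "education_year10")
    ),
    class = "census_profile"
  )
}

#' @export
print.census_profile <- function(x, ...) {
  cat("<census_profile> ", nrow(x$strata), " strata",
      if (!is.null(x$population_size)) paste0("; eligible population ", x$population_size),
      "\n", sep = "")
  cells <- dplyr::count(x$strata, .data$gender, .data$age_band,
                        wt = .data$proportion, name = "proportion")
  print(as_tibble(cells), n = 8)
  marg <- c(
    income = !is.null(x$income_distribution),
    language_at_home = !is.null(x$language_at_home),
    education_year10 = !is.null(x$education_year10)
  )
  cat("marginals present:", paste(names(marg)[marg], collapse = ", "), "\n")
  invisible(x)
}

#' Load a census profile from disk
#'
#' Reads the strata table from a CSV file with columns
#' `gender, age_band, ses, proportion` (UTF-8; en-dash or hyphen in band
#' labels) and, optionally, marginal distributions from a JSON sidecar with
#' any of the fields `population_size`, `income_distribution` (object,
#' ascending band order), `language_at_home`, `education_year10`.
#'
#' @param path Path to the strata CSV.
#' @param marginals Optional path to the JSON sidecar.
#' @param normalize,tolerance Passed to [census_profile()].
#' @return A `census_profile`.
#' @export
load_census_profile <- function(path, marginals = NULL, normalize = FALSE,
                                tolerance = 1e-6) {
  if (!file.exists(path)) stop("census profile file not found: ", path, call. = FALSE)
  strata <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- list()
  if (!is.null(marginals)) {
    if (!file.exists(marginals)) stop("marginals file not found: ", marginals, call. = FALSE)
    m <- jsonlite::read_json(marginals, simplifyVector = TRUE)
  }
  census_profile(
    strata,
    population_size = m$population_size,
    income_distribution = m$income_distribution,
    language_at_home = m$language_at_home,
    education_year10 = m$education_year10,
    normalize = normalize, tolerance = tolerance
  )
}

#' Diagnostic report on a census profile
#'
#' Report-only validation: lists deviations of the strata proportions from
#' 1, zero-proportion strata, and absent marginals.  Never mutates or
#' errors; an empty result means no findings.
#'
#' @param profile A `census_profile`, or anything list-like with a `strata`
#'   element (so partially built profiles can be checked too).
#' @return A tibble with columns `check`, `level` (`info`/`warning`) and
#'   `message`; zero rows when the profile is clean.
#' @export
validate_profile <- function(profile) {
  findings <- tibble(check = character(), level = character(), message = character())
  add <- function(check, level, message) {
    dplyr::bind_rows(findings, tibble(check = check, level = level, message = message))
  }
  strata <- profile$strata
  if (is.null(strata) || nrow(strata) == 0) {
    return(add("strata", "warning", "no strata"))
  }
  dev <- sum(strata$proportion) - 1
  if (abs(dev) > 1e-6) {
    findings <- add("strata_sum", "warning",
                    sprintf("strata proportions sum to %.6f (deviation %+.2e)", 1 + dev, dev))
  }
  zero <- strata[strata$proportion == 0, ]
  if (nrow(zero) > 0) {
    findings <- add("zero_proportion", "info",
                    paste("zero-proportion strata:",
                          paste(stratum_key(zero$gender, zero$age_band, zero$ses), collapse = ", ")))
  }
  if (is.null(profile$income_distribution)) {
    findings <- add("income", "info", "income marginal absent")
  }
  if (is.null(profile$language_at_home)) {
    findings <- add("language", "info", "language-at-home marginal absent")
  }
  if (is.null(profile$education_year10)) {
    findings <- add("education", "info", "education marginal absent")
  }
  if (is.null(profile$population_size)) {
    findings <- add("population", "info", "population size absent")
  }
  findings
}

#' Compute integer strata recruitment targets
#'
#' Multiplies the chosen sample size by each stratum's census proportion and
#' rounds the resulting real-valued quotas to integers.  The default
#' largest-remainder (Hamilton) method conserves the total exactly:
#' `sum(targets) == n_target`, and every integer target differs from its
#' raw quota by less than 1.  Remainder ties are broken deterministically by
#' stratum sort order (gender, then age band, then SES).
#'
#' @param profile A `census_profile`.
#' @param n_target Total sample size (persons), >= 1.
#' @param rounding `"largest_remainder"` (default, conserves the total) or
#'   `"round_half_even"` (base `round()`; the total may then drift and a
#'   warning is issued if it does).
#' @return An object of class `strata_targets`: a list with `targets` (a
#'   tibble with `gender`, `age_band`, `ses`, `proportion`, `raw`,
#'   `target`), `n_target` and `rounding`.
#' @export
#' @examples
#' prof <- census_profile(data.frame(
#'   gender = c("female", "male"), age_band = "25-44",
#'   ses = "general", proportion = c(0.5, 0.5)
#' ))
#' compute_strata_targets(prof, 100)
compute_strata_targets <- function(profile, n_target,
                                   rounding = c("largest_remainder", "round_half_even")) {
  stopifnot(inherits(profile, "census_profile"))
  rounding <- match.arg(rounding)
  if (!is.numeric(n_target) || length(n_target) != 1 || n_target < 1) {
    stop("n_target must be a single number >= 1", call. = FALSE)
  }
  n_target <- as.integer(round(n_target))
  tab <- arrange_strata(profile$strata)
  tab$raw <- n_target * tab$proportion
  tab$target <- switch(rounding,
    largest_remainder = largest_remainder(tab$raw, total = n_target),
    round_half_even = as.integer(round(tab$raw))
  )
  if (rounding == "round_half_even" && sum(tab$target) != n_target) {
    warning(sprintf("round-half-even targets sum to %d, not n_target = %d",
                    sum(tab$target), n_target), call. = FALSE)
  }
  n_zero <- sum(tab$proportion > 0 & tab$target == 0)
  if (n_zero > 0) {
    warning(n_zero, " stratum/strata with nonzero proportion received a zero target",
            call. = FALSE)
  }
  structure(
    list(targets = tab, n_target = n_target, rounding = rounding),
    class = "strata_targets"
  )
}

#' @export
print.strata_targets <- function(x, ...) {
  cat("<strata_targets> n_target =", x$n_target, "(", x$rounding, ")\n")
  print(x$targets, n = 16)
  invisible(x)
}

#' Reference census profile of an urban Indigenous community
#'
#' The gender-by-age-band composition (2016 Australian Census of Population
#' and Housing) of the urban South Australian Indigenous community that
#' motivates this package, shipped as the package's worked-example frame.
#' The eight gender x age cells carry the full census mass under the
#' residual `general` SES category; use `expand_ses = TRUE` to split each
#' cell across the socioeconomic categories with [default_ses_split()]
#' (a synthetic split: the census publishes no per-cell SES breakdown).
#' The income-band marginal is likewise synthetic, chosen so the median
#' weekly income falls in the $400-599 band, consistent with the published
#' census median of $420.
#'
#' @param expand_ses Split each gender x age cell across SES categories.
#' @param ses_split Split table used when `expand_ses = TRUE`; see
#'   [default_ses_split()].
#' @return A `census_profile`.
#' @export
reference_census_profile <- function(expand_ses = FALSE, ses_split = default_ses_split()) {
  path <- system.file("extdata", "census_profile.csv", package = "stratquota")
  marg <- system.file("extdata", "census_marginals.json", package = "stratquota")
  prof <- load_census_profile(path, marginals = marg)
  if (expand_ses) prof <- expand_ses(prof, ses_split)
  prof
}

#' Default socioeconomic split within gender-by-age cells
#'
#' Shares of each age band's population falling in the four named SES
#' strata, with the remainder in the residual `general` category.  These
#' are the package's fixed synthetic defaults (censuses rarely publish this
#' cross-tabulation): students concentrate in 16-24, full-time work peaks
#' in the middle bands, and almost all of the 65+ band is residual.
#'
#' @return Tibble with columns `age_band`, `ses`, `share`; shares sum to 1
#'   within each age band.
#' @export
default_ses_split <- function() {
  tab <- tibble(
    age_band = rep(age_band_levels, each = 5),
    ses = rep(ses_levels, times = 4),
    share = c(
      0.10, 0.35, 0.15, 0.05, 0.35, # 16-24
      0.30, 0.08, 0.15, 0.05, 0.42, # 25-44
      0.30, 0.03, 0.12, 0.05, 0.50, # 45-64
      0.05, 0.01, 0.05, 0.04, 0.85  # 65+
    )
  )
  tab$age_band <- normalize_age_band(tab$age_band)
  tab$ses <- check_levels(tab$ses, ses_levels, "SES")
  tab
}

#' Expand a gender-by-age profile across SES categories
#'
#' Distributes each (gender, age band) cell's census mass across SES strata
#' according to a split table, producing the full three-way sampling frame.
#' The input profile must carry each cell's mass in a single stratum row
#' (conventionally `ses = "general"`).
#'
#' @param profile A `census_profile` with one row per gender x age cell.
#' @param split Tibble with columns `age_band`, `ses`, `share` (shares
#'   summing to 1 per age band), as from [default_ses_split()].
#' @return A `census_profile` over the expanded frame; marginals carried over.
#' @export
expand_ses <- function(profile, split = default_ses_split()) {
  stopifnot(inherits(profile, "census_profile"))
  split <- as_tibble(split)
  split$age_band <- normalize_age_band(split$age_band)
  split$ses <- check_levels(split$ses, ses_levels, "SES")
  chk <- tapply(split$share, split$age_band, sum)
  if (any(abs(chk - 1) > 1e-8)) {
    stop("SES split shares must sum to 1 within each age band", call. = FALSE)
  }
  cells <- dplyr::count(profile$strata, .data$gender, .data$age_band,
                        wt = .data$proportion, name = "cell_mass")
  out <- dplyr::inner_join(cells, split, by = "age_band",
                           relationship = "many-to-many")
  out$proportion <- out$cell_mass * out$share
  census_profile(
    out[, c("gender", "age_band", "ses", "proportion")],
    population_size = profile$population_size,
    income_distribution = profile$income_distribution,
    language_at_home = profile$language_at_home,
    education_year10 = profile$education_year10
  )
}

#' Write a census profile to disk
#'
#' Inverse of [load_census_profile()]: writes the strata CSV and, when any
#' marginal is present, the JSON sidecar.
#'
#' @param profile A `census_profile`.
#' @param path Output CSV path.
#' @param marginals Optional output path for the JSON sidecar.
#' @return Invisibly, the paths written.
#' @export
write_census_profile <- function(profile, path, marginals = NULL) {
  stopifnot(inherits(profile, "census_profile"))
  readr::write_csv(profile$strata, path, progress = FALSE)
  written <- path
  if (!is.null(marginals)) {
    m <- list(
      population_size = profile$population_size,
      income_distribution = as.list(profile$income_distribution),
      language_at_home = profile$language_at_home,
      education_year10 = profile$education_year10
    )
    m <- m[!vapply(m, is.null, logical(1))]
    jsonlite::write_json(m, marginals, auto_unbox = TRUE, digits = NA)
    written <- c(written, marginals)
  }
  invisible(written)
}
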