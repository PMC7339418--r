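# Closed vocabularies for the sampling frame and survey records.
age_band_levels <- c("16-24", "25-44", "45-64", "65+")
gender_levels <- c("female", "male")
ses_levels <- c("full_time_worker", "student", "unemployed", "homeless", "general")
named_ses_levels <- c("full_time_worker", "student", "unemployed", "homeless")
incomplete_reason_levels <- c("left_time", "technical", "discomfort", "other")
residence_levels <- c("town_city", "indigenous_community", "parkland_scrub", "other")
channel_levels <- c("email", "phone", "text", "meeting", "facebook")
site_type_levels <- c(
  "indigenous_health_service", "community_group", "indigenous_adult_education",
  "unemployment_service", "public_housing_service", "homelessness_service",
  "mental_health_service", "aod_service", "childcare", "hobby_group",
  "cultural_group", "public_event", "public_space"
)

# Age-band labels arrive with en-dashes or hyphens; store hyphenated.
normalize_age_band <- function(x) {
  x <- gsub("–", "-", trimws(as.character(x)))
  bad <- setdiff(unique(x[!is.na(x)]), age_band_levels)
  if (length(bad) > 0) {
    stop("unknown age band label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = age_band_levels)
}

check_levels <- function(x, levels, what) {
  x <- trimws(as.character(x))
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = levels)
}

# Bands are closed on the left: a 25th birthday moves you into 25-44.
bin_age <- function(age) {
  cut(age, breaks = c(16, 25, 45, 65, Inf), right = FALSE, labels = age_band_levels)
}

stratum_key <- function(gender, age_band, ses) {
  paste(gender, age_band, ses, sep = "/")
}

# Canonical stratum sort order (gender, then age band, then SES); used for
# deterministic iteration and remainder tie-breaking.
arrange_strata <- function(df) {
  dplyr::arrange(
    df,
    factor(.data$gender, levels = gender_levels),
    factor(.data$age_band, levels = age_band_levels),
    factor(.data$ses, levels = ses_levels)
  )
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed
#'
#' Deterministically derives a fresh RNG seed from a base seed and an index
#' (for example a field-day number), so that repeated daily rebalancing runs
#' are reproducible from a single study seed.  The result always fits a
#' 32-bit integer.
#'
#' @param seed Base integer seed.
#' @param index Non-negative integer index (e.g. day number).
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index), length(index) == 1)
  s <- ((abs(as.numeric(seed)) %% 2147483646) * 69069 + (abs(as.numeric(index)) %% 104729) * 2654435761 + 1) %% 2147483647
  as.integer(s)
}

#' Largest-remainder (Hamilton) apportionment
#'
#' Rounds a vector of non-negative real quotas to integers that sum exactly
#' to `total`: each quota is floored, then the leftover units are given to
#' the entries with the largest fractional remainders.  Ties between equal
#' remainders are broken by position (first entry wins), so results are
#' deterministic for a fixed input order.
#'
#' @param raw Non-negative numeric vector of real-valued quotas.
#' @param total Integer total to conserve; defaults to `round(sum(raw))`.
#' @return An integer vector of the same length as `raw` summing to `total`,
#'   with `abs(result - raw) < 1` elementwise.
#' @export
#' @examples
#' largest_remainder(c(85.68, 144.69, 102.55, 29.68), total = 363)
largest_remainder <- function(raw, total = round(sum(raw))) {
  stopifnot(all(raw >= 0), is.finite(total), total >= 0)
  fl <- floor(raw)
  k <- as.integer(round(total)) - as.integer(sum(fl))
  if (k < 0) {
    stop("total is smaller than the sum of floors; quotas cannot be apportioned",
         call. = FALSE)
  }
  if (k > length(raw)) {
    stop("total exceeds sum(raw) by more than one unit per entry", call. = FALSE)
  }
  if (k > 0) {
    rem <- raw - fl
    topup <- order(rem, decreasing = TRUE)[seq_len(k)]  # order() is stable: ties by position
    fl[topup] <- fl[topup] + 1
  }
  as.integer(fl)
}

round1 <- function(x) round(x, 1)
round2 <- function(x) round(x, 2)
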