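# Printed gender-by-age composition table of the worked example:
# per-cell sample counts (total 706) and census percentages.
table3_counts <- function() {
  tibble::tibble(
    gender = rep(c("female", "male"), each = 4),
    age_band = rep(c("16-24", "25-44", "45-64", "65+"), 2),
    n = c(89L, 145L, 103L, 35L, 99L, 131L, 88L, 16L)
  )
}

table3_census_pct <- function() {
  c(12.24, 20.67, 14.65, 4.24, 14.87, 18.73, 12.35, 2.25)
}

table3_profile <- function() {
  census_profile(data.frame(
    gender = rep(c("female", "male"), each = 4),
    age_band = rep(c("16-24", "25-44", "45-64", "65+"), 2),
    ses = "general",
    proportion = table3_census_pct()
  ))
}

# Independent largest-remainder oracle: floor everything, then repeatedly
# give one unit to the not-yet-topped entry with the biggest remainder.
oracle_largest_remainder <- function(raw, total = round(sum(raw))) {
  out <- floor(raw)
  topped <- rep(FALSE, length(raw))
  while (sum(out) < total) {
    rem <- raw - floor(raw)
    rem[topped] <- -Inf
    i <- which.max(rem)  # first max wins, like order() with stable ties
    out[i] <- out[i] + 1
    topped[i] <- TRUE
  }
  as.integer(out)
}

# Exhaustive-enumeration oracle for the mean per-site allocation when `k`
# units are drawn uniformly without replacement from site-labelled units.
oracle_hypergeo_mean <- function(avail, k) {
  units <- rep(seq_along(avail), times = avail)
  combos <- utils::combn(length(units), k)
  counts <- sapply(seq_len(ncol(combos)), function(j) {
    tabulate(units[combos[, j]], nbins = length(avail))
  })
  rowMeans(matrix(counts, nrow = length(avail)))
}

# Minimal two-site registry covering one unemployed stratum plus a general
# public space.
small_registry <- function(avail_a = 30L, avail_b = 10L, capacity = 50) {
  site_registry(
    tibble::tibble(
      site_id = c("A", "B", "G"),
      name = c("Service A", "Service B", "Mall"),
      type = c("unemployment_service", "unemployment_service", "public_space"),
      is_general = c(FALSE, FALSE, TRUE),
      capacity = c(NA, NA, capacity),
      eligible_ses = list("unemployed", "unemployed", "all")
    ),
    tibble::tibble(
      site_id = c("A", "B"),
      gender = "male", age_band = "16-24", ses = "unemployed",
      count = c(avail_a, avail_b)
    )
  )
}

one_stratum_targets <- function(target, ses = "unemployed") {
  tibble::tibble(gender = "male", age_band = "16-24", ses = ses,
                 target = as.integer(target))
}

# Survey-record rows with sensible defaults, for terse test fixtures.
make_records <- function(n, status = "complete", gender = "female",
                         age = 30, ses = "general", date = as.Date("2019-08-01"),
                         site_id = "S01", duration = 15,
                         incomplete_reason = NA_character_, ...) {
  tibble::tibble(
    record_id = sprintf("R%05d", seq_len(n)),
    date = date, site_id = site_id, gender = gender, age = age, ses = ses,
    status = status, incomplete_reason = incomplete_reason,
    duration = duration, residence = "town_city",
    income_band = "400-599", language_at_home = FALSE, education_year10 = TRUE,
    ...
  )
}

# Records whose gender x age cells reproduce the printed composition table,
# with ids unique across the whole set.
table3_records <- function() {
  cells <- table3_counts()
  recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    age <- c(`16-24` = 20, `25-44` = 30, `45-64` = 50, `65+` = 70)[[cells$age_band[i]]]
    make_records(cells$n[i], gender = cells$gender[i], age = age)
  }))
  recs$record_id <- sprintf("R%05d", seq_len(nrow(recs)))
  recs
}
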