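test_that("strata percentages recompute from counts", {
  sp <- strata_percentages(table3_counts())
  expect_equal(round(sp$pct[sp$gender == "female" & sp$age_band == "16-24"], 2), 12.61)
  expect_equal(round(sp$pct[sp$gender == "female" & sp$age_band == "25-44"], 2), 20.54)
  expect_equal(sum(sp$pct), 100, tolerance = 1e-12)

  # record-level entry point agrees with the counts entry point
  sp2 <- strata_percentages(table3_records())
  expect_equal(dplyr::arrange(sp2, gender, age_band)$pct,
               dplyr::arrange(sp, gender, age_band)$pct)

  all_one <- strata_percentages(make_records(12, gender = "male", age = 70))
  expect_equal(all_one$pct, 100)
  expect_error(strata_percentages(make_records(3, status = "incomplete",
                                               incomplete_reason = "other")),
               "no complete records")
})

test_that("census comparison computes signed diffs unrounded-first", {
  rep <- compare_to_census(table3_counts(), table3_profile())
  rows <- rep$rows
  f1624 <- rows[rows$gender == "female" & rows$age_band == "16-24", ]
  expect_equal(f1624$sample_pct, 12.61)
  expect_equal(f1624$diff_pct, 0.37)
  m1624 <- rows[rows$gender == "male" & rows$age_band == "16-24", ]
  expect_equal(m1624$sample_pct, 14.02)
  expect_equal(m1624$diff_pct, -0.85)
  # diff is computed before rounding: round(a) - round(b) would give -0.86 here
  expect_equal(round(14.02266 - 14.87, 2), -0.85)

  expect_equal(sum(rows$sample_pct), 100.01)
  expect_true(sum(rows$sample_pct) >= 99.9 && sum(rows$sample_pct) <= 100.1)
  expect_equal(rep$overall$max_abs_diff, abs(100 * 99 / 706 - 14.87),
               tolerance = 1e-9)

  # sample cells missing from the census are flagged, diff retained as NA-safe
  prof_small <- census_profile(data.frame(gender = "female", age_band = "16-24",
                                          ses = "general", proportion = 1))
  cnt <- data.frame(gender = c("female", "male"), age_band = "16-24",
                    n = c(5L, 5L))
  expect_warning(r2 <- compare_to_census(cnt, prof_small), "absent from the census")
  expect_true(r2$rows$flagged[r2$rows$gender == "male"])
})

test_that("a sample drawn exactly proportional to census drives diffs to zero", {
  prof <- table3_profile()
  n <- 70600L
  counts <- dplyr::mutate(prof$strata,
                          n = round(n * proportion))[, c("gender", "age_band", "n")]
  rep <- compare_to_census(counts, prof)
  expect_lt(rep$overall$max_abs_diff, 100 * 0.5 / n + 1e-6)
})

test_that("categorical marginals reproduce uniquely invertible printed percentages", {
  prof <- reference_census_profile()
  recs <- make_records(706)
  recs$language_at_home <- c(rep(TRUE, 45), rep(FALSE, 661))
  recs$education_year10 <- c(rep(TRUE, 531), rep(FALSE, 175))
  lang <- categorical_comparison(recs, prof, "language_at_home")
  expect_equal(lang$sample_pct, 6.37)
  expect_equal(lang$census_pct, 6.70)
  edu <- categorical_comparison(recs, prof, "education_year10")
  expect_equal(edu$sample_pct, 75.21)
  expect_equal(edu$census_pct, 80.27)

  none <- make_records(10)
  none$language_at_home <- FALSE
  expect_equal(categorical_comparison(none, prof, "language_at_home")$sample_pct, 0)
  none$language_at_home <- NA
  expect_error(categorical_comparison(none, prof, "language_at_home"),
               "entirely missing")
})

test_that("median income band follows the lower-median convention", {
  bands <- c("A", "B", "C")
  recs <- make_records(9, gender = rep(c("female", "male"), length.out = 9))
  recs$income_band <- rep(bands, c(2, 5, 2))
  expect_equal(median_income_band(recs, bands)$median_band[1], "B")

  even <- make_records(6, gender = rep(c("female", "male"), 3))
  even$income_band <- rep(c("A", "B"), each = 3)
  expect_equal(median_income_band(even, c("A", "B"))$median_band[1], "A")

  # recovers the generated distribution's median band per gender
  spec <- community_spec(population_size = 4000, seed = 21)
  pop <- gen_population(spec)
  recs2 <- make_records(nrow(pop))
  recs2$gender <- pop$gender
  recs2$income_band <- pop$income_band
  band_order <- names(spec$census$income_distribution)
  got <- median_income_band(recs2, band_order)
  brute <- function(x) {
    counts <- table(factor(x, levels = band_order))
    band_order[which(cumsum(counts) >= floor((length(x) + 1) / 2))[1]]
  }
  expect_equal(got$median_band[got$group == "overall"], brute(pop$income_band))
  expect_equal(got$median_band[got$group == "female"],
               brute(pop$income_band[pop$gender == "female"]))
  # cumulative census distribution crosses 50% in the 400-599 band
  expect_equal(got$median_band[got$group == "overall"], "400-599")

  # income present only for women: exactly the male group warns
  missing <- make_records(4, gender = rep(c("female", "male"), 2))
  missing$income_band <- ifelse(missing$gender == "female", "A", NA_character_)
  expect_warning(out <- median_income_band(missing, bands),
                 "no income data for group 'male'")
  expect_true(is.na(out$median_band[out$group == "male"]))
  expect_equal(out$median_band[out$group == "overall"], "A")
})

test_that("pyramid data negates the female side and mirrors symmetric samples", {
  rep <- compare_to_census(table3_counts(), table3_profile())
  pyr <- pyramid_data(rep)
  expect_equal(nrow(pyr), 8)
  expect_true(all(pyr$sample_signed[pyr$gender == "female"] < 0))
  expect_true(all(pyr$sample_signed[pyr$gender == "male"] > 0))
  expect_equal(abs(pyr$sample_signed), pyr$sample_pct)

  # symmetric sample: mirror image
  sym <- data.frame(gender = rep(c("female", "male"), each = 4),
                    age_band = rep(c("16-24", "25-44", "45-64", "65+"), 2),
                    n = rep(c(10L, 20L, 15L, 5L), 2))
  prof_sym <- census_profile(data.frame(
    gender = rep(c("female", "male"), each = 4),
    age_band = rep(c("16-24", "25-44", "45-64", "65+"), 2),
    ses = "general", proportion = rep(c(0.1, 0.2, 0.15, 0.05), 2)
  ))
  psym <- pyramid_data(compare_to_census(sym, prof_sym))
  f <- psym[psym$gender == "female", ]
  m <- psym[psym$gender == "male", ]
  expect_equal(f$sample_signed, -m$sample_signed)

  # report CSV export round-trips
  csv <- withr::local_tempfile(fileext = ".csv")
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_repr_report(rep, csv, pcsv)
  expect_equal(nrow(readr::read_csv(pcsv, show_col_types = FALSE)), 8)
})
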