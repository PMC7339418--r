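test_that("ingest validates rows, rejects under-16s, and errors on duplicate ids", {
  recs <- make_records(5)
  recs$age[2] <- 15
  recs$status[3] <- "incomplete"
  recs$incomplete_reason[3] <- "left_time"
  tmp <- withr::local_tempfile(fileext = ".csv")
  rej <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(recs, tmp)
  expect_message(kept <- ingest_records(tmp, rejects_path = rej), "rejected")
  expect_equal(nrow(kept), 4)
  rejects <- attr(kept, "rejects")
  expect_equal(rejects$reason, "eligibility")
  expect_equal(readr::read_csv(rej, show_col_types = FALSE)$reason, "eligibility")

  dup <- make_records(2)
  dup$record_id <- c("R1", "R1")
  expect_error(validate_records(dup), "duplicate record id")

  # reason present iff incomplete
  bad <- make_records(2)
  bad$incomplete_reason[1] <- "technical"
  bad$status[2] <- "incomplete"
  expect_message(kept2 <- validate_records(bad), "rejected")
  expect_setequal(attr(kept2, "rejects")$reason,
                  c("reason_on_complete", "missing_incomplete_reason"))
})

test_that("completion summary conserves counts", {
  # the worked example: 730 commenced, reasons 12/4/8, final 706
  recs <- make_records(730)
  inc_idx <- 1:24
  recs$status[inc_idx] <- "incomplete"
  recs$incomplete_reason[inc_idx] <- rep(c("left_time", "technical", "discomfort"),
                                         times = c(12, 4, 8))
  cs <- completion_summary(validate_records(recs))
  expect_equal(cs$commenced, 730)
  expect_equal(cs$incomplete_by_reason,
               c(left_time = 12L, technical = 4L, discomfort = 8L))
  expect_equal(cs$final_n, 706)

  # all complete and empty edge cases
  expect_equal(completion_summary(make_records(10))$final_n, 10)
  expect_length(completion_summary(make_records(10))$incomplete_by_reason, 0)
  zero <- completion_summary(make_records(1)[0, ])
  expect_equal(zero$commenced, 0)
  expect_equal(zero$final_n, 0)

  # property: conservation on random record sets
  set.seed(77)
  for (i in 1:25) {
    n <- sample(1:120, 1)
    r <- make_records(n)
    inc <- runif(n) < 0.3
    r$status[inc] <- "incomplete"
    r$incomplete_reason[inc] <- sample(c("left_time", "technical", "discomfort", "other"),
                                       sum(inc), replace = TRUE)
    cs <- completion_summary(validate_records(r))
    expect_equal(cs$final_n, cs$commenced - sum(cs$incomplete_by_reason))
    expect_equal(cs$commenced, n)
  }
})

test_that("progress reports count completes up to the review date per stratum", {
  prof <- census_profile(data.frame(gender = "female", age_band = "16-24",
                                    ses = "general", proportion = 1))
  tg <- compute_strata_targets(prof, 86)
  recs <- make_records(89, gender = "female", age = 20)
  pr <- progress_report(recs, tg)
  expect_equal(pr$recruited, 89L)
  expect_equal(pr$remaining, 0L)
  expect_true(pr$over_flag)

  # date cut and incomplete exclusion
  recs2 <- make_records(10, gender = "female", age = 20,
                        date = as.Date("2019-08-01") + 0:9)
  recs2$status[10] <- "incomplete"
  recs2$incomplete_reason[10] <- "other"
  pr2 <- progress_report(recs2, tg, as_of = as.Date("2019-08-05"))
  expect_equal(pr2$recruited, 5L)
  expect_equal(sum(pr2$recruited), sum(recs2$status == "complete" &
                                         recs2$date <= as.Date("2019-08-05")))

  # empty records and exact-at-target
  expect_equal(progress_report(recs2[0, ], tg)$recruited, 0L)
  tg1 <- compute_strata_targets(prof, 1)
  pr3 <- progress_report(make_records(1, gender = "female", age = 20), tg1)
  expect_equal(attr(pr3, "overall_fraction"), 1)

  # out-of-frame records land in the catch-all, flagged
  stray <- make_records(3, gender = "male", age = 50)
  expect_warning(pr4 <- progress_report(rbind(recs2, stray), tg), "catch-all")
  expect_equal(attr(pr4, "catch_all"), 3L)
})

test_that("age band binning is closed on the left", {
  expect_equal(as.character(bin_age(c(16, 24, 25, 44, 45, 64, 65, 90))),
               c("16-24", "16-24", "25-44", "25-44", "45-64", "45-64", "65+", "65+"))
})

test_that("duration statistics use the sample standard deviation", {
  recs <- make_records(2, duration = c(10, 20))
  ds <- duration_stats(recs)
  expect_equal(round(ds$mean, 2), 15.00)
  expect_equal(round(ds$sd, 2), 7.07)
  expect_equal(ds$sd, sqrt(50), tolerance = 1e-12)
  expect_equal(c(ds$min, ds$max), c(10, 20))

  one <- duration_stats(make_records(1, duration = 12.5))
  expect_true(is.na(one$sd))
  expect_equal(c(one$mean, one$min, one$max), c(12.5, 12.5, 12.5))

  expect_equal(duration_stats(make_records(5, duration = 9))$sd, 0)
  expect_warning(none <- duration_stats(make_records(2, duration = NA_real_)),
                 "no durations")
  expect_equal(none$n, 0)
})

test_that("recruitment-source and residence breakdowns tally to printed percentages", {
  # recruitment-source composition of the worked example (total 706)
  groups <- c("Public space", "Indigenous health service", "Community groups",
              "Indigenous community colleges", "Unemployment and housing services",
              "Homelessness services", "Mental health and AOD services",
              "Childcare services", "Cultural groups")
  counts <- c(440, 68, 51, 43, 34, 34, 25, 7, 4)
  tab <- category_summary(rep(groups, counts))
  expect_equal(tab$n[tab$category == "Public space"], 440L)
  expect_equal(tab$pct[tab$category == "Public space"], 62.3)
  expect_equal(tab$pct[tab$category == "Indigenous health service"], 9.6)
  expect_equal(sum(tab$n), 706)

  # residence composition (total 706)
  res <- category_summary(rep(c("town_city", "indigenous_community",
                                "parkland_scrub", "other"),
                              c(629, 40, 10, 27)),
                          levels = c("town_city", "indigenous_community",
                                     "parkland_scrub", "other"))
  expect_equal(res$pct, c(89.1, 5.7, 1.4, 3.8))

  # the record-level wrappers agree with the raw tally
  reg <- small_registry()
  recs <- make_records(10, site_id = "A", ses = "unemployed", gender = "male",
                       age = 20)
  sc <- site_category_summary(recs, reg)
  expect_equal(sc$category, "Unemployment and housing services")
  expect_equal(sc$pct, 100)
  rs <- residence_summary(recs)
  expect_equal(rs$n[rs$category == "town_city"], 10L)
})

test_that("possible-duplicate screening is a labelled heuristic over demographics", {
  recs <- make_records(4, gender = "male", age = 30)
  recs$age[4] <- 31
  dup <- possible_duplicates(recs)
  expect_equal(nrow(dup), 1)
  expect_equal(dup$n_records, 3L)
})
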