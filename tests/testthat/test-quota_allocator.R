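test_that("the potential table pools positive client counts and general capacity", {
  reg <- small_registry()
  tab <- build_potential_table(reg)
  svc <- tab[tab$ses == "unemployed", ]
  expect_equal(sort(svc$available), c(10L, 30L))
  tot <- total_by_stratum(tab)
  expect_equal(tot$total[tot$gender == "male" & tot$age_band == "16-24" &
                           tot$ses == "unemployed"], 40L)
  # general site contributes capacity rows only for residual strata
  expect_true(all(tab$ses[tab$site_id == "G"] == "general"))
  expect_equal(unique(tab$available[tab$site_id == "G"]), 50L)

  # all-zero counts contribute no rows
  reg0 <- site_registry(
    tibble::tibble(site_id = "A", name = "a", type = "childcare",
                   is_general = FALSE, capacity = NA,
                   eligible_ses = list("unemployed")),
    tibble::tibble(site_id = "A", gender = "male", age_band = "16-24",
                   ses = "unemployed", count = 0L)
  )
  expect_equal(nrow(build_potential_table(reg0)), 0)
})

test_that("single-site and shortfall allocations are forced by conservation", {
  reg <- small_registry(avail_a = 30L, avail_b = 0L)
  tab <- build_potential_table(reg)
  elig <- eligibility_matrix(reg)
  plan <- allocate(one_stratum_targets(10), tab, elig, seed = 1,
                   general_fallback = FALSE)
  expect_equal(sum(plan$quotas$quota[plan$quotas$site_id == "A"]), 10L)
  expect_equal(sum(plan$unmet$shortfall), 0L)

  # target 12 against availability 9, no fallback: 9 allocated, 3 unmet
  reg2 <- small_registry(avail_a = 5L, avail_b = 4L)
  expect_warning(
    plan2 <- allocate(one_stratum_targets(12), build_potential_table(reg2),
                      eligibility_matrix(reg2), seed = 2,
                      general_fallback = FALSE),
    "3 unmet"
  )
  expect_equal(sum(plan2$quotas$quota), 9L)
  expect_equal(sum(plan2$unmet$shortfall), 3L)

  # with fallback the shortfall spills to the general site
  plan3 <- allocate(one_stratum_targets(12), build_potential_table(reg2),
                    eligibility_matrix(reg2), seed = 2, general_fallback = TRUE)
  expect_equal(sum(plan3$quotas$quota), 12L)
  expect_equal(sum(plan3$quotas$quota[plan3$quotas$site_id == "G"]), 3L)
  expect_equal(sum(plan3$unmet$shortfall), 0L)

  # no eligible site and no fallback: fully unmet, loudly
  reg3 <- site_registry(
    tibble::tibble(site_id = "CC", name = "c", type = "childcare",
                   is_general = FALSE, capacity = NA,
                   eligible_ses = list("full_time_worker"))
  )
  expect_warning(
    plan4 <- allocate(one_stratum_targets(5, ses = "homeless"),
                      build_potential_table(reg3), eligibility_matrix(reg3),
                      seed = 3, general_fallback = FALSE),
    "5 unmet"
  )
  expect_equal(sum(plan4$unmet$shortfall), 5L)
})

test_that("same seed gives byte-identical plans; different seeds differ", {
  reg <- small_registry()
  tab <- build_potential_table(reg)
  elig <- eligibility_matrix(reg)
  tgt <- one_stratum_targets(10)
  p1 <- allocate(tgt, tab, elig, seed = 42)
  p2 <- allocate(tgt, tab, elig, seed = 42)
  expect_identical(p1$quotas, p2$quotas)
  expect_identical(p1$log, p2$log)
  seeds <- vapply(1:30, function(s) {
    sum(allocate(tgt, tab, elig, seed = s)$quotas$quota *
          (allocate(tgt, tab, elig, seed = s)$quotas$site_id == "A"))
  }, numeric(1))
  expect_gt(length(unique(seeds)), 1)
})

test_that("conservation, eligibility and without-replacement hold across seeded runs", {
  set.seed(314)
  for (run in 1:60) {
    avail_a <- sample(0:20, 1)
    avail_b <- sample(0:20, 1)
    cap <- sample(5:30, 1)
    reg <- small_registry(avail_a, avail_b, capacity = cap)
    tab <- build_potential_table(reg)
    elig <- eligibility_matrix(reg)
    target <- sample(0:40, 1)
    fallback <- sample(c(TRUE, FALSE), 1)
    plan <- suppressWarnings(
      allocate(one_stratum_targets(target), tab, elig, seed = run,
               general_fallback = fallback)
    )
    # conservation
    expect_equal(sum(plan$quotas$quota) + sum(plan$unmet$shortfall), target)
    # without replacement: quota bounded by availability / capacity
    qa <- sum(plan$quotas$quota[plan$quotas$site_id == "A"])
    qb <- sum(plan$quotas$quota[plan$quotas$site_id == "B"])
    qg <- sum(plan$quotas$quota[plan$quotas$site_id == "G"])
    expect_lte(qa, avail_a)
    expect_lte(qb, avail_b)
    expect_lte(qg, if (fallback) cap else 0L)
    # eligibility: no quota lands outside the eligibility matrix
    elig_key <- paste(elig$gender, elig$age_band, elig$ses)
    for (i in seq_len(nrow(plan$quotas))) {
      q <- plan$quotas[i, ]
      hit <- match(paste(q$gender, q$age_band, q$ses), elig_key)
      expect_true(q$site_id %in% elig$sites[[hit]])
    }
  }
})

test_that("per-site allocation means match the exhaustive hypergeometric oracle", {
  # <= 8-unit instance: sites with 5 and 3 units, draw 4
  expected <- oracle_hypergeo_mean(c(5L, 3L), 4L)
  reg <- small_registry(avail_a = 5L, avail_b = 3L)
  tab <- build_potential_table(reg)
  elig <- eligibility_matrix(reg)
  n_rep <- 1200
  qa <- vapply(seq_len(n_rep), function(s) {
    p <- allocate(one_stratum_targets(4), tab, elig, seed = s)
    sum(p$quotas$quota[p$quotas$site_id == "A"])
  }, numeric(1))
  # variance of the hypergeometric count for site A
  v <- 4 * (5 / 8) * (3 / 8) * (8 - 4) / (8 - 1)
  se <- sqrt(v / n_rep)
  expect_lt(abs(mean(qa) - expected[1]), 3 * se)
  expect_equal(expected[1], 4 * 5 / 8, tolerance = 1e-12)

  # larger instance: closed-form mean 10 * 30/40 = 7.5
  reg2 <- small_registry(avail_a = 30L, avail_b = 10L)
  tab2 <- build_potential_table(reg2)
  elig2 <- eligibility_matrix(reg2)
  qa2 <- vapply(seq_len(n_rep), function(s) {
    p <- allocate(one_stratum_targets(10), tab2, elig2, seed = 10000 + s)
    sum(p$quotas$quota[p$quotas$site_id == "A"])
  }, numeric(1))
  v2 <- 10 * (30 / 40) * (10 / 40) * (40 - 10) / (40 - 1)
  expect_lt(abs(mean(qa2) - 7.5), 3 * sqrt(v2 / n_rep))
})

test_that("residual allocation splits general targets proportionally to capacity", {
  reg <- site_registry(
    tibble::tibble(site_id = c("G1", "G2"), name = c("mall", "festival"),
                   type = c("public_space", "public_event"),
                   is_general = TRUE, capacity = c(20, 10),
                   eligible_ses = list("all", "all"))
  )
  base <- allocate(one_stratum_targets(0), build_potential_table(reg),
                   eligibility_matrix(reg), seed = 1)
  rt <- tibble::tibble(gender = "male", age_band = "16-24", ses = "general",
                       target = 21L)
  plan <- allocate_residual(base, reg, rt)
  expect_equal(sum(plan$quotas$quota[plan$quotas$site_id == "G1"]), 14L)
  expect_equal(sum(plan$quotas$quota[plan$quotas$site_id == "G2"]), 7L)

  # equal capacities halve evenly; zero residual is the identity
  reg2 <- site_registry(
    tibble::tibble(site_id = c("G1", "G2"), name = c("a", "b"),
                   type = "public_space", is_general = TRUE, capacity = 50,
                   eligible_ses = list("all", "all"))
  )
  p2 <- allocate_residual(base, reg2,
                          tibble::tibble(gender = "female", age_band = "65+",
                                         ses = "general", target = 20L))
  expect_equal(sort(p2$quotas$quota[p2$quotas$ses == "general"]), c(10L, 10L))
  p3 <- allocate_residual(base, reg2,
                          tibble::tibble(gender = "female", age_band = "65+",
                                         ses = "general", target = 0L))
  expect_equal(nrow(p3$quotas[p3$quotas$ses == "general", ]), 0)

  # general-only SES constraint and missing general sites are errors
  expect_error(allocate_residual(base, reg2, one_stratum_targets(5)),
               "general")
  no_gen <- site_registry(
    tibble::tibble(site_id = "CC", name = "c", type = "childcare",
                   is_general = FALSE, capacity = NA,
                   eligible_ses = list("full_time_worker"))
  )
  expect_error(allocate_residual(base, no_gen, rt), "no general site")
})

test_that("rebalancing recomputes remaining quotas on a derived seed chain", {
  reg <- small_registry()
  tab <- build_potential_table(reg)
  elig <- eligibility_matrix(reg)
  tgt <- one_stratum_targets(10)
  plan <- allocate(tgt, tab, elig, seed = 7)

  # zero progress: identical to a fresh allocation under the derived seed
  fresh <- allocate(tgt, tab, elig, seed = derive_seed(7, 3))
  reb <- rebalance(plan, tibble::tibble(gender = "male", age_band = "16-24",
                                        ses = "unemployed", recruited = 0L),
                   tgt, day = 3)
  expect_identical(reb$quotas, fresh$quotas)

  # over-recruitment: zero remaining plus a flag
  reb2 <- rebalance(plan, tibble::tibble(gender = "male", age_band = "16-24",
                                         ses = "unemployed", recruited = 13L),
                    tgt, day = 4)
  expect_equal(sum(reb2$quotas$quota), 0L)
  over <- attr(reb2, "over_sampling")
  expect_equal(nrow(over), 1)
  expect_equal(over$recruited - over$target, 3L)

  # exact progress everywhere: the all-zero plan
  reb3 <- rebalance(plan, tibble::tibble(gender = "male", age_band = "16-24",
                                         ses = "unemployed", recruited = 10L),
                    tgt, day = 5)
  expect_equal(sum(reb3$quotas$quota), 0L)
  expect_equal(nrow(attr(reb3, "over_sampling")), 0)
})

test_that("plans export quotas and metadata", {
  reg <- small_registry()
  plan <- allocate(one_stratum_targets(10), build_potential_table(reg),
                   eligibility_matrix(reg), seed = 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, csv, meta)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(sum(back$quota), 10)
  m <- jsonlite::read_json(meta, simplifyVector = TRUE)
  expect_equal(m$seed, 5)
})
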