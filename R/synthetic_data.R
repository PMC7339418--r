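#' Specify a synthetic community
#'
#' Bundles everything needed to simulate a finite community and its
#' recruitment: the eligible population size, the census profile the
#' population is drawn from, the roster of services and public-space sites
#' with their per-stratum client coverage, the per-site attendance rate
#' for public spaces, the attrition process (probability an commenced
#' survey is not completed, and the distribution of reasons), and a
#' log-normal model for survey duration in minutes.
#'
#' Defaults emulate the study community the package's worked examples are
#' built around: ~1,863 eligible individuals (the sample of 706 being
#' 37.9% of them), attrition 24/730, reasons split 12/4/8 across leaving
#' for time reasons, technical problems and discomfort, and durations
#' log-normal with mean 14.77 and SD 6.33 minutes.
#'
#' @param population_size Eligible individuals to simulate.
#' @param census A `census_profile` over the full SES frame.
#' @param site_specs Tibble describing sites; see [default_site_specs()].
#' @param attendance_rate Probability an individual attends a given
#'   public-space site (general sites' client coverage).
#' @param attrition Probability a commenced survey ends incomplete.
#' @param reason_probs Named probabilities over incompleteness reasons.
#' @param duration_meanlog,duration_sdlog Log-normal duration parameters;
#'   the defaults match mean 14.77 / SD 6.33 minutes.
#' @param residence_probs Named probabilities over residence categories.
#' @param age_ceiling Upper age for the open-ended 65+ band.
#' @param seed Integer RNG seed.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(population_size = 1863,
                           census = reference_census_profile(expand_ses = TRUE),
                           site_specs = default_site_specs(),
                           attendance_rate = 0.3,
                           attrition = 24 / 730,
                           reason_probs = c(left_time = 12, technical = 4,
                                            discomfort = 8) / 24,
                           duration_meanlog = 2.6084,
                           duration_sdlog = 0.4108,
                           residence_probs = c(town_city = 0.891,
                                               indigenous_community = 0.057,
                                               parkland_scrub = 0.014,
                                               other = 0.038),
                           age_ceiling = 90,
                           seed = 1L) {
  stopifnot(inherits(census, "census_profile"),
            population_size >= 1,
            attrition >= 0, attrition <= 1,
            attendance_rate >= 0, attendance_rate <= 1)
  if (abs(sum(reason_probs) - 1) > 1e-8) {
    stop("reason_probs must sum to 1", call. = FALSE)
  }
  if (abs(sum(residence_probs) - 1) > 1e-8) {
    stop("residence_probs must sum to 1", call. = FALSE)
  }
  site_specs <- as_tibble(site_specs)
  if (any(site_specs$coverage < 0 | site_specs$coverage > 1, na.rm = TRUE)) {
    stop("site coverage must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size), census = census,
         site_specs = site_specs, attendance_rate = attendance_rate,
         attrition = attrition, reason_probs = reason_probs,
         duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
         residence_probs = residence_probs, age_ceiling = age_ceiling,
         seed = as.integer(seed)),
    class = "community_spec"
  )
}

#' Default synthetic site roster
#'
#' A realistic mix of community services and public spaces: an Indigenous
#' health service and community groups covering all named SES categories,
#' targeted services (adult education for students, an unemployment
#' service, a homelessness service, mental-health and AOD services), a
#' childcare service, and two public-space sites (a shopping mall and a
#' community festival) that take residual-category quotas and spill-over.
#' `coverage` is the probability that an eligible individual is a client
#' of (or, for public spaces, attends) the site.
#'
#' @param general_capacity Per-stratum capacity of the public-space sites.
#' @return Tibble `site_id`, `name`, `type`, `eligible_ses` (list-column),
#'   `coverage`, `is_general`, `capacity`.
#' @export
default_site_specs <- function(general_capacity = 500) {
  named <- list(named_ses_levels)
  tibble(
    site_id = sprintf("S%02d", 1:11),
    name = c("Aboriginal health service", "Community group A", "Community group B",
             "Adult education college", "Unemployment service",
             "Homelessness service", "Mental health service", "AOD service",
             "Childcare service", "Shopping mall", "Community festival"),
    type = c("indigenous_health_service", "community_group", "community_group",
             "indigenous_adult_education", "unemployment_service",
             "homelessness_service", "mental_health_service", "aod_service",
             "childcare", "public_space", "public_event"),
    eligible_ses = c(named, named, named,
                     list("student"), list("unemployed"), list("homeless"),
                     named, named,
                     list(c("full_time_worker", "unemployed")),
                     list(ses_levels), list(ses_levels)),
    coverage = c(0.35, 0.20, 0.15, 0.55, 0.45, 0.65, 0.10, 0.10, 0.05, NA, NA),
    is_general = c(rep(FALSE, 9), TRUE, TRUE),
    capacity = c(rep(NA_real_, 9), general_capacity, general_capacity)
  )
}

#' Generate a synthetic eligible population
#'
#' Draws individual-level data from the community spec: stratum membership
#' is multinomial on the census proportions; ages are uniform within their
#' band (the open 65+ band truncated at the configured ceiling); income
#' band, language-at-home and Year-10 flags are drawn independently from
#' the census marginal distributions; residence from the residence
#' distribution.  Fully seed-deterministic.
#'
#' @param spec A `community_spec`.
#' @return Tibble `id`, `gender`, `age_band`, `age`, `ses`, `income_band`,
#'   `language_at_home`, `education_year10`, `residence`.
#' @export
gen_population <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  strata <- spec$census$strata
  n <- spec$population_size
  with_seed(spec$seed, {
    idx <- sample.int(nrow(strata), n, replace = TRUE, prob = strata$proportion)
    band <- as.character(strata$age_band[idx])
    lower <- c(`16-24` = 16, `25-44` = 25, `45-64` = 45, `65+` = 65)[band]
    upper <- c(`16-24` = 24, `25-44` = 44, `45-64` = 64,
               `65+` = spec$age_ceiling)[band]
    age <- floor(runif(n, lower, upper + 1))
    inc <- spec$census$income_distribution
    income <- if (is.null(inc)) {
      rep(NA_character_, n)
    } else {
      sample(names(inc), n, replace = TRUE, prob = inc)
    }
    lang <- if (is.null(spec$census$language_at_home)) rep(NA, n) else
      runif(n) < spec$census$language_at_home
    edu <- if (is.null(spec$census$education_year10)) rep(NA, n) else
      runif(n) < spec$census$education_year10
    residence <- sample(names(spec$residence_probs), n, replace = TRUE,
                        prob = spec$residence_probs)
    tibble(
      id = sprintf("P%06d", seq_len(n)),
      gender = as.character(strata$gender[idx]),
      age_band = band,
      age = age,
      ses = as.character(strata$ses[idx]),
      income_band = income,
      language_at_home = lang,
      education_year10 = edu,
      residence = residence
    )
  })
}

#' Generate service client rosters from a population
#'
#' Each site's clients are drawn from the eligible population by
#' independent Bernoulli(coverage) membership per individual, per site —
#' so one individual can attend several sites, mirroring real service
#' overlap.  Service sites enrol only their eligible SES categories;
#' public-space sites "enrol" attendees from all strata at the spec's
#' attendance rate.  Returns a registry whose client counts are the
#' stratum tallies of the drawn rosters (what each organisation would
#' report), with the individual-level rosters attached for downstream
#' recruitment simulation.
#'
#' @param population Output of [gen_population()].
#' @param spec The `community_spec`.
#' @return A `site_registry` with a `clients` attribute (tibble `site_id`,
#'   `id`).
#' @export
gen_service_clients <- function(population, spec) {
  stopifnot(inherits(spec, "community_spec"))
  ss <- spec$site_specs
  clients <- with_seed(derive_seed(spec$seed, 7919), {
    out <- vector("list", nrow(ss))
    for (j in seq_len(nrow(ss))) {
      cov <- if (ss$is_general[j]) spec$attendance_rate else ss$coverage[j]
      eligible <- population[population$ses %in% ss$eligible_ses[[j]], ]
      member <- runif(nrow(eligible)) < cov
      out[[j]] <- tibble(site_id = ss$site_id[j], id = eligible$id[member])
    }
    dplyr::bind_rows(out)
  })
  joined <- dplyr::inner_join(clients, population, by = "id")
  counts <- dplyr::count(joined, .data$site_id, .data$gender, .data$age_band,
                         .data$ses, name = "count")
  registry <- site_registry(
    ss[, c("site_id", "name", "type", "is_general", "capacity", "eligible_ses")],
    counts
  )
  attr(registry, "clients") <- clients
  registry
}

#' Simulate the recruitment process for an allocation plan
#'
#' Walks the plan's (site, stratum) quotas: for each, that many *distinct*
#' attendees of the site in the stratum are recruited (the synthetic ids
#' make double-completion impossible — a bookkeeping capability anonymous
#' field studies lack); each commenced survey is independently incomplete
#' with the spec's attrition probability, with the reason drawn from the
#' reason distribution, and durations drawn from the log-normal duration
#' model.  If a quota exceeds the site's synthetic attendees, what exists
#' is recruited and the shortfall logged in the `shortfall` attribute.
#'
#' @param plan An `allocation_plan`.
#' @param registry The `site_registry` from [gen_service_clients()] (with
#'   its `clients` attribute).
#' @param population The population table.
#' @param spec The `community_spec`.
#' @param seed Optional seed override (defaults to a seed derived from the
#'   spec seed), so replicate recruitment runs can vary while everything
#'   upstream stays fixed.
#' @param start_date First of the simulated collection days.
#' @param n_days Number of collection days the records are spread over.
#' @return A validated survey-records tibble (one row per commenced
#'   survey), with a `shortfall` attribute.
#' @export
simulate_recruitment <- function(plan, registry, population, spec,
                                 seed = NULL, start_date = as.Date("2019-07-01"),
                                 n_days = 36) {
  stopifnot(inherits(plan, "allocation_plan"), inherits(registry, "site_registry"),
            inherits(spec, "community_spec"))
  clients <- attr(registry, "clients")
  if (is.null(clients)) stop("registry lacks a clients roster; use gen_service_clients()",
                             call. = FALSE)
  seed <- seed %||% derive_seed(spec$seed, 104651)
  quotas <- plan$quotas[plan$quotas$quota > 0, ]
  roster <- dplyr::inner_join(clients, population, by = "id")
  pools <- split(roster$id, paste(roster$site_id, roster$gender,
                                  roster$age_band, roster$ses))
  pool_keys <- paste(quotas$site_id, quotas$gender, quotas$age_band, quotas$ses)
  with_seed(seed, {
    taken <- new.env(parent = emptyenv())
    picks_site <- vector("list", nrow(quotas))
    picks_id <- vector("list", nrow(quotas))
    shortfall <- integer(nrow(quotas))
    for (i in seq_len(nrow(quotas))) {
      pool <- pools[[pool_keys[i]]] %||% character()
      if (length(pool) > 0) {
        pool <- pool[!vapply(pool, function(p) exists(p, envir = taken), logical(1))]
      }
      k <- min(quotas$quota[i], length(pool))
      shortfall[i] <- quotas$quota[i] - k
      ids <- if (k == 0) character(0) else if (length(pool) == 1) pool else
        sample(pool, k)
      for (p in ids) assign(p, TRUE, envir = taken)
      picks_site[[i]] <- rep(quotas$site_id[i], k)
      picks_id[[i]] <- ids
    }
    picks <- tibble(site_id = unlist(picks_site) %||% character(),
                    id = unlist(picks_id) %||% character())
    n <- nrow(picks)
    if (sum(shortfall) > 0) {
      message(sum(shortfall), " quota unit(s) could not be filled from synthetic attendees")
    }
    dat <- dplyr::inner_join(picks, population, by = "id")
    incomplete <- runif(n) < spec$attrition
    reasons <- rep(NA_character_, n)
    if (any(incomplete)) {
      reasons[incomplete] <- sample(names(spec$reason_probs), sum(incomplete),
                                    replace = TRUE, prob = spec$reason_probs)
    }
    records <- tibble(
      record_id = sprintf("R%06d", seq_len(n)),
      date = start_date + sample.int(n_days, n, replace = TRUE) - 1,
      site_id = dat$site_id,
      gender = dat$gender,
      age = dat$age,
      ses = dat$ses,
      status = ifelse(incomplete, "incomplete", "complete"),
      incomplete_reason = reasons,
      duration = round(rlnorm(n, spec$duration_meanlog, spec$duration_sdlog), 2),
      residence = dat$residence,
      income_band = dat$income_band,
      language_at_home = dat$language_at_home,
      education_year10 = dat$education_year10
    )
    records <- validate_records(records)
    attr(records, "shortfall") <-
      dplyr::bind_cols(quotas[, c("site_id", "gender", "age_band", "ses", "quota")],
                       shortfall = shortfall)
    records
  })
}

#' Write a complete synthetic fixture set
#'
#' One command that exercises the whole pipeline and leaves every input
#' file on disk: census profile CSV + marginals JSON, site registry CSV,
#' survey records CSV (from a full target-allocation-recruitment run),
#' organisation table CSV and contact log CSV.  Every file loads cleanly
#' through the corresponding loader.
#'
#' @param spec A `community_spec`.
#' @param dir Writable output directory (created if missing).
#' @param n_target Sample-size target driving the allocation.
#' @return Named character vector of the files written.
#' @export
end_to_end_fixture <- function(spec = community_spec(), dir = tempdir(),
                               n_target = 700) {
  stopifnot(inherits(spec, "community_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    census = file.path(dir, "census_profile.csv"),
    marginals = file.path(dir, "census_marginals.json"),
    sites = file.path(dir, "sites.csv"),
    records = file.path(dir, "records.csv"),
    orgs = file.path(dir, "orgs.csv"),
    contacts = file.path(dir, "contacts.csv")
  )
  write_census_profile(spec$census, paths["census"], paths["marginals"])
  population <- gen_population(spec)
  registry <- gen_service_clients(population, spec)
  write_sites(registry, paths["sites"])
  targets <- compute_strata_targets(spec$census, n_target)
  plan <- allocate_quotas(targets, registry, seed = derive_seed(spec$seed, 13))
  records <- simulate_recruitment(plan, registry, population, spec)
  readr::write_csv(records, paths["records"], progress = FALSE)
  orgs <- gen_orgs(seed = derive_seed(spec$seed, 17))
  org_out <- orgs
  org_out$referred_by <- vapply(org_out$referred_by, paste, "", collapse = "|")
  readr::write_csv(org_out, paths["orgs"], progress = FALSE)
  contacts <- gen_contact_log(orgs, seed = derive_seed(spec$seed, 19))
  readr::write_csv(contacts, paths["contacts"], progress = FALSE)
  paths
}

#' Generate a synthetic organisation engagement table
#'
#' Random organisation records with a referral digraph.  The defaults
#' reproduce the engagement structure of the package's worked example:
#' 77 organisations approached, 32 participating (each with a letter of
#' support), 16 of the participating and 19 of the non-participating
#' organisations referring at least one other organisation.  Referral
#' targets are drawn at random (a simple random digraph; no social-network
#' structure is modelled).
#'
#' @param n_approached Organisations approached.
#' @param n_participated Of which participated.
#' @param n_participating_referrers Participating orgs with >= 1 outgoing
#'   referral.
#' @param n_nonparticipating_referrers Non-participating orgs with >= 1
#'   outgoing referral.
#' @param max_referrals Maximum referrals per referring organisation.
#' @param seed Integer RNG seed.
#' @return Organisation tibble (`org_id`, `approached`, `participated`,
#'   `referred_by` list-column, `letter_date`).
#' @export
gen_orgs <- function(n_approached = 77, n_participated = 32,
                     n_participating_referrers = 16,
                     n_nonparticipating_referrers = 19,
                     max_referrals = 3, seed = 1L) {
  stopifnot(n_participated <= n_approached,
            n_participating_referrers <= n_participated,
            n_nonparticipating_referrers <= n_approached - n_participated)
  with_seed(seed, {
    ids <- sprintf("O%03d", seq_len(n_approached))
    participated <- ids %in% sample(ids, n_participated)
    referrers <- c(
      sample(ids[participated], n_participating_referrers),
      sample(ids[!participated], n_nonparticipating_referrers)
    )
    edges <- dplyr::bind_rows(lapply(referrers, function(from) {
      to <- sample(setdiff(ids, from), sample.int(max_referrals, 1))
      tibble(from = from, to = to)
    }))
    referred_by <- lapply(ids, function(id) unique(edges$from[edges$to == id]))
    letter_date <- as.Date(ifelse(participated,
                                  as.Date("2019-03-01") + sample.int(120, n_approached, replace = TRUE),
                                  NA),
                           origin = "1970-01-01")
    tibble(
      org_id = ids,
      approached = TRUE,
      participated = participated,
      referred_by = referred_by,
      letter_date = letter_date
    )
  })
}

#' Generate a synthetic contact log
#'
#' Contacts spread at random over the organisations with per-channel
#' totals given by `channel_counts` (defaults: 610 emails, 539 phone
#' calls, 33 texts, 34 meetings, one Facebook message — total 1217).
#' Phone calls and meetings get log-normal durations in hours; contacts
#' dated before a participating organisation's letter of support (or any
#' contact to a non-participating organisation) are flagged
#' `before_agreement`.
#'
#' @param orgs Organisation table, as from [gen_orgs()].
#' @param channel_counts Named integer vector of per-channel totals.
#' @param seed Integer RNG seed.
#' @return Contacts tibble (`org_id`, `date`, `channel`, `duration_hours`,
#'   `before_agreement`).
#' @export
gen_contact_log <- function(orgs,
                            channel_counts = c(email = 610, phone = 539,
                                               text = 33, meeting = 34,
                                               facebook = 1),
                            seed = 1L) {
  orgs <- validate_orgs(orgs)
  stopifnot(all(names(channel_counts) %in% channel_levels))
  with_seed(seed, {
    n <- sum(channel_counts)
    channel <- rep(names(channel_counts), times = channel_counts)
    org_id <- sample(orgs$org_id, n, replace = TRUE)
    date <- as.Date("2019-01-01") + sample.int(300, n, replace = TRUE) - 1
    duration <- ifelse(channel %in% c("phone", "meeting"),
                       round(rlnorm(n, meanlog = -2, sdlog = 0.8), 2), NA_real_)
    letter <- orgs$letter_date[match(org_id, orgs$org_id)]
    before <- is.na(letter) | date <= letter
    validate_contacts(tibble(
      org_id = org_id, date = date, channel = channel,
      duration_hours = duration, before_agreement = before
    ))
  })
}
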