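#' Build the table of potential participants
#'
#' Pools the demographic information reported by each organisation into one
#' table with a row per (site, stratum) pair with a positive client count —
#' e.g. a service currently serving thirty unemployed men aged 16-24
#' contributes a row of 30 in that cell.  General (public-space) sites do
#' not report client lists; they contribute capacity rows for the residual
#' `general` SES strata, and additionally act as spill-over targets during
#' allocation.
#'
#' @param registry A `site_registry`.
#' @param frame Strata frame used to enumerate general-site rows; defaults
#'   to the full frame.
#' @param general_capacity Default per-stratum capacity for general sites
#'   whose `capacity` field is missing.
#' @return An object of class `potential_table`: tibble with `site_id`,
#'   `gender`, `age_band`, `ses`, `available`, carrying the general-site
#'   capacity table as an attribute.
#' @export
build_potential_table <- function(registry, frame = NULL, general_capacity = 500) {
  stopifnot(inherits(registry, "site_registry"))
  if (is.null(frame)) frame <- full_frame()
  frame <- as_tibble(frame)
  general <- registry$sites[registry$sites$is_general, c("site_id", "capacity")]
  general$capacity <- ifelse(is.na(general$capacity), general_capacity, general$capacity)
  general$capacity <- as.integer(general$capacity)

  service_rows <- registry$client_counts[
    registry$client_counts$count > 0 &
      !registry$client_counts$site_id %in% general$site_id,
  ]
  rows <- tibble(
    site_id = service_rows$site_id,
    gender = service_rows$gender,
    age_band = service_rows$age_band,
    ses = service_rows$ses,
    available = service_rows$count
  )
  gen_strata <- dplyr::distinct(
    frame[as.character(frame$ses) == "general", c("gender", "age_band", "ses")]
  )
  if (nrow(general) > 0 && nrow(gen_strata) > 0) {
    gen_rows <- tidyr::expand_grid(site_id = general$site_id, gen_strata)
    gen_rows$available <- general$capacity[match(gen_rows$site_id, general$site_id)]
    gen_rows <- dplyr::mutate(gen_rows, dplyr::across(c("gender", "age_band", "ses"), as.character))
    rows <- dplyr::bind_rows(rows, gen_rows)
  }
  rows <- dplyr::arrange(rows,
                         factor(.data$gender, gender_levels),
                         factor(.data$age_band, age_band_levels),
                         factor(.data$ses, ses_levels),
                         .data$site_id)
  structure(rows, class = c("potential_table", class(rows)),
            general_sites = general)
}

#' Per-stratum totals of a potential table
#'
#' @param table A `potential_table`.
#' @return Tibble with `gender`, `age_band`, `ses`, `total`.
#' @export
total_by_stratum <- function(table) {
  dplyr::count(as_tibble(table), .data$gender, .data$age_band, .data$ses,
               wt = .data$available, name = "total")
}

# Draw `k` units uniformly without replacement from a pool of site-labelled
# units; returns a named integer vector of per-site draw counts.
draw_from_pool <- function(site_ids, avail, k) {
  pool <- rep(site_ids, times = avail)
  drawn <- if (k >= length(pool)) pool else sample(pool, k)
  counts <- table(factor(drawn, levels = unique(site_ids)))
  stats::setNames(as.integer(counts), names(counts))
}

#' Randomly allocate strata targets to eligible sites
#'
#' The heart of the quota design: for each stratum independently, the
#' target number of recruits is drawn uniformly at random *without
#' replacement* from that stratum's pooled potential participants across
#' its eligible sites; a site's quota is the number of units drawn from it
#' (so per-site quotas are multivariate-hypergeometric around
#' `target * available / total_available`).  If a stratum's target exceeds
#' availability, everything available is allocated and — when
#' `general_fallback` is on — the shortfall spills to general (public-space)
#' sites by the same random mechanism over their remaining capacity.
#' Anything still uncovered is recorded in `unmet`, never dropped
#' silently: conservation `sum(quotas) + unmet == target` holds per
#' stratum.
#'
#' @param targets A `strata_targets` object, or a tibble with `gender`,
#'   `age_band`, `ses`, `target`.
#' @param table A `potential_table`.
#' @param eligibility Output of [eligibility_matrix()].
#' @param seed Integer RNG seed; identical inputs and seed give an
#'   identical plan.
#' @param general_fallback Spill shortfalls to general sites (default `TRUE`).
#' @return An object of class `allocation_plan`: list with `quotas`
#'   (tibble `site_id`, `gender`, `age_band`, `ses`, `quota`), `unmet`
#'   (per-stratum shortfalls), `log` (ordered per-stratum allocation
#'   events), `seed`, and the `table`/`eligibility` used (so the plan can
#'   be rebalanced later).
#' @export
allocate <- function(targets, table, eligibility, seed, general_fallback = TRUE) {
  tgt <- if (inherits(targets, "strata_targets")) targets$targets else as_tibble(targets)
  stopifnot(all(c("gender", "age_band", "ses", "target") %in% names(tgt)))
  tgt <- arrange_strata(dplyr::mutate(
    tgt, dplyr::across(c("gender", "age_band", "ses"), as.character)
  ))
  table <- as_tibble(table)
  general <- attr(table, "general_sites") %||%
    tibble(site_id = character(), capacity = integer())
  elig_key <- stratum_key(eligibility$gender, eligibility$age_band, eligibility$ses)

  quotas <- list()
  unmet <- list()
  log <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(tgt))) {
      s <- tgt[i, ]
      key <- stratum_key(s$gender, s$age_band, s$ses)
      hit <- match(key, elig_key)
      elig_sites <- if (is.na(hit)) character() else eligibility$sites[[hit]]
      pool <- table[table$gender == s$gender & table$age_band == s$age_band &
                      table$ses == s$ses & table$site_id %in% elig_sites, ]
      t_s <- as.integer(s$target)
      q <- integer(0)
      if (t_s > 0 && nrow(pool) > 0) {
        q <- draw_from_pool(pool$site_id, pool$available, t_s)
      }
      allocated <- sum(q)
      shortfall <- t_s - allocated
      spilled <- 0L
      if (shortfall > 0 && general_fallback && nrow(general) > 0) {
        remaining_cap <- general$capacity -
          as.integer(q[general$site_id] %||% 0L)[seq_len(nrow(general))]
        remaining_cap[is.na(remaining_cap)] <- general$capacity[is.na(remaining_cap)]
        remaining_cap <- pmax(0L, remaining_cap)
        if (sum(remaining_cap) > 0) {
          q2 <- draw_from_pool(general$site_id, remaining_cap,
                               min(shortfall, sum(remaining_cap)))
          spilled <- sum(q2)
          all_ids <- union(names(q), names(q2))
          q <- stats::setNames(
            as.integer(ifelse(is.na(q[all_ids]), 0L, q[all_ids])) +
              as.integer(ifelse(is.na(q2[all_ids]), 0L, q2[all_ids])),
            all_ids
          )
          shortfall <- shortfall - spilled
        }
      }
      if (shortfall > 0) {
        warning(sprintf("stratum %s: target %d exceeds availability; %d unmet",
                        key, t_s, shortfall), call. = FALSE)
      }
      if (length(q) > 0) {
        quotas[[key]] <- tibble(site_id = names(q), gender = s$gender,
                                age_band = s$age_band, ses = s$ses,
                                quota = as.integer(q))
      }
      unmet[[key]] <- tibble(gender = s$gender, age_band = s$age_band,
                             ses = s$ses, shortfall = as.integer(shortfall))
      log[[key]] <- tibble(gender = s$gender, age_band = s$age_band, ses = s$ses,
                           target = t_s, available = sum(pool$available),
                           allocated = allocated, spilled = spilled,
                           unmet = as.integer(shortfall))
    }
  })
  plan <- list(
    quotas = dplyr::bind_rows(quotas) %||%
      tibble(site_id = character(), gender = character(), age_band = character(),
             ses = character(), quota = integer()),
    unmet = dplyr::bind_rows(unmet),
    log = dplyr::bind_rows(log),
    seed = seed,
    table = table,
    eligibility = eligibility
  )
  if (nrow(plan$quotas) == 0) {
    plan$quotas <- tibble(site_id = character(), gender = character(),
                          age_band = character(), ses = character(), quota = integer())
  }
  plan$quotas <- plan$quotas[plan$quotas$quota > 0, ]
  structure(plan, class = "allocation_plan")
}

#' @export
print.allocation_plan <- function(x, ...) {
  cat("<allocation_plan> seed ", x$seed, "; ", sum(x$quotas$quota),
      " allocated over ", length(unique(x$quotas$site_id)), " sites; ",
      sum(x$unmet$shortfall), " unmet\n", sep = "")
  invisible(x)
}

#' Allocate residual-category quotas to general sites
#'
#' Population portions outside the named SES strata (the residual `general`
#' category — part-time workers, retirees, and so on) are recruited at
#' sites likely to contain general community members: shopping malls,
#' festivals, other public spaces.  Their targets are spread over the
#' general sites proportionally to configured capacity and rounded by
#' largest remainder, so the stratum total is conserved exactly.
#'
#' @param plan An `allocation_plan` to extend (its quotas are added to).
#' @param registry The `site_registry` providing the general sites.
#' @param residual_targets Tibble `gender`, `age_band`, `ses`, `target`
#'   covering only `general`-SES strata.
#' @param general_capacity Default capacity where a site's is missing.
#' @return The extended `allocation_plan`.
#' @export
allocate_residual <- function(plan, registry, residual_targets, general_capacity = 500) {
  stopifnot(inherits(plan, "allocation_plan"), inherits(registry, "site_registry"))
  rt <- as_tibble(residual_targets)
  rt <- dplyr::mutate(rt, dplyr::across(c("gender", "age_band", "ses"), as.character))
  if (any(rt$ses != "general")) {
    stop("residual targets must cover only 'general' SES strata", call. = FALSE)
  }
  general <- registry$sites[registry$sites$is_general, c("site_id", "capacity")]
  if (nrow(general) == 0) stop("no general site in registry", call. = FALSE)
  general$capacity <- ifelse(is.na(general$capacity), general_capacity, general$capacity)
  rt <- arrange_strata(rt)
  for (i in seq_len(nrow(rt))) {
    s <- rt[i, ]
    t_s <- as.integer(s$target)
    if (t_s == 0) next
    cap_total <- as.integer(sum(general$capacity))
    alloc_total <- min(t_s, cap_total)
    shortfall <- t_s - alloc_total
    if (shortfall > 0) {
      warning(sprintf("residual stratum %s: target %d exceeds general capacity %d",
                      stratum_key(s$gender, s$age_band, s$ses), t_s, cap_total),
              call. = FALSE)
    }
    raw <- alloc_total * general$capacity / cap_total
    q <- largest_remainder(raw, total = alloc_total)
    add <- tibble(site_id = general$site_id, gender = s$gender,
                  age_band = s$age_band, ses = s$ses, quota = q)
    plan$quotas <- dplyr::bind_rows(plan$quotas, add[add$quota > 0, ])
    plan$log <- dplyr::bind_rows(plan$log, tibble(
      gender = s$gender, age_band = s$age_band, ses = s$ses,
      target = t_s, available = cap_total,
      allocated = alloc_total, spilled = 0L, unmet = as.integer(shortfall)
    ))
    key_match <- plan$unmet$gender == s$gender & plan$unmet$age_band == s$age_band &
      plan$unmet$ses == s$ses
    if (any(key_match)) {
      plan$unmet$shortfall[key_match] <- as.integer(shortfall)
    } else {
      plan$unmet <- dplyr::bind_rows(plan$unmet, tibble(
        gender = s$gender, age_band = s$age_band, ses = s$ses,
        shortfall = as.integer(shortfall)
      ))
    }
  }
  # merge duplicate (site, stratum) rows that may arise
  plan$quotas <- dplyr::summarise(
    dplyr::group_by(plan$quotas, .data$site_id, .data$gender, .data$age_band, .data$ses),
    quota = sum(.data$quota), .groups = "drop"
  )
  plan
}

#' Rebalance a plan against recruitment progress
#'
#' Daily review of recruitment against the sampling frame: strata already
#' at or above target get zero remaining quota (over-recruitment is
#' flagged, not clawed back — completed surveys are kept), and the
#' remaining quotas are re-spread over eligible sites by the same random
#' mechanism under a fresh seed derived deterministically from the plan's
#' base seed and the day index, so every daily correction is reproducible
#' from the study seed.
#'
#' @param plan The original `allocation_plan` (supplies the potential
#'   table, eligibility and base seed).
#' @param progress Tibble `gender`, `age_band`, `ses`, `recruited`.
#' @param targets The `strata_targets` the study is recruiting towards.
#' @param day Day index used to derive the fresh seed.
#' @param general_fallback Passed to [allocate()].
#' @return A new `allocation_plan` of the remaining quotas, with an
#'   `over_sampling` attribute flagging strata where recruited > target.
#' @export
rebalance <- function(plan, progress, targets, day = 1, general_fallback = TRUE) {
  stopifnot(inherits(plan, "allocation_plan"))
  tgt <- if (inherits(targets, "strata_targets")) targets$targets else as_tibble(targets)
  tgt <- dplyr::mutate(tgt, dplyr::across(c("gender", "age_band", "ses"), as.character))
  progress <- dplyr::mutate(as_tibble(progress),
                            dplyr::across(c("gender", "age_band", "ses"), as.character))
  if (any(progress$recruited < 0)) stop("recruited counts must be >= 0", call. = FALSE)
  merged <- dplyr::left_join(tgt, progress, by = c("gender", "age_band", "ses"))
  merged$recruited[is.na(merged$recruited)] <- 0L
  merged$remaining <- pmax(0L, merged$target - merged$recruited)
  merged$over <- merged$recruited > merged$target
  remaining_targets <- dplyr::transmute(
    merged, .data$gender, .data$age_band, .data$ses, target = .data$remaining
  )
  new_plan <- allocate(remaining_targets, plan$table, plan$eligibility,
                       seed = derive_seed(plan$seed, day),
                       general_fallback = general_fallback)
  attr(new_plan, "over_sampling") <- merged[merged$over,
                                            c("gender", "age_band", "ses",
                                              "recruited", "target")]
  new_plan
}

#' Run the full allocation for a set of strata targets
#'
#' Convenience wrapper over the allocator: named-SES strata are allocated
#' randomly from the table of potential participants; residual
#' `general`-SES strata are routed to general sites via
#' [allocate_residual()].
#'
#' @param targets A `strata_targets` object.
#' @param registry A `site_registry`.
#' @param seed Integer RNG seed.
#' @param general_capacity Default general-site capacity.
#' @param general_fallback Passed to [allocate()].
#' @return An `allocation_plan` covering all strata.
#' @export
allocate_quotas <- function(targets, registry, seed, general_capacity = 500,
                            general_fallback = TRUE) {
  stopifnot(inherits(targets, "strata_targets"), inherits(registry, "site_registry"))
  frame <- targets$targets[, c("gender", "age_band", "ses")]
  table <- build_potential_table(registry, frame = frame,
                                 general_capacity = general_capacity)
  elig <- eligibility_matrix(registry, frame = frame)
  tgt <- dplyr::mutate(targets$targets,
                       dplyr::across(c("gender", "age_band", "ses"), as.character))
  named <- tgt[tgt$ses != "general", ]
  resid <- tgt[tgt$ses == "general", ]
  plan <- allocate(named, table, elig, seed = seed,
                   general_fallback = general_fallback)
  if (nrow(resid) > 0 && sum(resid$target) > 0) {
    plan <- allocate_residual(plan, registry, resid,
                              general_capacity = general_capacity)
  }
  plan
}

#' Export an allocation plan
#'
#' Writes the per-(site, stratum) quotas as CSV and, optionally, run
#' metadata (seed, timestamp, unmet table) as JSON.
#'
#' @param plan An `allocation_plan`.
#' @param path Output CSV path.
#' @param metadata Optional JSON path for run metadata.
#' @return Invisibly, the paths written.
#' @export
write_plan <- function(plan, path, metadata = NULL) {
  stopifnot(inherits(plan, "allocation_plan"))
  readr::write_csv(plan$quotas, path, progress = FALSE)
  written <- path
  if (!is.null(metadata)) {
    jsonlite::write_json(
      list(seed = plan$seed, timestamp = format(Sys.time(), tz = "UTC"),
           unmet = plan$unmet),
      metadata, auto_unbox = TRUE, digits = NA
    )
    written <- c(written, metadata)
  }
  invisible(written)
}
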