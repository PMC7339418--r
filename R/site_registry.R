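#' Construct a site registry
#'
#' A registry of recruitment sites: community organisations and public
#' spaces where surveying takes place.  Each site has a service type, the
#' SES categories it is eligible to recruit (e.g. an adult-education site
#' recruits students), per-stratum client counts reported by the
#' organisation, and an `is_general` flag for public-space sites that
#' receive residual-category quotas (shopping malls, festivals).
#'
#' @param sites Data frame with columns `site_id`, `name`, `type` (one of
#'   the closed service-type vocabulary), `is_general` (logical),
#'   `capacity` (recruits a general site can absorb per stratum; `NA` for
#'   service sites) and `eligible_ses` (list-column of SES labels, or a
#'   pipe-separated character column; `"all"` expands to every category).
#' @param client_counts Data frame with columns `site_id`, `gender`,
#'   `age_band`, `ses`, `count` (one row per stratum a site currently
#'   serves), or `NULL` for an empty registry.
#' @return An object of class `site_registry`.
#' @export
site_registry <- function(sites, client_counts = NULL) {
  sites <- as_tibble(sites)
  required <- c("site_id", "name", "type", "is_general")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    stop("sites table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicate site id(s): ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "),
         call. = FALSE)
  }
  check_levels(sites$type, site_type_levels, "site type")
  sites$is_general <- as.logical(sites$is_general)
  if (!"capacity" %in% names(sites)) sites$capacity <- NA_real_
  if (!"eligible_ses" %in% names(sites)) sites$eligible_ses <- list(character())
  if (!is.list(sites$eligible_ses)) {
    sites$eligible_ses <- lapply(strsplit(as.character(sites$eligible_ses), "|", fixed = TRUE),
                                 trimws)
  }
  sites$eligible_ses <- lapply(sites$eligible_ses, function(x) {
    x <- x[nzchar(x)]
    if (any(x == "all")) return(ses_levels)
    bad <- setdiff(x, ses_levels)
    if (length(bad) > 0) {
      stop("unknown SES label(s) in eligible_ses: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    x
  })
  # A general site is eligible for every stratum by definition.
  sites$eligible_ses[sites$is_general] <- list(ses_levels)

  if (is.null(client_counts)) {
    client_counts <- tibble(site_id = character(), gender = character(),
                            age_band = character(), ses = character(),
                            count = integer())
  }
  client_counts <- as_tibble(client_counts)
  if (nrow(client_counts) > 0) {
    bad_site <- setdiff(unique(client_counts$site_id), sites$site_id)
    if (length(bad_site) > 0) {
      stop("client counts reference unknown site(s): ",
           paste(bad_site, collapse = ", "), call. = FALSE)
    }
    client_counts$gender <- as.character(check_levels(client_counts$gender, gender_levels, "gender"))
    client_counts$age_band <- as.character(normalize_age_band(client_counts$age_band))
    client_counts$ses <- as.character(check_levels(client_counts$ses, ses_levels, "SES"))
    if (any(is.na(client_counts$count)) || any(client_counts$count < 0)) {
      stop("client counts must be non-negative", call. = FALSE)
    }
    client_counts$count <- as.integer(client_counts$count)
  }
  structure(list(sites = sites, client_counts = client_counts),
            class = "site_registry")
}

#' @export
print.site_registry <- function(x, ...) {
  cat("<site_registry> ", nrow(x$sites), " sites (",
      sum(x$sites$is_general), " general); ",
      sum(x$client_counts$count), " reported clients\n", sep = "")
  print(dplyr::select(x$sites, "site_id", "name", "type", "is_general", "capacity"), n = 20)
  invisible(x)
}

#' Load a site registry from CSV
#'
#' Expects columns `site_id, name, type, is_general, capacity,
#' eligible_ses` (pipe-separated SES labels or `all`), followed by one
#' count column per stratum named `n_<gender>.<age_band>.<ses>`, e.g.
#' `n_male.16-24.unemployed`.
#'
#' @param path CSV path.
#' @return A `site_registry`.  An empty file yields an empty registry with
#'   a warning.
#' @export
load_sites <- function(path) {
  if (!file.exists(path)) stop("sites file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    warning("sites file has no rows; returning an empty registry", call. = FALSE)
    return(site_registry(tibble(site_id = character(), name = character(),
                                type = character(), is_general = logical())))
  }
  count_cols <- grep("^n_", names(raw), value = TRUE)
  counts <- NULL
  if (length(count_cols) > 0) {
    counts <- tidyr::pivot_longer(
      raw[, c("site_id", count_cols)], -"site_id",
      names_to = "stratum", values_to = "count"
    )
    parts <- strsplit(sub("^n_", "", counts$stratum), ".", fixed = TRUE)
    if (any(lengths(parts) != 3)) {
      stop("count column names must look like n_<gender>.<age_band>.<ses>", call. = FALSE)
    }
    counts$gender <- vapply(parts, `[`, "", 1)
    counts$age_band <- vapply(parts, `[`, "", 2)
    counts$ses <- vapply(parts, `[`, "", 3)
    counts$count[is.na(counts$count)] <- 0L
    counts <- counts[, c("site_id", "gender", "age_band", "ses", "count")]
  }
  site_registry(raw[, setdiff(names(raw), count_cols)], counts)
}

#' Write a site registry to CSV
#'
#' Inverse of [load_sites()]: serialises `eligible_ses` as a pipe-separated
#' column and client counts as wide `n_<gender>.<age_band>.<ses>` columns.
#'
#' @param registry A `site_registry`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(registry, path) {
  stopifnot(inherits(registry, "site_registry"))
  sites <- registry$sites
  sites$eligible_ses <- vapply(sites$eligible_ses, paste, "", collapse = "|")
  cc <- registry$client_counts
  if (nrow(cc) > 0) {
    cc$stratum <- paste0("n_", cc$gender, ".", cc$age_band, ".", cc$ses)
    wide <- tidyr::pivot_wider(cc[, c("site_id", "stratum", "count")],
                               names_from = "stratum", values_from = "count",
                               values_fill = 0L)
    sites <- dplyr::left_join(sites, wide, by = "site_id")
  }
  readr::write_csv(sites, path, progress = FALSE)
  invisible(path)
}

#' Map strata to eligible recruitment sites
#'
#' A stratum is covered by the sites whose eligibility includes its SES
#' category and which currently serve clients in it, plus every general
#' (public-space) site, since anyone can be encountered at a shopping mall
#' or festival.  Strata with no eligible site are flagged, not fatal — the
#' allocator records them as unmet.
#'
#' @param registry A `site_registry`.
#' @param frame Data frame of strata (`gender`, `age_band`, `ses`); default
#'   is the full 40-stratum frame.
#' @return Tibble with `gender`, `age_band`, `ses`, a list-column `sites`
#'   of eligible site ids, `n_sites`, and `uncovered` flag.
#' @export
eligibility_matrix <- function(registry, frame = NULL) {
  stopifnot(inherits(registry, "site_registry"))
  if (nrow(registry$sites) == 0) stop("registry is empty", call. = FALSE)
  if (is.null(frame)) frame <- full_frame()
  frame <- as_tibble(frame)[, c("gender", "age_band", "ses")]
  frame$gender <- as.character(frame$gender)
  frame$age_band <- as.character(frame$age_band)
  frame$ses <- as.character(frame$ses)
  general_ids <- registry$sites$site_id[registry$sites$is_general]
  cc <- registry$client_counts
  frame$sites <- lapply(seq_len(nrow(frame)), function(i) {
    s <- frame[i, ]
    served <- cc$site_id[cc$gender == s$gender & cc$age_band == s$age_band &
                           cc$ses == s$ses & cc$count > 0]
    ok <- vapply(seq_len(nrow(registry$sites)), function(j) {
      id <- registry$sites$site_id[j]
      (s$ses %in% registry$sites$eligible_ses[[j]]) && (id %in% served)
    }, logical(1))
    sort(unique(c(registry$sites$site_id[ok], general_ids)))
  })
  frame$n_sites <- lengths(frame$sites)
  frame$uncovered <- frame$n_sites == 0
  frame
}

# The full 2 x 4 x 5 sampling frame in canonical order.
full_frame <- function() {
  arrange_strata(tidyr::expand_grid(
    gender = gender_levels, age_band = age_band_levels, ses = ses_levels
  ))
}

#' Load organisation engagement records from CSV
#'
#' Expects columns `org_id, approached, participated, referred_by,
#' letter_date`: `referred_by` is a pipe-separated list of the org ids that
#' referred this organisation to the study, and `letter_date` the ISO-8601
#' date of the letter of support (participation is defined by receipt of
#' such a letter, so `participated` implies `approached`).
#'
#' @param path CSV path.
#' @return A tibble with `referred_by` as a list-column.
#' @export
load_orgs <- function(path) {
  if (!file.exists(path)) stop("orgs file not found: ", path, call. = FALSE)
  orgs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(
                            org_id = readr::col_character(),
                            approached = readr::col_logical(),
                            participated = readr::col_logical(),
                            referred_by = readr::col_character(),
                            letter_date = readr::col_date()
                          ))
  orgs$referred_by <- lapply(strsplit(ifelse(is.na(orgs$referred_by), "", orgs$referred_by),
                                      "|", fixed = TRUE),
                             function(x) x[nzchar(x)])
  validate_orgs(orgs)
}

validate_orgs <- function(orgs) {
  orgs <- as_tibble(orgs)
  if (anyDuplicated(orgs$org_id)) stop("duplicate org id(s)", call. = FALSE)
  if (!is.list(orgs$referred_by)) {
    orgs$referred_by <- lapply(strsplit(ifelse(is.na(orgs$referred_by), "", as.character(orgs$referred_by)),
                                        "|", fixed = TRUE),
                               function(x) x[nzchar(x)])
  }
  bad <- orgs$org_id[orgs$participated & !orgs$approached]
  if (length(bad) > 0) {
    stop("participation implies approach; violated by: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  orgs
}

#' Build the organisation referral graph
#'
#' Directed graph of referrals between organisations: an edge runs from the
#' referrer to the organisation it referred.  Node attributes carry the
#' participation flag and out-degree (the number of organisations each node
#' referred), matching how such recruitment networks are usually drawn
#' (participants filled, nodes sized by out-degree).  Cycles are allowed.
#'
#' @param orgs Organisation table as from [load_orgs()].
#' @return An object of class `referral_graph`: list with `edges`
#'   (tibble `from`, `to`), `nodes` (tibble `org_id`, `participated`,
#'   `out_degree`) and `graph` (an `igraph` object).
#' @export
referral_graph <- function(orgs) {
  orgs <- validate_orgs(orgs)
  edges <- tibble(
    to = rep(orgs$org_id, lengths(orgs$referred_by)),
    from = unlist(orgs$referred_by, use.names = FALSE) %||% character()
  )[, c("from", "to")]
  dangling <- setdiff(edges$from, orgs$org_id)
  if (length(dangling) > 0) {
    stop("referral from unknown organisation(s): ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = orgs$org_id, participated = orgs$participated)
  )
  nodes <- tibble(
    org_id = orgs$org_id,
    participated = orgs$participated,
    out_degree = as.integer(igraph::degree(g, v = orgs$org_id, mode = "out"))
  )
  structure(list(edges = edges, nodes = nodes, graph = g),
            class = "referral_graph")
}

#' @export
print.referral_graph <- function(x, ...) {
  cat("<referral_graph> ", nrow(x$nodes), " organisations, ",
      nrow(x$edges), " referrals\n", sep = "")
  invisible(x)
}

#' Export a referral graph
#'
#' Writes the edge list as CSV or the whole graph in DOT format (for
#' Graphviz rendering with participation-coloured, degree-sized nodes).
#'
#' @param graph A `referral_graph`.
#' @param path Output path.
#' @param format `"csv"` (edge list) or `"dot"`.
#' @return Invisibly, `path`.
#' @export
write_referral_graph <- function(graph, path, format = c("csv", "dot")) {
  stopifnot(inherits(graph, "referral_graph"))
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(graph$edges, path, progress = FALSE)
  } else {
    igraph::write_graph(graph$graph, path, format = "dot")
  }
  invisible(path)
}

#' Summarise organisation recruitment and referrals
#'
#' Tallies the engagement funnel: organisations approached, organisations
#' that participated (defined by receipt of a letter of support), the
#' participation rate, and — because snowball referral between services is
#' itself a recruitment channel — the share of participating and of
#' non-participating organisations that referred at least one other
#' service.  Percentages are reported to one decimal; unrounded values are
#' retained alongside.
#'
#' @param orgs Organisation table as from [load_orgs()].
#' @return An object of class `referral_summary` (a list of counts and
#'   percentages).
#' @export
summarize_referrals <- function(orgs) {
  g <- referral_graph(orgs)
  nodes <- g$nodes
  approached <- orgs$approached
  n_approached <- sum(approached)
  n_participated <- sum(orgs$participated)
  referrer <- nodes$out_degree > 0
  part <- nodes$participated
  appr <- approached[match(nodes$org_id, orgs$org_id)]
  n_part_ref <- sum(referrer & part)
  n_nonpart <- sum(appr & !part)
  n_nonpart_ref <- sum(referrer & appr & !part)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out <- list(
    n_approached = n_approached,
    n_participated = n_participated,
    participation_rate_pct = round1(pct(n_participated, n_approached)),
    participation_rate_raw = pct(n_participated, n_approached),
    n_participating_referrers = n_part_ref,
    participating_referrer_pct = round1(pct(n_part_ref, n_participated)),
    n_nonparticipating = n_nonpart,
    n_nonparticipating_referrers = n_nonpart_ref,
    nonparticipating_referrer_pct = round1(pct(n_nonpart_ref, n_nonpart))
  )
  structure(out, class = "referral_summary")
}

#' @export
print.referral_summary <- function(x, ...) {
  cat("<referral_summary>\n")
  cat(sprintf("  approached: %d; participated: %d (%.1f%%)\n",
              x$n_approached, x$n_participated, x$participation_rate_pct))
  cat(sprintf("  participating orgs that referred others: %d/%d (%.1f%%)\n",
              x$n_participating_referrers, x$n_participated,
              x$participating_referrer_pct))
  cat(sprintf("  non-participating orgs that referred others: %d/%d (%.1f%%)\n",
              x$n_nonparticipating_referrers, x$n_nonparticipating,
              x$nonparticipating_referrer_pct))
  invisible(x)
}
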