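#' Load a researcher-organisation contact log from CSV
#'
#' One row per contact between the research team and an organisation.
#' Expects columns `org_id, date (ISO-8601), channel (email, phone, text,
#' meeting, facebook), duration_hours (phone/meeting only, optional),
#' before_agreement (logical: did the contact precede the organisation's
#' agreement or refusal to participate)`.
#'
#' @param path CSV path.
#' @return Validated contacts tibble.
#' @export
load_contacts <- function(path) {
  if (!file.exists(path)) stop("contacts file not found: ", path, call. = FALSE)
  log <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           org_id = readr::col_character(),
                           date = readr::col_date(),
                           channel = readr::col_character(),
                           duration_hours = readr::col_double(),
                           before_agreement = readr::col_logical()
                         ))
  validate_contacts(log)
}

validate_contacts <- function(log) {
  log <- as_tibble(log)
  check_levels(log$channel, channel_levels, "contact channel")
  if (!"duration_hours" %in% names(log)) log$duration_hours <- NA_real_
  if (!"before_agreement" %in% names(log)) log$before_agreement <- TRUE
  if (any(!is.na(log$duration_hours) & log$duration_hours < 0)) {
    stop("contact durations must be >= 0", call. = FALSE)
  }
  log
}

#' Tally contacts by communication channel
#'
#' Exact integer counts of contacts per channel (emails, phone calls,
#' texts, meetings, Facebook messages — itemised separately, not grouped
#' under text) and the grand total.
#'
#' @param log Contacts tibble as from [load_contacts()].
#' @return An object of class `contact_counts`: list with `by_channel`
#'   (tibble `channel`, `n`) and `total`.
#' @export
contact_counts <- function(log) {
  log <- validate_contacts(log)
  tab <- table(factor(log$channel, levels = channel_levels))
  structure(
    list(
      by_channel = tibble(channel = names(tab), n = as.integer(tab)),
      total = nrow(log)
    ),
    class = "contact_counts"
  )
}

#' @export
print.contact_counts <- function(x, ...) {
  cat("<contact_counts> total ", x$total, ": ",
      paste(sprintf("%s = %d", x$by_channel$channel, x$by_channel$n),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mean engagement effort by participation outcome
#'
#' Compares recruitment effort between organisations that ultimately
#' participated in data collection and those that did not: the mean number
#' of contacts per organisation (all channels) and the mean hours spent on
#' the phone.  Organisations with zero logged contacts contribute zeros,
#' they are not excluded.  By default only contacts made before the
#' organisation agreed or declined count, mirroring how recruitment effort
#' is usually reported.
#'
#' @param log Contacts tibble.
#' @param orgs Organisation table (see [load_orgs()]); only approached
#'   organisations are compared.
#' @param pre_agreement_only Restrict to contacts flagged `before_agreement`.
#' @return Tibble `group` (`participated`/`declined`), `n_orgs`,
#'   `mean_contacts`, `mean_phone_hours` (unrounded; round for display).
#' @export
contacts_by_participation <- function(log, orgs, pre_agreement_only = TRUE) {
  log <- validate_contacts(log)
  orgs <- validate_orgs(orgs)
  unknown <- setdiff(unique(log$org_id), orgs$org_id)
  if (length(unknown) > 0) {
    stop("contact log references unknown organisation(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (pre_agreement_only) log <- log[log$before_agreement %in% TRUE, ]
  approached <- orgs[orgs$approached, ]
  per_org <- tibble(
    org_id = approached$org_id,
    participated = approached$participated,
    n_contacts = vapply(approached$org_id,
                        function(id) sum(log$org_id == id), integer(1)),
    phone_hours = vapply(approached$org_id, function(id) {
      sum(log$duration_hours[log$org_id == id & log$channel == "phone"], na.rm = TRUE)
    }, numeric(1))
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_org, group = ifelse(.data$participated, "participated", "declined")),
    n_orgs = dplyr::n(),
    mean_contacts = mean(.data$n_contacts),
    mean_phone_hours = mean(.data$phone_hours),
    .groups = "drop"
  )
  attr(out, "per_org") <- per_org
  out
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch t statistic with Welch-Satterthwaite degrees of
#' freedom, computed by direct formula:
#' `t = (mean(a) - mean(b)) / sqrt(va/na + vb/nb)` and
#' `df = (va/na + vb/nb)^2 / ((va/na)^2/(na-1) + (vb/nb)^2/(nb-1))`.
#' When both groups have zero variance and equal means, `t = 0`, `p = 1`
#' by convention (df undefined).
#'
#' @param a,b Numeric vectors, each with at least two values.
#' @return An object of class `welch_t`: list `statistic`, `df`,
#'   `p.value`, `means` (group means).
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
welch_t <- function(a, b) {
  a <- as.numeric(a[!is.na(a)])
  b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  se2 <- va + vb
  if (se2 == 0) {
    if (mean(a) == mean(b)) {
      out <- list(statistic = 0, df = NA_real_, p.value = 1,
                  means = c(mean(a), mean(b)))
      return(structure(out, class = "welch_t"))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  structure(
    list(statistic = tstat, df = df,
         p.value = 2 * stats::pt(-abs(tstat), df),
         means = c(mean(a), mean(b))),
    class = "welch_t"
  )
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("%.2f vs %.2f; t = %.2f, df = %.2f, p = %.2f\n",
              x$means[1], x$means[2], x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Engagement effort comparison with Welch tests
#'
#' Formats the participated-versus-declined comparison the way field
#' reports print it: group means for total contacts and phone hours, each
#' with the Welch t statistic, Welch-Satterthwaite df and two-sided p.
#'
#' @inheritParams contacts_by_participation
#' @return Tibble `measure`, `mean_participated`, `mean_declined`, `t`,
#'   `df`, `p` (means to 2 dp; t/df/p to 2 dp).
#' @export
compare_engagement <- function(log, orgs, pre_agreement_only = TRUE) {
  means <- contacts_by_participation(log, orgs, pre_agreement_only)
  per_org <- attr(means, "per_org")
  one <- function(measure, values) {
    part <- values[per_org$participated]
    decl <- values[!per_org$participated]
    w <- welch_t(decl, part)  # sign convention: declined minus participated
    tibble(
      measure = measure,
      mean_participated = round2(mean(part)),
      mean_declined = round2(mean(decl)),
      t = round2(w$statistic), df = round2(w$df), p = round2(w$p.value)
    )
  }
  dplyr::bind_rows(
    one("contacts", per_org$n_contacts),
    one("phone_hours", per_org$phone_hours)
  )
}

#' Export contact summaries as JSON
#'
#' @param log Contacts tibble.
#' @param orgs Organisation table.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_engagement_summary <- function(log, orgs, path) {
  cc <- contact_counts(log)
  jsonlite::write_json(
    list(
      by_channel = cc$by_channel, total = cc$total,
      by_participation = contacts_by_participation(log, orgs),
      referrals = unclass(summarize_referrals(orgs))
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
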