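# Turn records or a counts table into per-cell counts over `by`.
cell_counts <- function(x, by = c("gender", "age_band")) {
  x <- as_tibble(x)
  if ("n" %in% names(x) && !"status" %in% names(x)) {
    counts <- dplyr::mutate(x, dplyr::across(dplyr::any_of(by), as.character))
    counts <- dplyr::count(counts, dplyr::across(dplyr::all_of(by)), wt = .data$n,
                           name = "n")
    return(counts)
  }
  completes <- x[x$status == "complete", ]
  if ("age_band" %in% by && !"age_band" %in% names(completes)) {
    completes$age_band <- as.character(bin_age(completes$age))
  }
  dplyr::count(dplyr::mutate(completes, dplyr::across(dplyr::all_of(by), as.character)),
               dplyr::across(dplyr::all_of(by)), name = "n")
}

#' Sample percentages per demographic cell
#'
#' Shares of the analysable (complete) sample falling in each cell of the
#' frame, by default gender x age band.  Percentages are recomputed from
#' counts at full precision; the print method rounds to 2 decimals.
#'
#' @param records Validated survey records, or a counts table with columns
#'   `by` plus `n`.
#' @param by Cell variables (subset of `gender`, `age_band`, `ses`).
#' @return Tibble with the cell variables, `n` and unrounded `pct`.
#' @export
strata_percentages <- function(records, by = c("gender", "age_band")) {
  counts <- cell_counts(records, by)
  if (sum(counts$n) == 0) stop("no complete records", call. = FALSE)
  counts$pct <- 100 * counts$n / sum(counts$n)
  counts
}

#' Compare an achieved sample to the census profile
#'
#' The representativeness assessment: per demographic cell (default gender
#' x age band), the achieved sample percentage is set against the census
#' percentage, with a *signed* difference (sample minus census) computed on
#' unrounded percentages and rounded last, to 2 decimals.  Census
#' proportions are aggregated over SES to the requested cells.  Cells
#' present in the sample but absent from the census are flagged with an
#' undefined difference.
#'
#' @param records Validated survey records, or a per-cell counts table
#'   (columns `by` plus `n`) such as a published composition table.
#' @param profile A `census_profile`.
#' @param by Cell variables.
#' @return An object of class `repr_report`: list with `rows` (tibble
#'   `n`, `sample_pct`, `census_pct`, `diff_pct`, all 2 dp, plus `flagged`),
#'   `unrounded` (same at full precision) and `overall`
#'   (`max_abs_diff`, `mean_abs_diff`, `total_n`, computed unrounded).
#' @export
compare_to_census <- function(records, profile, by = c("gender", "age_band")) {
  stopifnot(inherits(profile, "census_profile"))
  sample_cells <- strata_percentages(records, by)
  census_cells <- dplyr::count(
    dplyr::mutate(profile$strata, dplyr::across(dplyr::all_of(by), as.character)),
    dplyr::across(dplyr::all_of(by)), wt = .data$proportion, name = "census_prop"
  )
  merged <- dplyr::full_join(census_cells, sample_cells, by = by)
  merged$n[is.na(merged$n)] <- 0L
  merged$pct[is.na(merged$pct)] <- 0
  merged$census_pct <- 100 * merged$census_prop
  merged$flagged <- is.na(merged$census_prop)
  merged$diff <- merged$pct - merged$census_pct
  if (any(merged$flagged)) {
    warning(sum(merged$flagged), " sample cell(s) absent from the census profile",
            call. = FALSE)
  }
  ord <- c(by, "n")
  unrounded <- dplyr::select(merged, dplyr::all_of(ord),
                             sample_pct = "pct", census_pct = "census_pct",
                             diff_pct = "diff", "flagged")
  if (all(c("gender", "age_band") %in% by)) {
    unrounded <- dplyr::arrange(unrounded,
                                factor(.data$gender, gender_levels),
                                factor(.data$age_band, age_band_levels))
  }
  rows <- dplyr::mutate(unrounded,
                        dplyr::across(c("sample_pct", "census_pct", "diff_pct"), round2))
  structure(
    list(
      rows = rows,
      unrounded = unrounded,
      overall = list(
        max_abs_diff = max(abs(unrounded$diff_pct[!unrounded$flagged])),
        mean_abs_diff = mean(abs(unrounded$diff_pct[!unrounded$flagged])),
        total_n = sum(unrounded$n)
      ),
      by = by
    ),
    class = "repr_report"
  )
}

#' @export
print.repr_report <- function(x, ...) {
  cat("<repr_report> n = ", x$overall$total_n,
      sprintf("; max |diff| = %.2f pp; mean |diff| = %.2f pp\n",
              x$overall$max_abs_diff, x$overall$mean_abs_diff), sep = "")
  print(x$rows, n = nrow(x$rows))
  invisible(x)
}

#' Compare a categorical marginal to the census
#'
#' Percentage of the analysable sample with the flag set (an Indigenous
#' language spoken at home; Year 10 completed), against the census
#' marginal, with the signed difference.  Percentages to 2 decimals,
#' recomputed from the underlying counts.
#'
#' @param records Validated survey records.
#' @param profile A `census_profile` carrying the corresponding marginal.
#' @param variable `"language_at_home"` or `"education_year10"`.
#' @return One-row tibble `variable`, `n`, `sample_pct`, `census_pct`,
#'   `diff_pct`.
#' @export
categorical_comparison <- function(records, profile,
                                   variable = c("language_at_home", "education_year10")) {
  stopifnot(inherits(profile, "census_profile"))
  variable <- match.arg(variable)
  records <- as_tibble(records)
  completes <- records[records$status == "complete", ]
  v <- completes[[variable]]
  if (is.null(v) || all(is.na(v))) {
    stop("variable '", variable, "' entirely missing from records", call. = FALSE)
  }
  v <- v[!is.na(v)]
  census <- profile[[variable]]
  if (is.null(census)) stop("census profile lacks marginal '", variable, "'", call. = FALSE)
  sample_pct <- 100 * sum(v) / length(v)
  tibble(
    variable = variable,
    n = length(v),
    sample_pct = round2(sample_pct),
    census_pct = round2(100 * census),
    diff_pct = round2(sample_pct - 100 * census)
  )
}

#' Median weekly income band
#'
#' The income band containing the 50th percentile of the ordered
#' categorical income distribution, overall and per gender.  For even
#' sample sizes the lower-median convention applies (the lower of the two
#' middle observations decides the band).
#'
#' @param records Validated survey records with an `income_band` column.
#' @param band_order Character vector of band labels in ascending order.
#' @return Tibble `group` (`overall`, `female`, `male`), `n`,
#'   `median_band`; groups with no income data get `NA` with a warning.
#' @export
median_income_band <- function(records, band_order) {
  stopifnot(is.character(band_order), length(band_order) > 0)
  records <- as_tibble(records)
  completes <- records[records$status == "complete", ]
  completes <- completes[!is.na(completes$income_band), ]
  bad <- setdiff(unique(completes$income_band), band_order)
  if (length(bad) > 0) {
    stop("income band(s) outside band_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  one <- function(df, label) {
    n <- nrow(df)
    if (n == 0) {
      warning("no income data for group '", label, "'", call. = FALSE)
      return(tibble(group = label, n = 0L, median_band = NA_character_))
    }
    counts <- table(factor(df$income_band, levels = band_order))
    pos <- floor((n + 1) / 2)  # lower median for even n
    band <- band_order[which(cumsum(counts) >= pos)[1]]
    tibble(group = label, n = n, median_band = band)
  }
  dplyr::bind_rows(
    one(completes, "overall"),
    one(completes[!is.na(completes$gender) & completes$gender == "female", ], "female"),
    one(completes[!is.na(completes$gender) & completes$gender == "male", ], "male")
  )
}

#' Population-pyramid data
#'
#' Plot-ready gender x age-band table from a representativeness report:
#' sample and census percentages with female rows negated so that females
#' plot to the left and males to the right of a horizontal pyramid.
#'
#' @param report A `repr_report` built over gender x age band cells.
#' @return Tibble `gender`, `age_band`, `sample_pct`, `census_pct`,
#'   `side` (-1 female, +1 male), `sample_signed`, `census_signed`.
#' @export
pyramid_data <- function(report) {
  stopifnot(inherits(report, "repr_report"))
  rows <- report$rows
  if (!all(c("gender", "age_band") %in% names(rows)) || nrow(rows) == 0) {
    return(tibble(gender = character(), age_band = character(),
                  sample_pct = numeric(), census_pct = numeric(),
                  side = numeric(), sample_signed = numeric(),
                  census_signed = numeric()))
  }
  out <- rows[, c("gender", "age_band", "sample_pct", "census_pct")]
  out$side <- ifelse(out$gender == "female", -1, 1)
  out$sample_signed <- out$sample_pct * out$side
  out$census_signed <- out$census_pct * out$side
  out
}

#' Plot a population pyramid
#'
#' Renders the sample-versus-census pyramid with ggplot2 (sample as bars,
#' census as outlines).  Requires ggplot2; errors informatively if absent.
#'
#' @param report A `repr_report` over gender x age band.
#' @return A ggplot object.
#' @export
plot_pyramid <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_pyramid() requires the ggplot2 package", call. = FALSE)
  }
  dat <- pyramid_data(report)
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$age_band)) +
    ggplot2::geom_col(ggplot2::aes(x = .data$sample_signed, fill = .data$gender),
                      width = 0.8) +
    ggplot2::geom_col(ggplot2::aes(x = .data$census_signed),
                      fill = NA, colour = "black", width = 0.8,
                      linetype = "dashed") +
    ggplot2::scale_x_continuous(labels = function(x) abs(x)) +
    ggplot2::labs(x = "% of population", y = "Age band",
                  title = "Sample (bars) vs census (outline)") +
    ggplot2::theme_minimal()
}

#' Export a representativeness report
#'
#' Writes the per-cell comparison rows (and optionally the pyramid table)
#' as CSV.
#'
#' @param report A `repr_report`.
#' @param path Output CSV path for the comparison rows.
#' @param pyramid_path Optional CSV path for the pyramid table.
#' @return Invisibly, the paths written.
#' @export
write_repr_report <- function(report, path, pyramid_path = NULL) {
  stopifnot(inherits(report, "repr_report"))
  readr::write_csv(report$rows, path, progress = FALSE)
  written <- path
  if (!is.null(pyramid_path)) {
    readr::write_csv(pyramid_data(report), pyramid_path, progress = FALSE)
    written <- c(written, pyramid_path)
  }
  invisible(written)
}
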