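#' Exposure-frequency derivations
#'
#' Convert questionnaire frequencies and durations into the exposure
#' factors (EF) the dose equations consume, using the 4.35 weeks-per-month
#' convention.  No rounding is applied inside these derivations; rounding
#' is a display concern only.
#'
#' * `days_per_month_onsite(d)` = `d x 4.35` days/month, for `d` in 0-7
#'   days/week.
#' * `hours_per_month_onsite(h, d)` = `h x d x 4.35` hours/month, bounded
#'   by 730.8 (= 24 x 7 x 4.35).
#' * `task_hours_per_month(h, d)` = `h x d` hours/month from a task's
#'   hours/day and days/month.
#'
#' @param days_per_week Days worked per week on-site (0-7).
#' @param hours_per_day Hours worked per day (0-24).
#' @param days_per_month Days per month engaged in a task (>= 0).
#' @return Numeric vector, full floating precision.
#' @export
#' @examples
#' days_per_month_onsite(5)          # 21.75
#' hours_per_month_onsite(8, 5)      # 174
#' task_hours_per_month(2.5, 6)      # 15
days_per_month_onsite <- function(days_per_week) {
  if (any(is.na(days_per_week) | days_per_week < 0 | days_per_week > 7)) {
    stop("days_per_week must be in [0, 7]", call. = FALSE)
  }
  days_per_week * time_constants()$weeks_per_month
}

#' @rdname days_per_month_onsite
#' @export
hours_per_month_onsite <- function(hours_per_day, days_per_week) {
  if (any(is.na(hours_per_day) | hours_per_day < 0 | hours_per_day > 24)) {
    stop("hours_per_day must be in [0, 24]", call. = FALSE)
  }
  hours_per_day * days_per_month_onsite(days_per_week)
}

#' @rdname days_per_month_onsite
#' @export
task_hours_per_month <- function(hours_per_day, days_per_month) {
  if (any(is.na(hours_per_day) | hours_per_day < 0) ||
      any(is.na(days_per_month) | days_per_month < 0)) {
    stop("task hours/day and days/month must be non-negative", call. = FALSE)
  }
  hours_per_day * days_per_month
}

#' Within-grower reliability difference
#'
#' Signed difference between reported on-site hours per month and the sum
#' of hours per month over the six meso-activities, for the same
#' grower-season.  A positive value is on-site time not attributable to
#' the six tasks; a negative value signals concurrent tasks (e.g. weeding
#' while irrigating).
#'
#' @param onsite_hours_per_month Hours/month on-site.
#' @param task_hours Numeric vector (or list of vectors, summed
#'   element-wise) of per-task hours/month.
#' @return Signed hours/month.
#' @export
#' @examples
#' reliability_difference(100, rep(10, 6))  # 40
reliability_difference <- function(onsite_hours_per_month, task_hours) {
  if (is.list(task_hours)) {
    task_hours <- Reduce(`+`, task_hours)
  }
  onsite_hours_per_month - sum(task_hours)
}

#' Per-activity mean soil-contact fractions
#'
#' Arithmetic mean of the reported soil-contact fraction for each
#' meso-activity, computed over engaged records only (`days_per_month >
#' 0`), pooled across seasons by default because one scaling factor per
#' task is used for all seasons.  An activity with no engaged records
#' yields `NA` (an explicit "no data" result, never zero).
#'
#' @param cohort A [grower_cohort()] (or its `tasks` tibble).
#' @param activity Optional single activity label; when supplied the bare
#'   mean is returned as a scalar.
#' @param by_season If `TRUE`, return per-season x activity means instead
#'   of pooling.
#' @return Tibble `activity`, (`season`,) `n_engaged`, `mean_contact`; or
#'   a scalar when `activity` is given.
#' @export
mean_contact_fraction <- function(cohort, activity = NULL, by_season = FALSE) {
  tasks <- if (is_grower_cohort(cohort)) cohort$tasks else
    tibble::as_tibble(cohort)
  engaged <- tasks[!is.na(tasks$days_per_month) & tasks$days_per_month > 0, ]
  grp <- if (by_season) c("activity", "season") else "activity"
  res <- engaged |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_engaged = sum(!is.na(.data$contact_fraction)),
      mean_contact = mean(.data$contact_fraction, na.rm = TRUE),
      .groups = "drop"
    )
  # activities absent from engaged records still get an explicit NA row
  frame <- tibble::tibble(activity = meso_activities())
  if (by_season) {
    frame <- tidyr::crossing(frame, season = seasons())
  }
  res <- dplyr::left_join(frame, res, by = grp)
  res$n_engaged[is.na(res$n_engaged)] <- 0L
  res$mean_contact[res$n_engaged == 0] <- NA_real_
  if (!is.null(activity)) {
    stopifnot(length(activity) == 1, activity %in% meso_activities())
    return(res$mean_contact[res$activity == activity][1])
  }
  res
}

#' Derive per-grower-season exposure factors
#'
#' Computes, for every grower x season in the cohort: days/month and
#' hours/month on-site, total task hours/month across the six
#' meso-activities, and the within-grower reliability difference (on-site
#' minus task total).
#'
#' @param cohort A [grower_cohort()].
#' @return Tibble: `grower_id`, `season`, `days_per_month_onsite`,
#'   `hours_per_month_onsite`, `task_hours_total`,
#'   `reliability_difference`.
#' @seealso [task_hours()] for the per-activity breakdown.
#' @export
exposure_factors <- function(cohort) {
  stopifnot(is_grower_cohort(cohort))
  o <- cohort$onsite
  ef <- tibble::tibble(
    grower_id = o$grower_id,
    season = o$season,
    days_per_month_onsite = days_per_month_onsite(o$days_per_week),
    hours_per_month_onsite = hours_per_month_onsite(o$hours_per_day,
                                                    o$days_per_week)
  )
  th <- task_hours(cohort) |>
    dplyr::group_by(.data$grower_id, .data$season) |>
    dplyr::summarise(task_hours_total = sum(.data$hours_per_month),
                     .groups = "drop")
  ef <- dplyr::left_join(ef, th, by = c("grower_id", "season"))
  ef$task_hours_total[is.na(ef$task_hours_total)] <- 0
  ef$reliability_difference <- ef$hours_per_month_onsite - ef$task_hours_total
  ef
}

#' Per-activity task hours per month
#'
#' @param cohort A [grower_cohort()].
#' @return Tibble: `grower_id`, `season`, `activity`, `hours_per_month`
#'   (= task hours/day x days/month; 0 for non-engagement).
#' @export
task_hours <- function(cohort) {
  stopifnot(is_grower_cohort(cohort))
  t <- cohort$tasks
  tibble::tibble(
    grower_id = t$grower_id,
    season = t$season,
    activity = t$activity,
    hours_per_month = task_hours_per_month(t$hours_per_day, t$days_per_month)
  )
}
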