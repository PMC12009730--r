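#' Default daily soil/dust ingestion rates
#'
#' High-contact-scenario modelled defaults: 378 mg/day soil + dust
#' (95th-percentile daily estimate used by the daily-rate dose method),
#' 362 mg/day soil while working outdoors, and 22 mg/day dust while
#' indoors.  Note 362 + 22 = 384, not 378; both figures come from the same
#' modelling source and are carried verbatim as separate constants, never
#' reconciled.
#'
#' @return Named list `daily_soil_dust`, `daily_outdoor_soil`,
#'   `daily_indoor_dust` (mg/day).
#' @export
ingestion_rate_defaults <- function() {
  list(
    daily_soil_dust = 378,
    daily_outdoor_soil = 362,
    daily_indoor_dust = 22
  )
}

#' Questionnaire-derived mean soil-contact fractions
#'
#' The per-activity mean fractions of task time with hands in direct soil
#' contact reported by the grower questionnaires, pooled across seasons:
#' transplanting 0.87, weeding 0.72, planting seeds 0.49, bed preparation
#' 0.41, harvesting 0.35, irrigation 0.08.  These drive the default
#' task-rate scaling-factor assignment.
#'
#' @return Named numeric vector over [meso_activities()].
#' @export
default_contact_means <- function() {
  c(bed_preparation = 0.41, planting_seeds = 0.49, transplanting = 0.87,
    irrigation = 0.08, weeding = 0.72, harvesting = 0.35)
}

#' Hourly ingestion rates from daily defaults
#'
#' `hourly_outdoor_rate()` divides the daily outdoor soil ingestion rate
#' by the hours of an outdoor workday (362/8 = 45.25 mg/h by default);
#' `hourly_indoor_rate()` divides the daily indoor dust ingestion rate by
#' the non-working hours assumed spent indoors (22/16 = 1.375 mg/h,
#' displayed as 1.38).  Full precision is kept internally.
#'
#' @param daily_outdoor_soil,daily_indoor_dust Daily rates, mg/day (> 0).
#' @param workday_hours,nonwork_hours Hours over which the daily rate is
#'   spread (> 0).
#' @return mg/h, full precision.
#' @export
#' @examples
#' hourly_outdoor_rate()  # 45.25
#' hourly_indoor_rate()   # 1.375
hourly_outdoor_rate <- function(daily_outdoor_soil = ingestion_rate_defaults()$daily_outdoor_soil,
                                workday_hours = time_constants()$outdoor_workday_hours) {
  if (any(daily_outdoor_soil <= 0) || any(workday_hours <= 0)) {
    stop("daily rate and workday hours must be positive", call. = FALSE)
  }
  daily_outdoor_soil / workday_hours
}

#' @rdname hourly_outdoor_rate
#' @export
hourly_indoor_rate <- function(daily_indoor_dust = ingestion_rate_defaults()$daily_indoor_dust,
                               nonwork_hours = time_constants()$indoor_nonwork_hours) {
  if (any(daily_indoor_dust <= 0) || any(nonwork_hours <= 0)) {
    stop("daily rate and non-work hours must be positive", call. = FALSE)
  }
  daily_indoor_dust / nonwork_hours
}

#' Scaling factor from a mean contact fraction
#'
#' Maps a task's mean soil-contact fraction to a multiplier on the
#' baseline hourly outdoor ingestion rate: high-contact tasks are doubled
#' (2.0), mid-contact tasks keep the baseline (1.0), low-contact tasks are
#' halved (0.5).  The default cut-points — double at >= 0.60, halve below
#' 0.40 — reproduce the judgment-based assignment implied by the
#' questionnaire means (0.87, 0.72 doubled; 0.49, 0.41 maintained; 0.35,
#' 0.08 halved) and are configurable.  The map is monotone non-decreasing
#' in the contact fraction.
#'
#' @param mean_contact Proportion(s) in 0-1.
#' @param thresholds Named numeric, `low` and `high` cut-points.
#' @return Multiplier(s) in {0.5, 1.0, 2.0}.
#' @export
#' @examples
#' scaling_factor_from_contact(c(0.87, 0.49, 0.08))  # 2, 1, 0.5
scaling_factor_from_contact <- function(mean_contact,
                                        thresholds = c(low = 0.40, high = 0.60)) {
  if (any(is.na(mean_contact) | mean_contact < 0 | mean_contact > 1)) {
    stop("mean_contact must be in [0, 1]", call. = FALSE)
  }
  stopifnot(thresholds[["low"]] <= thresholds[["high"]])
  ifelse(mean_contact >= thresholds[["high"]], 2.0,
         ifelse(mean_contact >= thresholds[["low"]], 1.0, 0.5))
}

#' Task-specific hourly rate
#'
#' @param hourly_outdoor Baseline outdoor hourly rate, mg/h (> 0).
#' @param scaling Multiplier (> 0).
#' @return mg/h.
#' @export
#' @examples
#' task_specific_rate(45.25, 2.0)  # 90.5
task_specific_rate <- function(hourly_outdoor, scaling) {
  if (any(hourly_outdoor <= 0) || any(scaling <= 0)) {
    stop("rate and scaling must be positive", call. = FALSE)
  }
  hourly_outdoor * scaling
}

#' Report-style display rounding
#'
#' Half-up decimal rounding (22.625 -> 22.63 at 2 digits), the convention
#' used when rates are printed in reports.  Base R's [round()] applies
#' IEC 60559 round-half-even (22.625 -> 22.62).  Internally all rates stay
#' at full precision; this is a formatting helper only.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' display_round(c(22.625, 1.375))  # 22.63 1.38
display_round <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build the full ingestion-rate set
#'
#' Assembles daily defaults, the hourly outdoor/indoor rates derived from
#' them, and one scaled hourly rate per meso-activity from the supplied
#' mean contact fractions.  With the default contact means the task rates
#' are transplanting/weeding 90.5, planting seeds/bed preparation 45.25,
#' harvesting/irrigation 22.625 mg/h (displayed 22.63).
#'
#' @param contact_means Named numeric over all six [meso_activities()];
#'   defaults to [default_contact_means()].
#' @param defaults Daily-rate defaults, see [ingestion_rate_defaults()].
#' @param thresholds Scaling cut-points, see
#'   [scaling_factor_from_contact()].
#' @param outdoor_workday_hours,indoor_nonwork_hours Hours used to convert
#'   daily rates to hourly rates.
#' @return Object of class `ingestion_rate_set`: list with
#'   `daily_soil_dust`, `daily_outdoor_soil`, `daily_indoor_dust`,
#'   `hourly_outdoor`, `hourly_indoor`, `scaling_factors` and `task_rates`
#'   (named over activities), plus the inputs used.
#' @export
#' @examples
#' rates <- build_rate_set()
#' rates$task_rates[["transplanting"]]  # 90.5
build_rate_set <- function(contact_means = default_contact_means(),
                           defaults = ingestion_rate_defaults(),
                           thresholds = c(low = 0.40, high = 0.60),
                           outdoor_workday_hours = time_constants()$outdoor_workday_hours,
                           indoor_nonwork_hours = time_constants()$indoor_nonwork_hours) {
  missing <- setdiff(meso_activities(), names(contact_means))
  if (length(missing) > 0) {
    stop("contact_means missing activities: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  contact_means <- contact_means[meso_activities()]
  h_out <- hourly_outdoor_rate(defaults$daily_outdoor_soil,
                               outdoor_workday_hours)
  h_in <- hourly_indoor_rate(defaults$daily_indoor_dust,
                             indoor_nonwork_hours)
  sf <- scaling_factor_from_contact(contact_means, thresholds)
  structure(
    list(
      daily_soil_dust = defaults$daily_soil_dust,
      daily_outdoor_soil = defaults$daily_outdoor_soil,
      daily_indoor_dust = defaults$daily_indoor_dust,
      hourly_outdoor = h_out,
      hourly_indoor = h_in,
      scaling_factors = sf,
      task_rates = task_specific_rate(h_out, sf),
      contact_means = contact_means,
      thresholds = thresholds
    ),
    class = "ingestion_rate_set"
  )
}

#' @export
print.ingestion_rate_set <- function(x, ...) {
  cat("<ingestion_rate_set>\n")
  cat(sprintf("  daily: soil+dust %g, outdoor soil %g, indoor dust %g mg/day\n",
              x$daily_soil_dust, x$daily_outdoor_soil, x$daily_indoor_dust))
  cat(sprintf("  hourly: outdoor %.2f, indoor %.2f mg/h\n",
              display_round(x$hourly_outdoor),
              display_round(x$hourly_indoor)))
  cat("  task rates (mg/h):\n")
  for (a in meso_activities()) {
    cat(sprintf("    %-16s x%.1f = %.2f\n", a, x$scaling_factors[[a]],
                display_round(x$task_rates[[a]])))
  }
  invisible(x)
}

#' @rdname build_rate_set
#' @param x Object to test.
#' @export
is_ingestion_rate_set <- function(x) inherits(x, "ingestion_rate_set")

#' Tidy view of an ingestion-rate set
#'
#' @param rates An `ingestion_rate_set`.
#' @return Tibble `activity`, `mean_contact`, `scaling_factor`,
#'   `rate_mg_per_h`, with baseline outdoor and indoor rows appended
#'   (activity `"outdoor_baseline"` / `"indoor"`).
#' @export
rate_table <- function(rates) {
  stopifnot(is_ingestion_rate_set(rates))
  dplyr::bind_rows(
    tibble::tibble(
      activity = meso_activities(),
      mean_contact = unname(rates$contact_means[meso_activities()]),
      scaling_factor = unname(rates$scaling_factors[meso_activities()]),
      rate_mg_per_h = unname(rates$task_rates[meso_activities()])
    ),
    tibble::tibble(
      activity = c("outdoor_baseline", "indoor"),
      mean_contact = NA_real_,
      scaling_factor = NA_real_,
      rate_mg_per_h = c(rates$hourly_outdoor, rates$hourly_indoor)
    )
  )
}
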