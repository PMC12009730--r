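#' Season and meso-activity vocabularies
#'
#' The pipeline works on four calendar seasons and six agricultural
#' meso-activities (tasks at an intermediate resolution between a whole
#' workday and fine-grained hand-to-mouth micro-activities).  The orderings
#' returned here are fixed and used for all reporting.
#'
#' @return A character vector of levels.
#' @export
#' @examples
#' seasons()
#' meso_activities()
seasons <- function() {
  c("spring", "summer", "fall", "winter")
}

#' @rdname seasons
#' @export
meso_activities <- function() {
  c("bed_preparation", "planting_seeds", "transplanting",
    "irrigation", "weeding", "harvesting")
}

#' Spoon-image soil amount categories
#'
#' The eight response options for self-reported daily soil ingestion
#' amounts, anchored on regulatory default soil/dust ingestion rates
#' (mg/day), plus open-ended low and high options.
#'
#' @return Character vector of the eight category labels.
#' @export
amount_categories <- function() {
  c("lt10", "10", "20", "50", "100", "200", "1000", "gt1000")
}

#' Time constants used by the dose equations
#'
#' A month is taken as 4.35 weeks; hence 30.45 days or 730.8 hours
#' (4.35 x 7 x 24).  The daily-rate dose model uses a 30.5-day averaging
#' time as conventionally printed for a one-month averaging period; the
#' hourly models use 730.8 h.  The 30.45/30.5 discrepancy is carried as-is,
#' not reconciled.  An 8-hour outdoor workday and its 16-hour indoor
#' complement convert daily ingestion-rate defaults to hourly rates.
#'
#' @return Named list: `weeks_per_month` (4.35), `hours_per_month` (730.8),
#'   `days_per_month_avg_method1` (30.5), `hours_per_day` (24),
#'   `outdoor_workday_hours` (8), `indoor_nonwork_hours` (16).
#' @export
#' @examples
#' time_constants()$hours_per_month  # 4.35 * 7 * 24
time_constants <- function() {
  list(
    weeks_per_month = 4.35,
    hours_per_month = 4.35 * 7 * 24, # 730.8
    days_per_month_avg_method1 = 30.5,
    hours_per_day = 24,
    outdoor_workday_hours = 8,
    indoor_nonwork_hours = 16
  )
}

#' Assemble a questionnaire cohort
#'
#' A cohort bundles the three related questionnaire tables:
#'
#' * `growers`: one row per respondent — `grower_id`, `sex`
#'   ("male"/"female"), `age` (years), `smoking` (logical),
#'   `employment_status` (1 = full time, 2 = part time, 3 = other),
#'   `farm_size`, `farm_size_unit` ("ha" or "acre"), `body_weight_kg`
#'   (optional; `NA` means look up from a body-weight table).
#' * `onsite`: one row per grower x season — `days_per_week` (0-7) and
#'   `hours_per_day` (0-24) spent on any agricultural task on-site.
#' * `tasks`: one row per grower x season x meso-activity —
#'   `days_per_month` (0-31), `hours_per_day` (0-24), `contact_fraction`
#'   (proportion of task time with hands in soil, 0-1; `NA` when not
#'   engaged), behaviour flags (`glove_use`, `glove_time_fraction`,
#'   `handwash_after`, `positions` as a ";"-separated string), and the
#'   incidental-ingestion report (`soil_in_mouth`, `ingestion_days`,
#'   `amount_category`), repeated across the six task rows of a
#'   grower-season.
#'
#' Missing task rows mean non-engagement (`days_per_month = 0`); the
#' constructor never invents engagement.  Fractions are proportions (0-1)
#' internally; percentages appear only at the CSV boundary
#' ([read_cohort()]/[write_cohort()]).
#'
#' @param growers,onsite,tasks Data frames with the columns above.
#' @return An object of class `grower_cohort` (a named list of the three
#'   tibbles).
#' @seealso [validate_cohort()], [generate_cohort()], [read_cohort()]
#' @export
grower_cohort <- function(growers, onsite, tasks) {
  structure(
    list(
      growers = tibble::as_tibble(growers),
      onsite = tibble::as_tibble(onsite),
      tasks = tibble::as_tibble(tasks)
    ),
    class = "grower_cohort"
  )
}

#' @export
print.grower_cohort <- function(x, ...) {
  cat("<grower_cohort>\n")
  cat("  growers:", nrow(x$growers), "\n")
  cat("  onsite rows:", nrow(x$onsite),
      " tasks rows:", nrow(x$tasks), "\n")
  invisible(x)
}

#' @rdname grower_cohort
#' @param x Object to test.
#' @export
is_grower_cohort <- function(x) inherits(x, "grower_cohort")

empty_cohort <- function() {
  grower_cohort(
    growers = tibble::tibble(
      grower_id = character(), sex = character(), age = numeric(),
      smoking = logical(), employment_status = integer(),
      farm_size = numeric(), farm_size_unit = character(),
      body_weight_kg = numeric()
    ),
    onsite = tibble::tibble(
      grower_id = character(), season = character(),
      days_per_week = numeric(), hours_per_day = numeric()
    ),
    tasks = tibble::tibble(
      grower_id = character(), season = character(), activity = character(),
      days_per_month = numeric(), hours_per_day = numeric(),
      contact_fraction = numeric(), glove_use = logical(),
      glove_time_fraction = numeric(), handwash_after = logical(),
      positions = character(), soil_in_mouth = logical(),
      ingestion_days = numeric(), amount_category = character()
    )
  )
}

violation <- function(table, row, grower_id, field, rule) {
  tibble::tibble(
    table = table, row = as.integer(row),
    grower_id = as.character(grower_id), field = field, rule = rule
  )
}

no_violations <- function() {
  violation(character(), integer(), character(), character(), character())
}

check_bound <- function(tab, name, df, field, lo, hi, allow_na = FALSE) {
  v <- df[[field]]
  bad <- !is.na(v) & (v < lo | v > hi)
  if (!allow_na) bad <- bad | is.na(v)
  if (!any(bad)) return(no_violations())
  violation(name, which(bad), df$grower_id[bad], field,
            sprintf("%s must be in [%s, %s]", field, lo, hi))
}

#' Validate a cohort against the questionnaire-record invariants
#'
#' Checks every type invariant of the questionnaire schema: bounds on
#' frequencies, durations and fractions; category levels; the
#' non-engagement rule (`days_per_month = 0` implies `hours_per_day = 0`);
#' ingestion days reported only when soil-in-mouth was answered yes;
#' adult age; and foreign-key consistency of `grower_id` across tables.
#'
#' Validation never raises: all violations are collected and returned, one
#' row each, naming the table, row, grower, field and rule.  An empty
#' result means the cohort is valid.  The function is side-effect-free and
#' idempotent.
#'
#' @param cohort A [grower_cohort()].
#' @return Tibble with columns `table`, `row`, `grower_id`, `field`,
#'   `rule`; zero rows iff all invariants hold.
#' @export
#' @examples
#' spec <- cohort_spec(n_growers = 3, seed = 1)
#' nrow(validate_cohort(generate_cohort(spec)))  # 0
validate_cohort <- function(cohort) {
  stopifnot(is_grower_cohort(cohort))
  g <- cohort$growers
  o <- cohort$onsite
  t <- cohort$tasks
  out <- list(no_violations())

  bad_age <- !is.na(g$age) & g$age < 18
  if (any(bad_age)) {
    out <- c(out, list(violation("growers", which(bad_age),
                                 g$grower_id[bad_age], "age",
                                 "age must be >= 18")))
  }
  bad_sex <- !g$sex %in% c("male", "female")
  if (any(bad_sex)) {
    out <- c(out, list(violation("growers", which(bad_sex),
                                 g$grower_id[bad_sex], "sex",
                                 "sex must be 'male' or 'female'")))
  }
  if (nrow(g) > 0 && anyDuplicated(g$grower_id) > 0) {
    d <- which(duplicated(g$grower_id))
    out <- c(out, list(violation("growers", d, g$grower_id[d], "grower_id",
                                 "grower_id must be unique")))
  }
  bad_unit <- !is.na(g$farm_size_unit) & !g$farm_size_unit %in% c("ha", "acre")
  if (any(bad_unit)) {
    out <- c(out, list(violation("growers", which(bad_unit),
                                 g$grower_id[bad_unit], "farm_size_unit",
                                 "farm_size_unit must be 'ha' or 'acre'")))
  }

  out <- c(out, list(
    check_bound("onsite", "onsite", o, "days_per_week", 0, 7),
    check_bound("onsite", "onsite", o, "hours_per_day", 0, 24),
    check_bound("tasks", "tasks", t, "days_per_month", 0, 31),
    check_bound("tasks", "tasks", t, "hours_per_day", 0, 24),
    check_bound("tasks", "tasks", t, "contact_fraction", 0, 1,
                allow_na = TRUE),
    check_bound("tasks", "tasks", t, "glove_time_fraction", 0, 1,
                allow_na = TRUE)
  ))

  for (tab in c("onsite", "tasks")) {
    df <- cohort[[tab]]
    bad <- !df$season %in% seasons()
    if (any(bad)) {
      out <- c(out, list(violation(tab, which(bad), df$grower_id[bad],
                                   "season", "unknown season label")))
    }
    orphan <- !df$grower_id %in% g$grower_id
    if (any(orphan)) {
      out <- c(out, list(violation(tab, which(orphan), df$grower_id[orphan],
                                   "grower_id",
                                   "grower_id not present in growers table")))
    }
  }

  bad_act <- !t$activity %in% meso_activities()
  if (any(bad_act)) {
    out <- c(out, list(violation("tasks", which(bad_act),
                                 t$grower_id[bad_act], "activity",
                                 "unknown meso-activity label")))
  }
  # non-engagement: zero days that season implies zero hours
  bad_ne <- !is.na(t$days_per_month) & !is.na(t$hours_per_day) &
    t$days_per_month == 0 & t$hours_per_day > 0
  if (any(bad_ne)) {
    out <- c(out, list(violation("tasks", which(bad_ne),
                                 t$grower_id[bad_ne], "hours_per_day",
                                 "hours_per_day must be 0 when days_per_month is 0")))
  }
  bad_ing <- !is.na(t$ingestion_days) &
    (is.na(t$soil_in_mouth) | !t$soil_in_mouth)
  if (any(bad_ing)) {
    out <- c(out, list(violation("tasks", which(bad_ing),
                                 t$grower_id[bad_ing], "ingestion_days",
                                 "ingestion_days present only when soil_in_mouth is TRUE")))
  }
  bad_ingd <- !is.na(t$ingestion_days) &
    (t$ingestion_days < 0 | t$ingestion_days > 30)
  if (any(bad_ingd)) {
    out <- c(out, list(violation("tasks", which(bad_ingd),
                                 t$grower_id[bad_ingd], "ingestion_days",
                                 "ingestion_days must be in [0, 30]")))
  }
  bad_amt <- !is.na(t$amount_category) &
    !t$amount_category %in% amount_categories()
  if (any(bad_amt)) {
    out <- c(out, list(violation("tasks", which(bad_amt),
                                 t$grower_id[bad_amt], "amount_category",
                                 "amount_category must be one of the eight spoon-image options")))
  }

  dplyr::bind_rows(out)
}

#' Convert farm size to hectares
#'
#' Canonical internal unit is hectares; 1 acre = 0.404686 ha.
#'
#' @param size Numeric sizes.
#' @param unit Character vector, "ha" or "acre", recycled against `size`.
#' @return Sizes in hectares.
#' @export
farm_size_ha <- function(size, unit) {
  if (any(!is.na(unit) & !unit %in% c("ha", "acre"))) {
    stop("farm_size_unit must be 'ha' or 'acre'", call. = FALSE)
  }
  ifelse(unit == "acre", size * 0.404686, size)
}
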