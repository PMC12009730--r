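GROWERS_COLS <- c("grower_id", "sex", "age", "smoking", "employment_status",
                  "farm_size", "farm_size_unit", "body_weight_kg")
ONSITE_COLS <- c("grower_id", "season", "days_per_week", "hours_per_day")
TASKS_FILE_COLS <- c("grower_id", "season", "activity", "days_per_month",
                     "hours_per_day", "contact_percent", "glove_use",
                     "glove_time_percent", "handwash_after", "positions",
                     "soil_in_mouth", "ingestion_days", "amount_category")

#' Write a cohort to the questionnaire CSV schema
#'
#' Writes `growers.csv`, `onsite.csv` and `tasks.csv` (RFC-4180 style,
#' UTF-8, header row) into `dir`.  Fractions are written as percentages
#' (`contact_percent`, `glove_time_percent` in 0-100) at the file
#' boundary, matching how the questionnaire asks the question; they are
#' proportions internally.  Column order and names are fixed.
#'
#' @param cohort A [grower_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(is_grower_cohort(cohort))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("growers.csv", "onsite.csv", "tasks.csv"))
  write.csv(cohort$growers[GROWERS_COLS], paths[1], row.names = FALSE,
            na = "")
  write.csv(cohort$onsite[ONSITE_COLS], paths[2], row.names = FALSE,
            na = "")
  t <- cohort$tasks
  tf <- tibble::tibble(
    grower_id = t$grower_id, season = t$season, activity = t$activity,
    days_per_month = t$days_per_month, hours_per_day = t$hours_per_day,
    contact_percent = t$contact_fraction * 100,
    glove_use = t$glove_use,
    glove_time_percent = t$glove_time_fraction * 100,
    handwash_after = t$handwash_after, positions = t$positions,
    soil_in_mouth = t$soil_in_mouth, ingestion_days = t$ingestion_days,
    amount_category = t$amount_category
  )
  write.csv(tf, paths[3], row.names = FALSE, na = "")
  invisible(paths)
}

read_table_checked <- function(path, required, label) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(label, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read a cohort from the questionnaire CSV schema
#'
#' Reads the three tables written by [write_cohort()] from `dir` (headers
#' matched case-insensitively), converts boundary percentages back to
#' proportions, and checks structural integrity: required columns, known
#' season and activity labels, percent columns within 0-100, and
#' `grower_id` foreign-key consistency across tables.  Structural
#' problems raise schema errors naming the offending column, label or
#' ids; value-level invariants are left to [validate_cohort()].
#'
#' @param dir Directory containing `growers.csv`, `onsite.csv`,
#'   `tasks.csv`.
#' @return A [grower_cohort()].
#' @export
read_cohort <- function(dir) {
  g <- read_table_checked(file.path(dir, "growers.csv"), GROWERS_COLS,
                          "growers.csv")
  o <- read_table_checked(file.path(dir, "onsite.csv"), ONSITE_COLS,
                          "onsite.csv")
  t <- read_table_checked(file.path(dir, "tasks.csv"), TASKS_FILE_COLS,
                          "tasks.csv")

  bad_act <- setdiff(unique(t$activity), meso_activities())
  if (length(bad_act) > 0) {
    stop("tasks.csv contains unknown activity label(s): ",
         paste(bad_act, collapse = ", "), call. = FALSE)
  }
  bad_season <- setdiff(unique(c(o$season, t$season)), seasons())
  if (length(bad_season) > 0) {
    stop("unknown season label(s): ", paste(bad_season, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("contact_percent", "glove_time_percent")) {
    v <- t[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop("tasks.csv column ", col, " must be within [0, 100]",
           call. = FALSE)
    }
  }
  orphans <- setdiff(unique(c(o$grower_id, t$grower_id)), g$grower_id)
  if (length(orphans) > 0) {
    stop("grower_id(s) absent from growers.csv: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }

  tasks <- tibble::tibble(
    grower_id = as.character(t$grower_id), season = t$season,
    activity = t$activity,
    days_per_month = as.numeric(t$days_per_month),
    hours_per_day = as.numeric(t$hours_per_day),
    contact_fraction = as.numeric(t$contact_percent) / 100,
    glove_use = as.logical(t$glove_use),
    glove_time_fraction = as.numeric(t$glove_time_percent) / 100,
    handwash_after = as.logical(t$handwash_after),
    positions = as.character(t$positions),
    soil_in_mouth = as.logical(t$soil_in_mouth),
    ingestion_days = as.numeric(t$ingestion_days),
    amount_category = as.character(t$amount_category)
  )
  growers <- tibble::tibble(
    grower_id = as.character(g$grower_id), sex = g$sex,
    age = as.numeric(g$age), smoking = as.logical(g$smoking),
    employment_status = as.integer(g$employment_status),
    farm_size = as.numeric(g$farm_size),
    farm_size_unit = as.character(g$farm_size_unit),
    body_weight_kg = as.numeric(g$body_weight_kg)
  )
  onsite <- tibble::tibble(
    grower_id = as.character(o$grower_id), season = o$season,
    days_per_week = as.numeric(o$days_per_week),
    hours_per_day = as.numeric(o$hours_per_day)
  )
  grower_cohort(growers, onsite, tasks)
}

#' Default pipeline configuration
#'
#' One nested list with every constant pre-filled, mirroring the sections
#' a YAML/JSON config file may override: `constants` (contaminant
#' concentration `C_mg_per_kg`), `ingestion_rates` (daily defaults,
#' workday split, scaling thresholds, contact means), `simulation`
#' (`n_growers`, `rate_perturbation_halfwidth`, `include_zeros`) and
#' `cohort_spec` arguments for the synthetic generator.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    constants = list(C_mg_per_kg = 400),
    ingestion_rates = c(
      ingestion_rate_defaults(),
      list(outdoor_workday_hours = time_constants()$outdoor_workday_hours,
           indoor_nonwork_hours = time_constants()$indoor_nonwork_hours,
           thresholds = list(low = 0.40, high = 0.60),
           contact_means = as.list(default_contact_means()))
    ),
    simulation = list(n_growers = 5000,
                      rate_perturbation_halfwidth = 0.2,
                      include_zeros = TRUE),
    cohort_spec = list(n_growers = 38, seed = 2020)
  )
}

#' Read a configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), recursively merged over
#' [default_config()] so partial files are fine.
#'
#' @param path Config file path; `NULL` returns the defaults.
#' @return Nested named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
  merge_lists(cfg, user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Rate set from a configuration list
#'
#' @param config As from [read_config()].
#' @return An [build_rate_set()] object.
#' @export
rate_set_from_config <- function(config = default_config()) {
  ir <- config$ingestion_rates
  build_rate_set(
    contact_means = unlist(ir$contact_means),
    defaults = list(daily_soil_dust = ir$daily_soil_dust,
                    daily_outdoor_soil = ir$daily_outdoor_soil,
                    daily_indoor_dust = ir$daily_indoor_dust),
    thresholds = c(low = ir$thresholds$low, high = ir$thresholds$high),
    outdoor_workday_hours = ir$outdoor_workday_hours,
    indoor_nonwork_hours = ir$indoor_nonwork_hours
  )
}
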