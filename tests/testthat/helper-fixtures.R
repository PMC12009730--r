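# Small hand-built fixtures, constructed in code.

tiny_growers <- function() {
  tibble::tibble(
    grower_id = c("A", "B", "C"),
    sex = c("male", "female", "male"),
    age = c(40, 29, 63),
    smoking = c(FALSE, FALSE, TRUE),
    employment_status = c(1L, 2L, 3L),
    farm_size = c(4, 0.5, 120),
    farm_size_unit = c("ha", "ha", "acre"),
    body_weight_kg = c(NA, 70, NA)
  )
}

tiny_onsite <- function() {
  tibble::tibble(
    grower_id = c("A", "A", "B", "C"),
    season = c("spring", "summer", "spring", "winter"),
    days_per_week = c(5, 6, 3, 2),
    hours_per_day = c(8, 10, 4, 3)
  )
}

tiny_task_row <- function(grower_id, season, activity, days, hours,
                          contact) {
  tibble::tibble(
    grower_id = grower_id, season = season, activity = activity,
    days_per_month = days, hours_per_day = hours,
    contact_fraction = contact, glove_use = NA,
    glove_time_fraction = NA_real_, handwash_after = NA,
    positions = NA_character_, soil_in_mouth = FALSE,
    ingestion_days = NA_real_, amount_category = NA_character_
  )
}

tiny_cohort <- function() {
  tasks <- dplyr::bind_rows(
    tiny_task_row("A", "spring", "transplanting", 10, 2, 0.9),
    tiny_task_row("A", "spring", "weeding", 8, 1.5, 0.7),
    tiny_task_row("A", "spring", "irrigation", 0, 0, NA),
    tiny_task_row("A", "summer", "harvesting", 20, 3, 0.4),
    tiny_task_row("B", "spring", "bed_preparation", 4, 2, 0.5),
    tiny_task_row("C", "winter", "planting_seeds", 2, 1, 0.3)
  )
  grower_cohort(tiny_growers(), tiny_onsite(), tasks)
}

# single-bracket weighted body-weight table
bw_point_table <- function(kg = 80) {
  tab <- tibble::tibble(weight_kg = kg, population_weight = 1)
  attr(tab, "bw_mode") <- "weighted_sample"
  tab
}

default_lookup_table <- function() generate_bodyweight_table("median_lookup")
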