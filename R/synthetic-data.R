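#' Specification for a synthetic questionnaire cohort
#'
#' Parameters of the synthetic-data generator.  Defaults are calibrated to
#' the questionnaire study conditions the pipeline targets: seasonal
#' on-site time highest in summer and lowest in winter (mean on-site
#' hours/month roughly 205 in summer and 77 in winter), six
#' meso-activities with engagement most prevalent in spring/summer,
#' per-activity mean soil-contact fractions at the questionnaire means
#' ([default_contact_means()]), a 52/48 male/female mix aged 26-69, and a
#' positive on-site-minus-task-hours difference for most grower-seasons
#' with concurrency (task hours exceeding on-site hours) in about 29%.
#'
#' Distribution families are deliberate modelling choices, not claims of
#' distributional fidelity: truncated lognormals for frequencies and
#' durations, Beta for contact fractions, Bernoulli for engagement and
#' behaviour flags.
#'
#' @param n_growers Number of respondents; every grower responds in all
#'   four seasons.
#' @param seed Integer seed; the same spec yields an identical cohort.
#' @param onsite_days_per_week_mean,onsite_hours_per_day_mean Named
#'   numeric over [seasons()]: seasonal means of on-site days/week and
#'   hours/day.
#' @param onsite_sdlog Lognormal log-sd for both on-site draws.
#' @param engagement_prob Named numeric over [seasons()]: per-activity
#'   engagement probability each season.
#' @param contact_means Named numeric over [meso_activities()]: target
#'   Beta means of the contact fractions.
#' @param contact_concentration Beta concentration (a+b); larger is
#'   tighter around the mean.
#' @param task_share_weights Named numeric over [meso_activities()]:
#'   relative expected share of total task time.
#' @param task_days_mean Mean days/month for an engaged task draw.
#' @param unaccounted_time_fraction Mean proportion of on-site hours not
#'   attributable to the six tasks (0 disables, exactly).
#' @param concurrency_fraction Probability that a grower-season's task
#'   hours exceed its on-site hours (concurrent tasks).
#' @param sex_prob_male,smoking_prob,employment_probs Demographic mix.
#' @param age_range Inclusive integer age range.
#' @param farm_size_median_ha,farm_size_sdlog Lognormal farm size, ha.
#' @param glove_prob,handwash_prob,soil_in_mouth_prob Behaviour-flag
#'   probabilities.
#' @return Object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_growers = 38,
                        seed = 2020L,
                        onsite_days_per_week_mean = c(spring = 5.0, summer = 5.5,
                                                      fall = 4.5, winter = 3.5),
                        onsite_hours_per_day_mean = c(spring = 7.0, summer = 8.5,
                                                      fall = 5.5, winter = 5.0),
                        onsite_sdlog = 0.3,
                        engagement_prob = c(spring = 0.85, summer = 0.85,
                                            fall = 0.60, winter = 0.40),
                        contact_means = default_contact_means(),
                        contact_concentration = 8,
                        task_share_weights = c(bed_preparation = 1.5,
                                               planting_seeds = 0.7,
                                               transplanting = 1.0,
                                               irrigation = 1.5,
                                               weeding = 1.2,
                                               harvesting = 1.5),
                        task_days_mean = 8,
                        unaccounted_time_fraction = 0.30,
                        concurrency_fraction = 0.29,
                        sex_prob_male = 0.52,
                        smoking_prob = 0.05,
                        employment_probs = c(0.71, 0.03, 0.26),
                        age_range = c(26L, 69L),
                        farm_size_median_ha = 3.8,
                        farm_size_sdlog = 1.8,
                        glove_prob = 0.55,
                        handwash_prob = 0.60,
                        soil_in_mouth_prob = 0.30) {
  spec <- as.list(environment())
  probs <- c(spec$engagement_prob, spec$sex_prob_male, spec$smoking_prob,
             spec$employment_probs, spec$glove_prob, spec$handwash_prob,
             spec$soil_in_mouth_prob, spec$concurrency_fraction,
             spec$unaccounted_time_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities/fractions must be in [0, 1]", call. = FALSE)
  }
  if (any(spec$contact_means < 0 | spec$contact_means > 1)) {
    stop("contact_means must be in [0, 1]", call. = FALSE)
  }
  if (spec$n_growers < 0) stop("n_growers must be >= 0", call. = FALSE)
  missing <- setdiff(meso_activities(), names(spec$contact_means))
  if (length(missing) > 0) {
    stop("contact_means missing activities: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

# lognormal with the requested arithmetic mean, truncated at `cap`
rlnorm_mean <- function(n, mean, sdlog, cap) {
  pmin(cap, rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog))
}

rbeta_mean <- function(n, mean, concentration) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  rbeta(n, shape1 = mean * concentration,
        shape2 = (1 - mean) * concentration)
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws a cohort of grower records with the structure of the seasonal
#' soil-contact activity questionnaire.  Per grower-season, on-site
#' days/week and hours/day are drawn from truncated lognormals; total task
#' time is the on-site hours times `(1 - f)` where `f` is a Beta-drawn
#' unaccounted-time fraction (negative — i.e. task time exceeding on-site
#' time, modelling concurrent tasks — for a `concurrency_fraction` share
#' of grower-seasons); total task time is split across the engaged
#' activities with Dirichlet-style gamma weights and converted to
#' days/month and hours/day so that their product reproduces the task
#' hours exactly.  Contact fractions are Beta draws around the
#' per-activity target means.
#'
#' Every generated record satisfies the schema invariants
#' ([validate_cohort()] returns zero rows) and the same spec (including
#' seed) reproduces the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A [grower_cohort()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_growers = 5, seed = 42))
#' cohort
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_growers == 0) return(empty_cohort())
  set.seed(spec$seed)
  n <- spec$n_growers
  acts <- meso_activities()

  growers <- tibble::tibble(
    grower_id = sprintf("G%04d", seq_len(n)),
    sex = ifelse(runif(n) < spec$sex_prob_male, "male", "female"),
    age = sample(seq(spec$age_range[1], spec$age_range[2]), n,
                 replace = TRUE),
    smoking = runif(n) < spec$smoking_prob,
    employment_status = sample(1:3, n, replace = TRUE,
                               prob = spec$employment_probs),
    farm_size = rlnorm(n, log(spec$farm_size_median_ha),
                       spec$farm_size_sdlog),
    farm_size_unit = "ha",
    body_weight_kg = NA_real_
  )

  onsite_list <- list()
  tasks_list <- list()
  for (s in seasons()) {
    dpw <- rlnorm_mean(n, spec$onsite_days_per_week_mean[[s]],
                       spec$onsite_sdlog, cap = 7)
    hpd <- rlnorm_mean(n, spec$onsite_hours_per_day_mean[[s]],
                       spec$onsite_sdlog, cap = 24)
    onsite_list[[s]] <- tibble::tibble(
      grower_id = growers$grower_id, season = s,
      days_per_week = dpw, hours_per_day = hpd
    )

    onsite_hours <- hpd * dpw * time_constants()$weeks_per_month
    u <- spec$unaccounted_time_fraction
    f <- if (u > 0) rbeta_mean(n, u, 10) else rep(0, n)
    conc <- runif(n) < spec$concurrency_fraction
    f[conc] <- -runif(sum(conc), 0, 0.4)
    total_task <- onsite_hours * (1 - f)

    engaged <- matrix(runif(n * 6) < spec$engagement_prob[[s]],
                      nrow = n, dimnames = list(NULL, acts))
    w <- matrix(rgamma(n * 6, shape = 2 * rep(spec$task_share_weights[acts],
                                              each = n)),
                nrow = n, dimnames = list(NULL, acts))
    w[!engaged] <- 0
    rs <- rowSums(w)
    share <- w / ifelse(rs > 0, rs, 1)
    hours_m <- share * total_task # n x 6 task hours/month
    hours_m <- pmin(hours_m, 24 * 31) # a task cannot exceed the month

    days_m <- matrix(pmin(30, pmax(1, round(rlnorm_mean(
      n * 6, spec$task_days_mean, 0.5, cap = 30)))),
      nrow = n, dimnames = list(NULL, acts))
    # enough days that hours/day stays within a 24-hour day
    days_m <- pmax(days_m, ceiling(hours_m / 24))
    days_m[days_m > 31] <- 31
    hpd_task <- hours_m / days_m
    days_m[!engaged | hours_m == 0] <- 0
    hpd_task[!engaged | hours_m == 0] <- 0

    contact <- matrix(NA_real_, n, 6, dimnames = list(NULL, acts))
    for (a in acts) {
      k <- engaged[, a] & days_m[, a] > 0
      contact[k, a] <- rbeta_mean(sum(k), spec$contact_means[[a]],
                                  spec$contact_concentration)
    }

    sim <- runif(n) < spec$soil_in_mouth_prob
    ing_days <- ifelse(sim, sample(1:15, n, replace = TRUE), NA_real_)
    amt <- ifelse(sim,
                  sample(amount_categories(), n, replace = TRUE,
                         prob = c(8, 6, 5, 3, 2, 1, 0.5, 0.2)),
                  NA_character_)

    for (a in acts) {
      eng_a <- days_m[, a] > 0
      glove <- eng_a & runif(n) < spec$glove_prob
      tasks_list[[paste(s, a)]] <- tibble::tibble(
        grower_id = growers$grower_id,
        season = s,
        activity = a,
        days_per_month = days_m[, a],
        hours_per_day = hpd_task[, a],
        contact_fraction = contact[, a],
        glove_use = ifelse(eng_a, glove, NA),
        glove_time_fraction = ifelse(glove, rbeta_mean(n, 0.7, 8),
                                     NA_real_),
        handwash_after = ifelse(eng_a, runif(n) < spec$handwash_prob, NA),
        positions = ifelse(eng_a,
                           sample(c("kneeling", "standing", "bending",
                                    "sitting", "kneeling;standing",
                                    "standing;bending"),
                                  n, replace = TRUE),
                           NA_character_),
        soil_in_mouth = sim,
        ingestion_days = ing_days,
        amount_category = amt
      )
    }
  }

  tasks <- dplyr::bind_rows(tasks_list) |>
    dplyr::arrange(.data$grower_id,
                   factor(.data$season, levels = seasons()),
                   factor(.data$activity, levels = meso_activities()))
  onsite <- dplyr::bind_rows(onsite_list) |>
    dplyr::arrange(.data$grower_id,
                   factor(.data$season, levels = seasons()))
  grower_cohort(growers, onsite, tasks)
}

#' Generate a synthetic body-weight table
#'
#' The dose models need adult body weights; the shipped tables are
#' synthetic stand-ins (documented placeholders) for the reference
#' sources an analysis of real data would use — sex/age-bracket median
#' body weights for the empirical mode, and a population-weighted
#' body-weight sample for the simulation mode.
#'
#' * `median_lookup`: fixed sex x age-bracket medians tiling ages
#'   `[18, 100)` with no overlap (deterministic; `seed` unused).
#' * `weighted_sample`: `n_rows` (weight, population-weight) pairs; weight
#'   values are drawn from a right-skewed lognormal (median 80 kg, log-sd
#'   0.22) truncated to `[40, 180]` kg, population weights are uniform
#'   draws on roughly 0.5-1.5 million persons per row.  Weights need not
#'   sum to one; sampling normalises them.
#'
#' @param mode `"median_lookup"` or `"weighted_sample"`.
#' @param seed Integer seed (weighted_sample mode).
#' @param n_rows Rows in weighted_sample mode (>= 100).
#' @return Tibble: either `sex`, `age_low`, `age_high`, `median_kg`, or
#'   `weight_kg`, `population_weight`; with attribute `bw_mode`.
#' @export
#' @examples
#' generate_bodyweight_table("median_lookup")
generate_bodyweight_table <- function(mode = c("median_lookup",
                                               "weighted_sample"),
                                      seed = 1L, n_rows = 150L) {
  mode <- match.arg(mode)
  if (mode == "median_lookup") {
    tab <- tibble::tibble(
      sex = rep(c("male", "female"), each = 4),
      age_low = rep(c(18, 30, 50, 70), 2),
      age_high = rep(c(30, 50, 70, 100), 2),
      # synthetic placeholder medians, kg
      median_kg = c(83.8, 88.8, 88.0, 80.5,
                    71.1, 76.4, 74.9, 68.2)
    )
  } else {
    if (n_rows < 100) stop("n_rows must be >= 100", call. = FALSE)
    set.seed(seed)
    vals <- numeric(0)
    while (length(vals) < n_rows) {
      draw <- rlnorm(n_rows * 2, meanlog = log(80), sdlog = 0.22)
      vals <- c(vals, draw[draw >= 40 & draw <= 180])
    }
    tab <- tibble::tibble(
      weight_kg = vals[seq_len(n_rows)],
      population_weight = runif(n_rows, 5e5, 1.5e6)
    )
  }
  attr(tab, "bw_mode") <- mode
  tab
}
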