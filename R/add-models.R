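MG_TO_KG <- 1e-6 # mg ingested soil -> kg; applied exactly once, here

#' Average daily dose, daily-ingestion-rate model (method 1)
#'
#' ADD = (C x IR x 1e-6 x EF_days x ED) / (BW x AT_days), in
#' mg contaminant / kg body weight / day.  The 1e-6 converts the ingestion
#' rate from mg soil/day to kg soil/day.  EF is days on-site per month;
#' AT defaults to 30.5 days (one month as conventionally printed for the
#' daily-rate model).
#'
#' All arguments are vectorised with recycling.
#'
#' @param C Contaminant concentration in soil, mg/kg (default 400).
#' @param IR_daily Daily soil + dust ingestion rate, mg/day (default 378).
#' @param days_per_month Exposure frequency, days/month (>= 0).
#' @param BW Body weight, kg (> 0).
#' @param AT_days Averaging time, days (> 0; default 30.5).
#' @param ED_months Exposure duration, months (default 1).
#' @return Tibble: `method`, `add_total` (mg/kgBW/day), `add_outdoor`,
#'   `add_indoor` (`NA` — this model has no indoor/outdoor split).
#' @export
#' @examples
#' add_method1(400, 378, days_per_month = 30.5, BW = 80)$add_total # 1.89e-3
add_method1 <- function(C = 400,
                        IR_daily = ingestion_rate_defaults()$daily_soil_dust,
                        days_per_month, BW,
                        AT_days = time_constants()$days_per_month_avg_method1,
                        ED_months = 1) {
  if (any(C <= 0) || any(IR_daily <= 0) || any(BW <= 0) || any(AT_days <= 0)) {
    stop("C, IR, BW and AT must be positive", call. = FALSE)
  }
  if (any(days_per_month < 0)) {
    stop("days_per_month must be >= 0", call. = FALSE)
  }
  add <- (C * IR_daily * MG_TO_KG * days_per_month * ED_months) /
    (BW * AT_days)
  tibble::tibble(method = 1L, add_total = add,
                 add_outdoor = NA_real_, add_indoor = NA_real_)
}

#' Average daily dose, hourly-ingestion-rate model (method 2)
#'
#' Outdoor (working) and indoor (non-working) doses are computed with
#' separate hourly rates and summed.  The indoor exposure frequency is the
#' complement of outdoor hours within the 730.8-hour month, exactly:
#' `ef_indoor = AT_hours - outdoor_hours`.  Each hourly dose is multiplied
#' by 24 to convert an average hourly dose to an average daily dose:
#'
#' `add = 24 x (C x IR_hourly x 1e-6 x EF_hours x ED) / (BW x AT_hours)`
#'
#' @param C Contaminant concentration, mg/kg.
#' @param hourly_outdoor,hourly_indoor Hourly ingestion rates, mg/h.
#' @param outdoor_hours_per_month Hours/month worked outdoors on-site
#'   (0 to `AT_hours`; values above the month length are an error, since
#'   the indoor complement would be negative).
#' @param BW Body weight, kg (> 0).
#' @param AT_hours Averaging time, hours (default 730.8).
#' @param ED_months Exposure duration, months (default 1).
#' @return Tibble: `method`, `add_total`, `add_outdoor`, `add_indoor`
#'   (mg/kgBW/day), `ef_outdoor_hours`, `ef_indoor_hours`.
#' @export
#' @examples
#' add_method2(400, 45.25, 1.375, outdoor_hours_per_month = 174, BW = 70)
add_method2 <- function(C = 400,
                        hourly_outdoor = hourly_outdoor_rate(),
                        hourly_indoor = hourly_indoor_rate(),
                        outdoor_hours_per_month, BW,
                        AT_hours = time_constants()$hours_per_month,
                        ED_months = 1) {
  if (any(C <= 0) || any(hourly_outdoor <= 0) || any(hourly_indoor <= 0) ||
      any(BW <= 0) || any(AT_hours <= 0)) {
    stop("C, rates, BW and AT must be positive", call. = FALSE)
  }
  if (any(outdoor_hours_per_month < 0 |
          outdoor_hours_per_month > AT_hours)) {
    stop("outdoor_hours_per_month must be in [0, ", AT_hours,
         "] (the indoor complement cannot be negative)", call. = FALSE)
  }
  ef_out <- outdoor_hours_per_month
  ef_in <- AT_hours - outdoor_hours_per_month
  add_out <- 24 * (C * hourly_outdoor * MG_TO_KG * ef_out * ED_months) /
    (BW * AT_hours)
  add_in <- 24 * (C * hourly_indoor * MG_TO_KG * ef_in * ED_months) /
    (BW * AT_hours)
  tibble::tibble(
    method = 2L,
    add_total = add_out + add_in,
    add_outdoor = add_out,
    add_indoor = add_in,
    ef_outdoor_hours = ef_out + numeric(length(add_out)),
    ef_indoor_hours = ef_in + numeric(length(add_out))
  )
}

#' Average daily dose, hourly task-specific model (method 3)
#'
#' Each meso-activity gets its own hourly ingestion rate (the baseline
#' outdoor rate times the task's scaling factor) applied to the task's
#' hours per month; all hours of the 730.8-hour month not accounted for by
#' the six tasks are assumed indoors at the indoor dust rate.  Per-task
#' and indoor doses use the same hourly dose equation as method 2
#' (including the x24 conversion) and are summed.
#'
#' When reported task hours sum above the month length (concurrent tasks),
#' the indoor complement is clamped at zero and the result is flagged
#' `indoor_hours_clamped`.
#'
#' @param C Contaminant concentration, mg/kg.
#' @param rate_set An [build_rate_set()] object supplying per-task rates
#'   and the indoor rate.
#' @param task_hours Task hours/month: a named numeric vector over (a
#'   subset of) [meso_activities()] for a single observation, or a data
#'   frame / matrix with one column per activity for many observations.
#'   Missing activities count as 0 hours.
#' @param BW Body weight, kg (> 0), recycled over observations.
#' @param AT_hours Averaging time, hours (default 730.8).
#' @param ED_months Exposure duration, months (default 1).
#' @param task_rates Optional override of the per-task rates: named
#'   vector, or a matrix (rows = observations, columns = activities) of
#'   mg/h — used by the Monte Carlo engine where rates are sampled per
#'   draw.
#' @param hourly_indoor Optional override of the indoor rate, mg/h.
#' @return Tibble: `method`, `add_total`, `add_outdoor` (sum over tasks),
#'   `add_indoor`, one `add_<activity>` column per meso-activity
#'   (mg/kgBW/day), `ef_indoor_hours`, and logical
#'   `indoor_hours_clamped`.
#' @export
#' @examples
#' rates <- build_rate_set()
#' add_method3(400, rates, c(transplanting = 20, weeding = 30), BW = 75)
add_method3 <- function(C = 400, rate_set = build_rate_set(), task_hours,
                        BW, AT_hours = time_constants()$hours_per_month,
                        ED_months = 1, task_rates = NULL,
                        hourly_indoor = NULL) {
  acts <- meso_activities()
  H <- task_hours_matrix(task_hours)
  n <- nrow(H)
  if (any(H < 0)) stop("task hours must be >= 0", call. = FALSE)
  if (is.null(task_rates)) task_rates <- rate_set$task_rates
  if (is.null(hourly_indoor)) hourly_indoor <- rate_set$hourly_indoor
  if (is.matrix(task_rates)) {
    R <- task_rates[, acts, drop = FALSE]
    stopifnot(nrow(R) == n)
  } else {
    R <- matrix(rep(task_rates[acts], each = n), nrow = n,
                dimnames = list(NULL, acts))
  }
  if (any(R <= 0) || any(C <= 0) || any(hourly_indoor <= 0) ||
      any(BW <= 0) || any(AT_hours <= 0)) {
    stop("C, rates, BW and AT must be positive", call. = FALSE)
  }
  total_task <- rowSums(H)
  ef_in <- pmax(0, AT_hours - total_task)
  clamped <- total_task > AT_hours
  denom <- BW * AT_hours
  add_tasks <- 24 * C * MG_TO_KG * ED_months * (H * R) / denom
  add_out <- rowSums(add_tasks)
  add_in <- 24 * (C * hourly_indoor * MG_TO_KG * ef_in * ED_months) / denom
  out <- tibble::tibble(
    method = 3L,
    add_total = add_out + add_in,
    add_outdoor = add_out,
    add_indoor = add_in,
    ef_indoor_hours = ef_in,
    indoor_hours_clamped = clamped
  )
  colnames(add_tasks) <- paste0("add_", acts)
  dplyr::bind_cols(out, tibble::as_tibble(add_tasks))
}

# normalize task-hours input to an n x 6 matrix in canonical activity order
task_hours_matrix <- function(task_hours) {
  acts <- meso_activities()
  if (is.numeric(task_hours) && !is.matrix(task_hours)) {
    unknown <- setdiff(names(task_hours), acts)
    if (length(unknown) > 0 || is.null(names(task_hours))) {
      stop("task_hours vector must be named by meso-activity", call. = FALSE)
    }
    full <- setNames(numeric(length(acts)), acts)
    full[names(task_hours)] <- task_hours
    return(matrix(full, nrow = 1, dimnames = list(NULL, acts)))
  }
  m <- as.matrix(as.data.frame(task_hours))
  present <- intersect(acts, colnames(m))
  out <- matrix(0, nrow = nrow(m), ncol = length(acts),
                dimnames = list(NULL, acts))
  out[, present] <- m[, present]
  out
}

#' Body weight for a grower
#'
#' Looks up the median body weight for the grower's sex and age bracket in
#' a `median_lookup`-mode body-weight table.  A grower-supplied body
#' weight (non-`NA` `body_weight`) overrides the lookup.  Vectorised.
#'
#' @param sex Character vector, "male"/"female".
#' @param age Ages in years.
#' @param table A body-weight table in `median_lookup` mode, e.g. from
#'   [generate_bodyweight_table()]: columns `sex`, `age_low`, `age_high`
#'   (bracket is `[age_low, age_high)`), `median_kg`.
#' @param body_weight Optional reported weights, kg; `NA` means use the
#'   lookup.
#' @return Body weights, kg.
#' @export
body_weight_for <- function(sex, age, table, body_weight = NULL) {
  stopifnot(is.data.frame(table),
            all(c("sex", "age_low", "age_high", "median_kg") %in%
                  names(table)))
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n)
  age <- rep_len(age, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hit <- table$sex == sex[i] & table$age_low <= age[i] &
      age[i] < table$age_high
    if (sum(hit) != 1) {
      stop("no unique body-weight bracket for sex=", sex[i], ", age=",
           age[i], call. = FALSE)
    }
    out[i] <- table$median_kg[hit]
  }
  if (!is.null(body_weight)) {
    body_weight <- rep_len(body_weight, n)
    out <- ifelse(is.na(body_weight), out, body_weight)
  }
  out
}

#' Annual aggregation of seasonal doses
#'
#' Aggregates exactly four seasonal ADDs (one per season, same grower and
#' method) into a cumulative annual index (the sum of the four seasonal
#' ADDs, the stacked-bar analogue) and the time-weighted mean seasonal
#' ADD.  The cumulative figure is an index, not a dose rate.
#'
#' @param seasonal Tibble with columns `grower_id`, `season`, `method`,
#'   `add_total`, covering all four seasons for one grower and one method.
#' @return One-row tibble: `grower_id`, `method`, `cumulative`,
#'   `mean_seasonal`.
#' @seealso [annualize_cohort()] for many growers at once.
#' @export
annualize <- function(seasonal) {
  stopifnot(all(c("grower_id", "season", "method", "add_total") %in%
                  names(seasonal)))
  if (length(unique(seasonal$grower_id)) != 1 ||
      length(unique(seasonal$method)) != 1) {
    stop("annualize() expects one grower and one method", call. = FALSE)
  }
  if (!setequal(seasonal$season, seasons()) || nrow(seasonal) != 4) {
    stop("annualize() requires exactly the four seasons", call. = FALSE)
  }
  tibble::tibble(
    grower_id = seasonal$grower_id[1],
    method = seasonal$method[1],
    cumulative = sum(seasonal$add_total),
    mean_seasonal = mean(seasonal$add_total)
  )
}

#' @rdname annualize
#' @param results Seasonal results for many growers/methods (as from
#'   [estimate_add()]); growers without all four seasons for a method are
#'   dropped.
#' @export
annualize_cohort <- function(results) {
  results |>
    dplyr::group_by(.data$grower_id, .data$method) |>
    dplyr::filter(dplyr::n() == 4, setequal(.data$season, seasons())) |>
    dplyr::summarise(cumulative = sum(.data$add_total),
                     mean_seasonal = mean(.data$add_total),
                     .groups = "drop")
}

#' Empirical per-grower dose estimation over a cohort
#'
#' Runs one of the three dose models for every grower x season in a
#' cohort: exposure factors are derived from the questionnaire tables
#' ([exposure_factors()], [task_hours()]); body weight is the grower's
#' reported weight when present, otherwise the sex/age-bracket median from
#' `bw_table`.
#'
#' @param cohort A [grower_cohort()].
#' @param method 1 (daily rate), 2 (hourly rates) or 3 (hourly
#'   task-specific rates).
#' @param rates An [build_rate_set()] object.
#' @param bw_table `median_lookup` body-weight table (see
#'   [body_weight_for()]).
#' @param C Contaminant concentration, mg/kg.
#' @return Tidy tibble: `grower_id`, `season`, `body_weight_kg`, `method`
#'   and the dose columns of the corresponding `add_method*()`.
#' @export
estimate_add <- function(cohort, method, rates = build_rate_set(),
                         bw_table = generate_bodyweight_table("median_lookup"),
                         C = 400) {
  stopifnot(is_grower_cohort(cohort), method %in% 1:3)
  if (nrow(cohort$growers) == 0) {
    stop("no records: the cohort has no growers", call. = FALSE)
  }
  ef <- exposure_factors(cohort)
  g <- cohort$growers
  idx <- match(ef$grower_id, g$grower_id)
  bw <- body_weight_for(g$sex[idx], g$age[idx], bw_table,
                        g$body_weight_kg[idx])
  res <- if (method == 1) {
    add_method1(C, rates$daily_soil_dust, ef$days_per_month_onsite, bw)
  } else if (method == 2) {
    add_method2(C, rates$hourly_outdoor, rates$hourly_indoor,
                ef$hours_per_month_onsite, bw)
  } else {
    th <- task_hours(cohort) |>
      tidyr::pivot_wider(names_from = "activity",
                         values_from = "hours_per_month",
                         values_fill = 0)
    th <- th[match(paste(ef$grower_id, ef$season),
                   paste(th$grower_id, th$season)), ]
    H <- task_hours_matrix(th[intersect(meso_activities(), names(th))])
    H[is.na(H)] <- 0
    add_method3(C, rates, H, bw)
  }
  dplyr::bind_cols(
    tibble::tibble(grower_id = ef$grower_id, season = ef$season,
                   body_weight_kg = bw),
    res
  )
}
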