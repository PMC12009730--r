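#' Monte Carlo samplers
#'
#' Building blocks of the population simulation:
#'
#' * `sample_body_weight()` draws body weights from a `weighted_sample`
#'   table with probability proportional to each row's population weight
#'   (weights are normalised at sampling time).
#' * `sample_exposure_factor()` is an empirical bootstrap: a uniform draw
#'   with replacement from the pool of questionnaire-reported values for
#'   one exposure factor in one season.
#' * `sample_task_rate()` perturbs a task's ingestion rate: the multiplier
#'   is uniform on `[scaling - halfwidth, scaling + halfwidth]` (e.g. a
#'   doubled task with halfwidth 0.2 samples between 1.8 and 2.2 times the
#'   baseline rate).
#'
#' @param table A `weighted_sample` body-weight table (columns
#'   `weight_kg`, `population_weight` > 0).
#' @param pool Nonempty numeric vector of reported values.
#' @param base_hourly Baseline hourly rate, mg/h.
#' @param scaling Central multiplier (> halfwidth).
#' @param halfwidth Half-width of the uniform multiplier band (>= 0).
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' set.seed(1)
#' range(sample_task_rate(45.25, 2, 0.2, 1000))  # within [81.45, 99.55]
sample_body_weight <- function(table, n = 1) {
  if (!is.data.frame(table) || nrow(table) == 0 ||
      !all(c("weight_kg", "population_weight") %in% names(table))) {
    stop("body-weight table must have >= 1 (weight_kg, population_weight) row",
         call. = FALSE)
  }
  if (any(table$population_weight <= 0)) {
    stop("population_weight must be > 0", call. = FALSE)
  }
  table$weight_kg[sample.int(nrow(table), n, replace = TRUE,
                             prob = table$population_weight)]
}

#' @rdname sample_body_weight
#' @param label Pool name used in the empty-pool error message.
#' @export
sample_exposure_factor <- function(pool, n = 1, label = "exposure factor") {
  if (length(pool) == 0) {
    stop("empty value pool for ", label, call. = FALSE)
  }
  # sample.int, not sample(): a length-1 numeric pool must not be
  # interpreted as 1:pool
  pool[sample.int(length(pool), n, replace = TRUE)]
}

#' @rdname sample_body_weight
#' @export
sample_task_rate <- function(base_hourly, scaling, halfwidth = 0.2, n = 1) {
  if (halfwidth < 0 || scaling - halfwidth <= 0) {
    stop("need 0 <= halfwidth < scaling so sampled multipliers stay positive",
         call. = FALSE)
  }
  base_hourly * runif(n, scaling - halfwidth, scaling + halfwidth)
}

#' Empirical exposure-factor pools from a cohort
#'
#' Extracts the per-season value pools the simulation bootstraps from:
#' days/month on-site (method 1), hours/month on-site (method 2), or
#' per-task hours/month (method 3).  Zeros (non-engagement) are kept by
#' default so the simulated population reflects engagement prevalence.
#'
#' @param cohort A [grower_cohort()].
#' @param method 1, 2 or 3.
#' @param season One of [seasons()].
#' @param include_zeros Keep zero values in the pools?
#' @return Numeric vector (methods 1-2) or named list of six numeric
#'   vectors (method 3).
#' @export
factor_pools <- function(cohort, method, season, include_zeros = TRUE) {
  stopifnot(is_grower_cohort(cohort), method %in% 1:3,
            season %in% seasons())
  drop0 <- function(x) if (include_zeros) x else x[x > 0]
  if (method %in% 1:2) {
    ef <- exposure_factors(cohort)
    ef <- ef[ef$season == season, ]
    pool <- if (method == 1) ef$days_per_month_onsite else
      ef$hours_per_month_onsite
    return(drop0(pool))
  }
  th <- task_hours(cohort)
  th <- th[th$season == season, ]
  lapply(setNames(meso_activities(), meso_activities()), function(a) {
    drop0(th$hours_per_month[th$activity == a])
  })
}

#' Configure a population simulation
#'
#' @param n_growers Number of simulated growers (default 5000).
#' @param seed Integer seed; identical configs give identical draws.
#' @param method 1, 2 or 3.
#' @param season One of [seasons()] (recorded in the output strata).
#' @param bw_table `weighted_sample` body-weight table (see
#'   [sample_body_weight()]).
#' @param pools Value pool(s) for the method/season, as returned by
#'   [factor_pools()]: a numeric vector for methods 1-2, a named list of
#'   six vectors for method 3.
#' @param rate_perturbation_halfwidth Uniform half-width for method 3 rate
#'   sampling (default 0.2; must stay below every scaling factor).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_growers = 5000, seed, method, season,
                              bw_table, pools,
                              rate_perturbation_halfwidth = 0.2) {
  stopifnot(n_growers > 0, method %in% 1:3, season %in% seasons())
  if (method == 3) {
    if (!is.list(pools) ||
        !all(meso_activities() %in% names(pools))) {
      stop("method 3 needs a named list of pools over all six activities",
           call. = FALSE)
    }
    empty <- names(pools)[vapply(pools, length, 1L) == 0]
    if (length(empty) > 0) {
      stop("empty value pool for season ", season, ", task(s): ",
           paste(empty, collapse = ", "), call. = FALSE)
    }
  } else if (length(pools) == 0) {
    stop("empty value pool for season ", season, call. = FALSE)
  }
  structure(
    list(n_growers = as.integer(n_growers), seed = as.integer(seed),
         method = as.integer(method), season = season,
         bw_table = bw_table, pools = pools,
         rate_perturbation_halfwidth = rate_perturbation_halfwidth),
    class = "simulation_config"
  )
}

#' Run a Monte Carlo dose simulation
#'
#' Simulates `n_growers` hypothetical growers for one season and one dose
#' method.  Each draw samples a body weight (population-weighted), the
#' method's exposure factor(s) from the empirical pools (independently per
#' task for method 3), and — for method 3 — a perturbed ingestion rate per
#' task; the corresponding `add_method*()` is then evaluated.  All
#' randomness flows from `config$seed`; the same config reproduces the
#' identical result.
#'
#' @param config A [simulation_config()].
#' @param rates An [build_rate_set()] object.
#' @param C Contaminant concentration, mg/kg.
#' @return Object of class `simulation_result`: list with `draws` (tibble
#'   of per-draw doses, sampled factors and body weights), `summary`
#'   (median, 5th/95th percentiles, mean of `add_total` — plus per-task
#'   doses for method 3), and the `config`.
#' @export
run_simulation <- function(config, rates = build_rate_set(), C = 400) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_growers
  bw <- sample_body_weight(config$bw_table, n)
  acts <- meso_activities()

  if (config$method == 1) {
    days <- sample_exposure_factor(config$pools, n, "days/month on-site")
    res <- add_method1(C, rates$daily_soil_dust, days, bw)
    res$ef_days_per_month <- days
  } else if (config$method == 2) {
    hours <- sample_exposure_factor(config$pools, n, "hours/month on-site")
    res <- add_method2(C, rates$hourly_outdoor, rates$hourly_indoor,
                       hours, bw)
  } else {
    H <- matrix(0, n, 6, dimnames = list(NULL, acts))
    R <- matrix(0, n, 6, dimnames = list(NULL, acts))
    for (a in acts) {
      H[, a] <- sample_exposure_factor(config$pools[[a]], n, a)
      R[, a] <- sample_task_rate(rates$hourly_outdoor,
                                 rates$scaling_factors[[a]],
                                 config$rate_perturbation_halfwidth, n)
    }
    res <- add_method3(C, rates, H, bw, task_rates = R)
  }
  res$body_weight_kg <- bw
  res$season <- config$season
  res$draw <- seq_len(n)

  qs <- function(x) {
    tibble::tibble(mean = mean(x), p5 = quantile(x, 0.05, names = FALSE),
                   median = median(x), p95 = quantile(x, 0.95,
                                                      names = FALSE))
  }
  summary <- dplyr::bind_cols(
    tibble::tibble(season = config$season, method = config$method,
                   component = "total", n = n),
    qs(res$add_total)
  )
  if (config$method == 3) {
    per_task <- dplyr::bind_rows(lapply(acts, function(a) {
      dplyr::bind_cols(
        tibble::tibble(season = config$season, method = 3L,
                       component = a, n = n),
        qs(res[[paste0("add_", a)]])
      )
    }))
    summary <- dplyr::bind_rows(summary, per_task)
  }
  structure(list(draws = res, summary = summary, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> method %d, %s, n = %d draws\n",
              x$config$method, x$config$season, x$config$n_growers))
  print(x$summary)
  invisible(x)
}
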