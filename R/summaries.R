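#' Descriptive summary of an exposure factor
#'
#' Order statistics in the reporting convention used throughout the
#' pipeline: optionally excluding zeros, so that box-plot style summaries
#' describe only growers who engaged in an activity.  Quantiles use linear
#' interpolation between closest order statistics (`stats::quantile`
#' type 7); the convention is configurable because box-plot quartile
#' rules differ between tools.
#'
#' @param values Numeric vector.
#' @param exclude_zeros Drop zero values before summarising?
#' @param stratum Optional label carried through to the output.
#' @param quantile_type Passed to [stats::quantile()].
#' @return One-row tibble: `stratum`, `n` (input size), `n_engaged`
#'   (values retained), `mean`, `median`, `q1`, `q3`, `min`, `max`, `p5`,
#'   `p95`, `zeros_excluded`.  When nothing is retained the statistics are
#'   `NA` (an explicit "no data" row, not zeros).
#' @export
#' @examples
#' summarize_factor(c(0, 0, 10, 20, 30), exclude_zeros = TRUE)
summarize_factor <- function(values, exclude_zeros = FALSE, stratum = NA_character_,
                             quantile_type = 7) {
  n <- length(values)
  kept <- if (exclude_zeros) values[values != 0] else values
  kept <- kept[!is.na(kept)]
  if (length(kept) == 0) {
    return(tibble::tibble(
      stratum = stratum, n = n, n_engaged = 0L,
      mean = NA_real_, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
      min = NA_real_, max = NA_real_, p5 = NA_real_, p95 = NA_real_,
      zeros_excluded = exclude_zeros
    ))
  }
  q <- quantile(kept, c(0.05, 0.25, 0.5, 0.75, 0.95),
                type = quantile_type, names = FALSE)
  tibble::tibble(
    stratum = stratum, n = n, n_engaged = length(kept),
    mean = mean(kept), median = q[3], q1 = q[2], q3 = q[4],
    min = min(kept), max = max(kept), p5 = q[1], p95 = q[5],
    zeros_excluded = exclude_zeros
  )
}

#' Rank-based k-sample comparison across groups
#'
#' Thin contract over the standard Kruskal-Wallis rank-sum test, used to
#' assess whether an exposure factor differs across seasons or
#' meso-activities.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 nonempty
#'   groups), or a data frame with columns `value` and `group`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_groups`, `n`,
#'   `method` (`"rank-based k-sample"`), `groups` (collapsed labels).
#' @export
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(101, 102, 103)))
compare_groups <- function(values_by_group) {
  if (is.data.frame(values_by_group)) {
    values_by_group <- split(values_by_group$value, values_by_group$group)
  }
  values_by_group <- values_by_group[lengths(values_by_group) > 0]
  if (length(values_by_group) < 2) {
    stop("compare_groups() needs >= 2 nonempty groups", call. = FALSE)
  }
  kt <- kruskal.test(values_by_group)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    n_groups = length(values_by_group),
    n = sum(lengths(values_by_group)),
    method = "rank-based k-sample",
    groups = paste(names(values_by_group), collapse = ",")
  )
}

#' Normality / lognormality test of a distribution
#'
#' Shapiro-Wilk test of `values` (family `"normal"`) or of `log(values)`
#' (family `"lognormal"`; requires strictly positive values).  A
#' zero-variance input is degenerate: it is reported explicitly with an
#' `NA` p-value and a note rather than raising.
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @param family `"normal"` or `"lognormal"`.
#' @return One-row tibble: `family`, `n`, `statistic`, `p_value`, `note`.
#' @export
test_distribution <- function(values, family = c("normal", "lognormal")) {
  family <- match.arg(family)
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    stop("test_distribution() needs n >= 3", call. = FALSE)
  }
  if (family == "lognormal") {
    if (any(values <= 0)) {
      stop("lognormal family requires strictly positive values",
           call. = FALSE)
    }
    values <- log(values)
  }
  if (diff(range(values)) == 0) {
    return(tibble::tibble(family = family, n = length(values),
                          statistic = NA_real_, p_value = NA_real_,
                          note = "degenerate: zero variance"))
  }
  sw <- shapiro.test(values)
  tibble::tibble(family = family, n = length(values),
                 statistic = unname(sw$statistic), p_value = sw$p.value,
                 note = NA_character_)
}

#' Correlation between two variables
#'
#' Delegated Pearson product-moment or Kendall's tau correlation, as used
#' for farm size vs hours worked (Pearson) and employment status vs hours
#' worked (Kendall, for the ordinal predictor).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"kendall"`.
#' @return One-row tibble: `method`, `n`, `estimate`, `p_value`.
#' @export
#' @examples
#' correlate(1:10, (1:10)^2, method = "kendall")
correlate <- function(x, y, method = c("pearson", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3) stop("correlate() needs n >= 3", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble::tibble(method = method, n = length(x),
                 estimate = unname(ct$estimate), p_value = ct$p.value)
}
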