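# Clinical associations of heterogeneity metrics: median-split
# stratification, the product-limit survival estimator and the two-sample
# log-rank test (implemented from first principles), rank-based group
# contrasts, and the within-sample CNA vs non-CNA region contrast.

#' Split samples into low/high strata at the cohort median
#'
#' Adds a `stratum` column (`"low"`/`"high"`) splitting on the named metric
#' at its cohort median. Values tied with the median go to the low stratum
#' by default (`ties = "high"` reverses this). Errors if all values are
#' identical or either stratum would be empty.
#'
#' @param summaries Tibble of per-sample values (e.g. from
#'   [summarize_sample()] rows).
#' @param metric Column name of the metric to split on.
#' @param ties `"low"` or `"high"`: where values equal to the median go.
#' @return `summaries` with a `stratum` factor column added.
#' @export
stratify_by_metric <- function(summaries, metric, ties = c("low", "high")) {
  ties <- match.arg(ties)
  check_columns(summaries, metric, "summaries")
  v <- summaries[[metric]]
  if (any(is.na(v))) {
    abort(sprintf("`%s` contains missing values", metric),
          class = "methylhet_input_error")
  }
  if (length(v) < 4L) {
    abort("need at least 4 samples with a defined metric to stratify",
          class = "methylhet_input_error")
  }
  med <- median(v)
  if (all(v == v[1])) {
    abort(sprintf("all `%s` values identical; cannot stratify", metric),
          class = "methylhet_stratification_error")
  }
  low <- if (ties == "low") v <= med else v < med
  if (!any(low) || all(low)) {
    abort(sprintf("median split of `%s` leaves an empty stratum", metric),
          class = "methylhet_stratification_error")
  }
  mutate(summaries,
         stratum = factor(if_else(low, "low", "high"),
                          levels = c("low", "high")))
}

#' Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit survival curve per stratum. At each distinct
#' event time `t`, the survival probability is multiplied by
#' `1 - d(t)/n(t)` where `d(t)` counts events and `n(t)` the subjects still
#' at risk (subjects censored exactly at `t` are counted at risk at `t`).
#'
#' @param records Tibble with columns `time` (>= 0), `event` (1 = event,
#'   0 = censored) and optionally `stratum`.
#' @return Object of class `"methylhet_km"`; use [tidy()] for the step
#'   table, [glance()] for per-stratum summaries, and
#'   [autoplot.methylhet_km()] to plot.
#' @export
kaplan_meier <- function(records) {
  check_columns(records, c("time", "event"), "records")
  if (any(records$time < 0)) {
    abort("negative survival time", class = "methylhet_input_error")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("`event` must be 0 or 1", class = "methylhet_input_error")
  }
  if (!"stratum" %in% names(records)) {
    records <- mutate(records, stratum = "all")
  }
  steps <- records |>
    group_by(.data$stratum) |>
    dplyr::group_modify(function(df, key) {
      times <- sort(unique(df$time))
      n_risk <- vapply(times, function(t) sum(df$time >= t), integer(1))
      n_event <- vapply(times, function(t) sum(df$time == t & df$event == 1),
                        integer(1))
      n_censor <- vapply(times, function(t) sum(df$time == t & df$event == 0),
                         integer(1))
      tibble(time = times, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor,
             survival = cumprod(1 - n_event / n_risk))
    }) |>
    ungroup()
  structure(list(steps = steps,
                 n = nrow(records),
                 strata = unique(as.character(records$stratum))),
            class = "methylhet_km")
}

#' @export
print.methylhet_km <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,",
      length(x$strata), "stratum/strata\n")
  print(x$steps, ...)
  invisible(x)
}

#' @describeIn kaplan_meier Step table: one row per distinct observed time
#'   and stratum with `n_risk`, `n_event`, `n_censor` and `survival`.
#' @param x A `methylhet_km` object.
#' @param ... Unused.
#' @export
tidy.methylhet_km <- function(x, ...) x$steps

#' @describeIn kaplan_meier Per-stratum summary: subjects, events, and
#'   median survival time (first time survival drops to 0.5 or below).
#' @export
glance.methylhet_km <- function(x, ...) {
  x$steps |>
    group_by(.data$stratum) |>
    summarise(n = .data$n_risk[1],
              n_events = sum(.data$n_event),
              median_survival = {
                hit <- .data$time[.data$survival <= 0.5]
                if (length(hit)) hit[1] else NA_real_
              },
              .groups = "drop")
}

#' Two-sample log-rank test
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' distinct event times: at each event time the expected event count in
#' stratum 1 is `d * n1 / n` and the variance the hypergeometric
#' `d (n1/n) (n2/n) (n - d)/(n - 1)`; the statistic
#' `(O1 - E1)^2 / V` is referred to chi-square with 1 df.
#'
#' @param records Tibble with `time`, `event` and a two-level `stratum`
#'   column.
#' @return Object of class `"methylhet_logrank"` with `statistic`,
#'   `p_value`, `observed`/`expected` per stratum; `NA` fields (with a
#'   warning) when the pooled data contain no events.
#' @export
log_rank_test <- function(records) {
  check_columns(records, c("time", "event", "stratum"), "records")
  strata <- sort(unique(as.character(records$stratum)))
  if (length(strata) != 2L) {
    abort("log-rank test needs exactly two strata",
          class = "methylhet_input_error")
  }
  if (any(records$time < 0)) {
    abort("negative survival time", class = "methylhet_input_error")
  }
  ev_times <- sort(unique(records$time[records$event == 1]))
  if (length(ev_times) == 0L) {
    warn("no events in either stratum; log-rank test undefined")
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          df = 1L, observed = c(NA_real_, NA_real_),
                          expected = c(NA_real_, NA_real_),
                          strata = strata, n = nrow(records)),
                     class = "methylhet_logrank"))
  }
  in1 <- records$stratum == strata[1]
  o1 <- 0; e1 <- 0; v <- 0; o2 <- 0; e2 <- 0
  for (t in ev_times) {
    at_risk <- records$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(records$time == t & records$event == 1)
    d1 <- sum(records$time == t & records$event == 1 & in1)
    o1 <- o1 + d1
    o2 <- o2 + (d - d1)
    e <- d * n1 / n
    e1 <- e1 + e
    e2 <- e2 + (d - e)
    if (n > 1) {
      v <- v + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
    }
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  structure(list(statistic = stat,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 df = 1L,
                 observed = c(o1, o2), expected = c(e1, e2),
                 strata = strata, n = nrow(records)),
            class = "methylhet_logrank")
}

#' @export
print.methylhet_logrank <- function(x, ...) {
  cat("Log-rank test (", paste(x$strata, collapse = " vs "), ")\n",
      sep = "")
  cat(sprintf("  chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @describeIn log_rank_test One row per stratum with observed and expected
#'   event counts.
#' @param x A `methylhet_logrank` object.
#' @param ... Unused.
#' @export
tidy.methylhet_logrank <- function(x, ...) {
  tibble(stratum = x$strata, observed = x$observed, expected = x$expected)
}

#' @describeIn log_rank_test One-row tibble with `statistic`, `df`,
#'   `p_value`, `n`.
#' @export
glance.methylhet_logrank <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value, n = x$n)
}

#' Rank-based two-group test on a per-sample metric
#'
#' Mann-Whitney U test of a per-sample summary metric between two groups
#' (exact for small tie-free groups, tie-corrected normal approximation
#' otherwise).
#'
#' @param summaries Per-sample tibble containing `metric` and the grouping
#'   column.
#' @param metric Metric column name.
#' @param group Grouping column name (exactly two levels, >= 2 samples
#'   each).
#' @param exact_max Largest per-group size for the exact null (default 8).
#' @return One-row tibble: group levels and sizes, group means, `mean_diff`
#'   (second level minus first in sorted order), `statistic` (U for the
#'   first level), `p_value`.
#' @export
metric_group_test <- function(summaries, metric, group = "group",
                              exact_max = 8L) {
  check_columns(summaries, c(metric, group), "summaries")
  v <- summaries[[metric]]
  g <- as.character(summaries[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  lv <- sort(unique(g))
  if (length(lv) != 2L || min(table(g)) < 2L) {
    abort("need exactly two groups with >= 2 samples each",
          class = "methylhet_input_error")
  }
  x <- v[g == lv[1]]; y <- v[g == lv[2]]
  mw <- mann_whitney(x, y, exact_max)
  tibble(group_1 = lv[1], group_2 = lv[2],
         n_1 = length(x), n_2 = length(y),
         mean_1 = mean(x), mean_2 = mean(y),
         mean_diff = mean(y) - mean(x),
         statistic = mw$statistic, p_value = mw$p_value)
}

#' Within-sample heterogeneity contrast inside vs outside CNA regions
#'
#' Assigns each locus to "inside" when its midpoint falls in any supplied
#' region (half-open intervals; `mode = "containment"` instead requires the
#' whole locus span inside a region), averages the chosen metric per sample
#' inside and outside, and runs a paired Wilcoxon signed-rank test across
#' samples on the inside-outside difference.
#'
#' @param metrics Per-sample per-locus metrics: [locus_metrics()] output
#'   with an added `sample_id` column.
#' @param regions Region tibble (`contig`, `start`, `end`; 0-based
#'   half-open), e.g. CNA segments from [read_bed()].
#' @param metric Metric column to contrast (default `"entropy_norm"`).
#' @param mode `"midpoint"` or `"containment"` locus-region assignment.
#' @return List with `by_sample` (one row per sample: `mean_inside`,
#'   `mean_outside`, `difference`, locus counts) and `test` (paired
#'   Wilcoxon statistic and p over samples with both means defined; `NA`
#'   when fewer than two such samples).
#' @export
cna_region_contrast <- function(metrics, regions,
                                metric = "entropy_norm",
                                mode = c("midpoint", "containment")) {
  mode <- match.arg(mode)
  check_columns(metrics, c("sample_id", "contig", "start", "end", metric),
                "metrics")
  check_columns(regions, c("contig", "start", "end"), "regions")
  inside <- rep(FALSE, nrow(metrics))
  if (nrow(regions) > 0L) {
    mid <- (metrics$start + metrics$end) / 2
    for (r in seq_len(nrow(regions))) {
      same <- metrics$contig == regions$contig[r]
      hit <- if (mode == "midpoint") {
        same & mid >= regions$start[r] & mid < regions$end[r]
      } else {
        same & metrics$start >= regions$start[r] &
          metrics$end <= regions$end[r]
      }
      inside <- inside | hit
    }
  }
  by_sample <- metrics |>
    mutate(inside = inside) |>
    group_by(.data$sample_id) |>
    summarise(
      n_inside = sum(.data$inside),
      n_outside = sum(!.data$inside),
      mean_inside = if (any(.data$inside)) {
        mean(.data[[metric]][.data$inside], na.rm = TRUE)
      } else NA_real_,
      mean_outside = if (any(!.data$inside)) {
        mean(.data[[metric]][!.data$inside], na.rm = TRUE)
      } else NA_real_,
      .groups = "drop") |>
    mutate(difference = .data$mean_inside - .data$mean_outside)
  paired <- filter(by_sample, !is.na(.data$difference))
  test <- if (nrow(paired) >= 2L && any(paired$difference != 0)) {
    ht <- suppressWarnings(
      wilcox.test(paired$mean_inside, paired$mean_outside, paired = TRUE))
    tibble(n_pairs = nrow(paired), statistic = unname(ht$statistic),
           p_value = ht$p.value,
           mean_difference = mean(paired$difference))
  } else {
    tibble(n_pairs = nrow(paired), statistic = NA_real_,
           p_value = NA_real_,
           mean_difference = if (nrow(paired)) mean(paired$difference)
                             else NA_real_)
  }
  list(by_sample = by_sample, test = test)
}
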