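# ggplot2 views of the main result types.

#' Plot a Kaplan-Meier fit
#'
#' Step survival curves per stratum with censoring ticks.
#'
#' @param object A `methylhet_km` fit from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.methylhet_km <- function(object, ...) {
  steps <- tidy(object)
  base <- steps |>
    group_by(.data$stratum) |>
    dplyr::group_modify(function(df, key) {
      bind_rows(tibble(time = 0, survival = 1),
                select(df, "time", "survival"))
    }) |>
    ungroup()
  censors <- filter(steps, .data$n_censor > 0L)
  ggplot2::ggplot(base, ggplot2::aes(.data$time, .data$survival,
                                     colour = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = censors, shape = 3, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  colour = "Stratum") +
    ggplot2::theme_minimal()
}

#' Plot a metagene methylation profile
#'
#' @param profile Result of [metagene_profile()].
#' @return A ggplot object with TSS/TES guides.
#' @export
plot_metagene_profile <- function(profile) {
  check_columns(profile, c("zone", "bin", "mean_methylation"), "profile")
  n_flank <- sum(profile$zone == "upstream")
  n_body <- sum(profile$zone == "body")
  ggplot2::ggplot(profile,
                  ggplot2::aes(.data$bin, .data$mean_methylation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(n_flank + 0.5,
                                       n_flank + n_body + 0.5),
                        linetype = "dashed") +
    ggplot2::annotate("text", x = n_flank + 0.5, y = 0, label = "TSS",
                      vjust = 1.5, size = 3) +
    ggplot2::annotate("text", x = n_flank + n_body + 0.5, y = 0,
                      label = "TES", vjust = 1.5, size = 3) +
    ggplot2::labs(x = "Bin (5' flank - scaled gene body - 3' flank)",
                  y = "Mean methylation") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a per-sample metric split by group
#'
#' Box plots with jittered points of a per-sample summary metric (mean PDR,
#' entropy, epipolymorphism, CV, ...) between two groups.
#'
#' @param summaries Per-sample tibble.
#' @param metric Metric column name.
#' @param group Grouping column name.
#' @return A ggplot object.
#' @export
plot_metric_by_group <- function(summaries, metric, group = "group") {
  check_columns(summaries, c(metric, group), "summaries")
  ggplot2::ggplot(summaries,
                  ggplot2::aes(.data[[group]], .data[[metric]],
                               fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
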