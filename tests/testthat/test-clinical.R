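test_that("median stratification splits the cohort with ties going low", {
  s <- tibble::tibble(sample_id = letters[1:4], m = c(1, 2, 3, 4))
  out <- stratify_by_metric(s, "m")
  expect_equal(as.character(out$stratum), c("low", "low", "high", "high"))

  tied <- tibble::tibble(m = c(1, 2, 2, 3))
  out2 <- stratify_by_metric(tied, "m")
  expect_equal(as.character(out2$stratum), c("low", "low", "low", "high"))
  out3 <- stratify_by_metric(tied, "m", ties = "high")
  expect_equal(as.character(out3$stratum), c("low", "high", "high", "high"))

  expect_error(stratify_by_metric(tibble::tibble(m = rep(2, 4)), "m"),
               class = "methylhet_stratification_error")
  expect_error(stratify_by_metric(tibble::tibble(m = 1:3), "m"),
               class = "methylhet_input_error")
})

test_that("product-limit estimator matches hand-worked and oracle fits", {
  all_censored <- tibble::tibble(time = c(1, 2, 3), event = 0)
  km <- kaplan_meier(all_censored)
  expect_true(all(tidy(km)$survival == 1))

  two <- tibble::tibble(time = c(1, 2), event = 1)
  steps <- tidy(kaplan_meier(two))
  expect_equal(steps$survival, c(0.5, 0))
  expect_equal(steps$n_risk, c(2L, 1L))

  # censored exactly at an event time stays at risk for that event
  mix <- tibble::tibble(time = c(1, 1, 2), event = c(1, 0, 1))
  s_mix <- tidy(kaplan_meier(mix))
  expect_equal(s_mix$survival[s_mix$time == 1], 2 / 3)

  set.seed(89)
  rec <- tibble::tibble(time = round(rexp(10, 0.2), 1),
                        event = rbinom(10, 1, 0.7))
  ours <- tidy(kaplan_meier(rec))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  expect_equal(ours$survival[ours$time %in% sf$time], sf$surv,
               tolerance = 1e-12)

  expect_error(kaplan_meier(tibble::tibble(time = -1, event = 1)),
               class = "methylhet_input_error")
})

test_that("log-rank test agrees with the survival package and is invariant", {
  same <- tibble::tibble(time = rep(c(1, 2, 3, 4), 2),
                         event = rep(c(1, 1, 0, 1), 2),
                         stratum = rep(c("a", "b"), each = 4))
  lr <- log_rank_test(same)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  set.seed(97)
  rec <- tibble::tibble(time = rexp(60, rate = rep(c(0.1, 0.25), each = 30)),
                        event = rbinom(60, 1, 0.8),
                        stratum = rep(c("lo", "hi"), each = 30))
  ours <- log_rank_test(rec)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                               data = rec)
  expect_equal(ours$statistic, sd_fit$chisq, tolerance = 1e-9)
  expect_equal(glance(ours)$p_value,
               pchisq(sd_fit$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-9)

  # invariance under time rescaling and label swap
  rescaled <- dplyr::mutate(rec, time = time * 7.3)
  expect_equal(log_rank_test(rescaled)$statistic, ours$statistic,
               tolerance = 1e-12)
  swapped <- dplyr::mutate(rec,
                           stratum = ifelse(stratum == "lo", "hi", "lo"))
  sw <- log_rank_test(swapped)
  expect_equal(sw$statistic, ours$statistic, tolerance = 1e-12)
  expect_equal(sw$observed, rev(ours$observed))

  no_events <- tibble::tibble(time = 1:4, event = 0,
                              stratum = rep(c("a", "b"), 2))
  expect_warning(res <- log_rank_test(no_events), "no events")
  expect_true(is.na(res$statistic))
})

test_that("metric group test is an exact rank-sum for small groups", {
  s <- tibble::tibble(m = c(1, 2, 3, 4, 5, 6),
                      group = rep(c("x", "y"), each = 3))
  res <- metric_group_test(s, "m")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$mean_diff, 3)
  expect_error(metric_group_test(
    tibble::tibble(m = 1:3, group = c("x", "x", "y")), "m"),
    class = "methylhet_input_error")
})

test_that("CNA contrast assigns loci by half-open midpoint overlap", {
  lm <- tibble::tibble(sample_id = rep(c("s1", "s2"), each = 3),
                       contig = "c1",
                       start = rep(c(0L, 100L, 200L), 2),
                       end = rep(c(60L, 160L, 260L), 2),
                       entropy_norm = c(0.8, 0.7, 0.1, 0.9, 0.6, 0.2))
  cna <- tibble::tibble(contig = "c1", start = 0L, end = 180L)
  res <- cna_region_contrast(lm, cna)
  expect_equal(res$by_sample$n_inside, c(2L, 2L))
  expect_equal(res$by_sample$mean_inside, c(0.75, 0.75))
  expect_equal(res$by_sample$mean_outside, c(0.1, 0.2))
  expect_true(all(res$by_sample$difference > 0))

  # midpoint exactly at the region start is inside (half-open)
  edge <- tibble::tibble(sample_id = "s1", contig = "c1",
                         start = 90L, end = 110L, entropy_norm = 0.5)
  at_start <- cna_region_contrast(edge,
                                  tibble::tibble(contig = "c1",
                                                 start = 100L, end = 200L))
  expect_equal(at_start$by_sample$n_inside, 1L)
  # ... and at the region end it is outside
  at_end <- cna_region_contrast(edge,
                                tibble::tibble(contig = "c1",
                                               start = 0L, end = 100L))
  expect_equal(at_end$by_sample$n_inside, 0L)

  # regions covering everything leave the outside mean undefined
  all_in <- cna_region_contrast(lm, tibble::tibble(contig = "c1",
                                                   start = 0L, end = 300L))
  expect_true(all(is.na(all_in$by_sample$mean_outside)))
  expect_true(is.na(all_in$test$p_value))

  # containment mode requires the whole locus span inside
  res_cont <- cna_region_contrast(lm, cna, mode = "containment")
  expect_equal(res_cont$by_sample$n_inside, c(2L, 2L))
  straddle <- cna_region_contrast(lm, tibble::tibble(contig = "c1",
                                                     start = 0L, end = 150L),
                                  mode = "containment")
  expect_equal(straddle$by_sample$n_inside, c(1L, 1L))
})

test_that("loci simulated with more clonal mixing inside CNA regions show it", {
  cfg <- simulation_config(n_loci = 80, seed = 101)
  ref <- simulate_reference(cfg)
  # first 40 loci get strong subclonal mixing, last 40 stay near-clonal
  d_hi <- simulate_locus_distributions(cfg, alpha = 3, clonality = 8,
                                       seed = 1)
  d_lo <- simulate_locus_distributions(cfg, alpha = 0.1, clonality = 2,
                                       seed = 2)
  d <- dplyr::bind_rows(dplyr::filter(d_hi, locus_id <= "L00040"),
                        dplyr::filter(d_lo, locus_id > "L00040"))
  er <- simulate_epireads(cfg, d)
  loci <- enumerate_loci(ref$cpg_index)
  lm <- locus_metrics(count_epialleles(er, loci)) |>
    dplyr::mutate(sample_id = "s1")
  boundary <- loci$end[40]
  cna <- tibble::tibble(contig = "sim_contig", start = 0L, end = boundary)
  res <- cna_region_contrast(lm, cna, metric = "entropy_norm")
  expect_gt(res$by_sample$mean_inside, res$by_sample$mean_outside)
})

test_that("broom and ggplot methods return well-formed objects", {
  rec <- tibble::tibble(time = c(2, 4, 6, 8, 3, 5, 7, 9),
                        event = c(1, 1, 0, 1, 1, 0, 1, 1),
                        stratum = rep(c("low", "high"), each = 4))
  km <- kaplan_meier(rec)
  g <- glance(km)
  expect_equal(nrow(g), 2L)
  expect_true(all(c("n", "n_events", "median_survival") %in% names(g)))
  p <- autoplot(km)
  expect_s3_class(p, "ggplot")
  lr <- log_rank_test(rec)
  expect_equal(nrow(tidy(lr)), 2L)
  expect_s3_class(plot_metric_by_group(
    tibble::tibble(m = rnorm(8), group = rep(c("a", "b"), 4)), "m"),
    "ggplot")
})
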