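# End-to-end orchestration: validated run configuration, the
# simulate -> extract -> metrics -> summaries -> associations pipeline with
# a checksummed manifest, and DMR direction bookkeeping.

#' Build and validate a pipeline run configuration
#'
#' Collects the per-stage parameter blocks and validates every one before
#' any work starts. The echo of the effective configuration written into
#' each run directory records every default actually used.
#'
#' @param simulation A [simulation_config()].
#' @param cohort A [cohort_spec()].
#' @param metrics List of heterogeneity-metric parameters: `step`,
#'   `min_reads`, `min_cpgs_per_read`, `min_reads_per_cpg`.
#' @param tiles List of tiling parameters: `tile_width`, `depth_threshold`.
#' @param association List with `metric`, the per-sample summary column used
#'   for survival stratification.
#' @return Validated list of class `"methylhet_config"`.
#' @export
methylhet_config <- function(simulation = simulation_config(),
                             cohort = cohort_spec(),
                             metrics = list(),
                             tiles = list(),
                             association = list()) {
  if (!inherits(simulation, "simulation_config")) {
    abort("`simulation` must be a simulation_config()",
          class = "methylhet_config_error")
  }
  if (!inherits(cohort, "cohort_spec")) {
    abort("`cohort` must be a cohort_spec()",
          class = "methylhet_config_error")
  }
  metrics <- utils::modifyList(
    list(step = 4L, min_reads = 10L, min_cpgs_per_read = 4L,
         min_reads_per_cpg = 11L), metrics)
  tiles <- utils::modifyList(
    list(tile_width = 5000L, depth_threshold = 10L), tiles)
  association <- utils::modifyList(list(metric = "mean_pdr"), association)
  check_number(metrics$step, "metrics$step", lower = 1)
  check_number(metrics$min_reads, "metrics$min_reads", lower = 0)
  check_number(metrics$min_cpgs_per_read, "metrics$min_cpgs_per_read",
               lower = 1)
  check_number(metrics$min_reads_per_cpg, "metrics$min_reads_per_cpg",
               lower = 1)
  check_number(tiles$tile_width, "tiles$tile_width", lower = 1)
  check_number(tiles$depth_threshold, "tiles$depth_threshold", lower = 0)
  ok_metrics <- c("mean_pdr", "mean_entropy", "mean_entropy_norm",
                  "mean_epipolymorphism", "cv")
  if (!association$metric %in% ok_metrics) {
    abort(sprintf("association$metric must be one of: %s",
                  paste(ok_metrics, collapse = ", ")),
          class = "methylhet_config_error")
  }
  structure(list(simulation = simulation, cohort = cohort,
                 metrics = metrics, tiles = tiles,
                 association = association),
            class = "methylhet_config")
}

run_stage <- function(stage, outdir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    abort(sprintf("pipeline stage `%s` failed: %s", stage,
                  conditionMessage(e)),
          class = "methylhet_pipeline_error")
  })
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates the reference and cohort, writes the simulated inputs, computes
#' beta tracks, global methylation, tile methylation and CV, per-locus
#' heterogeneity metrics and per-CpG PDR for every sample, runs the group
#' contrasts and the survival stratification + log-rank test, and writes
#' every stage output into `outdir` together with a machine-readable
#' manifest of MD5 checksums. Identical configuration (including the seed)
#' reproduces identical checksums. A failing stage writes a `FAILED` marker
#' naming the stage and keeps partial outputs.
#'
#' @param config A [methylhet_config()].
#' @param outdir Run directory (created; must be empty or absent).
#' @return Invisibly, the manifest tibble (`file`, `md5`, `bytes`).
#' @export
run_pipeline <- function(config, outdir) {
  if (!inherits(config, "methylhet_config")) {
    abort("`config` must be a methylhet_config()",
          class = "methylhet_config_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config),
                       file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  reference <- run_stage("simulate_reference", outdir,
                         simulate_reference(config$simulation))
  cohort <- run_stage("simulate_cohort", outdir,
                      simulate_cohort(config$cohort, config$simulation))
  run_stage("write_inputs", outdir,
            write_simulation(cohort, file.path(outdir, "inputs")))

  loci <- run_stage("enumerate_loci", outdir,
                    enumerate_loci(reference$cpg_index,
                                   step = config$metrics$step))
  sample_ids <- unique(cohort$epireads$sample_id)
  per_sample <- run_stage("per_sample_metrics", outdir, {
    purrr::map(sample_ids, function(sid) {
      er <- filter(cohort$epireads, .data$sample_id == sid) |>
        select(-"sample_id")
      beta <- compute_beta_track(er, reference$cpg_index)
      tiles <- tile_methylation(beta,
                                tile_width = config$tiles$tile_width,
                                depth_threshold = config$tiles$depth_threshold)
      counts <- count_epialleles(er, loci,
                                 min_reads = config$metrics$min_reads)
      lm <- locus_metrics(counts)
      track <- pdr_track(er,
                         min_cpgs_per_read = config$metrics$min_cpgs_per_read,
                         min_reads_per_cpg = config$metrics$min_reads_per_cpg)
      summary <- summarize_sample(lm, track, sample_id = sid) |>
        bind_cols(sample_cv(tiles)) |>
        mutate(global_methylation = global_methylation(beta))
      list(summary = summary,
           locus_metrics = mutate(lm, sample_id = sid, .before = 1))
    })
  })
  summaries <- bind_rows(purrr::map(per_sample, "summary"))
  all_locus_metrics <- bind_rows(purrr::map(per_sample, "locus_metrics"))
  readr::write_tsv(summaries, file.path(outdir, "sample_summaries.tsv"))
  readr::write_tsv(all_locus_metrics, file.path(outdir, "locus_metrics.tsv"))

  assoc <- run_stage("associations", outdir, {
    meta <- inner_join(cohort$metadata, summaries, by = "sample_id")
    tests <- bind_rows(purrr::map(
      c("mean_pdr", "mean_entropy_norm", "mean_epipolymorphism", "cv"),
      function(m) {
        mutate(metric_group_test(meta, m, "group"), metric = m, .before = 1)
      }))
    strat <- stratify_by_metric(meta, config$association$metric)
    km <- kaplan_meier(strat)
    lr <- log_rank_test(strat)
    readr::write_tsv(tests, file.path(outdir, "group_tests.tsv"))
    readr::write_tsv(tidy(km), file.path(outdir, "km_curves.tsv"))
    readr::write_tsv(mutate(glance(lr),
                            metric = config$association$metric,
                            .before = 1),
                     file.path(outdir, "survival_test.tsv"))
    invisible(NULL)
  })

  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(outdir, files))),
                     bytes = file.size(file.path(outdir, files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' DMR direction bookkeeping
#'
#' Counts hyper- and hypomethylated regions, their total, and the
#' percentage hypomethylated; with an annotation, also the proportion of
#' each direction class whose midpoint falls in each annotation feature
#' class.
#'
#' @param regions Tibble of differentially methylated regions with a
#'   `direction` column over `"hyper"`/`"hypo"`; for annotation overlap it
#'   also needs `contig`, `start`, `end` (0-based half-open).
#' @param annotation Optional feature tibble (`contig`, `start`, `end`,
#'   `name`), e.g. from [read_bed()], whose `name` column carries the
#'   feature class (promoter, intergenic, ...).
#' @return One-row tibble: `n_hyper`, `n_hypo`, `n_total`, `pct_hypo`
#'   (percentage, 0-100). With `annotation`, a `feature_props` list-column
#'   nests the per-direction per-feature overlap proportions.
#' @examples
#' summarize_dmrs(tibble::tibble(direction = rep(c("hyper", "hypo"), c(1, 3))))
#' @export
summarize_dmrs <- function(regions, annotation = NULL) {
  check_columns(regions, "direction", "regions")
  if (nrow(regions) == 0L) {
    abort("no regions supplied", class = "methylhet_input_error")
  }
  bad <- setdiff(unique(regions$direction), c("hyper", "hypo"))
  if (length(bad) || anyNA(regions$direction)) {
    abort(sprintf("direction labels must be 'hyper' or 'hypo' (found: %s)",
                  paste(bad, collapse = ", ")),
          class = "methylhet_input_error")
  }
  n_hyper <- sum(regions$direction == "hyper")
  n_hypo <- sum(regions$direction == "hypo")
  out <- tibble(n_hyper = n_hyper, n_hypo = n_hypo,
                n_total = n_hyper + n_hypo,
                pct_hypo = 100 * n_hypo / (n_hyper + n_hypo))
  if (!is.null(annotation)) {
    check_columns(regions, c("contig", "start", "end"), "regions")
    check_columns(annotation, c("contig", "start", "end", "name"),
                  "annotation")
    mid <- (regions$start + regions$end) / 2
    props <- purrr::map(sort(unique(annotation$name)), function(feat) {
      fa <- filter(annotation, .data$name == feat)
      hit <- rep(FALSE, nrow(regions))
      for (r in seq_len(nrow(fa))) {
        hit <- hit | (regions$contig == fa$contig[r] &
                        mid >= fa$start[r] & mid < fa$end[r])
      }
      tibble(feature = feat, direction = c("hyper", "hypo"),
             proportion = c(
               if (n_hyper) mean(hit[regions$direction == "hyper"]) else NA,
               if (n_hypo) mean(hit[regions$direction == "hypo"]) else NA))
    }) |> bind_rows()
    out$feature_props <- list(props)
  }
  out
}
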