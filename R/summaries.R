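# Genome-scale methylation summaries: global level, tile methylation with
# the "more than ten reads" eligibility rule, per-sample coefficient of
# variation over tiles, metagene profiles, and region-wise two-group
# comparison on user-supplied regions.

#' Tile the genome and average methylation per tile
#'
#' Partitions every contig into half-open, non-overlapping tiles of
#' `tile_width` bp and averages the per-CpG betas inside each (unweighted).
#' A tile is eligible when it contains at least one CpG and its read depth
#' exceeds `depth_threshold` (strictly more), where depth is either the mean
#' per-CpG depth in the tile (`rule = "mean_depth"`, the default) or the
#' minimum (`rule = "every_cpg"`, requiring every CpG above threshold).
#'
#' @param beta Beta track from [compute_beta_track()].
#' @param tile_width Tile width in bp (default 5000).
#' @param depth_threshold Depth that must be exceeded (default 10).
#' @param rule `"mean_depth"` or `"every_cpg"`.
#' @param lengths Named contig lengths; defaults to the attribute carried by
#'   the beta track.
#' @return Tibble with one row per tile: `contig`, `start`, `end` (0-based
#'   half-open), `n_cpgs`, `n_covered_cpgs`, `mean_depth`, `methylation`,
#'   `eligible`.
#' @export
tile_methylation <- function(beta, tile_width = 5000L, depth_threshold = 10L,
                             rule = c("mean_depth", "every_cpg"),
                             lengths = NULL) {
  rule <- match.arg(rule)
  check_columns(beta, c("contig", "pos", "n_total", "beta"), "beta")
  check_number(tile_width, "tile_width", lower = 1)
  check_number(depth_threshold, "depth_threshold", lower = 0)
  if (is.null(lengths)) lengths <- contig_lengths(beta)
  tiles <- purrr::imap(lengths, function(len, ctg) {
    starts <- seq.int(0L, len - 1L, by = tile_width)
    tibble(contig = ctg, start = as.integer(starts),
           end = as.integer(pmin(starts + tile_width, len)))
  }) |> bind_rows()
  per_cpg <- beta |>
    mutate(start = as.integer((.data$pos - 1L) %/% tile_width) *
             as.integer(tile_width)) |>
    group_by(.data$contig, .data$start) |>
    summarise(n_cpgs = dplyr::n(),
              n_covered_cpgs = sum(.data$n_total > 0L),
              mean_depth = mean(.data$n_total),
              min_depth = min(.data$n_total),
              methylation = if (any(!is.na(.data$beta))) {
                mean(.data$beta, na.rm = TRUE)
              } else NA_real_,
              .groups = "drop")
  tiles |>
    left_join(per_cpg, by = c("contig", "start")) |>
    mutate(n_cpgs = dplyr::coalesce(.data$n_cpgs, 0L),
           n_covered_cpgs = dplyr::coalesce(.data$n_covered_cpgs, 0L),
           mean_depth = dplyr::coalesce(.data$mean_depth, 0),
           min_depth = dplyr::coalesce(.data$min_depth, 0L),
           depth_stat = if (rule == "mean_depth") .data$mean_depth
                        else .data$min_depth,
           eligible = .data$n_cpgs > 0L &
             .data$depth_stat > depth_threshold &
             !is.na(.data$methylation)) |>
    select("contig", "start", "end", "n_cpgs", "n_covered_cpgs",
           "mean_depth", "methylation", "eligible") |>
    arrange(.data$contig, .data$start)
}

#' Coefficient of variation of tile methylation
#'
#' The interindividual heterogeneity statistic: sample standard deviation
#' (n-1 denominator) over mean of the methylation levels of the eligible
#' tiles. Undefined (NA) with fewer than two eligible tiles or a zero mean.
#'
#' @param tiles Tile track from [tile_methylation()].
#' @param sample_id Optional sample label.
#' @return One-row tibble: `cv`, `n_eligible_tiles` (plus `sample_id`).
#' @export
sample_cv <- function(tiles, sample_id = NULL) {
  check_columns(tiles, c("methylation", "eligible"), "tiles")
  vals <- tiles$methylation[tiles$eligible]
  cv <- if (length(vals) < 2L || mean(vals) == 0) {
    NA_real_
  } else {
    sd(vals) / mean(vals)
  }
  out <- tibble(cv = cv, n_eligible_tiles = length(vals))
  if (!is.null(sample_id)) out <- mutate(out, sample_id = sample_id,
                                         .before = 1)
  out
}

#' Global methylation level
#'
#' Mean methylation over covered CpGs: unweighted mean of betas by default,
#' or the read-pooled ratio of methylated to total calls with
#' `weighted = TRUE`.
#'
#' @param beta Beta track from [compute_beta_track()].
#' @param weighted Coverage-weight the mean?
#' @return Single value in `[0, 1]`, `NA` with no covered CpG.
#' @export
global_methylation <- function(beta, weighted = FALSE) {
  check_columns(beta, c("n_meth", "n_total", "beta"), "beta")
  covered <- filter(beta, .data$n_total > 0L)
  if (nrow(covered) == 0L) return(NA_real_)
  if (weighted) {
    sum(covered$n_meth) / sum(covered$n_total)
  } else {
    mean(covered$beta)
  }
}

#' Metagene methylation profile
#'
#' Maps CpG betas onto a fixed-width upstream flank, a length-scaled gene
#' body (TSS to TES) and a fixed-width downstream flank, flipping
#' minus-strand genes so that bins always run in transcription direction.
#' Each gene contributes its own per-bin means, and the profile is the
#' unweighted mean per bin across genes; bins without data are `NA`.
#'
#' @param beta Beta track from [compute_beta_track()].
#' @param genes Gene tibble with columns `contig`, `start`, `end` (0-based
#'   half-open) and `strand` (`+`/`-`), e.g. from [read_bed()].
#' @param flank_bp Flank width in bp (default 2000).
#' @param n_body_bins Bins across the gene body (default 100).
#' @param n_flank_bins Bins per flank (default 20).
#' @return Tibble with one row per bin: `zone` (upstream/body/downstream),
#'   `bin` (1-based global bin index in transcription direction),
#'   `mean_methylation`, `n_genes` contributing. Genes shorter than
#'   `n_body_bins` bp are skipped; their count is in the `n_genes_skipped`
#'   attribute.
#' @export
metagene_profile <- function(beta, genes, flank_bp = 2000L,
                             n_body_bins = 100L, n_flank_bins = 20L) {
  check_columns(genes, c("contig", "start", "end", "strand"), "genes")
  if (nrow(genes) == 0L) {
    abort("empty gene set", class = "methylhet_input_error")
  }
  covered <- filter(beta, !is.na(.data$beta))
  total_bins <- 2L * n_flank_bins + n_body_bins
  skipped <- 0L
  per_gene <- purrr::map(seq_len(nrow(genes)), function(g) {
    gs <- genes$start[g]; ge <- genes$end[g]
    width <- ge - gs
    if (width < n_body_bins) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    cp <- covered |>
      filter(.data$contig == genes$contig[g],
             .data$pos - 1L >= gs - flank_bp,
             .data$pos - 1L < ge + flank_bp)
    if (nrow(cp) == 0L) return(NULL)
    pos0 <- cp$pos - 1L
    minus <- identical(genes$strand[g], "-")
    # distance along transcription direction, 5' flank first
    rel <- if (minus) (ge - 1L) - pos0 else pos0 - gs
    zone_bin <- integer(length(rel))
    up <- rel < 0L
    body <- rel >= 0L & rel < width
    down <- rel >= width
    zone_bin[up] <- pmax(1L, n_flank_bins +
                           1L + as.integer(floor(rel[up] / flank_bp *
                                                   n_flank_bins)))
    zone_bin[body] <- n_flank_bins +
      1L + as.integer(floor(rel[body] / width * n_body_bins))
    zone_bin[down] <- pmin(total_bins,
                           n_flank_bins + n_body_bins +
                             1L + as.integer(floor((rel[down] - width) /
                                                     flank_bp * n_flank_bins)))
    tibble(bin = zone_bin, beta = cp$beta) |>
      group_by(.data$bin) |>
      summarise(gene_mean = mean(.data$beta), .groups = "drop")
  })
  contrib <- bind_rows(per_gene)
  profile <- tibble(bin = seq_len(total_bins)) |>
    mutate(zone = dplyr::case_when(
      .data$bin <= n_flank_bins ~ "upstream",
      .data$bin <= n_flank_bins + n_body_bins ~ "body",
      TRUE ~ "downstream")) |>
    left_join(contrib |>
                group_by(.data$bin) |>
                summarise(mean_methylation = mean(.data$gene_mean),
                          n_genes = dplyr::n(), .groups = "drop"),
              by = "bin") |>
    mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L)) |>
    select("zone", "bin", "mean_methylation", "n_genes")
  attr(profile, "n_genes_skipped") <- skipped
  profile
}

# Mann-Whitney U via stats::wilcox.test; exact null distribution when both
# groups are small (n <= exact_max) and tie-free, tie-corrected normal
# approximation otherwise.
mann_whitney <- function(x, y, exact_max = 8L) {
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = !use_exact))
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         exact = use_exact)
}

#' Region-wise two-group comparison of methylation
#'
#' For each region, compares the per-sample region means between the two
#' groups with the Mann-Whitney U test (exact for small tie-free groups,
#' tie-corrected normal approximation otherwise) and adjusts p-values across
#' regions with Benjamini-Hochberg.
#'
#' @param region_means Long tibble `(region_id, sample_id, value)` of
#'   per-sample per-region methylation means.
#' @param groups Tibble `(sample_id, group)` with exactly two group levels
#'   and at least two samples in each.
#' @param exact_max Largest per-group size for the exact null (default 8).
#' @return Tibble with one row per region: `region_id`, group means,
#'   `mean_diff` (second group level minus first, in sorted level order),
#'   `statistic` (U for the first level's sample), `p_value`, `q_value`.
#' @export
region_group_comparison <- function(region_means, groups, exact_max = 8L) {
  check_columns(region_means, c("region_id", "sample_id", "value"),
                "region_means")
  check_columns(groups, c("sample_id", "group"), "groups")
  lv <- sort(unique(as.character(groups$group)))
  if (length(lv) != 2L) {
    abort("`groups` must contain exactly two group levels",
          class = "methylhet_input_error")
  }
  sizes <- table(groups$group)
  if (any(sizes < 2L)) {
    abort("each group needs at least two samples",
          class = "methylhet_input_error")
  }
  dat <- inner_join(region_means, groups, by = "sample_id")
  out <- dat |>
    group_by(.data$region_id) |>
    dplyr::group_modify(function(df, key) {
      x <- df$value[df$group == lv[1]]
      y <- df$value[df$group == lv[2]]
      mw <- mann_whitney(x, y, exact_max)
      tibble(mean_1 = mean(x), mean_2 = mean(y),
             mean_diff = mean(y) - mean(x),
             statistic = mw$statistic, p_value = mw$p_value)
    }) |>
    ungroup() |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"))
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lv[2])
  out
}
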