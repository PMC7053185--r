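# Intratumor heterogeneity statistics over 4-CpG epiallele loci: proportion
# of discordant reads (PDR), epiallele entropy and epipolymorphism, with the
# coverage and CpG-count filters used throughout ("more than ten reads"
# style rules), plus per-sample aggregation.

#' Enumerate 4-CpG loci along the CpG index
#'
#' Walks each contig's CpG index in consecutive quartets at a configurable
#' step: step 4 (the default) gives non-overlapping loci, step 1 a sliding
#' window. Contigs with fewer than 4 CpGs yield no loci.
#'
#' @param cpg_index CpG reference tibble from [build_cpg_index()].
#' @param step CpGs advanced between successive loci (>= 1).
#' @return Tibble with columns `locus_id`, `contig`, `first_cpg` (CpG index
#'   of the first of the 4 CpGs), `start`, `end` (0-based half-open genomic
#'   span from the first C through the G of the last CpG).
#' @export
enumerate_loci <- function(cpg_index, step = 4L) {
  check_columns(cpg_index, c("contig", "pos", "index"), "cpg_index")
  check_number(step, "step", lower = 1)
  step <- as.integer(step)
  loci <- cpg_index |>
    group_by(.data$contig) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 4L) {
        return(tibble(first_cpg = integer(), start = integer(),
                      end = integer()))
      }
      first <- seq.int(1L, n - 3L, by = step)
      tibble(first_cpg = df$index[first],
             start = df$pos[first] - 1L,
             end = df$pos[first + 3L] + 1L)
    }) |>
    ungroup()
  loci |>
    mutate(locus_id = sprintf("%s:%d-%d", .data$contig, .data$start,
                              .data$end),
           .before = 1) |>
    select("locus_id", "contig", "first_cpg", "start", "end")
}

#' Count epiallele patterns per locus
#'
#' A read contributes to a locus only when it covers all four of the locus's
#' CpGs with non-missing states; its pattern is the 4-state string in CpG
#' order. Loci whose total contributing reads fall below `min_reads` are
#' dropped.
#'
#' @param epireads Epiread tibble.
#' @param loci Locus tibble from [enumerate_loci()].
#' @param min_reads Minimum reads per locus to keep it (default 10).
#' @return Tibble with one row per (locus, observed pattern): `locus_id`,
#'   `contig`, `first_cpg`, `start`, `end`, `pattern`, `n`, `total`.
#' @export
count_epialleles <- function(epireads, loci, min_reads = 10L) {
  check_columns(loci, c("locus_id", "contig", "first_cpg", "start", "end"),
                "loci")
  check_number(min_reads, "min_reads", lower = 0)
  cells <- loci |>
    select("locus_id", "contig", "first_cpg") |>
    tidyr::uncount(4L, .id = "offset") |>
    mutate(cpg_index = .data$first_cpg + .data$offset - 1L) |>
    select("locus_id", "contig", "cpg_index", "offset")
  calls <- expand_epireads(epireads, drop_missing = TRUE) |>
    inner_join(cells, by = c("contig", "cpg_index"),
               relationship = "many-to-many")
  if (nrow(calls) == 0L) {
    return(tibble(locus_id = character(), contig = character(),
                  first_cpg = integer(), start = integer(), end = integer(),
                  pattern = character(), n = integer(), total = integer()))
  }
  patterns <- calls |>
    group_by(.data$locus_id, .data$read_id) |>
    filter(dplyr::n() == 4L) |>
    arrange(.data$offset, .by_group = TRUE) |>
    summarise(pattern = paste(.data$state, collapse = ""),
              .groups = "drop")
  patterns |>
    count(.data$locus_id, .data$pattern, name = "n") |>
    group_by(.data$locus_id) |>
    mutate(total = sum(.data$n)) |>
    ungroup() |>
    filter(.data$total >= min_reads) |>
    inner_join(select(loci, "locus_id", "contig", "first_cpg",
                      "start", "end"),
               by = "locus_id") |>
    select("locus_id", "contig", "first_cpg", "start", "end",
           "pattern", "n", "total") |>
    arrange(.data$contig, .data$first_cpg, .data$pattern)
}

#' Epipolymorphism of an epiallele count vector
#'
#' `1 - sum(p_i^2)` over the epiallele frequencies `p_i = n_i / total`: the
#' Gini-Simpson diversity of the 16 four-CpG patterns, maximal (0.9375) at
#' the uniform distribution.
#'
#' @param counts Numeric vector of pattern counts (length <= 16; zeros may
#'   be omitted).
#' @return Value in `[0, 0.9375]`, or `NA` when `counts` sums to zero.
#' @examples
#' epipolymorphism(c(MMMM = 5, UUUU = 5))
#' @export
epipolymorphism <- function(counts) {
  total <- sum(counts)
  if (total <= 0) return(NA_real_)
  p <- counts / total
  1 - sum(p^2)
}

#' Epiallele entropy of an epiallele count vector
#'
#' Shannon entropy `-sum(p_i log2 p_i)` of the epiallele frequency
#' distribution, in bits (maximum 4 at the uniform distribution over the 16
#' patterns). The /4-normalised value is available via `normalized = TRUE`.
#'
#' @param counts Numeric vector of pattern counts.
#' @param normalized Return entropy divided by 4 (range `[0, 1]`)?
#' @return Entropy in bits (or normalised), `NA` when `counts` sums to zero.
#' @examples
#' epiallele_entropy(c(MMMM = 5, UUUU = 5))
#' @export
epiallele_entropy <- function(counts, normalized = FALSE) {
  total <- sum(counts)
  if (total <= 0) return(NA_real_)
  p <- counts / total
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (normalized) h / 4 else h
}

#' Per-locus heterogeneity metrics from epiallele counts
#'
#' Computes coverage, epiallele entropy (bits and /4-normalised),
#' epipolymorphism and the per-locus discordant-read fraction for every
#' locus in an epiallele count table.
#'
#' @param counts Long count table from [count_epialleles()].
#' @return Tibble with one row per locus: `locus_id`, `contig`, `first_cpg`,
#'   `start`, `end`, `coverage`, `entropy_bits`, `entropy_norm`,
#'   `epipolymorphism`, `discordant_fraction` (share of the locus's reads
#'   whose pattern contains both M and U).
#' @export
locus_metrics <- function(counts) {
  check_columns(counts, c("locus_id", "pattern", "n"), "counts")
  disc <- discordant_patterns()
  has_coords <- all(c("contig", "first_cpg", "start", "end") %in%
                      names(counts))
  out <- counts |>
    group_by(.data$locus_id) |>
    summarise(coverage = sum(.data$n),
              entropy_bits = epiallele_entropy(.data$n),
              epipolymorphism = epipolymorphism(.data$n),
              discordant_fraction =
                sum(.data$n[.data$pattern %in% disc]) / sum(.data$n),
              .groups = "drop") |>
    mutate(entropy_norm = .data$entropy_bits / 4,
           .after = "entropy_bits")
  if (has_coords) {
    out <- counts |>
      distinct(.data$locus_id, .data$contig, .data$first_cpg,
               .data$start, .data$end) |>
      inner_join(out, by = "locus_id") |>
      arrange(.data$contig, .data$first_cpg)
  }
  out
}

#' Per-CpG proportion of discordant reads (PDR)
#'
#' A read is eligible when it carries at least `min_cpgs_per_read`
#' non-missing CpG states; an eligible read is discordant when those states
#' contain both M and U. Per CpG, PDR is the fraction of discordant reads
#' among the eligible reads covering it (with a non-missing call), and is
#' defined only where the eligible-read count reaches `min_reads_per_cpg`
#' (default 11, i.e. strictly more than ten reads).
#'
#' @param epireads Epiread tibble.
#' @param min_cpgs_per_read Minimum non-missing CpG states for a read to be
#'   eligible (default 4).
#' @param min_reads_per_cpg Minimum eligible reads for a CpG's PDR to be
#'   defined (default 11).
#' @return Tibble with one row per covered CpG: `contig`, `cpg_index`,
#'   `n_eligible`, `n_discordant`, `pdr` (`NA` below the coverage rule).
#'   Attributes `n_eligible_reads` and `n_discordant_reads` carry the
#'   read-level totals used by the pooled sample-level PDR.
#' @export
pdr_track <- function(epireads, min_cpgs_per_read = 4L,
                      min_reads_per_cpg = 11L) {
  check_number(min_cpgs_per_read, "min_cpgs_per_read", lower = 1)
  check_number(min_reads_per_cpg, "min_reads_per_cpg", lower = 1)
  calls <- expand_epireads(epireads, drop_missing = TRUE)
  read_info <- calls |>
    group_by(.data$read_id, .data$contig) |>
    summarise(n_states = dplyr::n(),
              discordant = any(.data$state == "M") &
                any(.data$state == "U"),
              .groups = "drop") |>
    filter(.data$n_states >= min_cpgs_per_read)
  track <- calls |>
    inner_join(read_info, by = c("read_id", "contig")) |>
    group_by(.data$contig, .data$cpg_index) |>
    summarise(n_eligible = dplyr::n(),
              n_discordant = sum(.data$discordant),
              .groups = "drop") |>
    mutate(pdr = if_else(.data$n_eligible >= min_reads_per_cpg,
                         .data$n_discordant / .data$n_eligible,
                         NA_real_))
  attr(track, "n_eligible_reads") <- nrow(read_info)
  attr(track, "n_discordant_reads") <- sum(read_info$discordant)
  track
}

#' Sample-level PDR from a per-CpG track
#'
#' `"per_cpg"` (default) averages PDR over the CpGs where it is defined;
#' `"pooled"` is the ratio of discordant to eligible reads, each read
#' counted once.
#'
#' @param track Result of [pdr_track()].
#' @param mode `"per_cpg"` or `"pooled"`.
#' @return Single numeric value (`NA` when undefined).
#' @export
sample_pdr <- function(track, mode = c("per_cpg", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "per_cpg") {
    vals <- track$pdr[!is.na(track$pdr)]
    if (length(vals) == 0L) return(NA_real_)
    mean(vals)
  } else {
    n_elig <- attr(track, "n_eligible_reads")
    if (is.null(n_elig) || n_elig == 0L) return(NA_real_)
    attr(track, "n_discordant_reads") / n_elig
  }
}

#' Per-sample heterogeneity summary
#'
#' Unweighted means of the per-locus entropy and epipolymorphism over
#' eligible loci and of PDR over CpGs where it is defined, with the
#' eligibility counts.
#'
#' @param metrics Per-locus metrics from [locus_metrics()].
#' @param track Per-CpG PDR track from [pdr_track()] (optional).
#' @param sample_id Optional sample label to prepend.
#' @param pdr_mode Passed to [sample_pdr()].
#' @return One-row tibble: `mean_pdr`, `mean_entropy` (bits),
#'   `mean_entropy_norm`, `mean_epipolymorphism`, `n_eligible_loci`,
#'   `n_eligible_cpgs`. Undefined means are `NA`.
#' @export
summarize_sample <- function(metrics, track = NULL, sample_id = NULL,
                             pdr_mode = "per_cpg") {
  n_loci <- if (is.null(metrics)) 0L else nrow(metrics)
  mean_or_na <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  out <- tibble(
    mean_pdr = if (is.null(track)) NA_real_ else sample_pdr(track, pdr_mode),
    mean_entropy = mean_or_na(metrics$entropy_bits[!is.na(metrics$entropy_bits)]),
    mean_entropy_norm = mean_or_na(metrics$entropy_norm[!is.na(metrics$entropy_norm)]),
    mean_epipolymorphism =
      mean_or_na(metrics$epipolymorphism[!is.na(metrics$epipolymorphism)]),
    n_eligible_loci = n_loci,
    n_eligible_cpgs = if (is.null(track)) 0L else sum(!is.na(track$pdr)))
  if (!is.null(sample_id)) {
    out <- mutate(out, sample_id = sample_id, .before = 1)
  }
  out
}

#' Write per-locus metrics and locus spans to disk
#'
#' @param metrics Per-locus metrics from [locus_metrics()].
#' @param tsv_path Output TSV path.
#' @param bed_path Optional BED path of locus spans.
#' @return Invisibly, the paths written.
#' @export
write_locus_metrics <- function(metrics, tsv_path, bed_path = NULL) {
  readr::write_tsv(metrics, tsv_path)
  written <- tsv_path
  if (!is.null(bed_path)) {
    readr::write_tsv(select(metrics, "contig", "start", "end", "locus_id"),
                     bed_path, col_names = FALSE)
    written <- c(written, bed_path)
  }
  invisible(written)
}
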