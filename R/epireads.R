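# CpG coordinate frame and conversion of bisulfite alignments (or epiread
# text) into per-read CpG state vectors.
#
# Conventions: CpG positions are 1-based coordinates of the C of each
# forward-strand CG dinucleotide; evidence from both strands collapses onto
# that C. Interval tables (BED-style tibbles) use 0-based half-open
# start/end. Epiread state strings are over {M, U, .} with '.' = missing.

EPIREAD_TSV_VERSION <- "#methylhet_epiread_v1"

#' Build the CpG coordinate frame from a genome
#'
#' Finds every forward-strand CG dinucleotide per contig (case-insensitive)
#' and assigns each a per-contig CpG index. This index is the coordinate
#' frame for all downstream per-read and per-CpG computations.
#'
#' @param genome A FASTA file path, a `Biostrings::DNAStringSet`, or a named
#'   character vector of sequences.
#' @return Tibble with columns `contig`, `pos` (1-based position of the C),
#'   `index` (1-based CpG index within the contig), carrying the contig
#'   lengths in the `contig_lengths` attribute. Contigs without CpGs
#'   contribute no rows but keep their length entry.
#' @examples
#' build_cpg_index(c(c1 = "ACGTCGCG"))
#' @export
build_cpg_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      abort("character genomes must be named by contig",
            class = "methylhet_format_error")
    }
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) {
    abort("`genome` must be a FASTA path, DNAStringSet or named character",
          class = "methylhet_format_error")
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  hits <- Biostrings::vmatchPattern("CG", genome)
  rows <- purrr::map2(names(genome), as.list(hits), function(ctg, ir) {
    tibble(contig = ctg,
           pos = as.integer(Biostrings::start(ir)),
           index = seq_along(ir))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(contig = character(), pos = integer(), index = integer())
  }
  attr(out, "contig_lengths") <-
    setNames(Biostrings::width(genome), names(genome))
  out
}

#' Contig lengths attached to a CpG index
#'
#' @param cpg_index A CpG reference tibble from [build_cpg_index()].
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(cpg_index) {
  lens <- attr(cpg_index, "contig_lengths")
  if (is.null(lens)) {
    abort("cpg_index carries no contig_lengths attribute",
          class = "methylhet_input_error")
  }
  lens
}

#' Expand epireads into one row per CpG call
#'
#' @param epireads Epiread tibble (`read_id`, `contig`, `first_cpg_index`,
#'   `states`; extra columns such as `sample_id` are carried along).
#' @param drop_missing Drop `.` (missing) calls? Default TRUE.
#' @return Tibble with columns of `epireads` minus `states`, plus
#'   `cpg_index` and `state`.
#' @export
expand_epireads <- function(epireads, drop_missing = TRUE) {
  check_columns(epireads, c("read_id", "contig", "first_cpg_index", "states"),
                "epireads")
  lens <- nchar(epireads$states)
  long <- epireads[rep.int(seq_len(nrow(epireads)), lens), ] |>
    mutate(cpg_index = .data$first_cpg_index + sequence(lens) - 1L,
           state = unlist(strsplit(epireads$states, "", fixed = TRUE),
                          use.names = FALSE)) |>
    select(-"states", -"first_cpg_index")
  if (drop_missing) long <- filter(long, .data$state != ".")
  long
}

#' Extract epireads from bisulfite alignments
#'
#' Lays each aligned read's sequence into reference space and calls a
#' methylation state at every reference CpG the aligned portion overlaps.
#' Top-strand (forward-flag) reads are read at the C of the CpG: C is called
#' methylated (`M`), T unmethylated (`U`), anything else (including a
#' deletion) missing (`.`). Reverse-flag reads follow the bottom-strand
#' bisulfite convention and are read at the G: G is `M`, A is `U`. Mates
#' sharing a query name are merged into one fragment-level epiread; where
#' both mates cover a CpG the first mate's call wins. Reads overlapping no
#' CpG are dropped; unmapped, secondary and supplementary records are
#' skipped and counted.
#'
#' @param alignments Path to a BAM or SAM file (SAM is converted on the fly),
#'   or a `GenomicAlignments::GAlignments` object with `qname`, `flag` and
#'   `seq` metadata columns.
#' @param cpg_index CpG reference tibble from [build_cpg_index()] for the
#'   same genome.
#' @return Epiread tibble (`read_id`, `contig`, `first_cpg_index`, `states`),
#'   with an attribute `skipped` counting records skipped per reason.
#' @export
extract_epireads <- function(alignments, cpg_index) {
  if (is.character(alignments)) {
    path <- alignments
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      dest <- tempfile(fileext = "")
      path <- Rsamtools::asBam(path, destination = dest,
                               overwrite = TRUE, indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
    rec <- Rsamtools::scanBam(path, param = param)[[1]]
  } else if (methods::is(alignments, "GAlignments")) {
    md <- S4Vectors::mcols(alignments)
    rec <- list(qname = md$qname, flag = md$flag,
                rname = GenomicAlignments::seqnames(alignments),
                pos = GenomicAlignments::start(alignments),
                cigar = GenomicAlignments::cigar(alignments),
                seq = md$seq)
  } else {
    abort("`alignments` must be a BAM/SAM path or a GAlignments object",
          class = "methylhet_input_error")
  }
  flag <- rec$flag
  unmapped <- bitwAnd(flag, 4L) > 0L | is.na(rec$pos)
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  bad_cigar <- is.na(rec$cigar) | rec$cigar == "*"
  keep <- !(unmapped | secondary | supplementary | bad_cigar)
  skipped <- c(unmapped = sum(unmapped),
               secondary = sum(secondary & !unmapped),
               supplementary = sum(supplementary & !unmapped & !secondary),
               bad_cigar = sum(bad_cigar & !unmapped & !secondary &
                                 !supplementary))
  empty <- tibble(read_id = character(), contig = character(),
                  first_cpg_index = integer(), states = character())
  if (!any(keep)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  qname <- as.character(rec$qname)[keep]
  flag <- flag[keep]
  contig <- as.character(rec$rname)[keep]
  pos <- rec$pos[keep]
  cigar <- rec$cigar[keep]
  seqs <- rec$seq[keep]
  # lay read bases into reference space: deletions/skips become '-',
  # insertions and clips are removed
  laid <- as.character(GenomicAlignments::sequenceLayer(
    seqs, cigar, from = "query", to = "reference"))
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  reverse <- bitwAnd(flag, 16L) > 0L

  calls <- vector("list", length(qname))
  for (i in seq_along(qname)) {
    idx <- cpg_index[cpg_index$contig == contig[i], ]
    if (nrow(idx) == 0L) next
    # bottom-strand evidence sits on the G, one base right of the C
    probe <- if (reverse[i]) idx$pos + 1L else idx$pos
    inside <- probe >= pos[i] & probe <= pos[i] + ref_width[i] - 1L
    if (!any(inside)) next
    off <- probe[inside] - pos[i] + 1L
    base <- substring(laid[i], off, off)
    state <- if (reverse[i]) {
      dplyr::case_match(base, "G" ~ "M", "A" ~ "U", .default = ".")
    } else {
      dplyr::case_match(base, "C" ~ "M", "T" ~ "U", .default = ".")
    }
    calls[[i]] <- tibble(read_id = qname[i], contig = contig[i],
                         cpg_index = idx$index[inside], state = state,
                         mate_order = i)
  }
  calls <- bind_rows(calls)
  if (is.null(calls) || nrow(calls) == 0L) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }
  # merge mates: first mate (file order) wins on CpGs covered by both
  merged <- calls |>
    arrange(.data$read_id, .data$cpg_index, .data$mate_order) |>
    distinct(.data$read_id, .data$contig, .data$cpg_index,
             .keep_all = TRUE) |>
    group_by(.data$read_id, .data$contig) |>
    summarise(first_cpg_index = min(.data$cpg_index),
              states = {
                span <- min(.data$cpg_index):max(.data$cpg_index)
                st <- rep(".", length(span))
                st[match(.data$cpg_index, span)] <- .data$state
                paste(st, collapse = "")
              },
              .groups = "drop")
  out <- merged |>
    mutate(states = stringr::str_remove(.data$states, "^\\.+"),
           trim = nchar(stringr::str_extract(merged$states, "^\\.*")),
           first_cpg_index = .data$first_cpg_index + .data$trim,
           states = stringr::str_remove(.data$states, "\\.+$")) |>
    filter(nchar(.data$states) > 0L) |>
    select("read_id", "contig", "first_cpg_index", "states") |>
    arrange(.data$contig, .data$first_cpg_index, .data$read_id)
  attr(out, "skipped") <- skipped
  out
}

#' Per-CpG methylation levels (beta track)
#'
#' Counts methylated and total (M + U) calls at every reference CpG and
#' computes beta = methylated / total. CpGs with no coverage keep `NA` beta.
#'
#' @param epireads Epiread tibble.
#' @param cpg_index CpG reference tibble.
#' @return Tibble with one row per reference CpG: `contig`, `pos`, `index`,
#'   `n_meth`, `n_total`, `beta`.
#' @export
compute_beta_track <- function(epireads, cpg_index) {
  check_columns(cpg_index, c("contig", "pos", "index"), "cpg_index")
  calls <- expand_epireads(epireads) |>
    group_by(.data$contig, .data$cpg_index) |>
    summarise(n_meth = sum(.data$state == "M"),
              n_total = dplyr::n(), .groups = "drop")
  out <- cpg_index |>
    left_join(calls, by = c(contig = "contig", index = "cpg_index")) |>
    mutate(n_meth = dplyr::coalesce(.data$n_meth, 0L),
           n_total = dplyr::coalesce(.data$n_total, 0L),
           beta = if_else(.data$n_total > 0L,
                          .data$n_meth / .data$n_total, NA_real_))
  attr(out, "contig_lengths") <- attr(cpg_index, "contig_lengths")
  out
}

#' Write / read the epiread TSV dialect
#'
#' Tab-separated columns `contig`, `first_cpg_index`, `read_id`, `states`
#' (string over `M`, `U`, `.`), preceded by a format-version line. The
#' round trip is lossless.
#'
#' @param epireads Epiread tibble.
#' @param path File path.
#' @return `write_epiread_tsv` returns `path` invisibly; `read_epiread_tsv`
#'   returns the epiread tibble.
#' @export
write_epiread_tsv <- function(epireads, path) {
  check_columns(epireads, c("read_id", "contig", "first_cpg_index", "states"),
                "epireads")
  writeLines(EPIREAD_TSV_VERSION, path)
  readr::write_tsv(select(epireads, "contig", "first_cpg_index",
                          "read_id", "states"),
                   path, col_names = TRUE, append = TRUE)
  invisible(path)
}

#' @rdname write_epiread_tsv
#' @export
read_epiread_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, EPIREAD_TSV_VERSION)) {
    abort(sprintf("%s: not an epiread TSV (missing %s header)",
                  path, EPIREAD_TSV_VERSION),
          class = "methylhet_format_error")
  }
  df <- readr::read_tsv(path, skip = 1L, col_types = readr::cols(
    contig = readr::col_character(),
    first_cpg_index = readr::col_integer(),
    read_id = readr::col_character(),
    states = readr::col_character()))
  bad <- which(!grepl("^[MU.]+$", df$states) |
                 grepl("^\\.", df$states) | grepl("\\.$", df$states))
  if (length(bad)) {
    abort(sprintf(
      "%s: invalid states string %s at line %d (allowed: M, U, '.'; ends must not be missing)",
      path, df$states[bad[1]], bad[1] + 2L),
      class = "methylhet_format_error")
  }
  select(df, "read_id", "contig", "first_cpg_index", "states")
}

#' Write a beta track as bedGraph
#'
#' One line per covered CpG: `chrom, start, start+1, beta` with 0-based
#' half-open coordinates at the C of the CpG.
#'
#' @param beta Beta track from [compute_beta_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_beta_bedgraph <- function(beta, path) {
  check_columns(beta, c("contig", "pos", "beta"), "beta")
  covered <- filter(beta, !is.na(.data$beta))
  readr::write_tsv(tibble(chrom = covered$contig,
                          start = covered$pos - 1L,
                          end = covered$pos,
                          beta = covered$beta),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file as a tibble
#'
#' Reads the first three to six BED columns (`contig`, `start`, `end`,
#' optionally `name`, `score`, `strand`), keeping the 0-based half-open
#' convention.
#'
#' @param path BED file path.
#' @return Tibble of intervals.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        col_types = readr::cols(.default = "c"))
  if (ncol(df) < 3L) {
    abort(sprintf("%s: BED needs at least 3 columns", path),
          class = "methylhet_format_error")
  }
  names(df)[1:3] <- c("contig", "start", "end")
  extra <- c("name", "score", "strand")
  n_extra <- min(ncol(df) - 3L, 3L)
  if (n_extra > 0L) names(df)[4:(3L + n_extra)] <- extra[seq_len(n_extra)]
  df |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    as_tibble()
}
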