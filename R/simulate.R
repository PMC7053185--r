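# Synthetic bisulfite-read generator.
#
# Every locus is a quartet of neighbouring CpGs whose single-molecule
# methylation patterns (epialleles) are drawn from a clonal mixture: a small
# number of clone patterns mixed with Dirichlet proportions. Reads observe a
# pattern through an independent per-CpG state-flip error channel (bisulfite
# conversion failure / sequencing error). Closed-form oracles for the
# heterogeneity metrics on the error-perturbed distribution make the whole
# pipeline testable without sequencing data.

#' Simulation configuration
#'
#' Parameters of the synthetic bisulfite-read generator. Defaults emulate a
#' WGBS tumour sample: mean coverage near the 25x of a typical whole-genome
#' bisulfite run, overdispersed read depth, a 1% per-CpG state-flip error
#' (incomplete conversion plus sequencing error), and a two-clone epiallele
#' mixture per locus.
#'
#' @param n_loci Number of 4-CpG loci on the synthetic contig.
#' @param cpg_spacing Mean distance in bp between neighbouring CpGs within a
#'   locus (minimum 2; spacing is jittered around the mean).
#' @param locus_spacing Mean distance in bp between the last CpG of one locus
#'   and the first CpG of the next.
#' @param coverage_mean Expected number of reads per locus (> 0).
#' @param coverage_dispersion Negative-binomial size parameter; larger means
#'   closer to Poisson. `Inf` gives exactly Poisson coverage.
#' @param coverage_model One of `"nbinom"`, `"poisson"`, `"fixed"`. `"fixed"`
#'   gives every locus exactly `round(coverage_mean)` reads (useful for
#'   checking sampling-theory identities at a known depth).
#' @param error_rate Per-CpG probability in `[0, 0.5)` that a read's state is
#'   flipped (M to U or U to M) relative to the molecule it came from.
#' @param clonality Number of distinct clone patterns per locus, in 1..16.
#' @param clone_mix_alpha Dirichlet concentration of the subclone mixing
#'   proportions. The ancestral concordant clone keeps a fixed concentration
#'   (`ancestral_alpha`), so raising `clone_mix_alpha` transfers expected
#'   mass from the concordant ancestral epiallele to the disordered
#'   subclones and raises every heterogeneity metric jointly.
#' @param ancestral_alpha Dirichlet concentration of the ancestral clone
#'   (default 5; the dominant-clone assumption).
#' @param partial_frac Probability that a read is truncated to fewer than 4
#'   CpGs (a uniform prefix/suffix of states is dropped), exercising
#'   missing-data handling downstream. Default 0: whole-locus reads.
#' @param seed Integer master seed; identical seed and configuration give
#'   byte-identical outputs.
#'
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_loci = 200,
                              cpg_spacing = 20,
                              locus_spacing = 150,
                              coverage_mean = 25,
                              coverage_dispersion = 5,
                              coverage_model = c("nbinom", "poisson", "fixed"),
                              error_rate = 0.01,
                              clonality = 2,
                              clone_mix_alpha = 0.3,
                              ancestral_alpha = 5,
                              partial_frac = 0,
                              seed = 1L) {
  coverage_model <- match.arg(coverage_model)
  check_number(n_loci, "n_loci", lower = 1)
  check_number(cpg_spacing, "cpg_spacing", lower = 2)
  check_number(locus_spacing, "locus_spacing", lower = 2)
  check_number(coverage_mean, "coverage_mean", lower = 0, strict_lower = TRUE)
  if (!identical(coverage_dispersion, Inf)) {
    check_number(coverage_dispersion, "coverage_dispersion",
                 lower = 0, strict_lower = TRUE)
  }
  check_number(error_rate, "error_rate", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  check_number(clonality, "clonality", lower = 1, upper = 16)
  check_number(clone_mix_alpha, "clone_mix_alpha",
               lower = 0, strict_lower = TRUE)
  check_number(ancestral_alpha, "ancestral_alpha",
               lower = 0, strict_lower = TRUE)
  check_number(partial_frac, "partial_frac", lower = 0, upper = 1)
  check_number(seed, "seed", lower = 0)
  structure(list(n_loci = as.integer(n_loci),
                 cpg_spacing = cpg_spacing,
                 locus_spacing = locus_spacing,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 coverage_model = coverage_model,
                 error_rate = error_rate,
                 clonality = as.integer(clonality),
                 clone_mix_alpha = clone_mix_alpha,
                 ancestral_alpha = ancestral_alpha,
                 partial_frac = partial_frac,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Cohort specification
#'
#' Parameters linking the read-level generator to a two-group cohort with
#' survival outcomes. Group `"B"` is the high-heterogeneity group: its
#' Dirichlet concentration is `clone_mix_alpha + group_effect`, giving more
#' even clone mixtures and hence higher epiallele diversity (the contrast
#' between patients with and without lymph-node metastasis). Survival times
#' are exponential with a log-linear hazard in the sample's mean expected
#' epipolymorphism; an independent exponential censoring process is applied.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param group_effect Additive shift (>= 0) on `clone_mix_alpha` for group B.
#' @param survival_baseline_hazard Baseline event rate per unit time (> 0).
#' @param survival_log_hazard_per_unit_het Log-hazard increase per unit of a
#'   sample's mean expected epipolymorphism.
#' @param censoring_rate Rate of the independent exponential censoring
#'   process; 0 means no censoring.
#'
#' @return A validated list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 20,
                        group_effect = 1,
                        survival_baseline_hazard = 0.075,
                        survival_log_hazard_per_unit_het = 2,
                        censoring_rate = 0.02) {
  check_number(n_per_group, "n_per_group", lower = 2)
  check_number(group_effect, "group_effect", lower = 0)
  check_number(survival_baseline_hazard, "survival_baseline_hazard",
               lower = 0, strict_lower = TRUE)
  check_number(survival_log_hazard_per_unit_het,
               "survival_log_hazard_per_unit_het")
  check_number(censoring_rate, "censoring_rate", lower = 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 group_effect = group_effect,
                 survival_baseline_hazard = survival_baseline_hazard,
                 survival_log_hazard_per_unit_het =
                   survival_log_hazard_per_unit_het,
                 censoring_rate = censoring_rate),
            class = "cohort_spec")
}

#' Validate an epiallele pattern distribution
#'
#' @param pattern_probs Named numeric vector: one probability per 4-CpG
#'   pattern (names from [epiallele_patterns()]); missing patterns are taken
#'   as probability 0.
#' @return A numeric vector of length 16 in canonical pattern order.
#' @export
epiallele_distribution <- function(pattern_probs) {
  pats <- epiallele_patterns()
  if (is.null(names(pattern_probs)) ||
      !all(names(pattern_probs) %in% pats) ||
      anyDuplicated(names(pattern_probs))) {
    abort("pattern_probs must be named by distinct 4-CpG patterns over {M,U}",
          class = "methylhet_input_error")
  }
  p <- setNames(numeric(16), pats)
  p[names(pattern_probs)] <- pattern_probs
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("pattern probabilities must be non-negative and sum to 1",
          class = "methylhet_input_error")
  }
  p
}

#' Simulate a reference contig with CpGs only at generated positions
#'
#' Builds a synthetic contig whose sequence contains CG dinucleotides exactly
#' at the generated CpG positions (4 per locus) and nowhere else; the
#' background is drawn from A/T so no accidental CpG can form.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` (named character vector of sequence) and
#'   `cpg_index`, the CpG reference tibble (see [build_cpg_index()]).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$seed, 1L))
  n_cpg <- 4L * config$n_loci
  within <- 2 + rpois(n_cpg, max(config$cpg_spacing - 2, 0))
  between <- 2 + rpois(n_cpg, max(config$locus_spacing - 2, 0))
  is_locus_start <- (seq_len(n_cpg) - 1L) %% 4L == 0L
  gaps <- ifelse(is_locus_start, between, within)
  pos <- cumsum(gaps) + 1L             # 1-based position of each C
  len <- pos[n_cpg] + 1L + config$cpg_spacing
  chars <- sample(c("A", "T"), len, replace = TRUE)
  chars[pos] <- "C"
  chars[pos + 1L] <- "G"
  genome <- setNames(paste(chars, collapse = ""), "sim_contig")
  index <- tibble(contig = "sim_contig", pos = as.integer(pos),
                  index = seq_len(n_cpg))
  attr(index, "contig_lengths") <- setNames(as.integer(len), "sim_contig")
  list(genome = genome, cpg_index = index)
}

#' Draw per-locus epiallele distributions from the clonal-mixture model
#'
#' For each locus the first clone is the ancestral concordant epiallele
#' (fully methylated or fully unmethylated, equiprobable); the remaining
#' `clonality - 1` clone patterns are drawn uniformly without replacement
#' from the other 15 patterns. Clones are mixed with Dirichlet(`alpha`)
#' proportions, so a fully clonal locus (`clonality = 1`) is concordant and
#' increasing clonality adds locally disordered epialleles.
#'
#' @param config A [simulation_config()].
#' @param alpha Dirichlet concentration; defaults to `config$clone_mix_alpha`.
#' @param clonality Clones per locus; defaults to `config$clonality`. May be
#'   a vector of length `n_loci` to grade clonality across loci.
#' @param seed Seed for this draw; defaults to a child of `config$seed`.
#' @return Tibble with columns `locus_id`, `pattern`, `prob` (16 rows per
#'   locus, zero-probability patterns included).
#' @export
simulate_locus_distributions <- function(config,
                                         alpha = config$clone_mix_alpha,
                                         clonality = config$clonality,
                                         seed = child_seed(config$seed, 2L)) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  pats <- epiallele_patterns()
  clonality <- rep_len(as.integer(clonality), config$n_loci)
  probs <- matrix(0, nrow = config$n_loci, ncol = 16,
                  dimnames = list(NULL, pats))
  concordant <- match(c("MMMM", "UUUU"), pats)
  for (i in seq_len(config$n_loci)) {
    k <- clonality[i]
    ancestral <- sample(concordant, 1L)
    clones <- c(ancestral,
                sample(setdiff(seq_len(16L), ancestral), k - 1L))
    w <- rgamma(k, shape = c(config$ancestral_alpha, rep(alpha, k - 1L)),
                rate = 1)
    if (sum(w) == 0) w <- rep(1, k)     # degenerate Dirichlet draw guard
    probs[i, clones] <- w / sum(w)
  }
  tibble(locus_id = rep(sprintf("L%05d", seq_len(config$n_loci)), each = 16),
         pattern = rep(pats, config$n_loci),
         prob = as.vector(t(probs)))
}

# long (locus_id, pattern, prob) -> loci x 16 matrix in canonical order
dist_matrix <- function(distributions) {
  check_columns(distributions, c("locus_id", "pattern", "prob"),
                "distributions")
  pats <- epiallele_patterns()
  wide <- tidyr::pivot_wider(distributions, id_cols = "locus_id",
                             names_from = "pattern", values_from = "prob",
                             values_fill = 0)
  m <- as.matrix(wide[, pats, drop = FALSE])
  rownames(m) <- wide$locus_id
  bad <- abs(rowSums(m) - 1) > 1e-9 | apply(m < 0, 1, any)
  if (any(bad)) {
    abort(sprintf("invalid pattern distribution for locus %s",
                  rownames(m)[which(bad)[1]]),
          class = "methylhet_input_error")
  }
  m
}

#' Simulate epireads from per-locus epiallele distributions
#'
#' Per locus the read count is drawn from the configured coverage model, each
#' read's pattern from that locus's distribution, and each CpG state is then
#' flipped independently with probability `error_rate`. Reads carry CpG
#' indices into the reference built by [simulate_reference()] (locus `i`
#' covers CpG indices `4i-3 .. 4i`).
#'
#' @param config A [simulation_config()].
#' @param distributions Tibble `(locus_id, pattern, prob)` with one
#'   distribution per locus, as from [simulate_locus_distributions()].
#' @param seed Seed for this draw; defaults to a child of `config$seed`.
#' @return Epiread tibble with columns `read_id`, `contig`,
#'   `first_cpg_index`, `states`.
#' @export
simulate_epireads <- function(config, distributions,
                              seed = child_seed(config$seed, 3L)) {
  stopifnot(inherits(config, "simulation_config"))
  pm <- dist_matrix(distributions)
  if (nrow(pm) != config$n_loci) {
    abort(sprintf("expected one distribution per locus (%d), got %d",
                  config$n_loci, nrow(pm)),
          class = "methylhet_input_error")
  }
  set.seed(seed)
  n_loci <- config$n_loci
  counts <- switch(config$coverage_model,
    nbinom = if (identical(config$coverage_dispersion, Inf)) {
      rpois(n_loci, config$coverage_mean)
    } else {
      rnbinom(n_loci, mu = config$coverage_mean,
              size = config$coverage_dispersion)
    },
    poisson = rpois(n_loci, config$coverage_mean),
    fixed = rep(as.integer(round(config$coverage_mean)), n_loci))
  locus_of <- rep(seq_len(n_loci), counts)
  n_reads <- length(locus_of)
  if (n_reads == 0L) {
    return(tibble(read_id = character(), contig = character(),
                  first_cpg_index = integer(), states = character()))
  }
  pat_idx <- integer(n_reads)
  for (i in seq_len(n_loci)) {
    if (counts[i] > 0L) {
      pat_idx[locus_of == i] <-
        sample.int(16L, counts[i], replace = TRUE, prob = pm[i, ])
    }
  }
  pats <- epiallele_patterns()
  meth <- do.call(rbind, strsplit(pats, ""))[pat_idx, , drop = FALSE] == "M"
  if (config$error_rate > 0) {
    flips <- matrix(runif(n_reads * 4L) < config$error_rate,
                    nrow = n_reads)
    meth <- xor(meth, flips)
  }
  states_mat <- matrix(ifelse(meth, "M", "U"), nrow = n_reads)
  states <- paste0(states_mat[, 1], states_mat[, 2],
                   states_mat[, 3], states_mat[, 4])
  first_cpg <- 4L * (locus_of - 1L) + 1L
  if (config$partial_frac > 0) {
    truncate <- runif(n_reads) < config$partial_frac
    pre <- ifelse(truncate, sample(0:2, n_reads, replace = TRUE), 0L)
    suf_max <- pmin(2L, 3L - pre)
    suf <- ifelse(truncate,
                  floor(runif(n_reads) * (suf_max + 1L)), 0L)
    states <- substr(states, pre + 1L, 4L - suf)
    first_cpg <- first_cpg + as.integer(pre)
  }
  tibble(read_id = sprintf("r%07d", seq_len(n_reads)),
         contig = "sim_contig",
         first_cpg_index = first_cpg,
         states = states)
}

#' Closed-form expected heterogeneity metrics under the error channel
#'
#' Perturbs a pattern distribution by exact enumeration over the independent
#' per-CpG flip events (transition probability `e^h (1-e)^(4-h)` between
#' patterns at Hamming distance `h`) and returns the population values of the
#' three heterogeneity metrics on the perturbed distribution: epipolymorphism
#' `1 - sum(p'^2)`, epiallele entropy `-sum(p' log2 p')` in bits (and its
#' /4-normalised variant), and expected PDR, the total probability of
#' patterns containing both an M and a U.
#'
#' @param dist Either a named probability vector (see
#'   [epiallele_distribution()]) or a tibble `(locus_id, pattern, prob)` for
#'   many loci.
#' @param error_rate Per-CpG flip probability in `[0, 0.5)`.
#' @return Tibble with one row per locus and columns `entropy_bits`,
#'   `entropy_norm`, `epipolymorphism`, `pdr` (plus `locus_id` for tibble
#'   input).
#' @export
expected_metrics <- function(dist, error_rate = 0) {
  check_number(error_rate, "error_rate", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  if (is.data.frame(dist)) {
    m <- dist_matrix(dist)
  } else {
    m <- matrix(epiallele_distribution(dist), nrow = 1,
                dimnames = list(NULL, epiallele_patterns()))
  }
  pats <- epiallele_patterns()
  h <- pattern_hamming()
  trans <- error_rate^h * (1 - error_rate)^(4 - h)
  dimnames(trans) <- list(pats, pats)
  perturbed <- m %*% trans                 # rows remain distributions
  epipoly <- 1 - rowSums(perturbed^2)
  plog <- ifelse(perturbed > 0, perturbed * log2(perturbed), 0)
  entropy <- -rowSums(plog)
  disc <- pats %in% discordant_patterns()
  pdr <- rowSums(perturbed[, disc, drop = FALSE])
  out <- tibble(entropy_bits = entropy,
                entropy_norm = entropy / 4,
                epipolymorphism = epipoly,
                pdr = pdr)
  if (is.data.frame(dist)) {
    out <- bind_cols(tibble(locus_id = rownames(m)), out)
  }
  out
}

#' Simulate a two-group cohort with survival outcomes
#'
#' Generates per-sample epiread sets for two groups that differ in clonal
#' mixing (group B receives `group_effect` extra Dirichlet concentration,
#' hence higher heterogeneity), together with per-locus ground-truth metric
#' values and a metadata table with exponential survival times whose
#' log-hazard is linear in the sample's mean expected epipolymorphism.
#'
#' @param spec A [cohort_spec()].
#' @param config A [simulation_config()]; `config$seed` is the master seed
#'   from which per-sample seeds are derived.
#' @return List with `epireads` (tibble with a `sample_id` column),
#'   `metadata` (tibble `sample_id`, `group`, `time`, `event`,
#'   `mean_expected_epipolymorphism`), and `truth` (per-sample per-locus
#'   expected metrics).
#' @export
simulate_cohort <- function(spec, config) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "simulation_config"))
  n <- 2L * spec$n_per_group
  groups <- rep(c("A", "B"), each = spec$n_per_group)
  sample_ids <- sprintf("S%02d_%s", seq_len(n), groups)
  reads <- vector("list", n)
  truths <- vector("list", n)
  het <- numeric(n)
  for (s in seq_len(n)) {
    alpha <- config$clone_mix_alpha +
      if (groups[s] == "B") spec$group_effect else 0
    seed_s <- child_seed(config$seed, 100L + s)
    dists <- simulate_locus_distributions(config, alpha = alpha,
                                          seed = seed_s)
    reads[[s]] <- simulate_epireads(config, dists,
                                    seed = child_seed(seed_s, 1L)) |>
      mutate(sample_id = sample_ids[s], .before = 1)
    tr <- expected_metrics(dists, config$error_rate) |>
      mutate(sample_id = sample_ids[s], .before = 1)
    truths[[s]] <- tr
    het[s] <- mean(tr$epipolymorphism)
  }
  set.seed(child_seed(config$seed, 99L))
  hazard <- spec$survival_baseline_hazard *
    exp(spec$survival_log_hazard_per_unit_het * het)
  event_time <- rexp(n, rate = hazard)
  censor_time <- if (spec$censoring_rate > 0) {
    rexp(n, rate = spec$censoring_rate)
  } else {
    rep(Inf, n)
  }
  metadata <- tibble(sample_id = sample_ids,
                     group = groups,
                     time = pmin(event_time, censor_time),
                     event = as.integer(event_time <= censor_time),
                     mean_expected_epipolymorphism = het)
  list(epireads = bind_rows(reads),
       metadata = metadata,
       truth = bind_rows(truths))
}

#' Write a simulated cohort to disk
#'
#' Writes one epiread TSV per sample, the metadata table, and the per-locus
#' ground-truth metric table. Optionally writes the reference contig as FASTA
#' and each sample's reads as a minimal SAM with bisulfite-converted
#' sequences.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @param reference Optional result of [simulate_reference()]; when supplied,
#'   `reference.fa` and per-sample SAM files are written too.
#' @return Invisibly, a character vector of the files written.
#' @export
write_simulation <- function(cohort, outdir, reference = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (sid in unique(cohort$epireads$sample_id)) {
    path <- file.path(outdir, paste0(sid, ".epireads.tsv"))
    write_epiread_tsv(filter(cohort$epireads, .data$sample_id == sid) |>
                        select(-"sample_id"), path)
    files <- c(files, path)
  }
  meta_path <- file.path(outdir, "metadata.tsv")
  readr::write_tsv(cohort$metadata, meta_path)
  truth_path <- file.path(outdir, "ground_truth.tsv")
  readr::write_tsv(cohort$truth, truth_path)
  files <- c(files, meta_path, truth_path)
  if (!is.null(reference)) {
    fa <- file.path(outdir, "reference.fa")
    writeLines(c(paste0(">", names(reference$genome)),
                 unname(reference$genome)), fa)
    files <- c(files, fa)
    for (sid in unique(cohort$epireads$sample_id)) {
      sam <- file.path(outdir, paste0(sid, ".sam"))
      write_epiread_sam(filter(cohort$epireads, .data$sample_id == sid),
                        reference$cpg_index, reference$genome, sam)
      files <- c(files, sam)
    }
  }
  invisible(files)
}

#' Write epireads as a minimal bisulfite SAM
#'
#' Emits one top-strand alignment per epiread: the read sequence is the
#' reference span with each covered CpG's C left as C (methylated) or
#' converted to T (unmethylated), mimicking bisulfite conversion of the
#' original-top strand. All reads are mapped, primary, forward-strand, with
#' full-match CIGARs.
#'
#' @param epireads Epiread tibble.
#' @param cpg_index CpG reference tibble (needs the `contig_lengths`
#'   attribute, as produced by [simulate_reference()] or [build_cpg_index()]).
#' @param genome Named character vector of contig sequences.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_epiread_sam <- function(epireads, cpg_index, genome, path) {
  lens <- attr(cpg_index, "contig_lengths")
  if (is.null(lens)) {
    lens <- vapply(genome, nchar, integer(1))
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  recs <- character(nrow(epireads))
  for (i in seq_len(nrow(epireads))) {
    contig <- epireads$contig[i]
    first <- epireads$first_cpg_index[i]
    states <- strsplit(epireads$states[i], "")[[1]]
    idx <- cpg_index[cpg_index$contig == contig, ]
    cpg_pos <- idx$pos[first:(first + length(states) - 1L)]
    start <- cpg_pos[1]
    end <- cpg_pos[length(cpg_pos)] + 1L   # include the G of the last CpG
    seq <- strsplit(substr(genome[[contig]], start, end), "")[[1]]
    off <- cpg_pos - start + 1L
    seq[off[states == "U"]] <- "T"
    seq[off[states == "."]] <- "N"
    recs[i] <- paste(epireads$read_id[i], 0L, contig, start, 60L,
                     paste0(length(seq), "M"), "*", 0L, 0L,
                     paste(seq, collapse = ""),
                     strrep("I", length(seq)), sep = "\t")
  }
  writeLines(c(header, recs), path)
  invisible(path)
}
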