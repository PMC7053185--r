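test_that("tile methylation averages CpG betas and applies the depth rule", {
  beta <- make_beta(n_meth = c(4, 8, 12), n_total = c(20, 20, 20),
                    spacing = 100L, contig_length = 1000L)
  tiles <- tile_methylation(beta, tile_width = 1000)
  expect_equal(nrow(tiles), 1L)
  expect_equal(tiles$methylation, 0.4)
  expect_true(tiles$eligible)

  # mean depth exactly at the threshold is NOT eligible (strictly more)
  at10 <- make_beta(n_meth = c(5, 5), n_total = c(10, 10),
                    contig_length = 500L)
  expect_false(tile_methylation(at10, tile_width = 500)$eligible)
  just_over <- make_beta(n_meth = c(5, 5), n_total = c(10, 12),
                         contig_length = 500L)
  expect_true(tile_methylation(just_over, tile_width = 500)$eligible)

  # CpG-free tiles are flagged ineligible with NA methylation
  sparse <- make_beta(n_meth = 5, n_total = 20, contig_length = 1000L)
  two <- tile_methylation(sparse, tile_width = 500)
  expect_equal(two$eligible, c(TRUE, FALSE))
  expect_true(is.na(two$methylation[2]))

  # every-CpG rule: one shallow CpG disqualifies the tile
  uneven <- make_beta(n_meth = c(1, 5), n_total = c(5, 40),
                      contig_length = 500L)
  expect_true(tile_methylation(uneven, tile_width = 500)$eligible)
  expect_false(tile_methylation(uneven, tile_width = 500,
                                rule = "every_cpg")$eligible)
})

test_that("tiling partitions each contig without gaps or overlap", {
  cfg <- simulation_config(n_loci = 40, seed = 71)
  ref <- simulate_reference(cfg)
  er <- simulate_epireads(cfg, simulate_locus_distributions(cfg))
  beta <- compute_beta_track(er, ref$cpg_index)
  tiles <- tile_methylation(beta, tile_width = 700)
  expect_equal(sum(tiles$end - tiles$start),
               unname(contig_lengths(ref$cpg_index)))
  expect_true(all(tiles$start == dplyr::lag(tiles$end, default = 0L)))
  expect_equal(sum(tiles$n_cpgs), nrow(ref$cpg_index))
})

test_that("tile CV is sd over mean of eligible tiles", {
  tiles <- tibble::tibble(methylation = c(0.5, 0.5, 0.5),
                          eligible = TRUE)
  expect_equal(sample_cv(tiles)$cv, 0)
  spread <- tibble::tibble(methylation = c(0.2, 0.4, 0.6), eligible = TRUE)
  expect_equal(sample_cv(spread)$cv, 0.5)
  expect_equal(sample_cv(spread)$n_eligible_tiles, 3L)
  none <- tibble::tibble(methylation = c(0.2, 0.4), eligible = FALSE)
  expect_true(is.na(sample_cv(none)$cv))
})

test_that("global methylation averages covered CpGs", {
  beta <- make_beta(n_meth = c(2, 2, 0, 0), n_total = c(2, 2, 2, 2))
  expect_equal(global_methylation(beta), 0.5)
  weighted <- make_beta(n_meth = c(1, 30), n_total = c(10, 30))
  expect_equal(global_methylation(weighted), (0.1 + 1) / 2)
  expect_equal(global_methylation(weighted, weighted = TRUE), 31 / 40)
  empty <- make_beta(n_meth = 0, n_total = 0)
  expect_true(is.na(global_methylation(empty)))
})

test_that("state-flip errors depress global methylation by the error rate", {
  cfg <- simulation_config(n_loci = 150, error_rate = 0.1, seed = 73)
  d <- tibble::tibble(
    locus_id = rep(sprintf("L%05d", 1:150), each = 16),
    pattern = rep(epiallele_patterns(), 150),
    prob = rep(as.numeric(epiallele_patterns() == "MMMM"), 150))
  er <- simulate_epireads(cfg, d)
  ref <- simulate_reference(cfg)
  beta <- compute_beta_track(er, ref$cpg_index)
  expect_equal(global_methylation(beta, weighted = TRUE), 0.9,
               tolerance = 0.01)
})

test_that("metagene profile is flat for constant methylation and flips strand", {
  cfg <- simulation_config(n_loci = 60, seed = 79)
  ref <- simulate_reference(cfg)
  n <- nrow(ref$cpg_index)
  flat <- make_beta(n_meth = rep(7, n), n_total = rep(10, n))
  flat$pos <- ref$cpg_index$pos
  attr(flat, "contig_lengths") <- contig_lengths(ref$cpg_index)
  flat$contig <- ref$cpg_index$contig
  len <- unname(contig_lengths(ref$cpg_index))
  genes <- tibble::tibble(contig = "sim_contig",
                          start = c(500L, 2500L),
                          end = c(2000L, 4000L),
                          strand = c("+", "-"))
  prof <- metagene_profile(flat, genes, flank_bp = 400, n_body_bins = 20,
                           n_flank_bins = 5)
  expect_equal(nrow(prof), 30L)
  expect_true(all(prof$mean_methylation[prof$n_genes > 0] == 0.7))

  # two genes at constant 0.2 and 0.6 average to 0.4
  grad <- flat
  grad$beta <- ifelse(grad$pos < 2450, 0.2, 0.6)
  prof2 <- metagene_profile(grad, genes, flank_bp = 400, n_body_bins = 20,
                            n_flank_bins = 5)
  both <- prof2$zone == "body" & prof2$n_genes == 2
  expect_true(any(both))
  expect_true(all(abs(prof2$mean_methylation[both] - 0.4) < 1e-9))

  # a minus-strand gene reads its bins in transcription direction
  asym <- flat
  asym$beta <- seq(0, 1, length.out = n)
  plus <- metagene_profile(asym, genes[1, ], flank_bp = 400,
                           n_body_bins = 20, n_flank_bins = 5)
  minus <- metagene_profile(asym,
                            dplyr::mutate(genes[1, ], strand = "-"),
                            flank_bp = 400, n_body_bins = 20,
                            n_flank_bins = 5)
  keep <- !is.na(plus$mean_methylation) & !is.na(rev(minus$mean_methylation))
  expect_gt(cor(plus$mean_methylation[keep],
                rev(minus$mean_methylation)[keep]), 0.99)

  expect_error(metagene_profile(flat, genes[0, ], flank_bp = 400),
               class = "methylhet_input_error")
  # genes shorter than the bin count are skipped and counted
  short <- metagene_profile(flat,
                            dplyr::bind_rows(genes,
                                             tibble::tibble(
                                               contig = "sim_contig",
                                               start = 10L, end = 15L,
                                               strand = "+")),
                            flank_bp = 400, n_body_bins = 20,
                            n_flank_bins = 5)
  expect_equal(attr(short, "n_genes_skipped"), 1L)
})

test_that("region comparison reproduces exact rank-sum inference", {
  groups <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           group = rep(c("g1", "g2"), each = 3))
  rm <- tibble::tibble(region_id = "r1",
                       sample_id = sprintf("s%d", 1:6),
                       value = 1:6)
  res <- region_group_comparison(rm, groups)
  expect_equal(res$statistic, 0)
  # oracle: enumerate all 20 assignments of ranks to groups
  combos <- utils::combn(6, 3)
  u_stats <- apply(combos, 2, function(ix) {
    x <- (1:6)[ix]
    sum(outer(x, (1:6)[-ix], ">")) # U for the first group
  })
  p_exact <- mean(abs(u_stats - 4.5) >= abs(0 - 4.5))
  expect_equal(p_exact, 0.1)
  expect_equal(res$p_value, p_exact)
  expect_equal(res$mean_diff, 3)

  # identical groups: zero mean difference, p = 1
  same <- tibble::tibble(region_id = "r1",
                         sample_id = sprintf("s%d", 1:6),
                         value = rep(c(1, 2, 3), 2))
  res_same <- region_group_comparison(same, groups)
  expect_equal(res_same$mean_diff, 0)
  expect_gt(res_same$p_value, 0.99)

  expect_error(region_group_comparison(
    rm, dplyr::mutate(groups, group = "g1")),
    class = "methylhet_input_error")
})

test_that("BH adjustment across regions equals the brute-force q-values", {
  set.seed(83)
  n_regions <- 40
  groups <- tibble::tibble(sample_id = sprintf("s%d", 1:12),
                           group = rep(c("g1", "g2"), each = 6))
  rm <- tidyr::expand_grid(region_id = sprintf("r%02d", 1:n_regions),
                           sample_id = sprintf("s%d", 1:12)) |>
    dplyr::mutate(value = runif(dplyr::n()))
  res <- region_group_comparison(rm, groups)
  p <- res$p_value
  # brute-force BH: q_(i) = min_{j >= i} p_(j) * n / j
  ord <- order(p)
  q_brute <- numeric(n_regions)
  q_sorted <- rev(cummin(rev(p[ord] * n_regions / seq_len(n_regions))))
  q_brute[ord] <- pmin(q_sorted, 1)
  expect_equal(res$q_value, q_brute, tolerance = 1e-12)
})

test_that("cohorts with more across-locus dispersion show higher tile CV", {
  # clonality 1 at skewed mixing: loci are pure MMMM or UUUU (dispersed
  # methylation); clonality 16 at even mixing: every locus near 0.5
  mk_cv <- function(clonality, alpha, seed) {
    cfg <- simulation_config(n_loci = 120, clonality = clonality,
                             clone_mix_alpha = alpha, seed = seed)
    d <- simulate_locus_distributions(cfg)
    er <- simulate_epireads(cfg, d)
    ref <- simulate_reference(cfg)
    beta <- compute_beta_track(er, ref$cpg_index)
    sample_cv(tile_methylation(beta, tile_width = 1000))$cv
  }
  dispersed <- vapply(1:3, function(s) mk_cv(1, 0.3, s), numeric(1))
  uniform <- vapply(1:3, function(s) mk_cv(16, 50, s + 10), numeric(1))
  expect_gt(mean(dispersed), mean(uniform))
})
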