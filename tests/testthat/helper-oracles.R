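# Independent brute-force oracles and small fixture builders.

# Gini-Simpson diversity by explicit summation.
brute_epipolymorphism <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (k in counts) acc <- acc + (k / total)^2
  1 - acc
}

# Shannon entropy (bits) by explicit summation over nonzero frequencies.
brute_entropy <- function(counts) {
  total <- sum(counts)
  acc <- 0
  for (k in counts) {
    if (k > 0) acc <- acc - (k / total) * log2(k / total)
  }
  acc
}

# Error-channel perturbation by exhaustive enumeration of the 16 flip
# events per source pattern (independent of the package's transition
# matrix).
brute_perturb <- function(p, e) {
  pats <- names(p)
  stopifnot(!is.null(pats))
  out <- setNames(numeric(length(p)), pats)
  flip_masks <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  for (i in seq_along(p)) {
    src <- strsplit(pats[i], "")[[1]]
    for (m in seq_len(nrow(flip_masks))) {
      mask <- unlist(flip_masks[m, ])
      tgt <- src
      tgt[mask] <- ifelse(src[mask] == "M", "U", "M")
      nf <- sum(mask)
      out[paste(tgt, collapse = "")] <- out[paste(tgt, collapse = "")] +
        p[i] * e^nf * (1 - e)^(4 - nf)
    }
  }
  out
}

# Epiread tibble from a vector of state strings.
make_epireads <- function(states, first_cpg = 1L, contig = "c1") {
  tibble::tibble(read_id = sprintf("r%03d", seq_along(states)),
                 contig = contig,
                 first_cpg_index = as.integer(rep_len(first_cpg,
                                                      length(states))),
                 states = states)
}

# Beta track built directly from per-CpG counts (bypassing epireads).
make_beta <- function(n_meth, n_total, contig = "c1", spacing = 50L,
                      contig_length = NULL) {
  n <- length(n_total)
  pos <- as.integer(seq(2L, by = spacing, length.out = n))
  out <- tibble::tibble(contig = contig, pos = pos, index = seq_len(n),
                        n_meth = as.integer(n_meth),
                        n_total = as.integer(n_total),
                        beta = ifelse(n_total > 0, n_meth / n_total,
                                      NA_real_))
  if (is.null(contig_length)) contig_length <- max(pos) + spacing
  attr(out, "contig_lengths") <-
    stats::setNames(as.integer(contig_length), contig)
  out
}

# Random epiallele count tables over the 16 patterns.
random_count_table <- function(max_total = 200) {
  k <- sample(1:16, 1)
  pats <- sample(epiallele_patterns(), k)
  stats::setNames(as.numeric(rmultinom(1, sample(5:max_total, 1),
                                       prob = runif(k))), pats)
}
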