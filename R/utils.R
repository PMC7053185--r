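# Shared helpers: the 16-pattern epiallele alphabet, seed derivation, and
# small input checks used across modules.

#' The 4-CpG epiallele pattern alphabet
#'
#' All 16 joint methylation patterns of four neighbouring CpGs on one DNA
#' molecule, as length-4 strings over `M` (methylated) and `U`
#' (unmethylated), in a fixed canonical order. This order is used everywhere
#' a pattern distribution or count vector is stored.
#'
#' @return Character vector of length 16.
#' @examples
#' epiallele_patterns()
#' @export
epiallele_patterns <- function() {
  grid <- expand.grid(p4 = c("U", "M"), p3 = c("U", "M"),
                      p2 = c("U", "M"), p1 = c("U", "M"),
                      stringsAsFactors = FALSE)
  paste0(grid$p1, grid$p2, grid$p3, grid$p4)
}

# patterns carrying both an M and a U (the discordant patterns)
discordant_patterns <- function() {
  pats <- epiallele_patterns()
  pats[grepl("M", pats) & grepl("U", pats)]
}

# Hamming distances between all pattern pairs; rows/cols in canonical order.
pattern_hamming <- function() {
  pats <- epiallele_patterns()
  mat <- do.call(rbind, strsplit(pats, ""))
  outer(seq_len(16), seq_len(16),
        Vectorize(function(i, j) sum(mat[i, ] != mat[j, ])))
}

# Deterministic child seed from a master seed and an index; keeps the result
# a positive 32-bit integer so it is portable across set.seed() calls.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %%
               2147483647L) + 1L
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name),
          class = "methylhet_config_error")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  ok_up <- if (strict_upper) x < upper else x <= upper
  if (!ok_low || !ok_up) {
    abort(sprintf("`%s` = %s is outside its allowed range", name, format(x)),
          class = "methylhet_config_error")
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame", what),
          class = "methylhet_input_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "methylhet_input_error")
  }
  invisible(df)
}
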