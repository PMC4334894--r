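# Independent brute-force oracles used against the interval algebra, plus
# small fixture builders. These stay deliberately naive (per-base counting,
# hand enumeration) so they are independent of the implementation they check.

# total length of the union of intervals on one toy chromosome, by marking
# individual bases
base_union_length <- function(iv, chrom_len) {
  covered <- logical(chrom_len)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) {
      covered[seq(iv$start[i] + 1, iv$end[i])] <- TRUE
    }
  }
  sum(covered)
}

# per-base set difference a \ b on one toy chromosome; returns base indices
# (0-based) in a but not in b
base_setdiff <- function(a, b, chrom_len) {
  in_a <- logical(chrom_len); in_b <- logical(chrom_len)
  in_a[seq(a$start + 1, a$end)] <- TRUE
  if (b$end > b$start) in_b[seq(b$start + 1, b$end)] <- TRUE
  which(in_a & !in_b) - 1
}

# evenly spaced single-bp marker panel on one chromosome
toy_panel <- function(n, chrom = "I", spacing = 1e6, prefix = "m") {
  marker_panel(paste0(prefix, seq_len(n)), chrom,
               seq_len(n) * spacing - 500, seq_len(n) * spacing + 500)
}

# calls implied by a truth interval on a panel (no errors)
truth_calls <- function(panel, start, end) {
  tibble::tibble(marker = panel$marker,
                 call = ifelse(panel$mid >= start & panel$mid < end, "+", "-"))
}

# likelihood-ratio (G) statistic for a multinomial goodness-of-fit
g_statistic <- function(observed, expected_frac) {
  e <- sum(observed) * expected_frac
  terms <- ifelse(observed == 0, 0, observed * log(observed / e))
  2 * sum(terms)
}
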