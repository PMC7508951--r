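# Independent oracles for global alignment scores.
#
# Under a linear gap cost, any global alignment is determined by the set of
# aligned residue pairs, which form an increasing matching between the two
# sequences; its score is sum(match/mismatch over pairs) + gap * (unmatched
# residues). The optimum can therefore be found by exhaustive enumeration of
# all increasing matchings — a formulation entirely independent of the
# dynamic-programming recurrence it checks.

# Plain enumeration for one pair of sequences (any alphabet).
bf_align_score <- function(a, b, match = 1, mismatch = -2, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  best <- gap * (n + m)  # k = 0: everything gapped
  for (k in seq_len(min(n, m))) {
    ia_set <- utils::combn(n, k, simplify = FALSE)
    ib_set <- utils::combn(m, k, simplify = FALSE)
    for (ia in ia_set) {
      for (ib in ib_set) {
        s <- sum(ifelse(av[ia] == bv[ib], match, mismatch)) +
          gap * (n + m - 2 * k)
        if (s > best) best <- s
      }
    }
  }
  best
}

# Vectorized enumeration over *all* sequence pairs of lengths (n, m) on a
# two-letter alphabet. Sequences of length n are encoded as the integers
# 0..2^n-1 (bit i = 1 means letter two at position i+1). Returns the
# 2^n x 2^m matrix of optimal scores.
bf_align_scores_shape <- function(n, m, match = 1, mismatch = -2, gap = -1) {
  pc <- vapply(0:63, function(x) sum(bitwAnd(bitwShiftR(x, 0:5), 1L)),
               integer(1))  # popcount lookup for up to 6 bits
  na <- 2^n
  nb <- 2^m
  best <- matrix(gap * (n + m), nrow = na, ncol = nb)
  abits <- vapply(0:(na - 1), function(x) bitwAnd(bitwShiftR(x, 0:(n - 1)), 1L),
                  integer(n))
  bbits <- vapply(0:(nb - 1), function(x) bitwAnd(bitwShiftR(x, 0:(m - 1)), 1L),
                  integer(m))
  abits <- matrix(abits, nrow = n)
  bbits <- matrix(bbits, nrow = m)
  for (k in seq_len(min(n, m))) {
    pow <- 2^(0:(k - 1))
    ia_set <- utils::combn(n, k, simplify = FALSE)
    ib_set <- utils::combn(m, k, simplify = FALSE)
    gap_part <- gap * (n + m - 2 * k)
    for (ia in ia_set) {
      ua <- as.integer(pow %*% abits[ia, , drop = FALSE])
      for (ib in ib_set) {
        vb <- as.integer(pow %*% bbits[ib, , drop = FALSE])
        mismatches <- pc[outer(ua, vb, bitwXor) + 1L]
        s <- match * (k - mismatches) + mismatch * mismatches + gap_part
        best <- pmax(best, matrix(s, nrow = na, ncol = nb))
      }
    }
  }
  best
}

decode_seq <- function(code, len, alphabet = c("A", "C")) {
  bits <- bitwAnd(bitwShiftR(code, 0:(len - 1)), 1L)
  paste(alphabet[bits + 1L], collapse = "")
}

# Exhaustive agreement check between the package aligner and the enumeration
# oracle for all ordered pairs of sequences of lengths 1..max_len over a
# two-letter alphabet. Returns the number of disagreements.
check_alignment_oracle <- function(max_len = 6, match = 1, mismatch = -2,
                                   gap = -1) {
  disagreements <- 0L
  for (n in seq_len(max_len)) {
    for (m in seq_len(max_len)) {
      oracle <- bf_align_scores_shape(n, m, match, mismatch, gap)
      for (ai in seq_len(2^n)) {
        a <- decode_seq(ai - 1L, n)
        for (bi in seq_len(2^m)) {
          b <- decode_seq(bi - 1L, m)
          got <- global_align(a, b, align_scoring(match, mismatch, gap))$score
          if (!isTRUE(all.equal(got, oracle[ai, bi]))) {
            disagreements <- disagreements + 1L
          }
        }
      }
    }
  }
  disagreements
}
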