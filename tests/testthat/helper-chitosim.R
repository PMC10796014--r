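# Shared helpers for the test suite.

# Independent run-length oracle for block statistics: weight-average block
# size computed directly from the true maximal runs of a sequence, with the
# same species weighting used by digest_and_score. Interior products of the
# after-DA cleavage pair the (block-1) remainder of an A-block, a full
# D-block, and the first A of the next block, so their (nA, nD) equal the
# originating block sizes; this oracle reconstructs those species without
# going through digest().
oracle_interior_species <- function(seq) {
  r <- rle(as_pa_sequence(seq)$units)
  # interior products exist between consecutive D->A transitions
  trans <- which(r$values == "D" & c(r$values[-1], "") == "A")
  # a transition whose A-run is a single unit ending the chain yields a cut
  # at the reducing end, i.e. no cut
  valid <- !(trans + 1L == length(r$lengths) & r$lengths[trans + 1L] == 1L)
  trans <- trans[valid]
  if (length(trans) < 2L) return(NULL)
  # product k (k >= 2) carries A-block following transition k-1 and D-block
  # of transition k
  a_sizes <- r$lengths[trans[-length(trans)] + 1L]
  d_sizes <- r$lengths[trans[-1L]]
  data.frame(nA = a_sizes, nD = d_sizes, dp = a_sizes + d_sizes)
}

expect_sums_to_one <- function(x, tol = 1e-9) {
  expect_lt(abs(sum(x) - 1), tol)
}
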