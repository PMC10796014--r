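# In silico chitinosanase fingerprinting. Chitinosanase cleaves a chitosan
# chain after every D,A dimer — i.e. one unit after each D-block to A-block
# transition — so each interior product carries exactly the A- and D-unit
# counts of the originating A- and D-blocks. Weight-average block sizes are
# computed from a (DP, N(A), N(D), I) fragment table.

#' Digest a sequence with chitinosanase
#'
#' Cleaves after every position i+1 where unit i is D and unit i+1 is A.
#' Fragments partition the input in order; the first fragment carries the
#' original nonreducing terminus (leading) and the last the reducing
#' terminus (trailing).
#'
#' @param seq A `pa_sequence` (or A/D string).
#' @return Data frame with one row per fragment: `sequence`, `dp`, `nA`,
#'   `nD`, `is_leading`, `is_trailing`.
#' @examples
#' digest("DDAAADDA")$sequence  # "DDA" "AADDA"
#' @export
digest <- function(seq) {
  seq <- as_pa_sequence(seq)
  u <- seq$units
  n <- seq$dp
  # cut after position i+1 whenever (u[i], u[i+1]) == (D, A)
  cuts <- if (n >= 2L) which(u[-n] == "D" & u[-1L] == "A") + 1L else integer()
  cuts <- cuts[cuts < n]  # a cut after the reducing end is no cut
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  frag <- vapply(seq_along(starts),
                 function(k) paste(u[starts[k]:ends[k]], collapse = ""),
                 character(1))
  nA <- vapply(seq_along(starts), function(k) sum(u[starts[k]:ends[k]] == "A"), integer(1))
  data.frame(
    sequence = frag,
    dp = ends - starts + 1L,
    nA = nA,
    nD = (ends - starts + 1L) - nA,
    is_leading = seq_along(starts) == 1L,
    is_trailing = seq_along(starts) == length(starts),
    stringsAsFactors = FALSE)
}

#' Maximal A- and D-runs of a sequence
#'
#' Run-length oracle for the block statistics: the maximal runs of
#' consecutive A units (A-blocks) and D units (D-blocks), in order of
#' appearance.
#'
#' @param seq A `pa_sequence` (or A/D string).
#' @return List with integer vectors `A` and `D` of run lengths.
#' @examples
#' true_blocks("DDAAADDA")  # A: 3 1, D: 2 2
#' @export
true_blocks <- function(seq) {
  seq <- as_pa_sequence(seq)
  r <- rle(seq$units)
  list(A = r$lengths[r$values == "A"],
       D = r$lengths[r$values == "D"])
}

#' Weight-average block statistics from a fragment table
#'
#' Computes the weight-average A- and D-block sizes
#' \deqn{block(A)_w = \frac{\sum_i DP_i I_i N(A)_i}{\sum_i DP_i I_i}}
#' (and analogously with N(D) for block(D)_w) over the fragment species i
#' whose DP lies within `dp_window`, plus the oligomeric fraction: the share
#' of total DP-weighted intensity falling inside the window.
#'
#' @param table Data frame with columns `dp`, `nA`, `nD`, `I` (relative
#'   intensity, >= 0). Column names `DP`/`NA`/`ND` are also accepted.
#' @param dp_window Length-2 integer range of DPs entering the block
#'   averages (default `c(2, 14)`, the resolvable oligomer window).
#' @return List with `blockA_w`, `blockD_w`, `oligomeric_fraction`.
#' @examples
#' block_stats(data.frame(dp = c(2, 5), nA = c(1, 3), nD = c(1, 2), I = c(2, 1)))
#' # blockA_w = (2*2*1 + 5*1*3) / (2*2 + 5*1) = 19/9
#' @export
block_stats <- function(table, dp_window = c(2, 14)) {
  table <- normalize_fragment_table(table)
  if (!nrow(table)) stop("undefined-statistics: empty fragment table", call. = FALSE)
  if (all(table$I == 0)) stop("undefined-statistics: all intensities zero", call. = FALSE)
  wt_all <- table$dp * table$I
  inw <- table$dp >= dp_window[1] & table$dp <= dp_window[2]
  denom <- sum(wt_all[inw])
  if (denom == 0)  # nothing resolvable in the oligomer window
    return(list(blockA_w = NA_real_, blockD_w = NA_real_,
                oligomeric_fraction = 0))
  list(
    blockA_w = sum(wt_all[inw] * table$nA[inw]) / denom,
    blockD_w = sum(wt_all[inw] * table$nD[inw]) / denom,
    oligomeric_fraction = denom / sum(wt_all))
}

normalize_fragment_table <- function(table) {
  stopifnot(is.data.frame(table))
  nm <- names(table)
  ren <- c(DP = "dp", "NA" = "nA", ND = "nD", intensity = "I")
  for (i in seq_along(ren)) nm[nm == names(ren)[i]] <- ren[[i]]
  names(table) <- nm
  need <- c("dp", "nA", "nD", "I")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("fragment table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(table$I < 0)) stop("negative intensity in fragment table", call. = FALSE)
  table
}

#' Digest a sequence and compute its block statistics
#'
#' Runs [digest()], groups interior fragments (terminal fragments excluded:
#' the block identity only holds away from the chain ends) into species by
#' (DP, N(A)) — mass spectrometry cannot distinguish sequence isomers — and
#' assigns each species an intensity: the fragment count (`molar`, MS-like)
#' or count x DP (`mass`, emulating refractive-index peak area; the
#' default). Block statistics are computed over `dp_window`; species above
#' the window still count toward the oligomeric-fraction denominator.
#'
#' @param seq A `pa_sequence` (or A/D string).
#' @param weighting `"mass"` (default) or `"molar"`.
#' @param dp_window DP window for [block_stats()] (default `c(2, 14)`).
#' @return List with `table` (species data frame: `dp`, `nA`, `nD`, `count`,
#'   `I`), `stats` (from [block_stats()]), `weighting`, and
#'   `n_terminal_excluded`.
#' @examples
#' digest_and_score(strrep("AD", 50))$stats$blockA_w  # 1 (alternating)
#' @export
digest_and_score <- function(seq, weighting = c("mass", "molar"),
                             dp_window = c(2, 14)) {
  weighting <- match.arg(weighting)
  fr <- digest(seq)
  interior <- fr[!fr$is_leading & !fr$is_trailing, , drop = FALSE]
  if (!nrow(interior))
    stop("undefined-statistics: fewer than 2 cleavage sites, no interior fragments",
         call. = FALSE)
  key <- paste(interior$dp, interior$nA, sep = "_")
  agg <- aggregate(list(count = rep(1L, nrow(interior))),
                   by = list(dp = interior$dp, nA = interior$nA), FUN = sum)
  agg$nD <- agg$dp - agg$nA
  agg$I <- if (weighting == "mass") agg$count * agg$dp else agg$count
  agg <- agg[order(agg$dp, agg$nA), c("dp", "nA", "nD", "count", "I")]
  rownames(agg) <- NULL
  list(table = agg,
       stats = block_stats(agg, dp_window),
       weighting = weighting,
       n_terminal_excluded = nrow(fr) - nrow(interior))
}
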