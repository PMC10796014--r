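# Sequence and composition types for partially acetylated chitooligosaccharides
# (paCOS) and chitosans. A = GlcNAc (N-acetylglucosamine), D = GlcN
# (glucosamine). Sequences are always written nonreducing -> reducing end.

#' Monoisotopic mass constants for A/D glycan chemistry
#'
#' Residue (anhydro) masses of GlcNAc (A, C8H13NO5) and GlcN (D, C6H11NO4),
#' water and the proton, computed from monoisotopic atomic masses
#' (C 12, H 1.0078250319, N 14.0030740, O 15.9949146). The difference
#' between the two residue masses is the acetyl delta C2H2O (42.0106 Da).
#'
#' @return Named list with elements `residue_mass_A`, `residue_mass_D`,
#'   `water`, `proton` (all Da).
#' @examples
#' mass_constants()$residue_mass_A  # 203.0794
#' @export
mass_constants <- function() {
  mC <- 12
  mH <- 1.0078250319
  mN <- 14.0030740
  mO <- 15.9949146
  list(
    residue_mass_A = 8 * mC + 13 * mH + mN + 5 * mO,  # C8H13NO5
    residue_mass_D = 6 * mC + 11 * mH + mN + 4 * mO,  # C6H11NO4
    water          = 2 * mH + mO,
    proton         = 1.00727646677
  )
}

#' Parse an A/D residue string into a pa_sequence
#'
#' Accepts a character string over the alphabet \{A, D\} (case-insensitive),
#' written from the nonreducing to the reducing end, e.g. `"AADA"`.
#'
#' @param text Single nonempty character string over \{A, D\}.
#' @return Object of class `pa_sequence`: a list with `units` (character
#'   vector of "A"/"D"), `dp` (degree of polymerization) and `fa` (fraction
#'   of acetylation, #A / dp).
#' @examples
#' s <- parse_sequence("AADA")
#' s$dp  # 4
#' s$fa  # 0.75
#' @export
parse_sequence <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("invalid-sequence: expected a single nonempty A/D string", call. = FALSE)
  units <- strsplit(toupper(text), "", fixed = TRUE)[[1L]]
  bad <- which(!units %in% c("A", "D"))
  if (length(bad))
    stop(sprintf("invalid-sequence: character '%s' at position %d (only A and D allowed)",
                 units[bad[1L]], bad[1L]), call. = FALSE)
  new_pa_sequence(units)
}

new_pa_sequence <- function(units) {
  structure(
    list(units = units,
         dp = length(units),
         fa = mean(units == "A")),
    class = "pa_sequence")
}

#' Render a pa_sequence back to its A/D string
#'
#' Inverse of [parse_sequence()]: `parse_sequence(render_sequence(s))` is
#' identical to `s`.
#'
#' @param seq A `pa_sequence`.
#' @return Uppercase character string, nonreducing -> reducing end.
#' @export
render_sequence <- function(seq) {
  stopifnot(inherits(seq, "pa_sequence"))
  paste(seq$units, collapse = "")
}

#' @export
print.pa_sequence <- function(x, ...) {
  cat(sprintf("pa_sequence: %s (DP = %d, F_A = %.3f)\n",
              render_sequence(x), x$dp, x$fa))
  invisible(x)
}

#' @export
format.pa_sequence <- function(x, ...) render_sequence(x)

as_pa_sequence <- function(x) {
  if (inherits(x, "pa_sequence")) x else parse_sequence(x)
}

#' Composition of a species: counts of A and D units
#'
#' @param nA Nonnegative integer count of GlcNAc units.
#' @param nD Nonnegative integer count of GlcN units.
#' @return Object of class `composition` with fields `nA`, `nD`.
#' @examples
#' composition(3, 1)  # the A3D1 species
#' @export
composition <- function(nA, nD) {
  nA <- as.integer(nA); nD <- as.integer(nD)
  if (is.na(nA) || is.na(nD) || nA < 0L || nD < 0L || nA + nD < 1L)
    stop("invalid composition: need nA >= 0, nD >= 0, nA + nD >= 1", call. = FALSE)
  structure(list(nA = nA, nD = nD), class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(composition_label(x), "\n", sep = "")
  invisible(x)
}

#' Composition of a sequence
#'
#' @param seq A `pa_sequence` (or A/D string).
#' @return `composition` with the counts of A and D units of `seq`.
#' @export
composition_of <- function(seq) {
  seq <- as_pa_sequence(seq)
  composition(sum(seq$units == "A"), sum(seq$units == "D"))
}

#' Parse a species label like "A3D1" into a composition
#'
#' @param label Species label of the form `AnDm` (e.g. `"A3D1"`, `"A4"`,
#'   `"D4"`); a missing count means that unit is absent.
#' @return `composition`.
#' @examples
#' parse_composition("A2D2")
#' @export
parse_composition <- function(label) {
  if (inherits(label, "composition")) return(label)
  stopifnot(is.character(label), length(label) == 1L)
  lab <- toupper(gsub("\\s", "", label))
  if (!grepl("^(A[0-9]+)?(D[0-9]+)?$", lab) || !nzchar(lab))
    stop(sprintf("cannot parse species label '%s'", label), call. = FALSE)
  getn <- function(code) {
    m <- regmatches(lab, regexec(paste0(code, "([0-9]+)"), lab))[[1L]]
    if (length(m) == 2L) as.integer(m[2L]) else 0L
  }
  composition(getn("A"), getn("D"))
}

#' Format a composition as a species label
#' @param comp A `composition`.
#' @return Character label, e.g. `"A3D1"`; zero counts are omitted
#'   (`"A4"`, `"D4"`), matching the field's species notation.
#' @export
composition_label <- function(comp) {
  paste0(if (comp$nA > 0L) sprintf("A%d", comp$nA),
         if (comp$nD > 0L) sprintf("D%d", comp$nD))
}

#' Monoisotopic m/z of the singly protonated [M+H]+ species
#'
#' Computes nA * mass(A) + nD * mass(D) + water + proton for an AnDm
#' species. Reproduces the standard MS1/MS2 target masses for fully and
#' partially acetylated tetramers, e.g. A3D1 at m/z 789.325 and A2D2 at
#' m/z 747.314.
#'
#' @param comp A `composition`, or a species label string (e.g. `"A3D1"`).
#' @return m/z in Da (full double precision; round for display).
#' @examples
#' round(mz_mh("A3D1"), 3)  # 789.325
#' @export
mz_mh <- function(comp) {
  comp <- parse_composition(comp)
  mc <- mass_constants()
  comp$nA * mc$residue_mass_A + comp$nD * mc$residue_mass_D + mc$water + mc$proton
}

#' Deacetylate or N-acetylate one unit of a sequence
#'
#' Applies a single catalytic event at a 1-based position (counted from the
#' nonreducing end): deacetylation converts A -> D, N-acetylation D -> A.
#'
#' @param seq A `pa_sequence` (or A/D string).
#' @param position 1-based position of the unit to modify.
#' @param direction `"deacetylate"` (requires A at `position`) or
#'   `"N-acetylate"` (requires D).
#' @return Modified `pa_sequence`; dp is conserved and fa changes by
#'   exactly 1/dp.
#' @examples
#' render_sequence(apply_modification("AAAA", 3, "deacetylate"))  # "AADA"
#' render_sequence(apply_modification("DDDD", 3, "N-acetylate"))  # "DDAD"
#' @export
apply_modification <- function(seq, position, direction = c("deacetylate", "N-acetylate")) {
  seq <- as_pa_sequence(seq)
  direction <- match.arg(direction)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > seq$dp)
    stop(sprintf("position %s out of range 1..%d", position, seq$dp), call. = FALSE)
  need <- if (direction == "deacetylate") "A" else "D"
  have <- seq$units[position]
  if (have != need)
    stop(sprintf("infeasible-modification: cannot %s %s unit at position %d",
                 direction, have, position), call. = FALSE)
  units <- seq$units
  units[position] <- if (need == "A") "D" else "A"
  new_pa_sequence(units)
}

# ---- sequence file I/O (FASTA-like and plain text) --------------------------

#' Read A/D sequences from a FASTA-like or plain text file
#'
#' FASTA-like files have header lines beginning with `>`; plain files hold
#' one sequence per line. Sequences are validated over \{A, D\}.
#'
#' @param path File path.
#' @return Named list of `pa_sequence` (names from headers, or `seq1`,
#'   `seq2`, ... for plain files).
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no sequences in ", path, call. = FALSE)
  if (any(startsWith(lines, ">"))) {
    idx <- cumsum(startsWith(lines, ">"))
    if (idx[1L] == 0L) stop("sequence data before first FASTA header", call. = FALSE)
    out <- list()
    for (i in seq_len(max(idx))) {
      chunk <- lines[idx == i]
      nm <- sub("^>\\s*", "", chunk[1L])
      out[[nm]] <- parse_sequence(paste(chunk[-1L], collapse = ""))
    }
    out
  } else {
    out <- lapply(lines, parse_sequence)
    names(out) <- paste0("seq", seq_along(out))
    out
  }
}

#' Write A/D sequences to a FASTA-like file
#'
#' @param seqs A `pa_sequence` or list of them (names become headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  if (inherits(seqs, "pa_sequence")) seqs <- list(seq1 = seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- render_sequence(as_pa_sequence(seqs[[nm]]))
    # wrap at 70 columns like conventional FASTA writers
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}
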