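# MS2 pattern-of-acetylation determination from B/Y glycosidic fragment
# ions. B ions are nonreducing-end oxocarbenium fragments (residues +
# proton), Y ions retain the reducing end (residues + water + proton).
# Sequence isomers of one composition differ only in which (ion_type,
# length, composition) species they produce; observed intensity shares are
# fitted onto the 0/1 incidence profiles of the candidate patterns by
# nonnegative least squares.

#' Theoretical B/Y fragment ions of an acetylation pattern
#'
#' All B_i (prefix) and Y_j (suffix) ions for i, j in 1..dp-1: 2(dp-1) ions.
#' The B1 ion of an A unit is the GlcNAc oxocarbenium at m/z 204.087.
#'
#' @param pattern A `pa_sequence` (or A/D string) with dp >= 2.
#' @return Data frame with `ion_type` ("B"/"Y"), `length`, `nA`, `nD`, `mz`.
#' @examples
#' theoretical_ions("AADA")
#' @export
theoretical_ions <- function(pattern) {
  pattern <- as_pa_sequence(pattern)
  if (pattern$dp < 2L) stop("pattern must have dp >= 2", call. = FALSE)
  mc <- mass_constants()
  u <- pattern$units
  dp <- pattern$dp
  len <- seq_len(dp - 1L)
  bA <- cumsum(u == "A")[len]  # prefix A counts
  yA <- vapply(len, function(l) sum(u[(dp - l + 1L):dp] == "A"), integer(1))  # suffix
  res_mass <- function(nA, n) nA * mc$residue_mass_A + (n - nA) * mc$residue_mass_D
  rbind(
    data.frame(ion_type = "B", length = len, nA = bA, nD = len - bA,
               mz = res_mass(bA, len) + mc$proton, stringsAsFactors = FALSE),
    data.frame(ion_type = "Y", length = len, nA = yA, nD = len - yA,
               mz = res_mass(yA, len) + mc$water + mc$proton,
               stringsAsFactors = FALSE))
}

#' All distinct acetylation patterns of a composition
#'
#' @param comp A `composition` or species label.
#' @return Character vector of all distinct A/D arrangements, sorted.
#' @examples
#' pattern_candidates("A3D1")  # "AAAD" "AADA" "ADAA" "DAAA"
#' @export
pattern_candidates <- function(comp) {
  comp <- parse_composition(comp)
  n <- comp$nA + comp$nD
  if (comp$nA == 0L) return(strrep("D", n))
  if (comp$nD == 0L) return(strrep("A", n))
  apos <- utils::combn(n, comp$nA, simplify = FALSE)
  sort(vapply(apos, function(idx) {
    u <- rep("D", n); u[idx] <- "A"; paste(u, collapse = "")
  }, character(1)))
}

ion_key <- function(ions) paste0(ions$ion_type, ions$length, "_A", ions$nA)

#' Incidence matrix of observable ion species over candidate patterns
#'
#' Rows are distinct observable ion species (ion type, fragment length,
#' composition — sequence isomers share m/z), columns are candidate
#' patterns; entries are 1 iff the candidate produces that ion species.
#' Rows identical across all candidates are uninformative for pattern
#' discrimination and are dropped when `drop_uninformative` is TRUE.
#'
#' @param candidates Character vector of patterns sharing one composition.
#' @param drop_uninformative Drop constant rows (default: only when more
#'   than one candidate is given).
#' @return 0/1 matrix with ion-species row names (e.g. `"B2_A1"`) and
#'   candidate column names; attribute `dropped` lists removed row keys.
#' @examples
#' incidence_matrix(c("ADDA", "AADD"))
#' @export
incidence_matrix <- function(candidates, drop_uninformative = length(candidates) > 1L) {
  stopifnot(length(candidates) >= 1L)
  comps <- vapply(candidates, function(p) composition_label(composition_of(p)), character(1))
  if (length(unique(comps)) != 1L)
    stop("candidates must share one composition", call. = FALSE)
  ion_sets <- lapply(candidates, function(p) unique(ion_key(theoretical_ions(p))))
  keys <- sort(unique(unlist(ion_sets)))
  M <- vapply(ion_sets, function(ks) as.numeric(keys %in% ks),
              numeric(length(keys)))
  M <- matrix(M, nrow = length(keys),
              dimnames = list(keys, candidates))
  dropped <- character()
  if (drop_uninformative && ncol(M) > 1L) {
    const <- apply(M, 1L, function(r) all(r == r[1L]))
    dropped <- rownames(M)[const]
    M <- M[!const, , drop = FALSE]
  }
  attr(M, "dropped") <- dropped
  M
}

#' Deconvolute observed MS2 ion intensities into a pattern distribution
#'
#' Fits the observed ion-species intensity shares onto the candidates'
#' incidence profiles by nonnegative least squares (Lawson-Hanson, with a
#' small ridge term for degenerate fits) and renormalizes the solution to
#' sum to 1. Candidates with identical incidence columns cannot be
#' distinguished; they trigger an ambiguity warning listing the classes.
#'
#' @param observed Data frame with columns `ion_type`, `length`, `nA`
#'   (`nD` optional), `intensity` (or a CSV path); or a named numeric
#'   vector keyed like `"B2_A1"`.
#' @param candidates Character vector of candidate patterns sharing the
#'   product composition; defaults to all distinct arrangements of
#'   `composition` when that is given instead.
#' @param ridge Ridge regularization weight (default 1e-9).
#' @return Object of class `pattern_distribution`: named numeric fractions
#'   (sum 1) over candidates, with attribute `residual` (relative residual
#'   norm of the NNLS fit on intensity shares).
#' @examples
#' obs <- synth_ms2(c(ADDA = 2/3, AADD = 1/3), seed = 1, noise_cv = 0)
#' deconvolute(obs, c("ADDA", "AADD"))
#' @export
deconvolute <- function(observed, candidates, ridge = 1e-9) {
  if (is.character(observed) && length(observed) == 1L)
    observed <- utils::read.csv(observed)
  if (is.data.frame(observed)) {
    stopifnot(all(c("ion_type", "length", "nA", "intensity") %in% names(observed)))
    b_all <- stats::setNames(observed$intensity,
                             paste0(observed$ion_type, observed$length, "_A", observed$nA))
  } else {
    stopifnot(is.numeric(observed), !is.null(names(observed)))
    b_all <- observed
  }
  if (!length(b_all) || all(b_all == 0))
    stop("no-signal: all observed ion intensities are zero", call. = FALSE)
  M <- incidence_matrix(candidates)
  # indistinguishable candidates: identical incidence columns
  colkey <- apply(M, 2L, paste, collapse = "")
  if (anyDuplicated(colkey)) {
    classes <- split(colnames(M), colkey)
    classes <- Filter(function(g) length(g) > 1L, classes)
    warning("ambiguity: indistinguishable candidate classes: ",
            paste(vapply(classes, paste, character(1), collapse = "="),
                  collapse = "; "), call. = FALSE)
  }
  b <- b_all[rownames(M)]
  b[is.na(b)] <- 0
  tot <- sum(b_all)
  b <- b / tot  # intensity shares; scale-invariant fit
  A <- rbind(M, sqrt(ridge) * diag(ncol(M)))
  rhs <- c(b, rep(0, ncol(M)))
  fit <- pracma::lsqnonneg(A, rhs)
  x <- fit$x
  if (sum(x) <= 0)
    stop("deconvolution failed: all-zero NNLS solution", call. = FALSE)
  frac <- x / sum(x)
  names(frac) <- colnames(M)
  resid <- sqrt(sum((as.vector(M %*% x) - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
  structure(frac, residual = resid, class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat("pattern distribution (residual", format(attr(x, "residual"), digits = 3), "):\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(round(v, 4))
  invisible(x)
}
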