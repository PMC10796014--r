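# MS1 species quantification for paCOS deacetylation assays. Peaks are
# matched to AnDm [M+H]+ targets within an absolute m/z tolerance; relative
# amounts assume equal ionization response across species of equal DP.

#' Build species targets for quantification
#'
#' @param species Character vector of species labels (e.g.
#'   `c("A4", "A3D1", "A2D2")`) or list of `composition` objects.
#' @param tolerance Absolute m/z half-window in Da (default 0.02).
#' @return Data frame with `species`, `nA`, `nD`, `target_mz`, `tolerance`.
#' @export
species_targets <- function(species, tolerance = 0.02) {
  stopifnot(tolerance > 0)
  comps <- lapply(species, parse_composition)
  data.frame(
    species = vapply(comps, composition_label, character(1)),
    nA = vapply(comps, `[[`, integer(1), "nA"),
    nD = vapply(comps, `[[`, integer(1), "nD"),
    target_mz = vapply(comps, mz_mh, numeric(1)),
    tolerance = tolerance,
    stringsAsFactors = FALSE)
}

#' Quantify relative species amounts from a peak list
#'
#' Sums peak intensities within +/- tolerance of each target m/z and
#' normalizes by the total matched intensity, so the relative amounts sum
#' to 1 over the detected species (substrate included).
#'
#' @param peaks Data frame with columns `mz`, `intensity` (or a CSV path).
#' @param targets Data frame from [species_targets()], or a character vector
#'   of species labels (default tolerance then applies).
#' @param tolerance Used when `targets` is a label vector.
#' @return Object of class `relative_amounts`: named numeric vector of
#'   fractions keyed by species label, with attributes `intensity` (raw
#'   matched intensities) and `targets`.
#' @examples
#' pk <- data.frame(mz = c(789.325, 831.335), intensity = c(300, 700))
#' quantify(pk, c("A3D1", "A4"))
#' @export
quantify <- function(peaks, targets, tolerance = 0.02) {
  if (is.character(peaks) && length(peaks) == 1L) peaks <- utils::read.csv(peaks)
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (any(peaks$mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
  if (any(peaks$intensity < 0)) stop("peak intensities must be nonnegative", call. = FALSE)
  if (!is.data.frame(targets)) targets <- species_targets(targets, tolerance)
  # windows must not overlap: pairwise separation > 2 * tolerance
  ord <- order(targets$target_mz)
  tmz <- targets$target_mz[ord]
  tol <- targets$tolerance[ord]
  if (nrow(targets) > 1L && any(diff(tmz) <= tol[-length(tol)] + tol[-1L]))
    stop("configuration error: target m/z windows overlap", call. = FALSE)
  inten <- vapply(seq_len(nrow(targets)), function(i) {
    sum(peaks$intensity[abs(peaks$mz - targets$target_mz[i]) <= targets$tolerance[i]])
  }, numeric(1))
  total <- sum(inten)
  if (total <= 0) stop("no-signal: no peak matched any target window", call. = FALSE)
  ra <- inten / total
  names(ra) <- targets$species
  structure(ra, intensity = stats::setNames(inten, targets$species),
            targets = targets, class = "relative_amounts")
}

#' Relative acetate release from relative species amounts
#'
#' For a declared substrate AnDm, each product species contributes
#' k = nD(product) - nD(substrate) released acetate units per molecule, so
#' rar = sum over products of k * ra. For an A4 substrate this is
#' raA3D1 + 2 raA2D2 (+ 3 raA1D3 + 4 raD4); for A3D1 it is
#' raA2D2 + 2 raA1D3 + 3 raD4.
#'
#' @param ra Named numeric vector of relative amounts keyed by species label
#'   (e.g. output of [quantify()]).
#' @param substrate Substrate species label or `composition`.
#' @return Relative acetate release (dimensionless, in `[0, nA(substrate)]`).
#' @examples
#' relative_acetate_release(c(A3D1 = 0.65, A2D2 = 0.2, A1D3 = 0.1, D4 = 0.05),
#'                          "A3D1")  # 0.55
#' @export
relative_acetate_release <- function(ra, substrate) {
  stopifnot(is.numeric(ra), !is.null(names(ra)))
  sub <- parse_composition(substrate)
  comps <- lapply(names(ra), parse_composition)
  k <- vapply(comps, `[[`, integer(1), "nD") - sub$nD
  dp_ok <- vapply(comps, function(cc) cc$nA + cc$nD, integer(1)) == (sub$nA + sub$nD)
  if (!all(dp_ok))
    stop("inconsistent-species: species DP differs from substrate DP", call. = FALSE)
  if (any(k < 0 & ra > 0))
    stop("inconsistent-species: species more acetylated than the substrate present",
         call. = FALSE)
  sum(k[k >= 1] * ra[k >= 1])
}

#' Normalize activities to reference (nonmutated-enzyme) wells
#'
#' Divides every value by the mean of the reference values, so references
#' average to 1.
#'
#' @param values Named numeric vector, id -> activity (e.g. rar values).
#' @param reference_ids Names of the reference entries.
#' @return Named numeric vector of relative activities.
#' @examples
#' normalize_to_reference(c(m1 = 0.45, ref = 0.9), "ref")
#' @export
normalize_to_reference <- function(values, reference_ids) {
  stopifnot(is.numeric(values), !is.null(names(values)))
  refs <- values[names(values) %in% reference_ids]
  refs <- refs[is.finite(refs)]
  if (!length(refs) || mean(refs) <= 0)
    stop("normalization error: no reference with finite positive value", call. = FALSE)
  values / mean(refs)
}

#' @export
print.relative_amounts <- function(x, ...) {
  cat("relative amounts:\n")
  print(round(unclass(x)[seq_along(x)], 4))
  invisible(x)
}
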