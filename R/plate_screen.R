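# Site-saturation-mutagenesis (SSM) plate-screen analytics: library
# enumeration, fluorescamine glucosamine standard curves, per-plate control
# normalization and the SD-threshold outlier-elimination rule.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Enumerate a site-saturation mutagenesis library
#'
#' For each selected position, generates all 19 substitutions (every
#' standard amino acid except the wild type), ordered by position then
#' alphabetical residue. 27 positions give the full 513-mutein library.
#'
#' @param wt_sequence Wild-type amino-acid string (one-letter codes).
#' @param positions Integer vector of 1-based positions to saturate, or a
#'   named vector / data.frame(`index`, `wt`) also declaring the expected
#'   wild-type residue for consistency checking.
#' @return Object of class `ssm_library`: data frame with `position`, `wt`,
#'   `substitution`, `mutein_id` (e.g. `"N75K"`).
#' @examples
#' nrow(enumerate_ssm(strrep("ACDEFGHIKLMNPQRSTVWY", 2), 1:27))  # 513
#' @export
enumerate_ssm <- function(wt_sequence, positions) {
  stopifnot(is.character(wt_sequence), length(wt_sequence) == 1L)
  seq_aa <- strsplit(toupper(wt_sequence), "")[[1L]]
  if (is.data.frame(positions)) {
    idx <- as.integer(positions$index)
    declared <- toupper(positions$wt)
  } else {
    idx <- as.integer(positions)
    declared <- NULL
  }
  if (any(idx < 1L | idx > length(seq_aa)))
    stop("position index out of sequence range", call. = FALSE)
  wt <- seq_aa[idx]
  if (!is.null(declared) && any(wt != declared)) {
    bad <- which(wt != declared)[1L]
    stop(sprintf("consistency error: declared wt %s at position %d but sequence has %s",
                 declared[bad], idx[bad], wt[bad]), call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_along(idx), function(i) {
    subs <- setdiff(AA1, wt[i])
    data.frame(position = idx[i], wt = wt[i], substitution = subs,
               mutein_id = paste0(wt[i], idx[i], subs),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$position, rows$substitution), ]
  rownames(rows) <- NULL
  structure(rows, class = c("ssm_library", "data.frame"))
}

#' Fit a glucosamine standard curve
#'
#' Ordinary least-squares line fluorescence ~ concentration, fitted on the
#' standard wells (typically 0, 75, 150 and 250 uM glucosamine).
#'
#' @param standards Data frame with columns `concentration` (uM) and
#'   `fluorescence`, or two numeric vectors.
#' @param fluorescence Fluorescence vector when `standards` is a
#'   concentration vector.
#' @return Object of class `standard_curve`: list with `slope` (fluorescence
#'   per uM), `intercept`, `r_squared`, `n`.
#' @examples
#' fit_standard(c(0, 75, 150, 250), 100 + 2 * c(0, 75, 150, 250))
#' @export
fit_standard <- function(standards, fluorescence = NULL) {
  if (!is.data.frame(standards))
    standards <- data.frame(concentration = standards, fluorescence = fluorescence)
  stopifnot(all(c("concentration", "fluorescence") %in% names(standards)))
  if (length(unique(standards$concentration)) < 2L)
    stop("degenerate-fit: need at least 2 distinct standard concentrations",
         call. = FALSE)
  fit <- stats::lm(fluorescence ~ concentration, data = standards)
  co <- stats::coef(fit)
  # exact standards are legitimate; silence lm's perfect-fit chatter
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(co[2L]), intercept = unname(co[1L]),
                 r_squared = r2, n = nrow(standards)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard curve: f = %.4g + %.4g * c (r^2 = %.4f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Free primary-amine concentration from fluorescence
#'
#' Inverts the standard curve: (fluorescence - intercept) / slope. Negative
#' raw values are clamped to 0 and flagged.
#'
#' @param fluorescence Numeric vector of fluorescence readings.
#' @param curve A `standard_curve`.
#' @return Numeric vector of concentrations (uM) with attribute `clamped`
#'   (logical vector marking readings below the blank).
#' @export
amine_concentration <- function(fluorescence, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("zero-slope standard curve", call. = FALSE)
  conc <- (fluorescence - curve$intercept) / curve$slope
  clamped <- conc < 0
  conc[clamped] <- 0
  attr(conc, "clamped") <- clamped
  conc
}

#' Normalize one plate's mutein concentrations to its control wells
#'
#' Divides every mutein amine concentration by the mean concentration of
#' that plate's nonmutated-enzyme control wells, so the controls average
#' to 1.
#'
#' @param records Data frame for one plate with columns `well`, `role`
#'   (`"standard"`, `"control"`, `"mutein"`, `"empty"`), `payload`
#'   (standard concentration in uM, or mutein id), `fluorescence`.
#' @param curve Optional `standard_curve`; fitted from the plate's own
#'   standard wells when NULL.
#' @return Data frame of the plate's mutein wells with added columns
#'   `concentration` and `activity` (normalized).
#' @export
normalize_plate <- function(records, curve = NULL) {
  stopifnot(all(c("role", "payload", "fluorescence") %in% names(records)))
  if (is.null(curve)) {
    std <- records[records$role == "standard", ]
    if (!nrow(std)) stop("no standard wells on plate", call. = FALSE)
    curve <- fit_standard(as.numeric(std$payload), std$fluorescence)
  }
  ctrl <- records[records$role == "control", ]
  if (!nrow(ctrl)) stop("normalization error: no control wells", call. = FALSE)
  ctrl_conc <- as.numeric(amine_concentration(ctrl$fluorescence, curve))
  if (mean(ctrl_conc) <= 0)
    stop("normalization error: mean control concentration <= 0", call. = FALSE)
  mut <- records[records$role == "mutein", , drop = FALSE]
  mut$concentration <- as.numeric(amine_concentration(mut$fluorescence, curve))
  mut$activity <- mut$concentration / mean(ctrl_conc)
  mut
}

#' Robust mean of replicate activities with one-shot outlier elimination
#'
#' Computes the mean and sample standard deviation of the replicates. If
#' SD > `sd_threshold`, the value furthest from the mean is removed (ties
#' broken toward the larger value) and the SD recomputed; the removal is
#' kept only if it lowers the SD by more than `sd_improvement` (relative),
#' otherwise it is withdrawn. At most one value is ever removed, and only
#' when 3 or more replicates are available.
#'
#' @param replicates Numeric vector of normalized activities.
#' @param sd_threshold SD above which elimination is attempted (default 0.2,
#'   on the normalized-activity scale).
#' @param sd_improvement Minimum relative SD decrease to keep the removal
#'   (default 0.2, i.e. 20 percent).
#' @return List with `mean`, `sd`, `n_total`, `n_used`, `outlier_removed`,
#'   `removed_value` (NA when none).
#' @examples
#' robust_mean(c(1.0, 1.0, 1.6))        # removes 1.6
#' robust_mean(c(0.0, 0.01, 0.99, 1.0)) # removal withdrawn (bimodal)
#' @export
robust_mean <- function(replicates, sd_threshold = 0.2, sd_improvement = 0.2) {
  x <- replicates[is.finite(replicates)]
  if (length(x) < 2L)
    stop("insufficient-data: need at least 2 finite replicates", call. = FALSE)
  m0 <- mean(x); s0 <- stats::sd(x)
  res <- list(mean = m0, sd = s0, n_total = length(replicates),
              n_used = length(x), outlier_removed = FALSE, removed_value = NA_real_)
  if (length(x) >= 3L && s0 > sd_threshold) {
    dev <- abs(x - m0)
    worst <- which(dev == max(dev))
    worst <- worst[which.max(x[worst])]  # tie: remove the larger value
    kept <- x[-worst]
    s1 <- stats::sd(kept)
    if ((s0 - s1) / s0 > sd_improvement) {
      res$mean <- mean(kept)
      res$sd <- s1
      res$n_used <- length(kept)
      res$outlier_removed <- TRUE
      res$removed_value <- x[worst]
    }
  }
  res
}

#' Aggregate a whole screen: per-plate normalization, then robust means
#'
#' @param records Data frame over all plates with columns `plate`, `well`,
#'   `role`, `payload`, `fluorescence` (or a CSV path). Each plate is
#'   normalized independently; plates failing normalization are reported
#'   and skipped.
#' @param sd_threshold,sd_improvement Passed to [robust_mean()].
#' @return List with `results` (data frame: `mutein_id`, `mean`, `sd`,
#'   `n_total`, `n_used`, `outlier_removed`), `failed_plates` (named list
#'   of error messages), `per_replicate` (long data frame of normalized
#'   activities).
#' @export
screen_activities <- function(records, sd_threshold = 0.2, sd_improvement = 0.2) {
  if (is.character(records) && length(records) == 1L)
    records <- utils::read.csv(records, stringsAsFactors = FALSE)
  stopifnot(all(c("plate", "role", "payload", "fluorescence") %in% names(records)))
  failed <- list()
  reps <- list()
  for (pl in unique(records$plate)) {
    one <- records[records$plate == pl, ]
    norm <- tryCatch(normalize_plate(one), error = function(e) e)
    if (inherits(norm, "error")) {
      failed[[as.character(pl)]] <- conditionMessage(norm)
      next
    }
    reps[[as.character(pl)]] <- data.frame(plate = pl,
                                           mutein_id = norm$payload,
                                           activity = norm$activity,
                                           stringsAsFactors = FALSE)
  }
  if (!length(reps))
    stop("all plates failed normalization", call. = FALSE)
  long <- do.call(rbind, reps)
  ids <- unique(long$mutein_id)
  rows <- lapply(ids, function(id) {
    r <- robust_mean(long$activity[long$mutein_id == id],
                     sd_threshold, sd_improvement)
    data.frame(mutein_id = id, mean = r$mean, sd = r$sd,
               n_total = r$n_total, n_used = r$n_used,
               outlier_removed = r$outlier_removed, stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, rows), failed_plates = failed,
       per_replicate = long)
}

#' Position x residue activity matrix from screen results
#'
#' Pivots per-mutein mean activities into the heatmap layout: rows are
#' substituted residues (alphabetical), columns are positions. Mutein ids
#' must follow the `<wt><position><substitution>` convention (e.g.
#' `"N75K"`).
#'
#' @param results Data frame with `mutein_id` and `mean` (from
#'   [screen_activities()]).
#' @return Numeric matrix, residues x positions; NA where no mutein.
#' @export
activity_matrix <- function(results) {
  m <- regmatches(results$mutein_id,
                  regexec("^([A-Z])([0-9]+)([A-Z])$", results$mutein_id))
  ok <- lengths(m) == 4L
  if (!any(ok)) stop("no mutein ids of the form <wt><pos><sub>", call. = FALSE)
  pos <- as.integer(vapply(m[ok], `[`, character(1), 3L))
  sub <- vapply(m[ok], `[`, character(1), 4L)
  wt <- vapply(m[ok], `[`, character(1), 2L)
  cols <- sort(unique(pos))
  colnm <- paste0(wt[match(cols, pos)], cols)
  mat <- matrix(NA_real_, nrow = length(AA1), ncol = length(cols),
                dimnames = list(AA1, colnm))
  means <- results$mean[ok]
  for (i in seq_along(pos))
    mat[sub[i], match(pos[i], cols)] <- means[i]
  mat
}
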