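# Seeded generators for every input the pipeline consumes, with known
# ground truth: A/D polymers, MS1 peak lists, MS2 ion tables and 96-well
# fluorescamine plates. All generators are bit-reproducible under their
# seed argument.

#' Random (Bernoulli) chitosan polymer
#'
#' Each unit is independently GlcNAc with probability `fa` — the chemical
#' (random-PA) control.
#'
#' @param dp Degree of polymerization (>= 1).
#' @param fa Target fraction of acetylation in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `pa_sequence`.
#' @examples
#' random_polymer(20, 0.5, seed = 1)
#' @export
random_polymer <- function(dp, fa, seed = 1L) {
  stopifnot(dp >= 1, fa >= 0, fa <= 1)
  set.seed(as.integer(seed))
  new_pa_sequence(ifelse(stats::runif(dp) < fa, "A", "D"))
}

#' Deterministic patterned polymer (alternating or blocky)
#'
#' Repeats a motif — `"AD"` for alternating, `A^a D^d` for blocky — and
#' truncates to `dp` units.
#'
#' @param dp Degree of polymerization.
#' @param kind `"alternating"` or `"blocky"`.
#' @param a_len,d_len Block lengths for the blocky kind (>= 1).
#' @return A `pa_sequence`.
#' @examples
#' render_sequence(patterned_polymer(10, "blocky", 3, 2))  # "AAADDAAADD"
#' @export
patterned_polymer <- function(dp, kind = c("alternating", "blocky"),
                              a_len = 1L, d_len = 1L) {
  kind <- match.arg(kind)
  stopifnot(dp >= 1, a_len >= 1, d_len >= 1)
  motif <- if (kind == "alternating") c("A", "D")
           else c(rep("A", a_len), rep("D", d_len))
  new_pa_sequence(rep_len(motif, dp))
}

#' Synthetic MS1 peak list from known relative amounts
#'
#' One peak per species at its [M+H]+ m/z plus Gaussian jitter, with
#' intensity `total_intensity * ra * (1 + N(0, cv))`, clamped at 0.
#'
#' @param true_ra Named numeric vector: species label -> fraction (sums
#'   to 1).
#' @param total_intensity Total ion intensity to distribute.
#' @param mz_sd m/z jitter SD in Da.
#' @param intensity_cv Multiplicative intensity noise CV.
#' @param seed Integer seed.
#' @return Data frame with `mz`, `intensity` and attribute `truth`.
#' @examples
#' synth_peaklist(c(A4 = 0.25, A3D1 = 0.5, A2D2 = 0.25), seed = 3)
#' @export
synth_peaklist <- function(true_ra, total_intensity = 1e6, mz_sd = 0.005,
                           intensity_cv = 0.02, seed = 1L) {
  stopifnot(abs(sum(true_ra) - 1) < 1e-9, mz_sd >= 0, intensity_cv >= 0)
  set.seed(as.integer(seed))
  n <- length(true_ra)
  mz <- vapply(names(true_ra), mz_mh, numeric(1)) + stats::rnorm(n, 0, mz_sd)
  inten <- pmax(0, total_intensity * true_ra * (1 + stats::rnorm(n, 0, intensity_cv)))
  out <- data.frame(mz = as.numeric(mz), intensity = as.numeric(inten))
  attr(out, "truth") <- true_ra
  out
}

#' Synthetic MS2 ion table from a known pattern mixture
#'
#' Ion-species intensities are the incidence-weighted mixture of the
#' patterns' B/Y ladders (equal response per ion), perturbed with
#' multiplicative Gaussian noise.
#'
#' @param mixture Named numeric vector: pattern -> fraction (sums to 1);
#'   patterns must share one composition.
#' @param intensity Total intensity scale per pattern unit.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @return Data frame with `ion_type`, `length`, `nA`, `nD`, `intensity`
#'   and attribute `truth`.
#' @examples
#' synth_ms2(c(ADDA = 2/3, AADD = 1/3), noise_cv = 0, seed = 1)
#' @export
synth_ms2 <- function(mixture, intensity = 1e4, noise_cv = 0, seed = 1L) {
  stopifnot(abs(sum(mixture) - 1) < 1e-9, all(mixture >= 0), noise_cv >= 0)
  set.seed(as.integer(seed))
  M <- incidence_matrix(names(mixture), drop_uninformative = FALSE)
  inten <- as.vector(M %*% mixture) * intensity
  inten <- pmax(0, inten * (1 + stats::rnorm(length(inten), 0, noise_cv)))
  key <- rownames(M)
  m <- regmatches(key, regexec("^([BY])([0-9]+)_A([0-9]+)$", key))
  ion_type <- vapply(m, `[`, character(1), 2L)
  len <- as.integer(vapply(m, `[`, character(1), 3L))
  nA <- as.integer(vapply(m, `[`, character(1), 4L))
  out <- data.frame(ion_type = ion_type, length = len, nA = nA,
                    nD = len - nA, intensity = inten,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- mixture
  out
}

#' Synthetic 96-well fluorescamine screen
#'
#' Generates `replicates` plates per chunk of up to 76 muteins. Each plate
#' carries 4 glucosamine standards (0, 75, 150, 250 uM) on the linear curve
#' `fluorescence = intercept + slope * concentration`, `n_controls`
#' nonmutated-enzyme control wells at `control_conc` uM, and one well per
#' mutein at `activity * control_conc` uM. Additive Gaussian noise
#' (`noise_sd`, uM) applies to control and mutein concentrations; with
#' probability `outlier_prob` a mutein well's concentration is multiplied
#' by `outlier_scale`.
#'
#' @param true_activities Named numeric vector: mutein id -> activity
#'   relative to the control.
#' @param control_conc Control amine concentration in uM.
#' @param slope,intercept Standard-curve parameters (fluorescence units).
#' @param n_controls Control wells per plate (default 4).
#' @param replicates Independent measurements per mutein (default 4).
#' @param noise_sd Additive concentration noise SD in uM.
#' @param outlier_prob Per-well probability of a planted outlier.
#' @param outlier_scale Multiplier applied to outlier wells.
#' @param seed Integer seed.
#' @return Data frame with `plate`, `well`, `role`, `payload`,
#'   `fluorescence` and attribute `truth`.
#' @examples
#' plates <- synth_plate(c(N75K = 0.1, H199Y = 1.4), noise_sd = 0, seed = 1)
#' @export
synth_plate <- function(true_activities, control_conc = 100, slope = 20,
                        intercept = 500, n_controls = 4L, replicates = 4L,
                        noise_sd = 0, outlier_prob = 0, outlier_scale = 3,
                        seed = 1L) {
  stopifnot(outlier_prob >= 0, outlier_prob <= 1, control_conc > 0)
  set.seed(as.integer(seed))
  std_conc <- c(0, 75, 150, 250)
  ids <- names(true_activities)
  chunks <- split(ids, ceiling(seq_along(ids) / 76L))
  out <- list()
  for (r in seq_len(replicates)) {
    for (ci in seq_along(chunks)) {
      plate_id <- sprintf("rep%d_plate%d", r, ci)
      conc_ctrl <- control_conc + stats::rnorm(n_controls, 0, noise_sd)
      mut_ids <- chunks[[ci]]
      conc_mut <- true_activities[mut_ids] * control_conc +
        stats::rnorm(length(mut_ids), 0, noise_sd)
      is_out <- stats::runif(length(mut_ids)) < outlier_prob
      conc_mut[is_out] <- conc_mut[is_out] * outlier_scale
      conc <- c(std_conc, conc_ctrl, conc_mut)
      wells <- well_ids(length(conc))
      out[[plate_id]] <- data.frame(
        plate = plate_id,
        well = wells,
        role = c(rep("standard", length(std_conc)),
                 rep("control", n_controls),
                 rep("mutein", length(mut_ids))),
        payload = c(as.character(std_conc), rep("nm", n_controls), mut_ids),
        fluorescence = intercept + slope * pmax(0, conc),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- true_activities
  res
}

well_ids <- function(n) {
  stopifnot(n <= 96)
  grid <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  grid[seq_len(n)]
}

#' Write a full synthetic fixture set with ground truth
#'
#' Drives every generator from one spec and writes sequences (FASTA-like),
#' an MS1 peak list, an MS2 ion table and a plate table as plain-text
#' files, plus `truth.json` holding every generator's ground truth.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed; per-generator seeds are derived from it.
#' @return Invisibly, the list of written paths.
#' @export
make_synthetic <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  seqs <- list(
    random = random_polymer(1000, 0.3, seed = seed),
    alternating = patterned_polymer(1000, "alternating"),
    blocky = patterned_polymer(1000, "blocky", 3, 2))
  ra <- c(A4 = 0.25, A3D1 = 0.5, A2D2 = 0.25)
  mix <- c(ADDA = 2 / 3, AADD = 1 / 3)
  set.seed(seed)
  act <- stats::setNames(round(stats::runif(20), 3),
                         paste0("N", 70 + seq_len(20), "K"))
  paths <- list(
    sequences = file.path(out_dir, "sequences.fasta"),
    peaklist = file.path(out_dir, "peaklist.csv"),
    ms2 = file.path(out_dir, "ms2.csv"),
    plates = file.path(out_dir, "plates.csv"),
    truth = file.path(out_dir, "truth.json"))
  write_sequences(seqs, paths$sequences)
  utils::write.csv(synth_peaklist(ra, seed = seed + 1L), paths$peaklist,
                   row.names = FALSE)
  utils::write.csv(synth_ms2(mix, noise_cv = 0.05, seed = seed + 2L),
                   paths$ms2, row.names = FALSE)
  utils::write.csv(synth_plate(act, noise_sd = 5, outlier_prob = 0.05,
                               seed = seed + 3L),
                   paths$plates, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, ms1_ra = as.list(ra), ms2_mixture = as.list(mix),
         plate_activities = as.list(act),
         noise = list(ms1_mz_sd = 0.005, ms1_intensity_cv = 0.02,
                      ms2_noise_cv = 0.05, plate_noise_sd = 5,
                      plate_outlier_prob = 0.05)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
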