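# End-to-end workflows: the polymer N-acetylation study (simulate ->
# chitinosanase digest -> block statistics across an F_A grid, per subsite
# profile, with a random-PA chemical control) and the mutein plate screen
# (standard curve -> amine concentrations -> per-plate normalization ->
# robust means -> activity matrix).

#' Polymer N-acetylation workflow across an F_A grid
#'
#' For each named subsite profile, N-acetylates a polyglucosamine chain to
#' the last checkpoint, snapshotting at every F_A checkpoint, digests each
#' snapshot with chitinosanase and records the weight-average block sizes
#' and the oligomeric fraction. A Bernoulli random polymer at the same F_A
#' serves as the chemical (random-PA) control. Results are averaged over
#' `n_seeds` independent trajectories per profile.
#'
#' @param profiles Named list of `subsite_profile` objects (e.g. from
#'   [profile_preset()]).
#' @param dp Polymer length (default 1000).
#' @param checkpoints Increasing F_A values to snapshot (default
#'   `seq(0.1, 0.5, 0.1)`, mirroring typical F_A series).
#' @param n_seeds Trajectories per profile (default 5).
#' @param seed Master seed; per-trajectory seeds are derived from it.
#' @param weighting Fragment-table weighting for [digest_and_score()].
#' @param out_dir Optional directory; when given, writes `polymer_report.csv`
#'   and a JSON manifest echoing the configuration.
#' @return Data frame with columns `profile`, `fa`, `blockA_w`, `blockD_w`,
#'   `oligomeric_fraction`, `a1d1_share` (intensity share of the A1D1
#'   species), averaged over seeds; the control appears as profile
#'   `"random"`.
#' @export
run_polymer_workflow <- function(profiles = list(nm = profile_preset("nm")),
                                 dp = 1000L,
                                 checkpoints = seq(0.1, 0.5, 0.1),
                                 n_seeds = 5L, seed = 1L,
                                 weighting = c("mass", "molar"),
                                 out_dir = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)),
            all(diff(checkpoints) > 0))
  start <- new_pa_sequence(rep("D", dp))
  target <- checkpoints[length(checkpoints)]
  score_snap <- function(s) {
    sc <- digest_and_score(s, weighting = weighting)
    tab <- sc$table
    a1d1 <- sum(tab$I[tab$dp == 2L & tab$nA == 1L]) / sum(tab$I)
    c(blockA_w = sc$stats$blockA_w, blockD_w = sc$stats$blockD_w,
      oligomeric_fraction = sc$stats$oligomeric_fraction, a1d1_share = a1d1)
  }
  rows <- list()
  for (nm in names(profiles)) {
    for (k in seq_len(n_seeds)) {
      tr <- simulate_polymer(start, profiles[[nm]], "N-acetylate",
                             target_fa = target, checkpoints = checkpoints,
                             seed = seed + 1000L * k)
      for (cp in names(tr$snapshots)) {
        rows[[length(rows) + 1L]] <- data.frame(
          profile = nm, seed_rep = k, fa = as.numeric(cp),
          t(score_snap(tr$snapshots[[cp]])), stringsAsFactors = FALSE)
      }
    }
  }
  # random-PA chemical control at the same F_A grid
  for (k in seq_len(n_seeds)) {
    for (cp in checkpoints) {
      ctrl <- random_polymer(dp, cp, seed = seed + 2000L * k + round(1e3 * cp))
      rows[[length(rows) + 1L]] <- data.frame(
        profile = "random", seed_rep = k, fa = cp,
        t(score_snap(ctrl)), stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(
    long[c("blockA_w", "blockD_w", "oligomeric_fraction", "a1d1_share")],
    by = long[c("profile", "fa")], FUN = mean)
  agg <- agg[order(agg$profile, agg$fa), ]
  rownames(agg) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(agg, file.path(out_dir, "polymer_report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(workflow = "polymer", package_version = as.character(
             utils::packageVersion("chitosim")),
           dp = dp, checkpoints = checkpoints, n_seeds = n_seeds,
           seed = seed, weighting = weighting, profiles = names(profiles)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  agg
}

#' Mutein screen workflow: plates in, activity table and matrix out
#'
#' Runs the full fluorescamine-screen analysis on a plate table: per-plate
#' glucosamine standard regression, amine-concentration conversion,
#' normalization to the plate's nonmutated-enzyme controls, and robust
#' means with the SD-threshold outlier rule. Failing plates are skipped
#' and reported.
#'
#' @param records Plate data frame or CSV path (columns `plate`, `well`,
#'   `role`, `payload`, `fluorescence`).
#' @param sd_threshold,sd_improvement Outlier-rule parameters (defaults
#'   0.2 / 0.2).
#' @param out_dir Optional directory; writes `screen_results.csv`,
#'   `activity_matrix.csv` and a JSON manifest.
#' @return List with `results`, `matrix` (position x residue activity
#'   matrix, NULL when mutein ids are not of the `<wt><pos><sub>` form),
#'   `failed_plates`.
#' @export
run_screen_workflow <- function(records, sd_threshold = 0.2,
                                sd_improvement = 0.2, out_dir = NULL) {
  sc <- screen_activities(records, sd_threshold, sd_improvement)
  mat <- tryCatch(activity_matrix(sc$results), error = function(e) NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sc$results, file.path(out_dir, "screen_results.csv"),
                     row.names = FALSE)
    if (!is.null(mat))
      utils::write.csv(mat, file.path(out_dir, "activity_matrix.csv"))
    jsonlite::write_json(
      list(workflow = "screen", package_version = as.character(
             utils::packageVersion("chitosim")),
           sd_threshold = sd_threshold, sd_improvement = sd_improvement,
           n_muteins = nrow(sc$results),
           failed_plates = sc$failed_plates),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(results = sc$results, matrix = mat, failed_plates = sc$failed_plates)
}
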