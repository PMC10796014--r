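# Reference profile used throughout: GlcNAc preference at -2 (-3 kT) and
# -1 (-1 kT), +1 kT penalty for an uncovered +1 subsite.
ref_profile <- subsite_profile(A = c(`-2` = -3, `-1` = -1), empty = c(`1` = 1))

test_that("enumerate_frames lists one frame per eligible subsite-0 position", {
  fr <- enumerate_frames("AAAA", "deacetylate")
  expect_equal(fr$position, 1:4)
  expect_equal(fr$span_label, c("[+0,+3]", "[-1,+2]", "[-2,+1]", "[-3,+0]"))
  expect_equal(enumerate_frames("AADA", "deacetylate")$position, c(1L, 2L, 4L))
  expect_equal(nrow(enumerate_frames("DDDD", "deacetylate")), 0L)
  expect_equal(enumerate_frames("AADA", "N-acetylate")$position, 3L)
})

test_that("frame_energy sums covered-subsite and occupancy terms", {
  expect_equal(frame_energy("AAAA", 3, ref_profile), -4)
  expect_equal(frame_energy("AAAA", 1:4, subsite_profile()), rep(0, 4))
  hard <- subsite_profile(D = c(`-2` = Inf))
  expect_equal(frame_energy("DAAA", 3, hard), Inf)
  # hand sums for the remaining frames of the reference case
  expect_equal(frame_energy("AAAA", 1, ref_profile), 0)   # -2, -1 uncovered (empty = 0)
  expect_equal(frame_energy("AAAA", 2, ref_profile), -1)  # A at -1 only
  expect_equal(frame_energy("AAAA", 4, ref_profile), -3)  # A at -2, -1; +1 uncovered
})

test_that("product_distribution is the exact Boltzmann distribution", {
  pd <- product_distribution("AAAA", subsite_profile(), "deacetylate", 1)
  expect_equal(unclass(pd),
               c(AAAD = 0.25, AADA = 0.25, ADAA = 0.25, DAAA = 0.25))
  pd2 <- product_distribution("AAAA", ref_profile, "deacetylate", 1)
  w <- exp(-c(0, -1, -4, -3))  # energies of frames at positions 1..4
  expect_equal(unname(pd2["AADA"]), w[3] / sum(w), tolerance = 1e-12)
  expect_sums_to_one(pd2)
  # strong -2 preference concentrates mass on the two frames covering -2 with A
  pd3 <- product_distribution("AAAA", subsite_profile(A = c(`-2` = -10)),
                              "deacetylate", 1)
  expect_gt(pd3["AADA"] + pd3["AAAD"], 0.99)
  expect_error(product_distribution(strrep("A", 100), ref_profile,
                                    "deacetylate", 3), "too-large")
})

test_that("cda_step samples frames at their Boltzmann frequencies", {
  set.seed(42)
  n <- 10000
  draws <- replicate(n, cda_step("AAAA", subsite_profile(), "deacetylate")$position)
  cs <- chisq.test(tabulate(draws, 4), p = rep(0.25, 4))
  expect_gt(cs$p.value, 0.01)
  # non-uniform case against the exact distribution, 3 sigma binomial bound
  set.seed(43)
  draws2 <- replicate(n, cda_step("AAAA", ref_profile, "deacetylate")$position)
  w <- exp(-c(0, -1, -4, -3)); p <- w / sum(w)
  for (k in 1:4) {
    phat <- mean(draws2 == k)
    expect_lt(abs(phat - p[k]), 3 * sqrt(p[k] * (1 - p[k]) / n) + 1e-12)
  }
  expect_error(cda_step("DDDD", ref_profile, "deacetylate"), "stalled")
  all_inf <- subsite_profile(A = c(`0` = Inf))
  expect_error(cda_step("AAAA", all_inf, "deacetylate"), "stalled")
})

test_that("exact product_distribution matches Monte-Carlo frequencies", {
  prof <- profile_preset("nm")
  pd <- product_distribution("AADA", prof, "N-acetylate", 1)
  set.seed(44)
  n <- 4000
  mc <- replicate(n, render_sequence(cda_step("AADA", prof, "N-acetylate")$seq))
  for (s in names(pd)) {
    phat <- mean(mc == s)
    expect_lt(abs(phat - pd[s]), 3 * sqrt(pd[s] * (1 - pd[s]) / n) + 1e-9)
  }
})

test_that("simulate_polymer is deterministic, conservative and stops on target", {
  start <- strrep("D", 400)
  tr1 <- simulate_polymer(start, profile_preset("nm"), "N-acetylate",
                          target_fa = 0.3, checkpoints = c(0.1, 0.2, 0.3), seed = 11)
  tr2 <- simulate_polymer(start, profile_preset("nm"), "N-acetylate",
                          target_fa = 0.3, checkpoints = c(0.1, 0.2, 0.3), seed = 11)
  expect_identical(tr1$events, tr2$events)
  expect_identical(render_sequence(tr1$final), render_sequence(tr2$final))
  expect_equal(tr1$final$fa, 0.3, tolerance = 1 / 400)
  expect_equal(tr1$final$dp, 400L)
  expect_false(tr1$stalled)
  # fa strictly monotone, one unit per event
  expect_true(all(diff(tr1$events$fa) > 0))
  expect_equal(nrow(tr1$events), 120L)
  expect_equal(names(tr1$snapshots), c("0.1", "0.2", "0.3"))
  expect_equal(tr1$snapshots[["0.2"]]$fa, 0.2, tolerance = 1 / 400)
  # different seed, different trajectory
  tr3 <- simulate_polymer(start, profile_preset("nm"), "N-acetylate",
                          target_fa = 0.3, seed = 12)
  expect_false(identical(tr1$events$position, tr3$events$position))
  expect_error(simulate_polymer("AAAA", profile_preset("nm"), "N-acetylate",
                                target_fa = 0.5), "requires")
})

test_that("deacetylation direction mirrors N-acetylation", {
  tr <- simulate_polymer(strrep("A", 300), profile_preset("neutral"),
                         "deacetylate", target_fa = 0.5,
                         checkpoints = c(0.8, 0.6, 0.5), seed = 3)
  expect_true(all(diff(tr$events$fa) < 0))
  expect_equal(tr$final$fa, 0.5, tolerance = 1 / 300)
  expect_equal(names(tr$snapshots), c("0.8", "0.6", "0.5"))
})

test_that("stronger GlcNAc preference at -1 gives larger A-blocks", {
  # 3-point ladder on the -1 A preference at fixed target F_A, 20 seeds
  mean_blockA <- function(dE, seeds = 1:20) {
    prof <- subsite_profile(A = c(`-2` = -2, `-1` = -dE))
    mean(vapply(seeds, function(s) {
      tr <- simulate_polymer(strrep("D", 600), prof, "N-acetylate",
                             target_fa = 0.3, seed = 100 + s)
      digest_and_score(tr$final)$stats$blockA_w
    }, numeric(1)))
  }
  ladder <- vapply(c(0, 1, 2), mean_blockA, numeric(1))
  expect_true(all(diff(ladder) > 0))
})

test_that("profile presets load and JSON profile round-trips", {
  for (nm in c("neutral", "nm", "H199K", "H199Y"))
    expect_s3_class(profile_preset(nm), "subsite_profile")
  expect_equal(sum(profile_preset("neutral")), 0)
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(`-2` = list(A = -4, D = 0, empty = 1),
         `-1` = list(A = -2, D = "inf", empty = 1)),
    tmp, auto_unbox = TRUE)
  pr <- read_profile(tmp)
  expect_equal(pr["A", "-2"], -4)
  expect_equal(pr["D", "-1"], Inf)
  expect_equal(pr["empty", "-1"], 1)
  expect_equal(pr["A", "2"], 0)
})
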