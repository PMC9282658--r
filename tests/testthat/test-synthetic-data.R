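test_that("cohort simulation is deterministic and substream-stable", {
  ev1 <- simulateCohort("wt_tl", n_larvae = 12, seed = 7)
  ev2 <- simulateCohort("wt_tl", n_larvae = 12, seed = 7)
  expect_identical(ev1, ev2)

  ev3 <- simulateCohort("wt_tl", n_larvae = 12, seed = 8)
  expect_false(identical(ev1$responded, ev3$responded))

  # enlarging the cohort leaves earlier larvae untouched
  big <- simulateCohort("wt_tl", n_larvae = 20, seed = 7)
  expect_identical(ev1, big[big$larva_id %in% unique(ev1$larva_id), ])
})

test_that("phase probabilities drive the simulated response frequencies", {
  sched <- buildHabituationSchedule()
  ev <- simulateCohort("wt_tl", sched, n_larvae = 500, seed = 3)
  # baseline phase calibrated to ~80% responsiveness
  pre <- ev[ev$stimulus_index %in% 11:20, ]
  expect_lt(abs(mean(pre$responded) - 0.80), 0.03)

  # non-habituating preset: the measured group habituation is zero and the
  # late-phase frequency sits at the generator's calibrated plateau
  flat <- genotypePreset("flat", p_sensitivity = 0.1, p_baseline = 0.8,
                         habituation_pct = 0)
  ev0 <- simulateCohort(flat, sched, n_larvae = 400, seed = 5)
  hab0 <- scoreHabituation(classifyResponses(ev0))
  expect_lt(abs(hab0$group_mean_habituation_pct), 3)
  late <- ev0[ev0$stimulus_index %in% 41:50, ]
  plateau <- startlehab:::.habituationPlateau(flat)
  expect_lt(abs(mean(late$responded) - plateau), 0.03)

  # unknown phase labels are a protocol error
  bad <- sched
  bad$phase[1] <- "warmup"
  expect_error(simulateCohort("wt_tl", bad, n_larvae = 2, seed = 1),
               "unknown")
})

test_that("habituation decay reaches its plateau by stimulus 41", {
  preset <- startlePreset("wt_tl")
  p <- startlehab:::.responseProbabilities(preset,
                                           buildHabituationSchedule())
  p_final <- startlehab:::.habituationPlateau(preset)
  expect_true(all(abs(p[41:50] - p_final) <= 0.01 * (0.8 - p_final) + 1e-12))
  # monotone decay across the habituation phase
  expect_true(all(diff(p[21:50]) < 0))
})

test_that("the generator's plateau inverts the ratio-statistic inflation", {
  # brute-force oracle for E[n_pre/X | X >= 4], X ~ Binomial(10, p)
  for (p in c(0.65, 0.8)) {
    x <- 0:10
    w <- dbinom(x, 10, p)
    keep <- x >= 4
    oracle <- sum(w[keep] * 10 / x[keep]) / sum(w[keep])
    expect_equal(startlehab:::.ratioInflation(p), oracle, tolerance = 1e-12)
  }
  # with that inflation, the expected measured habituation equals the preset
  preset <- startlePreset("sa16189_hom")
  plateau <- startlehab:::.habituationPlateau(preset)
  kappa <- startlehab:::.ratioInflation(preset@p_baseline)
  tail_amp <- mean(startlehab:::.HAB_DECAY_RATE^(21:30))
  late_mean <- plateau + (preset@p_baseline - plateau) * tail_amp
  expect_equal(100 * (1 - late_mean * kappa), preset@habituation_pct,
               tolerance = 1e-9)
})

test_that("simulated cohorts recover each preset's habituation percentage", {
  for (name in startlePreset()) {
    preset <- startlePreset(name)
    got <- meanHabituationOverSeeds(preset, n_larvae = 80, seeds = 11:14)
    expect_lt(abs(got - preset@habituation_pct), 5,
              label = sprintf("|%.1f - %.1f| for %s", got,
                              preset@habituation_pct, name))
  }
})

test_that("Mendelian crosses segregate correctly", {
  expect_true(all(mate("+/+", "+/+", 100, seed = 1) == "+/+"))

  off <- mate("m/+", "m/+", 4000, seed = 2)
  expect_lt(abs(mean(off == "m/m") - 0.25), 0.02)
  expect_lt(abs(mean(off == "m/+") - 0.50), 0.02)

  off2 <- mate("m/m", "m/+", 4000, seed = 3)
  expect_setequal(unique(off2), c("m/m", "m/+"))
  expect_lt(abs(mean(off2 == "m/m") - 0.5), 0.02)

  expect_identical(mate("m/+", "m/+", 50, seed = 9),
                   mate("m/+", "m/+", 50, seed = 9))
  expect_error(mate("m/q", "+/+", 5), "genotype")
})

test_that("pooled markers carry the expected TL allele fractions", {
  mk <- makeMarkerMap(n_chrom = 2, markers_per_chrom = 11,
                      chrom_length_bp = 4e7)
  # place the causal locus exactly on a marker
  causal_cM <- mk$cM[6]
  pool <- simulateMutantPool(mk, "chr1", causal_cM, n_larvae = 64,
                             coverage = 50, error_rate = 0, seed = 1)
  at <- pool[pool$chrom == "chr1" & pool$cM == causal_cM, ]
  expect_equal(at$tl_count / (at$tl_count + at$wik_count), 1.0)

  # unlinked chromosome converges to 0.5 at deep coverage
  mk2 <- makeMarkerMap(n_chrom = 2, markers_per_chrom = 5000)
  pool2 <- simulateMutantPool(mk2, "chr1", 30, n_larvae = 64,
                              coverage = 80, error_rate = 0, seed = 4)
  un <- pool2[pool2$chrom == "chr2", ]
  expect_lt(abs(mean(un$tl_count / (un$tl_count + un$wik_count)) - 0.5),
            0.01)

  expect_error(simulateMutantPool(mk, "chr9", 10), "no markers")
  expect_error(simulateMutantPool(mk, "chr1", 1e5), "outside")
})

test_that("linked-marker fractions follow the Haldane map function", {
  # closed form: at d cM the expected TL fraction is 1 - (1 - e^(-2d/100))/2
  expect_equal(haldane(0), 0)
  expect_equal(haldane(50), (1 - exp(-1)) / 2)
  expect_equal(1 - haldane(50), 0.6839397, tolerance = 1e-6)

  mk <- data.frame(chrom = "chr1", pos_bp = c(1, 4e7), cM = c(0, 50))
  frac <- vapply(1:300, function(s) {
    pool <- simulateMutantPool(mk, "chr1", 0, n_larvae = 64, coverage = 60,
                               error_rate = 0, seed = s)
    with(pool[pool$cM == 50, ], tl_count / (tl_count + wik_count))
  }, numeric(1L))
  expect_lt(abs(mean(frac) - (1 - haldane(50))), 0.01)
})

test_that("intensity-assay simulation follows the psychometric curve", {
  f <- psychometricCurve(cbind(c(7.6, 13), c(0.334, 0.888)))
  expect_equal(f(7.6), 0.334, tolerance = 1e-9)
  expect_equal(f(13), 0.888, tolerance = 1e-9)
  expect_error(psychometricCurve(cbind(7.6, 0.3)), "at least 2")

  # flat zero anchors silence the assay entirely
  mute <- genotypePreset("mute", p_sensitivity = 0, p_baseline = 0,
                         habituation_pct = 0,
                         psychometric_anchors = cbind(c(5, 25), c(0, 0)))
  ev <- simulateIntensityAssay(mute, n_larvae = 30, seed = 2)
  expect_true(all(ev$responded == 0L))

  # monotone anchors give frequencies non-decreasing in intensity (large n)
  ev2 <- simulateIntensityAssay("sa16189_hom", n_larvae = 400, seed = 6)
  freq <- tapply(ev2$responded, ev2$intensity_dbu, mean)
  expect_true(all(diff(freq) > -0.02))
  # and the curve itself is non-decreasing
  curve <- psychometricCurve(startlePreset("sa16189_hom")@psychometric_anchors)
  x <- seq(0, 40, by = 0.5)
  expect_true(all(diff(curve(x)) >= 0))

  expect_error(
    simulateIntensityAssay("wt_tl", buildHabituationSchedule(), 5, seed = 1),
    "intensity-block")
})

test_that("latency shift is disabled at the lowest psychometric anchor", {
  het <- startlePreset("sa16189_het")
  hom <- startlePreset("sa16189_hom")
  # force both genotypes through the same anchors so every intensity has
  # responses in both groups
  anchors <- cbind(c(7.6, 13), c(0.5, 0.9))
  het2 <- genotypePreset("het2", p_sensitivity = het@p_sensitivity,
                         habituation_pct = het@habituation_pct,
                         psychometric_anchors = anchors,
                         latency_shift = 1)
  hom2 <- genotypePreset("hom2", p_sensitivity = hom@p_sensitivity,
                         habituation_pct = hom@habituation_pct,
                         psychometric_anchors = anchors,
                         latency_median_ms = het2@latency_median_ms,
                         latency_shift = 0.8)
  ev_het <- classifyResponses(simulateIntensityAssay(het2, n_larvae = 200,
                                                     seed = 3))
  ev_hom <- classifyResponses(simulateIntensityAssay(hom2, n_larvae = 200,
                                                     seed = 4))
  lat <- function(ev, dbu) {
    x <- ev[ev$intensity_dbu == dbu & ev$response_class == "SLC", ]
    c(mean = mean(x$latency_ms), sd = sd(x$latency_ms))
  }
  # indistinguishable at the lowest anchor (difference well under 1 SD) ...
  at_low <- abs(lat(ev_hom, 7.6)["mean"] - lat(ev_het, 7.6)["mean"])
  expect_lt(at_low, lat(ev_het, 7.6)["sd"])
  # ... but clearly shifted above it
  expect_lt(lat(ev_hom, 13)["mean"], lat(ev_het, 13)["mean"])
})
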