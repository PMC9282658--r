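test_that("responses classify into SLC/LLC/none by latency", {
  ev <- data.frame(larva_id = "a", stimulus_index = 1:5, phase = "prehab",
                   intensity_dbu = 25, responded = c(1, 1, 1, 0, 1),
                   latency_ms = c(8, 30, 15, NA, 150),
                   duration_ms = c(9, 9, 9, NA, 9))
  cls <- classifyResponses(ev)$response_class
  expect_equal(cls, c("SLC", "LLC", "SLC", "none", "none"))

  # configurable cutoff moves the boundary
  cls2 <- classifyResponses(ev, slc_cutoff_ms = 10)$response_class
  expect_equal(cls2[3], "LLC")

  ev$latency_ms[1] <- NA
  expect_error(classifyResponses(ev), "missing latency")
  expect_error(classifyResponses(ev, slc_cutoff_ms = 100, llc_cutoff_ms = 15),
               "cutoffs")
})

test_that("habituation percentage is the percent drop from baseline", {
  expect_equal(habituationPercent(0.8, 0.8), 0)
  expect_equal(habituationPercent(1.0, 0.0), 100)
  expect_equal(habituationPercent(0.9, 0.15), 100 * (1 - 1 / 6))
  # sensitization gives negative habituation
  expect_lt(habituationPercent(0.5, 0.8), 0)
  expect_error(habituationPercent(0, 0.1), "undefined")
})

test_that("pipeline habituation equals the raw-count arithmetic oracle", {
  set.seed(21)
  patterns <- lapply(1:30, function(i) {
    as.integer(runif(50) < runif(1, 0.3, 0.95))
  })
  ev <- classifyResponses(eventsFromPatterns(patterns))
  res <- scoreHabituation(ev)$per_larva
  for (i in seq_along(patterns)) {
    k_pre <- sum(patterns[[i]][11:20])
    k_late <- sum(patterns[[i]][41:50])
    row <- res[res$larva_id == sprintf("L%02d", i), ]
    expect_equal(row$freq_prehab, k_pre / 10)
    expect_equal(row$freq_late, k_late / 10)
    expect_equal(row$included, k_pre >= 4)
    if (k_pre >= 4) {
      expect_equal(row$habituation_pct, 100 * (1 - k_late / k_pre))
    } else {
      expect_true(is.na(row$habituation_pct))
    }
  }
})

test_that("non-responder filter excludes below 40% and keeps the boundary", {
  ev <- classifyResponses(eventsFromPatterns(list(
    pattern(k_pre = 3, k_late = 0),   # 3/10 -> excluded
    pattern(k_pre = 4, k_late = 1),   # exactly 40% -> retained
    pattern(k_pre = 8, k_late = 1)
  )))
  res <- scoreHabituation(ev)
  expect_equal(res$per_larva$included, c(FALSE, TRUE, TRUE))
  # group mean over included larvae only
  expect_equal(res$group_mean_habituation_pct,
               mean(c(100 * (1 - 1 / 4), 100 * (1 - 1 / 8))))
})

test_that("a uniform cohort recovers the exact group habituation", {
  ev <- classifyResponses(eventsFromPatterns(
    replicate(10, pattern(k_pre = 8, k_late = 1), simplify = FALSE)))
  expect_equal(scoreHabituation(ev)$group_mean_habituation_pct, 87.5)
  # zero change means zero habituation regardless of filtering
  ev0 <- classifyResponses(eventsFromPatterns(
    replicate(6, pattern(k_pre = 6, k_late = 6), simplify = FALSE)))
  expect_equal(scoreHabituation(ev0)$group_mean_habituation_pct, 0)
})

test_that("LLC responses do not count toward startle responsiveness", {
  ev <- eventsFromPatterns(list(pattern(k_pre = 8, k_late = 8)),
                           latency_ms = 30)  # all long-latency
  res <- scoreHabituation(classifyResponses(ev))
  expect_equal(res$per_larva$freq_prehab, 0)
  expect_false(res$per_larva$included)
})

test_that("missing stimuli raise a data error naming the larva", {
  ev <- classifyResponses(eventsFromPatterns(list(pattern())))
  expect_error(scoreHabituation(ev[ev$stimulus_index <= 25, ]),
               "L01.*missing stimuli|missing stimuli")
})

test_that("sensitivity-phase rate averages per-larva frequencies, unfiltered", {
  ev <- classifyResponses(eventsFromPatterns(list(
    pattern(k_sens = 0, k_pre = 2),   # non-responder: still counted here
    pattern(k_sens = 2, k_pre = 8)
  )))
  expect_equal(sensitivityPhaseRate(ev), 10)

  ev2 <- classifyResponses(eventsFromPatterns(
    replicate(4, pattern(k_sens = 1), simplify = FALSE)))
  expect_equal(sensitivityPhaseRate(ev2), 10)
  expect_error(sensitivityPhaseRate(ev2[0, ]), "no larvae")
})

test_that("sensitivity index is the trapezoidal area under the curve", {
  expect_equal(sensitivityIndex(c("0.3" = 0, "13" = 0, "35" = 0)), 0)
  levels <- c(0.3, 7.6, 13, 19.8, 25.6, 35)
  const <- setNames(rep(100, 6), levels)
  expect_equal(sensitivityIndex(const), 100 * 34.7)  # 3470
  expect_equal(sensitivityIndex(c("0.3" = 0, "35" = 100)), 1735)
  expect_error(sensitivityIndex(c("13" = 50)), ">= 2")
})

test_that("sensitivity index is additive, monotone and duplicate-invariant", {
  set.seed(31)
  x <- sort(runif(7, 0, 40))
  y <- runif(7, 0, 100)
  f <- setNames(y, x)
  # additivity over adjacent sub-ranges split at an interior point
  left <- f[x <= x[4]]
  right <- f[x >= x[4]]
  expect_equal(sensitivityIndex(left) + sensitivityIndex(right),
               sensitivityIndex(f))
  # raising every frequency raises the area
  expect_gt(sensitivityIndex(setNames(y + 5, x)), sensitivityIndex(f))
  # duplicated intensity point with equal frequency changes nothing
  dup <- setNames(c(y, y[3]), c(x, x[3]))
  expect_equal(sensitivityIndex(dup), sensitivityIndex(f))
  expect_error(sensitivityIndex(setNames(c(0, 50, 60), c(1, 10, 10))),
               "conflicting")
})

test_that("per-larva profiles feed the group sensitivity index", {
  ev <- classifyResponses(simulateIntensityAssay("sa16189_hom",
                                                 n_larvae = 40, seed = 9))
  prof <- sensitivityProfiles(ev)
  expect_equal(nrow(prof$index), 40L)
  expect_true(all(prof$per_larva$freq_pct >= 0 &
                    prof$per_larva$freq_pct <= 100))
  expect_equal(prof$group_mean_index, mean(prof$index$sensitivity_index))
  # hypersensitive mutants score higher than their heterozygous siblings
  ev_het <- classifyResponses(simulateIntensityAssay("sa16189_het",
                                                     n_larvae = 40, seed = 9))
  expect_gt(prof$group_mean_index,
            sensitivityProfiles(ev_het)$group_mean_index)
})

test_that("kinematic summaries cover prehab SLCs only", {
  ev <- eventsFromPatterns(list(pattern(k_pre = 6, k_late = 2)))
  ev$latency_ms[ev$responded == 1] <- c(10, 12, 10, 12, 10, 12, 99, 99)
  ev$duration_ms[ev$responded == 1] <- 9
  ks <- kinematicSummary(classifyResponses(ev))
  expect_equal(nrow(ks), 1L)
  expect_equal(ks$mean_latency_ms, 11)
  expect_equal(ks$n_slc, 6L)

  # no SLC in the window -> no summary row
  none <- eventsFromPatterns(list(pattern(k_pre = 0, k_late = 2)))
  expect_equal(nrow(kinematicSummary(classifyResponses(none),
                                     apply_filter = FALSE)), 0L)
  # non-responders are dropped from kinematic aggregation
  low <- classifyResponses(eventsFromPatterns(list(pattern(k_pre = 3))))
  expect_equal(nrow(kinematicSummary(low)), 0L)
  expect_equal(nrow(kinematicSummary(low, apply_filter = FALSE)), 1L)
})

test_that("mutant cohorts show the generator's reduced SLC latency", {
  wt <- classifyResponses(simulateCohort("wt_tl", n_larvae = 200, seed = 13))
  mut <- classifyResponses(simulateCohort("p177_hom", n_larvae = 200,
                                          seed = 14))
  expect_lt(mean(kinematicSummary(mut)$mean_latency_ms),
            mean(kinematicSummary(wt)$mean_latency_ms))
  # C-turn duration is untouched by genotype
  d <- abs(mean(kinematicSummary(mut)$mean_duration_ms) -
             mean(kinematicSummary(wt)$mean_duration_ms))
  expect_lt(d, 0.3)
})

test_that("latency-by-intensity flags sparse levels and drops empty ones", {
  ev <- data.frame(
    larva_id = rep("a", 8), genotype = "g",
    stimulus_index = 1:8, phase = "intensity_block",
    intensity_dbu = c(0.3, 0.3, 13, 13, 13, 13, 35, 35),
    responded = c(1, 0, 1, 1, 1, 1, 0, 0),
    latency_ms = c(9, NA, 7, 7, 7, 7, NA, NA),
    duration_ms = c(9, NA, 9, 9, 9, 9, NA, NA)
  )
  tab <- latencyByIntensity(classifyResponses(ev))
  expect_equal(nrow(tab), 2L)           # 35 dBu had no SLCs
  expect_true(tab$low_n[tab$intensity_dbu == 0.3])
  expect_false(tab$low_n[tab$intensity_dbu == 13])
  expect_equal(tab$mean_latency_ms[tab$intensity_dbu == 13], 7)
})
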