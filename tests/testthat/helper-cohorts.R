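# Build a classified event table directly from per-larva response patterns,
# bypassing the simulator, for exact-arithmetic checks. `responses` is a
# list: one 0/1 vector of length 50 per larva (stimuli 1..50 of the
# standard schedule).
eventsFromPatterns <- function(responses, latency_ms = 8, duration_ms = 9) {
  sched <- buildHabituationSchedule()
  do.call(rbind, lapply(seq_along(responses), function(i) {
    r <- responses[[i]]
    stopifnot(length(r) == nrow(sched))
    data.frame(
      larva_id = sprintf("L%02d", i),
      genotype = "fixture",
      stimulus_index = sched$index,
      phase = sched$phase,
      intensity_dbu = sched$intensity_dbu,
      responded = as.integer(r),
      latency_ms = ifelse(r == 1, latency_ms, NA_real_),
      duration_ms = ifelse(r == 1, duration_ms, NA_real_),
      stringsAsFactors = FALSE
    )
  }))
}

# A 0/1 pattern with k_sens responses in stimuli 1-10, k_pre in 11-20 and
# k_late in 41-50 (responses placed at the start of each window).
pattern <- function(k_sens = 0, k_pre = 8, k_late = 1) {
  r <- integer(50)
  r[seq_len(k_sens)] <- 1L
  r[10 + seq_len(k_pre)] <- 1L
  r[40 + seq_len(k_late)] <- 1L
  r
}

# Mean group habituation over several simulator seeds, as the acceptance
# checks use it.
meanHabituationOverSeeds <- function(preset, n_larvae, seeds) {
  mean(vapply(seeds, function(s) {
    ev <- classifyResponses(simulateCohort(preset, n_larvae = n_larvae,
                                           seed = s))
    scoreHabituation(ev)$group_mean_habituation_pct
  }, numeric(1L)))
}

meanSensitivityOverSeeds <- function(preset, n_larvae, seeds) {
  mean(vapply(seeds, function(s) {
    ev <- classifyResponses(simulateCohort(preset, n_larvae = n_larvae,
                                           seed = s))
    sensitivityPhaseRate(ev)
  }, numeric(1L)))
}
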