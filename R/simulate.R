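# Deterministic per-unit substream: a small counter-based hash of the master
# seed and a unit index, kept inside 32-bit integer range so the same cohort
# is reproducible regardless of how many units were generated before it.
.substreamSeed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + index * 1000003) %%
               2147483647)
}

# Geometric decay rate of the habituation phase: the decaying amplitude
# (p_baseline - p_final) shrinks by a factor of 100 over the first 21
# habituating stimuli, i.e. the response probability is within 1% of its
# plateau by stimulus 41 of the standard 50-stimulus protocol.
.HAB_DECAY_RATE <- 0.01^(1 / 21)

# Expected value of n_pre / X given X >= ceiling(threshold * n_pre), for
# X ~ Binomial(n_pre, p_baseline): the inflation factor the per-larva ratio
# statistic mean(1 - late/pre) picks up from dividing by the noisy baseline
# frequency of the included larvae.
.ratioInflation <- function(p_baseline, n_pre = 10L, threshold = 0.4) {
  x <- seq.int(ceiling(threshold * n_pre), n_pre)
  w <- dbinom(x, n_pre, p_baseline)
  sum(w * n_pre / x) / sum(w)
}

# Habituation-phase plateau that makes the cohort-level habituation
# statistic recover habituation_pct in expectation. The preset's
# habituation percentage is a calibration target for the *measured* group
# statistic, so the generator inverts the measurement model: the ratio
# estimator's baseline-noise inflation (.ratioInflation) and the small
# excess of the geometric decay tail over stimuli 41-50.
.habituationPlateau <- function(preset, n_hab = 30L) {
  kappa <- .ratioInflation(preset@p_baseline)
  # mean decay amplitude remaining over the last 10 habituating stimuli
  j <- seq.int(max(1L, n_hab - 9L), n_hab)
  tail_amp <- mean(.HAB_DECAY_RATE^j)
  p_final <- ((1 - preset@habituation_pct / 100) / kappa -
                preset@p_baseline * tail_amp) / (1 - tail_amp)
  min(max(p_final, 0), preset@p_baseline)
}

# Per-stimulus SLC probability trajectory for one preset on one schedule.
.responseProbabilities <- function(preset, schedule) {
  phase <- schedule$phase
  known <- c("sensitivity", "prehab", "habituation")
  if (!all(phase %in% known)) {
    stop("schedule contains phases unknown to the cohort generator: ",
         paste(setdiff(unique(phase), known), collapse = ", "))
  }
  p <- numeric(nrow(schedule))
  p[phase == "sensitivity"] <- preset@p_sensitivity
  p[phase == "prehab"] <- preset@p_baseline
  hab <- which(phase == "habituation")
  if (length(hab)) {
    p_final <- .habituationPlateau(preset, n_hab = length(hab))
    j <- seq_along(hab)
    p[hab] <- p_final + (preset@p_baseline - p_final) * .HAB_DECAY_RATE^j
  }
  p
}

# Draw kinematics for responding trials; latency log-normal, duration normal
# (truncated at a small positive floor). latency_factor scales the median.
.drawKinematics <- function(preset, n, latency_factor = 1) {
  latency <- rlnorm(n,
                    meanlog = log(preset@latency_median_ms * latency_factor),
                    sdlog = preset@latency_sdlog)
  duration <- pmax(rnorm(n, preset@duration_mean_ms, preset@duration_sd_ms),
                   0.5)
  list(latency_ms = latency, duration_ms = duration)
}

.simulateEvents <- function(preset, schedule, n_larvae, seed, p_by_stimulus,
                            latency_factor_by_stimulus) {
  n_stim <- nrow(schedule)
  out <- vector("list", n_larvae)
  for (i in seq_len(n_larvae)) {
    set.seed(.substreamSeed(seed, i))
    responded <- rbinom(n_stim, 1L, p_by_stimulus)
    latency <- rep(NA_real_, n_stim)
    duration <- rep(NA_real_, n_stim)
    hit <- responded == 1L
    if (any(hit)) {
      kin <- .drawKinematics(preset, sum(hit))
      latency[hit] <- kin$latency_ms * latency_factor_by_stimulus[hit]
      duration[hit] <- kin$duration_ms
    }
    out[[i]] <- data.frame(
      larva_id = sprintf("larva_%03d", i),
      genotype = preset@name,
      stimulus_index = schedule$index,
      phase = schedule$phase,
      intensity_dbu = schedule$intensity_dbu,
      responded = responded,
      latency_ms = latency,
      duration_ms = duration,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate a behavioral cohort on the habituation schedule
#'
#' Draws each larva's response to each stimulus as a Bernoulli trial whose
#' probability follows the preset: `p_sensitivity` during the sensitivity
#' phase, `p_baseline` during pre-habituation, and a geometric decay from
#' `p_baseline` toward a plateau during the habituation phase (within 1% of
#' the plateau by the 21st habituating stimulus, i.e. stimulus 41 of the
#' standard protocol). Responding trials receive a log-normal latency and a
#' normal C-turn duration.
#'
#' The plateau is calibrated so that the cohort-level habituation statistic
#' ([scoreHabituation()]: mean over included larvae of
#' `100 * (1 - late/baseline)`) recovers the preset's `habituation_pct` in
#' expectation. Because that statistic divides by each larva's noisy
#' baseline frequency, its expectation sits slightly above the naive
#' plateau-to-baseline ratio; the generator inverts this measurement model
#' (including the non-responder filter) rather than equating the plateau
#' with `p_baseline * (1 - habituation_pct/100)` directly.
#'
#' Reproducibility: every larva uses its own substream derived from `seed`
#' and the larva index, so the same `seed` yields an identical event table
#' and individual larvae are stable under changes of cohort size.
#'
#' @param preset a [GenotypePreset-class] or a built-in preset name.
#' @param schedule schedule from [buildHabituationSchedule()].
#' @param n_larvae number of larvae.
#' @param seed integer master seed.
#' @return A data.frame of response events with columns `larva_id`,
#'   `genotype`, `stimulus_index`, `phase`, `intensity_dbu`, `responded`
#'   (0/1), `latency_ms`, `duration_ms` (NA when `responded == 0`).
#' @examples
#' ev <- simulateCohort("wt_tl", buildHabituationSchedule(), n_larvae = 4,
#'                      seed = 1)
#' head(ev)
#' @export
simulateCohort <- function(preset, schedule = buildHabituationSchedule(),
                           n_larvae, seed = 1L) {
  if (is.character(preset)) preset <- startlePreset(preset)
  stopifnot(is(preset, "GenotypePreset"), n_larvae > 0)
  validObject(preset)
  p <- .responseProbabilities(preset, schedule)
  # in the habituation assay the latency shift applies to the high-intensity
  # phases; sub-threshold stimuli are at the unshifted baseline latency
  fac <- ifelse(schedule$phase == "sensitivity", 1, preset@latency_shift)
  .simulateEvents(preset, schedule, n_larvae, seed, p, fac)
}

#' Fit a logistic psychometric curve through anchor points
#'
#' Least-squares fit (on the logit scale) of a two-parameter logistic with
#' fixed floor 0 and ceiling `ceiling`:
#' `p(x) = ceiling / (1 + exp(-(a + b x)))`. With exactly two anchors the
#' curve passes through them exactly. If every anchor probability is 0 the
#' returned curve is identically zero.
#'
#' @param anchors two-column matrix (`intensity_dbu`, `p`) with at least two
#'   rows.
#' @param ceiling asymptotic maximum response probability; startle
#'   responsiveness saturates below 100%, hence the 0.95 default.
#' @return A function mapping intensity (dBu) to response probability.
#' @examples
#' f <- psychometricCurve(cbind(c(7.6, 13), c(0.334, 0.888)))
#' f(13)  # 0.888
#' @export
psychometricCurve <- function(anchors, ceiling = 0.95) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2L) {
    stop("need at least 2 psychometric anchors to fit a curve")
  }
  x <- anchors[, 1L]
  p <- anchors[, 2L]
  if (all(p <= 0)) {
    return(function(intensity_dbu) rep(0, length(intensity_dbu)))
  }
  eps <- 1e-6
  y <- qlogis(pmin(pmax(p / ceiling, eps), 1 - eps))
  fit <- lm(y ~ x)
  a <- coef(fit)[[1L]]
  b <- coef(fit)[[2L]]
  function(intensity_dbu) ceiling * plogis(a + b * intensity_dbu)
}

#' Simulate the multi-intensity sensitivity assay
#'
#' Response probability at each stimulus intensity follows the logistic
#' psychometric curve fitted through the preset's anchors (floor 0, ceiling
#' 0.95; see [psychometricCurve()]). The preset's latency shift applies only
#' at intensities above the lowest anchor: at the lowest anchor intensity
#' mutant and control latencies are indistinguishable by construction.
#'
#' @inheritParams simulateCohort
#' @param schedule schedule from [buildSensitivitySchedule()].
#' @return Event data.frame as for [simulateCohort()], phase
#'   `"intensity_block"`.
#' @export
simulateIntensityAssay <- function(preset,
                                   schedule = buildSensitivitySchedule(),
                                   n_larvae, seed = 1L) {
  if (is.character(preset)) preset <- startlePreset(preset)
  stopifnot(is(preset, "GenotypePreset"), n_larvae > 0)
  validObject(preset)
  if (!all(schedule$phase == "intensity_block")) {
    stop("simulateIntensityAssay needs an intensity-block schedule")
  }
  curve <- psychometricCurve(preset@psychometric_anchors)
  p <- curve(schedule$intensity_dbu)
  lowest_anchor <- min(preset@psychometric_anchors[, 1L])
  fac <- ifelse(schedule$intensity_dbu > lowest_anchor,
                preset@latency_shift, 1)
  .simulateEvents(preset, schedule, n_larvae, seed, p, fac)
}

#' Simulate a Mendelian cross
#'
#' Each parent passes one of its two alleles to each offspring with equal
#' probability, so an incross of heterozygotes yields the expected 1:2:1
#' genotype ratio. Genotypes are written `"+/+"`, `"m/+"`, `"m/m"` (the
#' heterozygote is always normalized to `"m/+"`).
#'
#' @param parent1,parent2 parental genotypes, each one of `"+/+"`, `"m/+"`,
#'   `"m/m"`.
#' @param n_offspring clutch size.
#' @param seed integer seed.
#' @return Character vector of offspring genotypes.
#' @examples
#' table(mate("m/+", "m/+", 400, seed = 1))
#' @export
mate <- function(parent1, parent2, n_offspring, seed = 1L) {
  parseGenotype <- function(g) {
    alleles <- strsplit(g, "/", fixed = TRUE)[[1L]]
    if (length(alleles) != 2L || !all(alleles %in% c("+", "m"))) {
      stop("genotype must be one of '+/+', 'm/+', 'm/m'; got '", g, "'")
    }
    alleles
  }
  a1 <- parseGenotype(parent1)
  a2 <- parseGenotype(parent2)
  set.seed(.substreamSeed(seed, 0L))
  g1 <- sample(a1, n_offspring, replace = TRUE)
  g2 <- sample(a2, n_offspring, replace = TRUE)
  n_mut <- (g1 == "m") + (g2 == "m")
  c("+/+", "m/+", "m/m")[n_mut + 1L]
}

#' Build a uniform SNP marker map
#'
#' Evenly spaced markers on each chromosome with genetic positions from a
#' uniform recombination rate. A convenience input for
#' [simulateMutantPool()]; real marker maps can be supplied as any
#' data.frame with columns `chrom`, `pos_bp`, `cM`.
#'
#' @param n_chrom number of chromosomes (zebrafish has 25).
#' @param chrom_length_bp chromosome length (bp).
#' @param markers_per_chrom markers per chromosome.
#' @param cM_per_Mb uniform genetic map rate.
#' @return data.frame with columns `chrom`, `pos_bp`, `cM`.
#' @export
makeMarkerMap <- function(n_chrom = 25L, chrom_length_bp = 6e7,
                          markers_per_chrom = 200L, cM_per_Mb = 1.25) {
  pos <- round(seq(1, chrom_length_bp, length.out = markers_per_chrom))
  do.call(rbind, lapply(seq_len(n_chrom), function(k) {
    data.frame(
      chrom = sprintf("chr%d", k),
      pos_bp = pos,
      cM = pos / 1e6 * cM_per_Mb,
      stringsAsFactors = FALSE
    )
  }))
}

#' Haldane map function
#'
#' Recombination fraction between two loci `d` centimorgans apart assuming
#' no interference: `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM genetic distance in cM.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d_cM) {
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Simulate pooled sequencing of behaviorally selected mutants
#'
#' Emulates bulk-segregant homozygosity mapping: a pool of homozygous mutant
#' larvae from a TL x WIK mapping cross is sequenced, and at every SNP
#' marker the reads are split between the mutagenized-strain (TL) and
#' mapping-strain (WIK) alleles. Every pooled chromosome carries the TL
#' allele at the causal locus; at a marker `d` cM away it carries the TL
#' allele with probability `1 - haldane(d)`, and markers on other
#' chromosomes are unlinked (probability 0.5). Sequencing depth at each
#' marker is Poisson with the given mean coverage; reads are drawn
#' binomially from the pool allele fraction and miscalled (allele flipped)
#' with probability `error_rate`.
#'
#' @param markers marker map data.frame (`chrom`, `pos_bp`, `cM`), e.g. from
#'   [makeMarkerMap()].
#' @param causal_chrom,causal_pos_cM location of the lesion on the genetic
#'   map; must fall on a chromosome present in `markers` and within its cM
#'   range.
#' @param n_larvae number of pooled homozygous mutants (2 chromosomes each).
#' @param coverage mean reads per marker.
#' @param error_rate per-read allele miscall probability, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return Marker table data.frame with columns `chrom`, `pos_bp`, `cM`,
#'   `tl_count`, `wik_count`.
#' @examples
#' mk <- makeMarkerMap(n_chrom = 3, markers_per_chrom = 50)
#' pool <- simulateMutantPool(mk, "chr2", 30, n_larvae = 64, coverage = 50,
#'                            error_rate = 0, seed = 1)
#' @export
simulateMutantPool <- function(markers, causal_chrom, causal_pos_cM,
                               n_larvae = 64L, coverage = 50,
                               error_rate = 0.01, seed = 1L) {
  stopifnot(all(c("chrom", "pos_bp", "cM") %in% names(markers)),
            n_larvae > 0, coverage > 0,
            error_rate >= 0, error_rate < 0.5)
  on_chrom <- markers$chrom == causal_chrom
  if (!any(on_chrom)) {
    stop("causal chromosome '", causal_chrom, "' has no markers on the map")
  }
  rng <- range(markers$cM[on_chrom])
  if (causal_pos_cM < rng[1L] || causal_pos_cM > rng[2L]) {
    stop(sprintf(
      "causal position %.2f cM is outside the %s marker map (%.2f-%.2f cM)",
      causal_pos_cM, causal_chrom, rng[1L], rng[2L]))
  }
  markers <- markers[order(markers$chrom, markers$pos_bp), , drop = FALSE]
  n_chromosomes <- 2L * as.integer(n_larvae)
  p_tl <- ifelse(markers$chrom == causal_chrom,
                 1 - haldane(abs(markers$cM - causal_pos_cM)),
                 0.5)
  set.seed(.substreamSeed(seed, 0L))
  n_marker <- nrow(markers)
  pool_tl <- rbinom(n_marker, n_chromosomes, p_tl)
  frac <- pool_tl / n_chromosomes
  frac_obs <- frac * (1 - error_rate) + (1 - frac) * error_rate
  depth <- rpois(n_marker, coverage)
  tl <- rbinom(n_marker, depth, frac_obs)
  data.frame(
    chrom = markers$chrom,
    pos_bp = markers$pos_bp,
    cM = markers$cM,
    tl_count = tl,
    wik_count = depth - tl,
    stringsAsFactors = FALSE
  )
}
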