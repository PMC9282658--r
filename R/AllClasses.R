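#' @import methods
#' @import stats
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Stimulus protocol configuration
#'
#' Holds the timing and intensity structure of the two behavioral assays:
#' the 50-stimulus habituation assay (a sensitivity phase of sub-threshold
#' stimuli, a pre-habituation baseline phase, and a short-ISI habituation
#' phase) and the multi-intensity sensitivity assay (repeated trials at a
#' ladder of stimulus intensities).
#'
#' Intensities are in dBu (decibels referenced to 0.775 V); see
#' [dbuFromVolts()]. The low/high/intermediate stimulus intensities are
#' calibrated empirically on each rig rather than fixed physical constants,
#' so they are configuration values.
#'
#' @slot n_sensitivity number of sub-threshold sensitivity-phase stimuli.
#' @slot n_prehab number of high-intensity baseline (pre-habituation) stimuli.
#' @slot n_hab number of high-intensity habituating stimuli.
#' @slot isi_long_s interstimulus interval (s) in the sensitivity and
#'   pre-habituation phases.
#' @slot isi_short_s interstimulus interval (s) in the habituation phase.
#' @slot inter_phase_break_s extra break (s) inserted between phases.
#' @slot low_intensity_dbu,high_intensity_dbu stimulus intensities (dBu).
#' @slot sensitivity_levels_dbu intensity ladder (dBu) for the
#'   multi-intensity assay, strictly increasing.
#' @slot trials_per_level trials at each intensity in the multi-intensity assay.
#' @slot sensitivity_isi_s interstimulus interval (s) in the multi-intensity
#'   assay.
#'
#' @seealso [protocolConfig()], [buildHabituationSchedule()],
#'   [buildSensitivitySchedule()]
#' @export
setClass("ProtocolConfig",
  representation(
    n_sensitivity = "integer",
    n_prehab = "integer",
    n_hab = "integer",
    isi_long_s = "numeric",
    isi_short_s = "numeric",
    inter_phase_break_s = "numeric",
    low_intensity_dbu = "numeric",
    high_intensity_dbu = "numeric",
    sensitivity_levels_dbu = "numeric",
    trials_per_level = "integer",
    sensitivity_isi_s = "numeric"
  )
)

setValidity("ProtocolConfig", function(object) {
  msg <- character(0)
  counts <- c(
    n_sensitivity = object@n_sensitivity,
    n_prehab = object@n_prehab,
    trials_per_level = object@trials_per_level
  )
  if (any(counts <= 0L)) {
    msg <- c(msg, sprintf(
      "counts must be > 0 (%s)",
      paste(names(counts)[counts <= 0L], collapse = ", ")
    ))
  }
  if (object@n_hab < 0L) {
    msg <- c(msg, "n_hab must be >= 0")
  }
  isis <- c(object@isi_long_s, object@isi_short_s, object@sensitivity_isi_s)
  if (any(!is.finite(isis)) || any(isis <= 0)) {
    msg <- c(msg, "all interstimulus intervals must be finite and > 0")
  }
  if (object@inter_phase_break_s < 0) {
    msg <- c(msg, "inter_phase_break_s must be >= 0")
  }
  lv <- object@sensitivity_levels_dbu
  if (length(lv) == 0L) {
    msg <- c(msg, "sensitivity_levels_dbu must be non-empty")
  } else if (any(diff(lv) <= 0)) {
    msg <- c(msg, "sensitivity_levels_dbu must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Genotype simulation preset
#'
#' A named bundle of generative parameters describing how larvae of one
#' genotype behave in the startle assays: the probability of a short-latency
#' C-bend (SLC) to sub-threshold stimuli, the baseline probability to
#' high-intensity stimuli, the asymptotic habituation percentage, anchor
#' points of the psychometric (intensity vs. response probability) curve,
#' and log-normal latency / normal C-turn-duration kinematic parameters.
#'
#' @slot name preset label, e.g. `"wt_tl"` or `"p177_hom"`.
#' @slot p_sensitivity probability of an SLC to a sub-threshold stimulus.
#' @slot p_baseline probability of an SLC to a high-intensity stimulus in the
#'   pre-habituation phase.
#' @slot habituation_pct asymptotic habituation percentage (0-100); the
#'   late-phase response probability decays toward
#'   `p_baseline * (1 - habituation_pct/100)`.
#' @slot psychometric_anchors two-column matrix (`intensity_dbu`, `p`) of
#'   anchor points the logistic psychometric curve is fitted through;
#'   strictly increasing in intensity, non-decreasing in probability.
#' @slot latency_median_ms median SLC latency (ms); latencies are drawn
#'   log-normally around `log(latency_median_ms)`.
#' @slot latency_sdlog standard deviation of log-latency (dimensionless).
#' @slot latency_shift multiplicative latency factor applied at stimulus
#'   intensities above the lowest psychometric anchor (mutants < 1); at the
#'   lowest anchor intensity the shift is disabled.
#' @slot duration_mean_ms,duration_sd_ms normal C-turn duration parameters (ms).
#'
#' @seealso [genotypePreset()], [startlePreset()], [simulateCohort()]
#' @export
setClass("GenotypePreset",
  representation(
    name = "character",
    p_sensitivity = "numeric",
    p_baseline = "numeric",
    habituation_pct = "numeric",
    psychometric_anchors = "matrix",
    latency_median_ms = "numeric",
    latency_sdlog = "numeric",
    latency_shift = "numeric",
    duration_mean_ms = "numeric",
    duration_sd_ms = "numeric"
  )
)

setValidity("GenotypePreset", function(object) {
  msg <- character(0)
  pr <- c(p_sensitivity = object@p_sensitivity, p_baseline = object@p_baseline)
  if (any(pr < 0 | pr > 1)) {
    msg <- c(msg, "p_sensitivity and p_baseline must lie in [0, 1]")
  }
  if (object@habituation_pct < 0 || object@habituation_pct > 100) {
    msg <- c(msg, "habituation_pct must lie in [0, 100]")
  }
  a <- object@psychometric_anchors
  if (ncol(a) != 2L) {
    msg <- c(msg, "psychometric_anchors must have two columns (intensity, p)")
  } else if (nrow(a) >= 2L) {
    if (any(diff(a[, 1L]) <= 0)) {
      msg <- c(msg, "anchor intensities must be strictly increasing")
    }
    if (any(diff(a[, 2L]) < 0)) {
      msg <- c(msg, "anchor probabilities must be non-decreasing")
    }
  }
  if (nrow(a) && (any(a[, 2L] < 0) || any(a[, 2L] > 1))) {
    msg <- c(msg, "anchor probabilities must lie in [0, 1]")
  }
  if (object@latency_median_ms <= 0 || object@latency_sdlog < 0) {
    msg <- c(msg, "latency parameters must be positive")
  }
  if (object@latency_shift <= 0) {
    msg <- c(msg, "latency_shift must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Restriction-digest genotyping assay
#'
#' Bookkeeping for a CAPS/dCAPS assay: the PCR amplicon produced from each
#' allele template, the enzyme, and where the enzyme cuts each template
#' (offsets from the amplicon 5' end). For a dCAPS assay a mismatch primer
#' creates the allele-specific restriction site, so the two templates can
#' differ in which one is cleaved.
#'
#' @slot allele_name label of the mutant allele the assay genotypes.
#' @slot enzyme restriction endonuclease label (e.g. `"RsaI"`, `"EcoRV"`).
#' @slot recognition_site recognition motif (e.g. `"GTAC"` for RsaI).
#' @slot cut_offset_in_site cut position within the recognition site
#'   (0-based offset from the motif start; RsaI GT^AC has offset 2).
#' @slot amplicon_length_bp named numeric, amplicon length per allele
#'   template (names `"wt"` and `"mut"`).
#' @slot cut_positions_bp named list, cut offsets (bp from the amplicon
#'   5' end) per allele template; an uncut template has an empty vector.
#'
#' @seealso [digestAssay()], [builtinAssays()], [predictFragments()],
#'   [callGenotype()]
#' @export
setClass("DigestAssay",
  representation(
    allele_name = "character",
    enzyme = "character",
    recognition_site = "character",
    cut_offset_in_site = "numeric",
    amplicon_length_bp = "numeric",
    cut_positions_bp = "list"
  )
)

setValidity("DigestAssay", function(object) {
  msg <- character(0)
  alleles <- c("wt", "mut")
  if (!all(alleles %in% names(object@amplicon_length_bp)) ||
      !all(alleles %in% names(object@cut_positions_bp))) {
    msg <- c(msg, "amplicon_length_bp and cut_positions_bp need entries 'wt' and 'mut'")
  } else {
    for (al in alleles) {
      len <- object@amplicon_length_bp[[al]]
      cuts <- object@cut_positions_bp[[al]]
      if (len <= 0) msg <- c(msg, sprintf("amplicon length for '%s' must be > 0", al))
      if (length(cuts) && (any(cuts <= 0) || any(cuts >= len))) {
        msg <- c(msg, sprintf("cut positions for '%s' must lie strictly inside the amplicon", al))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pooled-sequencing homozygosity track
#'
#' Per-marker mutagenized-strain (TL) allele fractions from a pool of
#' behaviorally selected homozygous mutants, with a running-median smoothed
#' track and, when a region reaches the homozygosity threshold, the called
#' linkage interval. Scores near 1 indicate linkage to TL alleles, scores
#' near 0 linkage to the WIK mapping strain, and unlinked markers hover
#' around 0.5.
#'
#' Markers are held as a [GenomicRanges::GRanges] (1-based positions) with
#' metadata columns `tl_count`, `wik_count`, `score`, `smoothed` and
#' `masked` (low-coverage markers excluded from smoothing).
#'
#' @slot markers `GRanges` of markers with score metadata columns.
#' @slot interval `GRanges` of length 0 or 1: the called linkage interval,
#'   closed on both ends.
#' @slot window running-median window (markers, odd).
#' @slot threshold smoothed-score threshold used for interval calling.
#' @slot min_coverage minimum reads for a marker to enter smoothing.
#'
#' @seealso [homozygosityTrack()], [callInterval()], [scores()],
#'   [calledInterval()]
#' @export
setClass("HomozygosityTrack",
  representation(
    markers = "GRanges",
    interval = "GRanges",
    window = "integer",
    threshold = "numeric",
    min_coverage = "integer"
  )
)

setValidity("HomozygosityTrack", function(object) {
  msg <- character(0)
  mc <- S4Vectors::mcols(object@markers)
  need <- c("tl_count", "wik_count", "score", "smoothed", "masked")
  missing <- setdiff(need, colnames(mc))
  if (length(missing)) {
    msg <- c(msg, sprintf("markers lack metadata columns: %s",
                          paste(missing, collapse = ", ")))
  } else {
    sc <- mc$score[!is.na(mc$score)]
    if (length(sc) && (any(sc < 0) || any(sc > 1))) {
      msg <- c(msg, "scores must lie in [0, 1]")
    }
  }
  if (length(object@interval) > 1L) {
    msg <- c(msg, "interval must have length 0 or 1")
  }
  if (object@window < 1L || object@window %% 2L == 0L) {
    msg <- c(msg, "window must be odd and >= 1")
  }
  if (length(msg)) msg else TRUE
})
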