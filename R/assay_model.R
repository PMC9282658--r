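#' Create a stimulus protocol configuration
#'
#' Defaults encode the standard habituation assay: 10 sub-threshold
#' "sensitivity" stimuli at a 30 s interstimulus interval (ISI), 10
#' high-intensity "pre-habituation" stimuli at 30 s ISI, then 30
#' high-intensity habituating stimuli at 3 s ISI, with a 30 s break between
#' phases; and the multi-intensity sensitivity assay of 5 trials at each of
#' 6 intensities (0.3, 7.6, 13, 19.8, 25.6, 35 dBu) at a 40 s ISI.
#'
#' The low and high stimulus intensities are calibrated per rig (chosen to
#' elicit SLCs in roughly 10% and 80% of wild-type trials respectively);
#' the dBu defaults here are nominal placeholders on the same scale as the
#' sensitivity ladder, not published calibration values.
#'
#' @param n_sensitivity,n_prehab,n_hab stimulus counts per phase.
#' @param isi_long_s,isi_short_s,sensitivity_isi_s interstimulus intervals (s).
#' @param inter_phase_break_s extra break between phases (s).
#' @param low_intensity_dbu,high_intensity_dbu stimulus intensities (dBu).
#' @param sensitivity_levels_dbu increasing intensity ladder (dBu).
#' @param trials_per_level trials per intensity in the sensitivity assay.
#'
#' @return A [ProtocolConfig-class] object.
#' @examples
#' cfg <- protocolConfig()
#' sched <- buildHabituationSchedule(cfg)
#' nrow(sched)  # 50
#' @export
protocolConfig <- function(n_sensitivity = 10L, n_prehab = 10L, n_hab = 30L,
                           isi_long_s = 30, isi_short_s = 3,
                           inter_phase_break_s = 30,
                           low_intensity_dbu = 5, high_intensity_dbu = 25,
                           sensitivity_levels_dbu = c(0.3, 7.6, 13, 19.8, 25.6, 35),
                           trials_per_level = 5L,
                           sensitivity_isi_s = 40) {
  new("ProtocolConfig",
    n_sensitivity = as.integer(n_sensitivity),
    n_prehab = as.integer(n_prehab),
    n_hab = as.integer(n_hab),
    isi_long_s = as.numeric(isi_long_s),
    isi_short_s = as.numeric(isi_short_s),
    inter_phase_break_s = as.numeric(inter_phase_break_s),
    low_intensity_dbu = as.numeric(low_intensity_dbu),
    high_intensity_dbu = as.numeric(high_intensity_dbu),
    sensitivity_levels_dbu = as.numeric(sensitivity_levels_dbu),
    trials_per_level = as.integer(trials_per_level),
    sensitivity_isi_s = as.numeric(sensitivity_isi_s)
  )
}

setMethod("show", "ProtocolConfig", function(object) {
  cat("ProtocolConfig\n")
  cat(sprintf("  habituation assay: %d sensitivity + %d prehab (%.0f s ISI) + %d habituating (%.0f s ISI)\n",
              object@n_sensitivity, object@n_prehab, object@isi_long_s,
              object@n_hab, object@isi_short_s))
  cat(sprintf("  intensities: low %.1f dBu, high %.1f dBu\n",
              object@low_intensity_dbu, object@high_intensity_dbu))
  cat(sprintf("  sensitivity assay: %d trials x %d levels (%s dBu), %.0f s ISI\n",
              object@trials_per_level, length(object@sensitivity_levels_dbu),
              paste(object@sensitivity_levels_dbu, collapse = ", "),
              object@sensitivity_isi_s))
})

#' Build the habituation-assay stimulus schedule
#'
#' Lays out the three phases of the habituation assay as an ordered stimulus
#' table. With defaults: stimuli 1-10 at the low (sub-threshold) intensity
#' with 30 s spacing, 11-20 at the high intensity with 30 s spacing, and
#' 21-50 at the high intensity with 3 s spacing. Inter-phase breaks appear as
#' extra gaps in `time_s` after the last stimulus of a phase, never as
#' sentinel rows, so stimulus indices stay aligned with phase language like
#' "stimuli 41-50".
#'
#' @param config a [ProtocolConfig-class].
#' @return A data.frame with columns `index`, `time_s`, `intensity_dbu`,
#'   `phase` (one of `"sensitivity"`, `"prehab"`, `"habituation"`).
#' @examples
#' sched <- buildHabituationSchedule(protocolConfig())
#' diff(sched$time_s)[20]  # 30 s break before the habituation phase
#' @export
buildHabituationSchedule <- function(config = protocolConfig()) {
  stopifnot(is(config, "ProtocolConfig"))
  validObject(config)
  phases <- c(
    rep("sensitivity", config@n_sensitivity),
    rep("prehab", config@n_prehab),
    rep("habituation", config@n_hab)
  )
  isi <- c(
    rep(config@isi_long_s, config@n_sensitivity),
    rep(config@isi_long_s, config@n_prehab),
    rep(config@isi_short_s, config@n_hab)
  )
  n <- length(phases)
  # gap preceding each stimulus: the phase ISI, except at a phase boundary
  # where the inter-phase break replaces the ISI; the first stimulus fires
  # at t = 0
  gaps <- isi
  gaps[1L] <- 0
  boundary <- which(phases[-1L] != phases[-n]) + 1L
  gaps[boundary] <- config@inter_phase_break_s
  intensity <- ifelse(phases == "sensitivity",
                      config@low_intensity_dbu, config@high_intensity_dbu)
  data.frame(
    index = seq_len(n),
    time_s = cumsum(gaps),
    intensity_dbu = intensity,
    phase = phases,
    stringsAsFactors = FALSE
  )
}

#' Build the multi-intensity sensitivity-assay schedule
#'
#' Five trials (by default) at each of the configured stimulus intensities,
#' every stimulus separated by a 40 s ISI and labeled `"intensity_block"`.
#' Trials cycle through the intensity ladder so that the trials at any one
#' level are spread across the session.
#'
#' @param config a [ProtocolConfig-class].
#' @return A data.frame with columns `index`, `time_s`, `intensity_dbu`,
#'   `phase` (all `"intensity_block"`).
#' @examples
#' sched <- buildSensitivitySchedule(protocolConfig())
#' table(sched$intensity_dbu)  # 5 trials at each of 6 levels
#' @export
buildSensitivitySchedule <- function(config = protocolConfig()) {
  stopifnot(is(config, "ProtocolConfig"))
  validObject(config)
  levels <- config@sensitivity_levels_dbu
  if (length(levels) == 0L) {
    stop("sensitivity_levels_dbu is empty: no intensities to schedule")
  }
  intensity <- rep(levels, times = config@trials_per_level)
  n <- length(intensity)
  data.frame(
    index = seq_len(n),
    time_s = (seq_len(n) - 1L) * config@sensitivity_isi_s,
    intensity_dbu = intensity,
    phase = rep("intensity_block", n),
    stringsAsFactors = FALSE
  )
}

#' Convert a voltage to the dBu scale
#'
#' Stimulus intensities are calibrated from accelerometer voltage outputs as
#' decibels referenced to 0.775 V: `dBu = 20 * log10(v / 0.775)`.
#'
#' @param v voltage(s), strictly positive.
#' @return Intensity in dBu; 0.775 V maps to 0 dBu and each factor of 10 in
#'   voltage adds 20 dBu.
#' @examples
#' dbuFromVolts(0.775)  # 0
#' dbuFromVolts(7.75)   # 20
#' @export
dbuFromVolts <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
    stop("voltage must be finite and > 0")
  }
  20 * log10(v / 0.775)
}

#' Write or read a stimulus schedule as CSV
#'
#' @param schedule a schedule data.frame from [buildHabituationSchedule()] or
#'   [buildSensitivitySchedule()].
#' @param path file path.
#' @return `readSchedule` returns the schedule data.frame;
#'   `writeSchedule` returns `path` invisibly.
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(all(c("index", "time_s", "intensity_dbu", "phase") %in%
                names(schedule)))
  utils::write.csv(schedule, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  sched <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "time_s", "intensity_dbu", "phase")
  missing <- setdiff(need, names(sched))
  if (length(missing)) {
    stop("schedule file lacks columns: ", paste(missing, collapse = ", "))
  }
  sched[need]
}

#' Read a protocol configuration from JSON
#'
#' Fields mirror the arguments of [protocolConfig()]; absent fields fall back
#' to the defaults.
#'
#' @param path path to a JSON file.
#' @return A [ProtocolConfig-class].
#' @export
readProtocolConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(protocolConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown protocol fields: ", paste(unknown, collapse = ", "))
  }
  do.call(protocolConfig, raw)
}
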