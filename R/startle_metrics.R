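#' Classify responses into SLC / LLC / none by latency
#'
#' Short-latency C-bends (SLCs) are Mauthner-neuron-driven startle maneuvers
#' with initiation latency below a short cutoff; long-latency C-bends (LLCs)
#' initiate later. Classification is by latency alone: `none` for
#' non-responses, `SLC` for latency at or below `slc_cutoff_ms`, `LLC` for
#' latency in `(slc_cutoff_ms, llc_cutoff_ms]`, `none` beyond.
#'
#' @param events event data.frame (see [simulateCohort()] for the schema).
#' @param slc_cutoff_ms SLC latency cutoff (ms), default 15.
#' @param llc_cutoff_ms LLC latency cutoff (ms), default 100.
#' @return `events` with a `response_class` column added.
#' @examples
#' ev <- data.frame(larva_id = "a", stimulus_index = 1:3, phase = "prehab",
#'                  intensity_dbu = 25, responded = c(1, 1, 0),
#'                  latency_ms = c(8, 30, NA), duration_ms = c(9, 9, NA))
#' classifyResponses(ev)$response_class  # "SLC" "LLC" "none"
#' @export
classifyResponses <- function(events, slc_cutoff_ms = 15,
                              llc_cutoff_ms = 100) {
  if (!(slc_cutoff_ms > 0 && slc_cutoff_ms < llc_cutoff_ms)) {
    stop("cutoffs must satisfy 0 < slc_cutoff_ms < llc_cutoff_ms")
  }
  responded <- events$responded == 1L
  bad <- responded & !is.finite(events$latency_ms)
  if (any(bad)) {
    stop("responded events with missing latency at rows: ",
         paste(utils::head(which(bad), 10L), collapse = ", "))
  }
  cls <- rep("none", nrow(events))
  lat <- events$latency_ms
  cls[responded & lat <= slc_cutoff_ms] <- "SLC"
  cls[responded & lat > slc_cutoff_ms & lat <= llc_cutoff_ms] <- "LLC"
  events$response_class <- cls
  events
}

#' Per-larva habituation percentage
#'
#' Habituation is the percent reduction of late-phase startle responsiveness
#' relative to baseline: `100 * (1 - freq_late / freq_prehab)`, where
#' `freq_prehab` is the SLC frequency over the pre-habituation stimuli
#' (11-20) and `freq_late` over the last ten habituating stimuli (41-50).
#' A larva that habituates completely scores 100; one whose responsiveness
#' does not change scores 0; sensitization gives negative values.
#'
#' @param freq_prehab baseline SLC frequency in `(0, 1]`.
#' @param freq_late late-phase SLC frequency in `[0, 1]`.
#' @return Habituation percentage.
#' @examples
#' habituationPercent(0.9, 0.15)  # 83.33
#' @export
habituationPercent <- function(freq_prehab, freq_late) {
  if (any(freq_prehab <= 0)) {
    stop("habituation is undefined at zero baseline responsiveness; ",
         "such larvae are excluded by the non-responder filter")
  }
  100 * (1 - freq_late / freq_prehab)
}

.slcFrequency <- function(cls, sel) {
  if (!any(sel)) return(NA_real_)
  mean(cls[sel] == "SLC")
}

# Split events per larva, checking each larva covers the expected stimuli.
.perLarva <- function(events, required_stimuli = NULL, min_coverage = 0.8) {
  split_ev <- split(events, events$larva_id)
  if (!is.null(required_stimuli)) {
    keep <- vapply(split_ev, function(ev) {
      present <- required_stimuli %in% ev$stimulus_index
      if (!all(present)) {
        frac <- mean(present)
        if (frac < min_coverage) {
          stop("larva ", ev$larva_id[1L], " is missing stimuli ",
               paste(utils::head(required_stimuli[!present], 10L),
                     collapse = ", "))
        }
        warning("larva ", ev$larva_id[1L], " tracked on only ",
                round(100 * frac), "% of stimuli; dropped")
        return(FALSE)
      }
      TRUE
    }, logical(1L))
    split_ev <- split_ev[keep]
  }
  split_ev
}

#' Score habituation for a cohort
#'
#' Computes, per larva, the SLC frequencies over the sensitivity phase
#' (stimuli 1-10 by default), the pre-habituation baseline (11-20) and the
#' last ten habituating stimuli (41-50), and the habituation percentage
#' ([habituationPercent()]). Larvae with baseline SLC frequency below the
#' non-responder threshold (responding to fewer than 40% of pre-habituation
#' stimuli) are flagged `included = FALSE` and carry no habituation value;
#' the threshold is a strict inequality, so a larva at exactly 40% is
#' retained. The group statistic is the mean of per-larva habituation
#' percentages over included larvae.
#'
#' @param events classified event data.frame (run [classifyResponses()]
#'   first, or pass `classify = TRUE`).
#' @param filter_threshold non-responder exclusion threshold on the baseline
#'   SLC frequency (default 0.40; exclusion is `freq_prehab < threshold`).
#' @param sensitivity_stimuli,prehab_stimuli,late_stimuli stimulus index
#'   windows of the three frequencies.
#' @param classify if `TRUE`, apply [classifyResponses()] with default
#'   cutoffs first.
#' @return A list with `per_larva` (data.frame: `larva_id`,
#'   `freq_sensitivity`, `freq_prehab`, `freq_late`, `habituation_pct`,
#'   `included`) and `group_mean_habituation_pct`.
#' @examples
#' ev <- simulateCohort("wt_tl", n_larvae = 20, seed = 1)
#' res <- scoreHabituation(ev, classify = TRUE)
#' res$group_mean_habituation_pct
#' @export
scoreHabituation <- function(events, filter_threshold = 0.40,
                             sensitivity_stimuli = 1:10,
                             prehab_stimuli = 11:20,
                             late_stimuli = 41:50,
                             classify = FALSE) {
  if (classify) events <- classifyResponses(events)
  if (!"response_class" %in% names(events)) {
    stop("events are not classified; run classifyResponses() first ",
         "or pass classify = TRUE")
  }
  required <- c(sensitivity_stimuli, prehab_stimuli, late_stimuli)
  split_ev <- .perLarva(events, required)
  per_larva <- do.call(rbind, lapply(split_ev, function(ev) {
    f_sens <- .slcFrequency(ev$response_class,
                            ev$stimulus_index %in% sensitivity_stimuli)
    f_pre <- .slcFrequency(ev$response_class,
                           ev$stimulus_index %in% prehab_stimuli)
    f_late <- .slcFrequency(ev$response_class,
                            ev$stimulus_index %in% late_stimuli)
    included <- f_pre >= filter_threshold
    data.frame(
      larva_id = ev$larva_id[1L],
      freq_sensitivity = f_sens,
      freq_prehab = f_pre,
      freq_late = f_late,
      habituation_pct = if (included) habituationPercent(f_pre, f_late)
                        else NA_real_,
      included = included,
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_larva) <- NULL
  list(
    per_larva = per_larva,
    group_mean_habituation_pct =
      mean(per_larva$habituation_pct[per_larva$included])
  )
}

#' Group sensitivity-phase response rate
#'
#' Mean over larvae of the per-larva SLC frequency across the sub-threshold
#' sensitivity-phase stimuli (1-10 by default), expressed as a percentage.
#' The non-responder filter does not apply here: hypersensitive larvae that
#' would be excluded from habituation scoring still count.
#'
#' @inheritParams scoreHabituation
#' @param stimuli stimulus indices of the sensitivity phase.
#' @return Group mean SLC response rate in percent.
#' @export
sensitivityPhaseRate <- function(events, stimuli = 1:10, classify = FALSE) {
  if (classify) events <- classifyResponses(events)
  if (!"response_class" %in% names(events)) {
    stop("events are not classified; run classifyResponses() first")
  }
  split_ev <- .perLarva(events, stimuli)
  if (length(split_ev) == 0L) stop("no larvae in the event table")
  rates <- vapply(split_ev, function(ev) {
    .slcFrequency(ev$response_class, ev$stimulus_index %in% stimuli)
  }, numeric(1L))
  100 * mean(rates)
}

#' Per-larva sensitivity profiles from an intensity assay
#'
#' SLC response frequency (percent) of each larva at each stimulus intensity
#' of the multi-intensity assay, plus the per-larva sensitivity index
#' ([sensitivityIndex()]).
#'
#' @inheritParams scoreHabituation
#' @return A list with `per_larva` (data.frame: `larva_id`,
#'   `intensity_dbu`, `freq_pct` in long form), `index` (data.frame:
#'   `larva_id`, `sensitivity_index`) and `group_mean_index`.
#' @export
sensitivityProfiles <- function(events, classify = FALSE) {
  if (classify) events <- classifyResponses(events)
  if (!"response_class" %in% names(events)) {
    stop("events are not classified; run classifyResponses() first")
  }
  split_ev <- .perLarva(events)
  prof <- do.call(rbind, lapply(split_ev, function(ev) {
    agg <- tapply(ev$response_class == "SLC", ev$intensity_dbu, mean)
    data.frame(
      larva_id = ev$larva_id[1L],
      intensity_dbu = as.numeric(names(agg)),
      freq_pct = 100 * as.numeric(agg),
      stringsAsFactors = FALSE
    )
  }))
  rownames(prof) <- NULL
  idx <- do.call(rbind, lapply(split(prof, prof$larva_id), function(p) {
    data.frame(
      larva_id = p$larva_id[1L],
      sensitivity_index = sensitivityIndex(
        setNames(p$freq_pct, p$intensity_dbu)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(idx) <- NULL
  list(per_larva = prof, index = idx,
       group_mean_index = mean(idx$sensitivity_index))
}

#' Sensitivity index: area under the percent-startle curve
#'
#' Trapezoidal area under the percent-startle vs. stimulus-intensity curve,
#' in units of percent x dBu. A larva responding 100% across the default
#' 0.3-35 dBu ladder scores 3470; higher indices mean lower startle
#' thresholds.
#'
#' @param freq_by_intensity named numeric vector: names are intensities
#'   (dBu), values percent startle in `[0, 100]`; at least two intensities.
#' @return Area in percent x dBu.
#' @examples
#' sensitivityIndex(c("0.3" = 0, "35" = 100))  # 1735
#' @export
sensitivityIndex <- function(freq_by_intensity) {
  x <- as.numeric(names(freq_by_intensity))
  y <- as.numeric(freq_by_intensity)
  if (length(x) < 2L || any(is.na(x))) {
    stop("need frequencies at >= 2 named intensities")
  }
  o <- order(x)
  x <- x[o]
  y <- y[o]
  # collapse duplicate intensity points (equal frequencies) so duplicates
  # cannot inflate the area
  keep <- c(TRUE, diff(x) > 0)
  if (!all(keep)) {
    dup <- which(!keep)
    if (any(abs(y[dup] - y[dup - 1L]) > sqrt(.Machine$double.eps))) {
      stop("duplicate intensities with conflicting frequencies")
    }
    x <- x[keep]
    y <- y[keep]
  }
  if (length(x) < 2L) stop("need >= 2 distinct intensities")
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Per-larva SLC kinematic summaries
#'
#' Mean SLC latency and C-turn duration per larva over the pre-habituation
#' stimuli (11-20 by default) — the high-intensity, non-habituating baseline
#' phase the kinematic analysis is restricted to. Larvae excluded by the
#' non-responder filter are dropped; larvae with no SLC in the window yield
#' no summary row.
#'
#' @inheritParams scoreHabituation
#' @param stimuli stimulus window summarized.
#' @param apply_filter drop larvae failing the non-responder filter
#'   (default `TRUE`).
#' @return data.frame: `larva_id`, `mean_latency_ms`, `mean_duration_ms`,
#'   `n_slc`.
#' @export
kinematicSummary <- function(events, stimuli = 11:20,
                             filter_threshold = 0.40, apply_filter = TRUE,
                             classify = FALSE) {
  if (classify) events <- classifyResponses(events)
  if (!"response_class" %in% names(events)) {
    stop("events are not classified; run classifyResponses() first")
  }
  split_ev <- .perLarva(events, stimuli)
  rows <- lapply(split_ev, function(ev) {
    sel_win <- ev$stimulus_index %in% stimuli
    if (apply_filter &&
        .slcFrequency(ev$response_class, sel_win) < filter_threshold) {
      return(NULL)
    }
    sel <- sel_win & ev$response_class == "SLC"
    if (!any(sel)) return(NULL)
    data.frame(
      larva_id = ev$larva_id[1L],
      mean_latency_ms = mean(ev$latency_ms[sel]),
      mean_duration_ms = mean(ev$duration_ms[sel]),
      n_slc = sum(sel),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(larva_id = character(0), mean_latency_ms = numeric(0),
                      mean_duration_ms = numeric(0), n_slc = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' SLC latency by stimulus intensity
#'
#' Mean SLC latency per intensity level (and per genotype when the event
#' table carries one), pooling SLC responses across larvae; intensities
#' contributing fewer than `min_n` SLCs are flagged `low_n` (too few
#' responses to report).
#'
#' @inheritParams scoreHabituation
#' @param min_n minimum SLC count for a reportable mean.
#' @return data.frame: `intensity_dbu`, `genotype`, `mean_latency_ms`, `n`,
#'   `low_n`; intensities with no SLCs yield no row.
#' @export
latencyByIntensity <- function(events, min_n = 3L, classify = FALSE) {
  if (classify) events <- classifyResponses(events)
  if (!"response_class" %in% names(events)) {
    stop("events are not classified; run classifyResponses() first")
  }
  slc <- events[events$response_class == "SLC", , drop = FALSE]
  if (nrow(slc) == 0L) {
    return(data.frame(intensity_dbu = numeric(0), genotype = character(0),
                      mean_latency_ms = numeric(0), n = integer(0),
                      low_n = logical(0)))
  }
  if (!"genotype" %in% names(slc)) slc$genotype <- "all"
  groups <- split(slc, list(slc$intensity_dbu, slc$genotype), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      intensity_dbu = g$intensity_dbu[1L],
      genotype = g$genotype[1L],
      mean_latency_ms = mean(g$latency_ms),
      n = nrow(g),
      low_n = nrow(g) < min_n,
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$intensity_dbu, out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}
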