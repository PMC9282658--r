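.EVENT_COLUMNS <- c("larva_id", "genotype", "stimulus_index", "phase",
                    "intensity_dbu", "responded", "latency_ms", "duration_ms")
.KNOWN_PHASES <- c("sensitivity", "prehab", "habituation", "intensity_block")

#' Read and write behavioral event tables
#'
#' Event CSV schema: `larva_id, genotype, stimulus_index, phase,
#' intensity_dbu, responded, latency_ms, duration_ms`, with `responded` in
#' {0, 1} and empty latency/duration on non-response rows. Reading
#' validates the schema: missing columns, unknown phase labels, and
#' responded rows with missing latency are errors naming the offending
#' rows.
#'
#' @param path CSV path.
#' @return `readEvents` returns the validated event data.frame;
#'   `writeEvents` returns `path` invisibly.
#' @export
readEvents <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.EVENT_COLUMNS, names(ev))
  if (length(missing)) {
    stop("event file lacks columns: ", paste(missing, collapse = ", "))
  }
  ev <- ev[.EVENT_COLUMNS]
  bad_phase <- !ev$phase %in% .KNOWN_PHASES
  if (any(bad_phase)) {
    stop("unknown phase label(s): ",
         paste(unique(ev$phase[bad_phase]), collapse = ", "),
         " (rows ", paste(utils::head(which(bad_phase), 10L), collapse = ", "),
         ")")
  }
  if (!all(ev$responded %in% c(0L, 1L))) {
    stop("responded must be 0 or 1")
  }
  bad_lat <- ev$responded == 1L & !is.finite(ev$latency_ms)
  if (any(bad_lat)) {
    stop("responded rows with empty latency_ms: rows ",
         paste(utils::head(which(bad_lat), 10L), collapse = ", "))
  }
  ev
}

#' @rdname readEvents
#' @param events event data.frame.
#' @export
writeEvents <- function(events, path) {
  missing <- setdiff(.EVENT_COLUMNS, names(events))
  if (length(missing)) {
    stop("event table lacks columns: ", paste(missing, collapse = ", "))
  }
  utils::write.csv(events[.EVENT_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read and write pooled marker tables
#'
#' Marker TSV schema: `chrom, pos_bp, cM, tl_count, wik_count` with 1-based
#' positions (`cM` optional on read).
#'
#' @param path TSV path.
#' @return `readMarkerTable` returns the marker data.frame;
#'   `writeMarkerTable` returns `path` invisibly.
#' @export
readMarkerTable <- function(path) {
  mk <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos_bp", "tl_count", "wik_count")
  missing <- setdiff(need, names(mk))
  if (length(missing)) {
    stop("marker file lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(mk$tl_count < 0) || any(mk$wik_count < 0)) {
    stop("negative read counts")
  }
  mk
}

#' @rdname readMarkerTable
#' @param marker_table marker data.frame.
#' @export
writeMarkerTable <- function(marker_table, path) {
  utils::write.table(marker_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a homozygosity track and its called interval
#'
#' The per-marker track goes to TSV (`chrom, pos_bp, tl_count, wik_count,
#' score, smoothed, masked`); the called interval, when present, to BED.
#' Internally positions are 1-based and intervals closed; BED output is
#' converted to 0-based half-open at write time.
#'
#' @param track a [HomozygosityTrack-class].
#' @param path output TSV path.
#' @param bed_path optional BED path for the called interval.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path, bed_path = NULL) {
  stopifnot(is(track, "HomozygosityTrack"))
  gr <- markers(track)
  mc <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos_bp = GenomicRanges::start(gr),
    tl_count = mc$tl_count,
    wik_count = mc$wik_count,
    score = mc$score,
    smoothed = mc$smoothed,
    masked = as.integer(mc$masked),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(bed_path)) {
    iv <- calledInterval(track)
    bed <- if (length(iv)) {
      data.frame(
        chrom = as.character(GenomicRanges::seqnames(iv)),
        start = GenomicRanges::start(iv) - 1L,  # BED is 0-based half-open
        end = GenomicRanges::end(iv),
        name = "linkage_interval"
      )
    } else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 name = character(0))
    }
    utils::write.table(bed, bed_path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Run the full behavioral pipeline on a simulated cohort pair
#'
#' End-to-end demonstration run: simulate a control and a mutant cohort,
#' classify responses, score habituation, compute sensitivity-phase rates,
#' compare the per-larva habituation percentages between genotypes, and
#' write per-larva CSVs, a group-summary JSON and a provenance JSON (seed,
#' configuration hash, package version) to `out_dir`. The same seed and
#' configuration give byte-identical numeric outputs.
#'
#' @param control_preset,mutant_preset preset names or
#'   [GenotypePreset-class] objects.
#' @param n_control,n_mutant cohort sizes.
#' @param config a [ProtocolConfig-class].
#' @param seed master seed; all randomness derives from it.
#' @param out_dir output directory, created if needed; `NULL` writes
#'   nothing.
#' @return List with `habituation` (per-genotype score lists),
#'   `sensitivity_rate_pct` (named vector), `comparison` (data.frame from
#'   [compareGroups()]), `provenance`.
#' @export
runPipeline <- function(control_preset = "wt_tl", mutant_preset = "p177_hom",
                        n_control = 68L, n_mutant = 63L,
                        config = protocolConfig(), seed = 1L,
                        out_dir = NULL) {
  if (is.character(control_preset)) control_preset <- startlePreset(control_preset)
  if (is.character(mutant_preset)) mutant_preset <- startlePreset(mutant_preset)
  schedule <- buildHabituationSchedule(config)
  cohorts <- list(
    control = simulateCohort(control_preset, schedule, n_control, seed = seed),
    mutant = simulateCohort(mutant_preset, schedule, n_mutant,
                            seed = seed + 1L)
  )
  cohorts <- lapply(cohorts, classifyResponses)
  hab <- lapply(cohorts, scoreHabituation)
  sens <- vapply(cohorts, sensitivityPhaseRate, numeric(1L))
  per_larva <- do.call(rbind, lapply(names(hab), function(g) {
    cbind(genotype = c(control = control_preset@name,
                       mutant = mutant_preset@name)[[g]],
          hab[[g]]$per_larva)
  }))
  included <- per_larva[per_larva$included, , drop = FALSE]
  comparison <- compareGroups(included$habituation_pct, included$genotype,
                              reference = control_preset@name,
                              metric = "habituation_pct")
  prov <- list(
    seed = seed,
    n_control = n_control,
    n_mutant = n_mutant,
    control_preset = control_preset@name,
    mutant_preset = mutant_preset@name,
    config_hash = .hashObject(list(
      control_preset, mutant_preset, n_control, n_mutant, config, seed)),
    package_version = as.character(utils::packageVersion("startlehab"))
  )
  result <- list(
    habituation = hab,
    sensitivity_rate_pct = sens,
    comparison = comparison,
    provenance = prov
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_larva, file.path(out_dir, "habituation_per_larva.csv"),
                     row.names = FALSE, quote = FALSE)
    summary <- list(
      group_mean_habituation_pct = lapply(hab, `[[`,
                                          "group_mean_habituation_pct"),
      sensitivity_rate_pct = as.list(sens),
      comparison = comparison
    )
    jsonlite::write_json(summary, file.path(out_dir, "group_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

# Content hash of an arbitrary configuration object via its serialization.
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
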