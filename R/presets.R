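#' Create a genotype simulation preset
#'
#' @param name preset label.
#' @param p_sensitivity SLC probability per sub-threshold stimulus.
#' @param p_baseline SLC probability per high-intensity stimulus before
#'   habituation.
#' @param habituation_pct asymptotic habituation percentage (0-100).
#' @param psychometric_anchors two-column matrix or data.frame
#'   (`intensity_dbu`, `p`) of psychometric anchor points.
#' @param latency_median_ms median SLC latency (ms).
#' @param latency_sdlog sd of log-latency.
#' @param latency_shift multiplicative latency factor at intensities above
#'   the lowest anchor (1 = no shift).
#' @param duration_mean_ms,duration_sd_ms C-turn duration parameters (ms).
#' @return A [GenotypePreset-class].
#' @seealso [startlePreset()] for the built-in calibrated presets.
#' @export
genotypePreset <- function(name,
                           p_sensitivity,
                           p_baseline = 0.80,
                           habituation_pct,
                           psychometric_anchors =
                             cbind(intensity_dbu = c(5, 25), p = c(p_sensitivity, p_baseline)),
                           latency_median_ms = 6.0,
                           latency_sdlog = 0.25,
                           latency_shift = 1.0,
                           duration_mean_ms = 9.0,
                           duration_sd_ms = 1.5) {
  anchors <- as.matrix(psychometric_anchors)
  colnames(anchors) <- c("intensity_dbu", "p")
  new("GenotypePreset",
    name = name,
    p_sensitivity = as.numeric(p_sensitivity),
    p_baseline = as.numeric(p_baseline),
    habituation_pct = as.numeric(habituation_pct),
    psychometric_anchors = anchors,
    latency_median_ms = as.numeric(latency_median_ms),
    latency_sdlog = as.numeric(latency_sdlog),
    latency_shift = as.numeric(latency_shift),
    duration_mean_ms = as.numeric(duration_mean_ms),
    duration_sd_ms = as.numeric(duration_sd_ms)
  )
}

setMethod("show", "GenotypePreset", function(object) {
  cat("GenotypePreset:", object@name, "\n")
  cat(sprintf("  p_sensitivity %.3f | p_baseline %.2f | habituation %.1f%%\n",
              object@p_sensitivity, object@p_baseline, object@habituation_pct))
  cat(sprintf("  latency: median %.1f ms (sdlog %.2f, shift x%.2f); duration %.1f +/- %.1f ms\n",
              object@latency_median_ms, object@latency_sdlog,
              object@latency_shift, object@duration_mean_ms,
              object@duration_sd_ms))
  cat(sprintf("  psychometric anchors: %s\n",
              paste(sprintf("(%.1f dBu, %.3f)",
                            object@psychometric_anchors[, 1L],
                            object@psychometric_anchors[, 2L]),
                    collapse = " ")))
})

# Built-in presets, calibrated to the reported group statistics for each
# cacna2d3 genotype: sensitivity-phase SLC rates, asymptotic habituation
# percentages, and the psychometric anchor points of the sa16189
# intensity-response curves. Baseline responsiveness is 0.80 everywhere
# because the high-intensity stimulus is calibrated to elicit SLCs ~80% of
# the time; the reduced-intensity variant uses an intermediate baseline.
# Mutant latency factors < 1 encode the reduced C-turn latency of mutants.
.builtinPresets <- function() {
  list(
    wt_tl = genotypePreset("wt_tl",
      p_sensitivity = 0.093, habituation_pct = 83.3,
      psychometric_anchors = cbind(c(5, 25), c(0.093, 0.80))),
    p177_hom = genotypePreset("p177_hom",
      p_sensitivity = 0.524, habituation_pct = 5.4,
      latency_median_ms = 4.8, latency_shift = 0.80,
      psychometric_anchors = cbind(c(5, 25), c(0.524, 0.90))),
    sa16189_het = genotypePreset("sa16189_het",
      p_sensitivity = 0.16, habituation_pct = 76.7,
      psychometric_anchors = cbind(c(7.6, 25.6), c(0.024, 0.888))),
    sa16189_hom = genotypePreset("sa16189_hom",
      p_sensitivity = 0.70, habituation_pct = 12.4,
      latency_median_ms = 5.1, latency_shift = 0.85,
      psychometric_anchors = cbind(c(7.6, 13), c(0.334, 0.888))),
    sa16051_het = genotypePreset("sa16051_het",
      p_sensitivity = 0.11, habituation_pct = 86.0,
      psychometric_anchors = cbind(c(7.6, 25.6), c(0.03, 0.85))),
    sa16051_hom = genotypePreset("sa16051_hom",
      p_sensitivity = 0.60, habituation_pct = 19.9,
      latency_median_ms = 5.1, latency_shift = 0.85,
      psychometric_anchors = cbind(c(7.6, 14), c(0.30, 0.85))),
    sa16051_hom_reduced = genotypePreset("sa16051_hom_reduced",
      p_sensitivity = 0.60, p_baseline = 0.65, habituation_pct = 32.6,
      latency_median_ms = 5.1, latency_shift = 0.85,
      psychometric_anchors = cbind(c(7.6, 14), c(0.30, 0.85))),
    p177_sa16189_transhet = genotypePreset("p177_sa16189_transhet",
      p_sensitivity = 0.382, habituation_pct = 39.5,
      latency_median_ms = 5.4, latency_shift = 0.90,
      psychometric_anchors = cbind(c(7.6, 15), c(0.20, 0.85))),
    p177_sa16051_transhet = genotypePreset("p177_sa16051_transhet",
      p_sensitivity = 0.424, habituation_pct = 39.0,
      latency_median_ms = 5.4, latency_shift = 0.90,
      psychometric_anchors = cbind(c(7.6, 15), c(0.22, 0.85)))
  )
}

#' Built-in calibrated genotype presets
#'
#' Returns one of the calibrated presets by name, or (with no argument) the
#' names of all built-ins. Presets cover wild-type TL larvae, the three
#' cacna2d3 mutant alleles (p177 splice-donor, sa16189 and sa16051 nonsense)
#' as homozygotes and heterozygotes, the two trans-heterozygous allele
#' combinations, and a reduced-intensity variant of the sa16051 homozygote
#' used with intermediate-strength stimuli.
#'
#' @param name preset name; omit to list available names.
#' @return A [GenotypePreset-class], or a character vector of names.
#' @examples
#' startlePreset()
#' startlePreset("wt_tl")
#' @export
startlePreset <- function(name) {
  presets <- .builtinPresets()
  if (missing(name)) {
    return(names(presets))
  }
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}
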