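#' Per-marker homozygosity score
#'
#' Fraction of reads carrying the mutagenized-strain (TL) allele:
#' `tl_count / (tl_count + wik_count)`. Scores near 1 indicate linkage to TL
#' alleles (the pool is homozygous TL), near 0 linkage to the WIK mapping
#' strain, and unlinked markers average 0.5. Zero-coverage markers score
#' `NA`.
#'
#' @param tl_count,wik_count read counts for the two strain alleles.
#' @return TL allele fraction in `[0, 1]`, `NA` where coverage is zero.
#' @examples
#' homozygosityScore(50, 0)   # 1
#' homozygosityScore(25, 25)  # 0.5
#' @export
homozygosityScore <- function(tl_count, wik_count) {
  stopifnot(all(tl_count >= 0), all(wik_count >= 0))
  total <- tl_count + wik_count
  out <- ifelse(total > 0, tl_count / total, NA_real_)
  if (any(total == 0)) {
    warning(sum(total == 0), " marker(s) with zero coverage skipped")
  }
  out
}

#' Running-median smoothing of a score track
#'
#' Median over a sliding window of `window` markers, computed independently
#' per chromosome; at chromosome ends the window shrinks symmetrically so
#' the smoother stays centered, and `window = 1` is the identity. `NA`
#' scores (masked or zero-coverage markers) are tolerated: the median is
#' taken over the non-missing scores in the window.
#'
#' @param scores numeric score vector for one chromosome.
#' @param window odd window size in markers.
#' @return Smoothed scores, same length as `scores`.
#' @export
smoothScores <- function(scores, window = 51L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  n <- length(scores)
  if (window == 1L || n == 0L) return(scores)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    w <- scores[(i - h):(i + h)]
    if (all(is.na(w))) NA_real_ else median(w, na.rm = TRUE)
  }, numeric(1L))
}

#' Build a homozygosity track from a pooled marker table
#'
#' Computes per-marker homozygosity scores, masks low-coverage markers,
#' smooths with a running median per chromosome, and calls the candidate
#' linkage interval ([callInterval()]).
#'
#' @param marker_table data.frame with columns `chrom`, `pos_bp`,
#'   `tl_count`, `wik_count` (and optionally `cM`), e.g. from
#'   [simulateMutantPool()] or [readMarkerTable()].
#' @param window running-median window in markers (odd), default 51.
#' @param threshold smoothed-score threshold for interval calling,
#'   default 0.95.
#' @param min_coverage markers with fewer reads are masked before smoothing.
#' @return A [HomozygosityTrack-class].
#' @examples
#' mk <- makeMarkerMap(n_chrom = 2, markers_per_chrom = 100)
#' pool <- simulateMutantPool(mk, "chr1", 40, coverage = 50, seed = 7)
#' trk <- homozygosityTrack(pool, window = 21)
#' calledInterval(trk)
#' @export
homozygosityTrack <- function(marker_table, window = 51L, threshold = 0.95,
                              min_coverage = 4L) {
  need <- c("chrom", "pos_bp", "tl_count", "wik_count")
  missing <- setdiff(need, names(marker_table))
  if (length(missing)) {
    stop("marker table lacks columns: ", paste(missing, collapse = ", "))
  }
  marker_table <- marker_table[order(marker_table$chrom,
                                     marker_table$pos_bp), , drop = FALSE]
  dup <- duplicated(marker_table[c("chrom", "pos_bp")])
  if (any(dup)) stop("duplicate marker positions within a chromosome")
  total <- marker_table$tl_count + marker_table$wik_count
  score <- suppressWarnings(
    homozygosityScore(marker_table$tl_count, marker_table$wik_count))
  masked <- total < min_coverage
  usable <- ifelse(masked, NA_real_, score)
  # rows are sorted by (chrom, pos), so split() preserves marker order
  smoothed <- unlist(lapply(
    split(usable, marker_table$chrom),
    smoothScores, window = as.integer(window)
  ), use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = marker_table$chrom,
    ranges = IRanges::IRanges(start = marker_table$pos_bp, width = 1L)
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    tl_count = marker_table$tl_count,
    wik_count = marker_table$wik_count,
    score = score,
    smoothed = smoothed,
    masked = masked
  )
  obj <- new("HomozygosityTrack",
    markers = gr,
    interval = GenomicRanges::GRanges(),
    window = as.integer(window),
    threshold = as.numeric(threshold),
    min_coverage = as.integer(min_coverage)
  )
  obj@interval <- callInterval(obj)
  validObject(obj)
  obj
}

#' Call the candidate linkage interval
#'
#' Returns the maximal contiguous run of markers whose smoothed score
#' reaches `threshold` and which contains the genome-wide smoothed-score
#' maximum; the interval is closed on both ends, spanning the first to last
#' marker of the run. If no marker reaches the threshold, an empty
#' `GRanges` is returned. When two disjoint runs exceed the threshold, only
#' the run containing the global maximum is called (ties broken by the
#' first maximum in genome order).
#'
#' @param track a [HomozygosityTrack-class].
#' @param threshold override the track's calling threshold.
#' @return A `GRanges` of length 0 (no call) or 1.
#' @export
callInterval <- function(track, threshold = NULL) {
  stopifnot(is(track, "HomozygosityTrack"))
  if (is.null(threshold)) threshold <- track@threshold
  gr <- track@markers
  sm <- S4Vectors::mcols(gr)$smoothed
  ok <- !is.na(sm) & sm >= threshold
  if (!any(ok)) return(GenomicRanges::GRanges())
  imax <- which.max(ifelse(is.na(sm), -Inf, sm))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  # contiguous run of above-threshold markers on imax's chromosome
  # containing imax
  run_id <- cumsum(c(TRUE, diff(ok) != 0 | chrom[-1L] != chrom[-length(chrom)]))
  if (!ok[imax]) {
    # global max is masked/NA-adjacent; fall back to the highest
    # above-threshold marker
    imax <- which(ok)[which.max(sm[ok])]
  }
  members <- which(run_id == run_id[imax] & ok)
  GenomicRanges::GRanges(
    seqnames = chrom[imax],
    ranges = IRanges::IRanges(
      start = min(GenomicRanges::start(gr)[members]),
      end = max(GenomicRanges::start(gr)[members])
    )
  )
}

#' @describeIn homozygosityTrack marker-level `GRanges` with score columns.
#' @param track a [HomozygosityTrack-class].
#' @export
markers <- function(track) {
  stopifnot(is(track, "HomozygosityTrack"))
  track@markers
}

#' @describeIn homozygosityTrack raw per-marker homozygosity scores.
#' @export
scores <- function(track) {
  stopifnot(is(track, "HomozygosityTrack"))
  S4Vectors::mcols(track@markers)$score
}

#' @describeIn homozygosityTrack smoothed per-marker scores.
#' @export
smoothedScores <- function(track) {
  stopifnot(is(track, "HomozygosityTrack"))
  S4Vectors::mcols(track@markers)$smoothed
}

#' @describeIn homozygosityTrack the called linkage interval (`GRanges`,
#'   length 0 or 1).
#' @export
calledInterval <- function(track) {
  stopifnot(is(track, "HomozygosityTrack"))
  track@interval
}

setMethod("show", "HomozygosityTrack", function(object) {
  gr <- object@markers
  nchr <- length(unique(as.character(GenomicRanges::seqnames(gr))))
  cat(sprintf("HomozygosityTrack: %d markers on %d chromosome(s)\n",
              length(gr), nchr))
  cat(sprintf("  window %d markers, threshold %.2f, %d masked (coverage < %d)\n",
              object@window, object@threshold,
              sum(S4Vectors::mcols(gr)$masked), object@min_coverage))
  if (length(object@interval)) {
    iv <- object@interval
    cat(sprintf("  called interval: %s:%d-%d\n",
                as.character(GenomicRanges::seqnames(iv)),
                GenomicRanges::start(iv), GenomicRanges::end(iv)))
  } else {
    cat("  called interval: none\n")
  }
})
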