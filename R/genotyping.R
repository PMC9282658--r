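#' Define a CAPS/dCAPS digest assay
#'
#' @param allele_name mutant allele label (e.g. `"p177"`).
#' @param enzyme restriction endonuclease label.
#' @param recognition_site recognition motif over A/C/G/T.
#' @param cut_offset_in_site cut offset within the motif (0-based bp from
#'   the motif start).
#' @param wt_amplicon_bp,mut_amplicon_bp amplicon length per allele template.
#' @param wt_cuts_bp,mut_cuts_bp cut offsets (bp from the 5' end) on each
#'   template; `numeric(0)` for an uncut template.
#' @return A [DigestAssay-class].
#' @seealso [builtinAssays()] for the three cacna2d3 allele assays.
#' @export
digestAssay <- function(allele_name, enzyme, recognition_site = "",
                        cut_offset_in_site = 0,
                        wt_amplicon_bp, mut_amplicon_bp = wt_amplicon_bp,
                        wt_cuts_bp = numeric(0), mut_cuts_bp = numeric(0)) {
  new("DigestAssay",
    allele_name = allele_name,
    enzyme = enzyme,
    recognition_site = toupper(recognition_site),
    cut_offset_in_site = as.numeric(cut_offset_in_site),
    amplicon_length_bp = c(wt = as.numeric(wt_amplicon_bp),
                           mut = as.numeric(mut_amplicon_bp)),
    cut_positions_bp = list(wt = as.numeric(wt_cuts_bp),
                            mut = as.numeric(mut_cuts_bp))
  )
}

setMethod("show", "DigestAssay", function(object) {
  cat("DigestAssay:", object@allele_name, "|", object@enzyme, "\n")
  for (al in c("wt", "mut")) {
    frag <- predictFragments(object, al)
    cat(sprintf("  %s template: %d bp -> %s\n", al,
                object@amplicon_length_bp[[al]],
                paste(frag, collapse = " + ")))
  }
})

#' Built-in dCAPS/CAPS assays for the three cacna2d3 alleles
#'
#' Cut positions follow the published fragment sizes. For p177 the mismatch
#' reverse primer creates an RsaI site on the wild-type template (cleaved
#' 204 + 16 bp; mutant uncut at 220 bp). The sa16051 assay is the mirror:
#' the mutant template is cleaved (147 + 24 bp) and the wild-type is uncut
#' (171 bp). The sa16189 CAPS assay cuts the mutant template with EcoRV
#' (129 + 40 bp; wild-type uncut at 169 bp).
#'
#' @return Named list of [DigestAssay-class] objects (`p177`, `sa16051`,
#'   `sa16189`).
#' @examples
#' predictFragments(builtinAssays()$p177, "wt")  # 16 204
#' @export
builtinAssays <- function() {
  list(
    p177 = digestAssay("p177", "RsaI",
      recognition_site = "GTAC", cut_offset_in_site = 2,
      wt_amplicon_bp = 220, mut_amplicon_bp = 220,
      wt_cuts_bp = 16, mut_cuts_bp = numeric(0)),
    sa16051 = digestAssay("sa16051", "RsaI",
      recognition_site = "GTAC", cut_offset_in_site = 2,
      wt_amplicon_bp = 171, mut_amplicon_bp = 171,
      wt_cuts_bp = numeric(0), mut_cuts_bp = 24),
    sa16189 = digestAssay("sa16189", "EcoRV",
      recognition_site = "GATATC", cut_offset_in_site = 3,
      wt_amplicon_bp = 169, mut_amplicon_bp = 169,
      wt_cuts_bp = numeric(0), mut_cuts_bp = 40)
  )
}

#' Predict restriction fragments for one allele template
#'
#' Cutting the amplicon at each cut position yields `n_cuts + 1` fragments
#' whose lengths sum to the amplicon length; an uncut template returns the
#' full-length amplicon.
#'
#' @param assay a [DigestAssay-class].
#' @param allele `"wt"` or `"mut"`.
#' @param detection_floor_bp fragments shorter than this are flagged (gel
#'   resolution); they are still returned.
#' @return Sorted numeric vector of fragment lengths (bp), with attribute
#'   `unresolvable` marking fragments below the detection floor.
#' @examples
#' assays <- builtinAssays()
#' predictFragments(assays$sa16189, "mut")  # 40 129
#' @export
predictFragments <- function(assay, allele = c("wt", "mut"),
                             detection_floor_bp = 20) {
  stopifnot(is(assay, "DigestAssay"))
  allele <- match.arg(allele)
  len <- assay@amplicon_length_bp[[allele]]
  cuts <- sort(assay@cut_positions_bp[[allele]])
  if (length(cuts) && (any(cuts <= 0) || any(cuts >= len))) {
    stop("cut position outside the ", allele, " amplicon of assay ",
         assay@allele_name)
  }
  frag <- sort(diff(c(0, cuts, len)))
  attr(frag, "unresolvable") <- frag < detection_floor_bp
  frag
}

#' Find restriction cut positions in a sequence
#'
#' Scans the forward strand for every (possibly overlapping) occurrence of
#' the recognition motif and converts match starts to cut positions. Both
#' enzymes used by the built-in assays (RsaI GT^AC, EcoRV GAT^ATC) are
#' blunt palindromic cutters, so the forward-strand scan is sufficient.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param recognition_site recognition motif.
#' @param cut_offset_in_site cut offset within the motif (0-based from the
#'   motif start); the returned cut position `k` means the template is cut
#'   between bases `k` and `k + 1`.
#' @return Numeric vector of cut positions (bp from the 5' end).
#' @examples
#' findCutSites("AAGTACAA", "GTAC", 2)  # 4
#' @export
findCutSites <- function(sequence, recognition_site, cut_offset_in_site) {
  sequence <- toupper(sequence)
  recognition_site <- toupper(recognition_site)
  if (nchar(recognition_site) == 0L) stop("empty recognition site")
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence contains ambiguous bases")
  }
  starts <- c()
  from <- 1L
  repeat {
    hit <- regexpr(recognition_site, substr(sequence, from, nchar(sequence)),
                   fixed = TRUE)
    if (hit == -1L) break
    pos <- from + as.integer(hit) - 1L
    starts <- c(starts, pos)
    from <- pos + 1L  # allow overlapping matches
  }
  if (is.null(starts)) return(numeric(0))
  starts - 1 + cut_offset_in_site
}

#' Call a genotype from observed digest fragments
#'
#' Compares the observed fragment multiset against the predicted homozygous
#' wild-type pattern, the homozygous mutant pattern, and their union (the
#' heterozygote shows both allele patterns on the gel). Matching is
#' multiset equality with a per-fragment size tolerance reflecting gel
#' resolution. If nothing matches the call is `"ambiguous"`.
#'
#' @param observed_fragments numeric vector of observed band sizes (bp).
#' @param assay a [DigestAssay-class].
#' @param tolerance_bp per-fragment size tolerance, default 5.
#' @return One of `"hom_wt"`, `"het"`, `"hom_mut"`, `"ambiguous"`.
#' @examples
#' callGenotype(c(220), builtinAssays()$p177)           # hom_mut
#' callGenotype(c(16, 204, 220), builtinAssays()$p177)  # het
#' @export
callGenotype <- function(observed_fragments, assay, tolerance_bp = 5) {
  stopifnot(is(assay, "DigestAssay"))
  if (length(observed_fragments) == 0L) {
    stop("no observed fragments; empty lane cannot be called")
  }
  obs <- sort(as.numeric(observed_fragments))
  wt <- as.numeric(predictFragments(assay, "wt"))
  mut <- as.numeric(predictFragments(assay, "mut"))
  het <- sort(unique(round(c(wt, mut))))  # co-migrating shared bands merge
  matches <- function(pattern) {
    pattern <- sort(pattern)
    length(obs) == length(pattern) && all(abs(obs - pattern) <= tolerance_bp)
  }
  if (matches(het) && !identical(sort(wt), sort(mut))) return("het")
  if (matches(wt) && matches(mut)) return("ambiguous")  # indistinguishable
  if (matches(wt)) return("hom_wt")
  if (matches(mut)) return("hom_mut")
  "ambiguous"
}

#' Read digest-assay definitions from JSON
#'
#' The JSON file is a list of objects with fields matching the arguments of
#' [digestAssay()].
#'
#' @param path path to a JSON file.
#' @return Named list of [DigestAssay-class] objects.
#' @export
readAssays <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  assays <- lapply(raw, function(a) do.call(digestAssay, a))
  names(assays) <- vapply(assays, function(a) a@allele_name, character(1L))
  assays
}
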