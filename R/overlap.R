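#' Length of the intersection of two 1-based inclusive intervals
#'
#' Vectorized; returns `max(0, min(aEnd, bEnd) - max(aStart, bStart) + 1)`.
#'
#' @param aStart,aEnd,bStart,bEnd interval bounds (start <= end).
#' @return non-negative integer vector of overlap lengths.
#' @examples
#' intervalOverlapLength(10, 20, 17, 30)  # 4
#' @export
intervalOverlapLength <- function(aStart, aEnd, bStart, bEnd) {
  if (any(aStart > aEnd) || any(bStart > bEnd))
    stop("malformed interval: start > end")
  pmax(0L, pmin(aEnd, bEnd) - pmax(aStart, bStart) + 1L)
}

#' Repeat/domain overlap summary for one residue-domain pair
#'
#' Among proteins carrying both a run of `residue` and an instance of
#' `domainId`, counts those in which ANY (run, domain-instance) pair on the
#' protein overlaps by at least `minOverlap` residues.
#'
#' @param residue repeat residue letter.
#' @param domainId domain identifier.
#' @param repeats run table (protein_id, residue, start, end) as from
#'   [scanRepeats()] or [repeatTable()].
#' @param annotations domain annotations with coordinates
#'   ([readDomainAnnotations()]); instances of `domainId` lacking
#'   coordinates are dropped with a warning.
#' @param minOverlap minimum shared residues (default 4).
#' @return one-row data.frame: residue, domain_id, n_total, n_overlap,
#'   fraction (`NA` when n_total is 0).
#' @export
overlapSummary <- function(residue, domainId, repeats, annotations,
                           minOverlap = 4L) {
  stopifnot(minOverlap >= 1)
  reps <- repeats[repeats$residue == residue, , drop = FALSE]
  doms <- annotations[annotations$domain_id == domainId, , drop = FALSE]
  noCoord <- is.na(doms$start) | is.na(doms$end)
  if (any(noCoord)) {
    warning(sum(noCoord), " instance(s) of ", domainId,
            " lack coordinates and are ignored")
    doms <- doms[!noCoord, , drop = FALSE]
  }
  both <- intersect(unique(reps$protein_id), unique(doms$protein_id))
  nOver <- sum(vapply(both, function(p) {
    r <- reps[reps$protein_id == p, , drop = FALSE]
    d <- doms[doms$protein_id == p, , drop = FALSE]
    pair <- expand.grid(ri = seq_len(nrow(r)), di = seq_len(nrow(d)))
    any(intervalOverlapLength(r$start[pair$ri], r$end[pair$ri],
                              d$start[pair$di], d$end[pair$di]) >= minOverlap)
  }, logical(1)))
  data.frame(residue = residue, domain_id = domainId,
             n_total = length(both), n_overlap = nOver,
             fraction = if (length(both)) nOver / length(both) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Overlap analysis across residue-domain pairs
#'
#' By default summarizes only pairs flagged significant by the enrichment
#' step; `allPairs = TRUE` evaluates every residue-domain co-occurrence.
#' Each pair is labelled with the band of its overlap fraction:
#' `none` (0), `partial` (< 25 percent) or `25-100%`.
#'
#' @param repeats run table (see [overlapSummary()]).
#' @param annotations coordinate-bearing annotation table.
#' @param enrichment result of [enrichAllGroups()] (needed unless
#'   `allPairs = TRUE`).
#' @param groups named list of group member ids (used with
#'   `allPairs = TRUE` to enumerate co-occurrences); defaults to groups
#'   derived from `repeats`.
#' @param minOverlap minimum shared residues (default 4).
#' @param allPairs evaluate all co-occurring pairs instead of only the
#'   significant ones.
#' @return data.frame: residue, domain_id, n_total, n_overlap, fraction,
#'   band.
#' @export
overlapAnalysis <- function(repeats, annotations, enrichment = NULL,
                            minOverlap = 4L, allPairs = FALSE,
                            groups = NULL) {
  if (allPairs) {
    resDom <- unique(merge(unique(repeats[, c("protein_id", "residue")]),
                           unique(annotations[, c("protein_id", "domain_id")]),
                           by = "protein_id")[, c("residue", "domain_id")])
  } else {
    if (is.null(enrichment))
      stop("enrichment table required unless allPairs = TRUE")
    resDom <- unique(enrichment[enrichment$significant,
                                c("residue", "domain_id"), drop = FALSE])
  }
  if (!nrow(resDom))
    return(data.frame(residue = character(), domain_id = character(),
                      n_total = integer(), n_overlap = integer(),
                      fraction = numeric(), band = character(),
                      stringsAsFactors = FALSE))
  resDom <- resDom[order(resDom$residue, resDom$domain_id), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(resDom)), function(i)
    overlapSummary(resDom$residue[i], resDom$domain_id[i],
                   repeats, annotations, minOverlap)))
  out$band <- ifelse(is.na(out$fraction), NA_character_,
              ifelse(out$fraction == 0, "none",
              ifelse(out$fraction < 0.25, "partial", "25-100%")))
  rownames(out) <- NULL
  out
}
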