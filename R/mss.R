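#' Alignment coverage profile of a query against one subject
#'
#' Marks each query position `TRUE` when it is covered by at least one
#' [localAlign()] hit passing the identity and E-value thresholds. The
#' complement of this profile is the raw material for mitotype-specific
#' sequence detection.
#'
#' @param query,subject [MitoGenome-class] objects.
#' @param params an [alignParams()] (supplies the E-value cutoff).
#' @param identityMin minimal hit identity to count as coverage.
#' @return logical vector over query positions.
#' @export
coverageProfile <- function(query, subject, params = alignParams(),
                            identityMin = 0.90) {
  hits <- localAlign(query, subject, params)
  hits <- hits[hits$identity >= identityMin, , drop = FALSE]
  L <- if (is(query, "MitoGenome")) genomeLength(query) else nchar(query)
  covered <- logical(L)
  for (i in seq_len(nrow(hits)))
    covered[hits$qstart[i]:hits$qend[i]] <- TRUE
  covered
}

# Close FALSE gaps of length <= mergeGap inside a TRUE mask (the mask
# marks candidate-specific positions); wrap-aware when circular.
.closeGaps <- function(mask, mergeGap, circular) {
  if (!any(mask) || mergeGap <= 0L) return(mask)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inner <- which(!r$values & r$lengths <= mergeGap &
                 seq_along(r$values) > 1L &
                 seq_along(r$values) < length(r$values))
  for (i in inner) mask[starts[i]:ends[i]] <- TRUE
  if (circular && length(r$values) >= 2L) {
    # a gap split across the origin: leading FALSE run + trailing FALSE run
    lead <- if (!r$values[1L]) r$lengths[1L] else 0L
    trail <- if (!r$values[length(r$values)]) r$lengths[length(r$values)] else 0L
    if ((lead + trail) > 0L && (lead + trail) <= mergeGap &&
        any(mask)) {
      if (lead > 0L) mask[1:lead] <- TRUE
      if (trail > 0L) mask[(length(mask) - trail + 1L):length(mask)] <- TRUE
    }
  }
  mask
}

# Maximal TRUE runs of a mask as (start, end) intervals, merging the two
# origin-adjacent runs into one wrapping interval on circular genomes.
.maskIntervals <- function(mask, circular) {
  if (!any(mask)) return(data.frame(start = integer(), end = integer()))
  runs <- .trueRuns(mask)
  L <- length(mask)
  if (circular && nrow(runs) >= 2L && runs[1L, "start"] == 1L &&
      runs[nrow(runs), "end"] == L && !all(mask)) {
    wrapped <- data.frame(start = runs[nrow(runs), "start"],
                          end = runs[1L, "end"])
    mid <- runs[-c(1L, nrow(runs)), , drop = FALSE]
    return(rbind(data.frame(start = mid[, "start"], end = mid[, "end"]),
                 wrapped))
  }
  data.frame(start = runs[, "start"], end = runs[, "end"])
}

#' Detect mitotype-specific sequences against a genome panel
#'
#' A mitotype-specific sequence (MSS) is a segment of the query
#' mitogenome with no qualifying alignment in at least one genome of the
#' comparison panel (per-genome grey/white presence patterns; uniqueness
#' across all genomes is not required). Per panel genome a coverage
#' profile is computed with [coverageProfile()]; query runs uncovered in
#' at least one genome are merged across gaps of at most `mergeGap` bp,
#' runs shorter than `minMssLen` are dropped, and each surviving record's
#' presence vector is recomputed per genome: a genome carries the MSS
#' when its hits cover at least `presenceFrac` of the record length.
#' Copy numbers within the query are counted by self-alignment
#' (additional occurrences at `identityMin` covering at least
#' `presenceFrac` of the record, outside its own locus).
#'
#' @param query a [MitoGenome-class]; the genome screened for specific
#'   sequences.
#' @param panel list of [MitoGenome-class] comparison genomes.
#' @param params an [alignParams()].
#' @param minMssLen minimal MSS length in bp (default 100).
#' @param mergeGap close uncovered-run gaps up to this many bp (default 50).
#' @param presenceFrac coverage fraction at which a genome is scored as
#'   carrying the sequence (default 0.8).
#' @param identityMin minimal alignment identity for coverage (default 0.90).
#' @return an [MssSet-class]: records `M1..Mn` in query coordinate order
#'   plus the presence/absence matrix (query column first, all `TRUE`).
#' @seealso [findMssDuplicates()], [annotateMssOverlaps()], [cseDistance()]
#' @export
detectMss <- function(query, panel, params = alignParams(),
                      minMssLen = 100L, mergeGap = 50L,
                      presenceFrac = 0.8, identityMin = 0.90) {
  if (length(panel) == 0L) stop("panel must contain at least one genome")
  L <- genomeLength(query)
  circ <- isCircular(query)
  panelIds <- vapply(panel, genomeId, character(1))
  cov <- matrix(FALSE, nrow = L, ncol = length(panel),
                dimnames = list(NULL, panelIds))
  for (j in seq_along(panel))
    cov[, j] <- coverageProfile(query, panel[[j]], params, identityMin)
  specific <- rowSums(!cov) > 0L
  specific <- .closeGaps(specific, mergeGap, circ)
  iv <- .maskIntervals(specific, circ)
  if (nrow(iv)) {
    iv$length <- intervalLength(iv$start, iv$end, L)
    iv <- iv[iv$length >= minMssLen, , drop = FALSE]
  }
  if (nrow(iv) == 0L) {
    out <- .emptyMssSet(genomeId(query))
    out@params <- list(minMssLen = minMssLen, mergeGap = mergeGap,
                       presenceFrac = presenceFrac,
                       identityMin = identityMin)
    return(out)
  }
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  # presence per genome: covered fraction of the record >= presenceFrac
  pres <- matrix(TRUE, nrow = nrow(iv), ncol = length(panel) + 1L,
                 dimnames = list(NULL, c(genomeId(query), panelIds)))
  for (r in seq_len(nrow(iv))) {
    mask <- .intervalMask(iv$start[r], iv$end[r], L)
    for (j in seq_along(panel))
      pres[r, j + 1L] <- mean(cov[mask, j]) >= presenceFrac
  }
  keep <- !apply(pres[, -1L, drop = FALSE], 1L, all)
  iv <- iv[keep, , drop = FALSE]
  pres <- pres[keep, , drop = FALSE]
  if (nrow(iv) == 0L) {
    out <- .emptyMssSet(genomeId(query))
    out@params <- list(minMssLen = minMssLen, mergeGap = mergeGap,
                       presenceFrac = presenceFrac,
                       identityMin = identityMin)
    return(out)
  }
  iv$id <- sprintf("M%d", seq_len(nrow(iv)))
  rownames(pres) <- iv$id
  iv$copies <- vapply(seq_len(nrow(iv)), function(r)
    .countCopies(iv$start[r], iv$end[r], query, params, presenceFrac,
                 identityMin), integer(1))
  rec <- iv[c("id", "start", "end", "length", "copies")]
  rownames(rec) <- NULL
  new("MssSet", records = rec, presence = pres, query = genomeId(query),
      params = list(minMssLen = minMssLen, mergeGap = mergeGap,
                    presenceFrac = presenceFrac, identityMin = identityMin,
                    align = unclass(params)))
}

# Occurrence count of one MSS within the query genome itself. The genome
# is the alignment query so that copies at distinct loci survive the
# overlapping-hit pruning (their query spans are disjoint).
.countCopies <- function(start, end, query, params, presenceFrac,
                         identityMin) {
  L <- genomeLength(query)
  mssSeq <- .intervalSeq(genomeSeq(query), start, end)
  hits <- localAlign(query, mssSeq, params)
  hits <- hits[hits$identity >= identityMin &
               (hits$send - hits$sstart + 1L) >=
                 presenceFrac * nchar(mssSeq), , drop = FALSE]
  extra <- 0L
  for (i in seq_len(nrow(hits))) {
    if (!.intervalsOverlap(hits$qstart[i], hits$qend[i], start, end, L))
      extra <- extra + 1L
  }
  1L + extra
}

#' Subset MSS records with duplicate copies in the query
#'
#' @param mss an [MssSet-class] from [detectMss()].
#' @return the records `data.frame` restricted to `copies >= 2`.
#' @export
findMssDuplicates <- function(mss) {
  rec <- mssRecords(mss)
  rec[rec$copies >= 2L, , drop = FALSE]
}

#' Overlaps between ORFs and mitotype-specific sequences
#'
#' Wrap-aware overlap (at least one shared position) between each ORF and
#' each MSS interval on the same genome.
#'
#' @param orfs ORF table from [findOrfs()].
#' @param mss an [MssSet-class].
#' @param genomeLength length of the genome both sets live on.
#' @return named list mapping `orf_id` to a character vector of MSS ids
#'   (empty when disjoint from all).
#' @export
annotateMssOverlaps <- function(orfs, mss, genomeLength) {
  rec <- mssRecords(mss)
  out <- lapply(seq_len(nrow(orfs)), function(i) {
    hit <- vapply(seq_len(nrow(rec)), function(r)
      .intervalsOverlap(orfs$start[i], orfs$end[i],
                        rec$start[r], rec$end[r], genomeLength),
      logical(1))
    rec$id[hit]
  })
  names(out) <- orfs$orf_id
  out
}
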