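# Maximal-scoring run of alignment columns under +1 per identical column
# and -4 per mismatch/indel column (Kadane, leftmost-longest on ties).
# Similarity-score local alignment may drag low-identity flanks along;
# this trims the segment back to its high-identity core (runs below 80%
# identity cannot sustain a positive score at these weights).
.identityCore <- function(eq) {
  sc <- ifelse(eq, 1, -4)
  best <- 0; bestRange <- c(0L, 0L)
  cur <- 0; curStart <- 1L
  for (i in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[i]; curStart <- i }
    else cur <- cur + sc[i]
    if (cur > best ||
        (cur == best && bestRange[1L] > 0L &&
         i - curStart > bestRange[2L] - bestRange[1L])) {
      best <- cur; bestRange <- c(curStart, i)
    }
  }
  if (bestRange[1L] == 0L) NULL else bestRange
}

# Alignment column table for one local protein alignment, with absolute
# 1-based positions (0 = gap) and stats; columns are trimmed to the
# high-identity core.
.segmentFromLocal <- function(res, av, bv, alpha) {
  ai <- res$a_idx; bi <- res$b_idx
  if (length(ai) == 0L) return(NULL)
  aCh <- ifelse(ai > 0, alpha[av[pmax(ai, 1)]], "-")
  bCh <- ifelse(bi > 0, alpha[bv[pmax(bi, 1)]], "-")
  eq <- ai > 0 & bi > 0 & aCh == bCh & aCh != "X"
  core <- .identityCore(eq)
  if (is.null(core)) return(NULL)
  keep <- core[1L]:core[2L]
  ai <- ai[keep]; bi <- bi[keep]; aCh <- aCh[keep]; bCh <- bCh[keep]
  st <- .columnStats(ai, bi, aCh, bCh, ambig = "X")
  apos <- ai[ai > 0]; bpos <- bi[bi > 0]
  list(cand_start = min(apos), cand_end = max(apos),
       parent_start = min(bpos), parent_end = max(bpos),
       identity = st$matches / st$alnlen, matches = st$matches,
       insertions = st$insertions, deletions = st$deletions,
       score = res$score,
       columns = data.frame(cand_pos = ai, parent_pos = bi,
                            cand_char = aCh, parent_char = bCh,
                            stringsAsFactors = FALSE))
}

#' Decompose a candidate protein into parental segments
#'
#' Chimeric CMS proteins arise by mitochondrial recombination fusing
#' fragments of ancestral ORFs. This routine aligns each parental
#' protein locally (Smith-Waterman, BLOSUM62, affine gaps) to the
#' candidate — repeatedly, masking already-claimed candidate residues, so
#' one parent may contribute several segments — keeps segments reaching
#' `segmentMinIdentity` (identity = exact residue matches over aligned
#' columns, indel columns counting against), and then selects a small
#' set of segments covering as much of the candidate as possible
#' (greedy maximum-new-coverage; ties by identity-weighted length, then
#' lexicographic parent id, then position). Consecutive selected
#' segments may overlap on the candidate: that junction overlap is the
#' recombination-homology signature and is reported as is.
#'
#' @param candidate candidate protein sequence.
#' @param parents named character vector (or named list) of parental
#'   protein sequences.
#' @param segmentMinIdentity minimal segment identity (default 0.85, the
#'   conventional recombinant-screen threshold).
#' @param minSegLen minimal segment length in aligned candidate residues
#'   (default 20).
#' @param maxSegmentsPerParent repeated-masking depth per parent.
#' @param gapOpen,gapExtend affine gap costs for the protein DP.
#' @return object of class `chimeraDecomposition`: list with `segments`
#'   (`data.frame` ordered by `cand_start` with `parent_id`,
#'   `cand_start`, `cand_end`, `parent_start`, `parent_end`, `identity`,
#'   `insertions` (candidate-only columns), `deletions` (parent-only
#'   columns), `score`), `alignments` (per-segment column tables used by
#'   [liftDomains()]), `candidate_length`, and `covered` (candidate
#'   positions claimed). No parent reaching the threshold yields a
#'   zero-row decomposition with a message.
#' @export
decomposeChimera <- function(candidate, parents,
                             segmentMinIdentity = 0.85, minSegLen = 20L,
                             maxSegmentsPerParent = 3L, gapOpen = 11,
                             gapExtend = 1) {
  if (length(parents) < 1L) stop("at least one parent required")
  parents <- unlist(parents)
  if (is.null(names(parents)) || any(!nzchar(names(parents))))
    stop("parents must be named")
  sm <- .blosum62()
  alpha <- rownames(sm)
  maskCode <- match("#", alpha)
  av0 <- .encodeAA(candidate, alpha)
  n <- length(av0)
  cands <- list()
  for (pid in sort(names(parents))) {
    bv <- .encodeAA(parents[[pid]], alpha)
    av <- av0
    for (rep_i in seq_len(maxSegmentsPerParent)) {
      res <- .localAlignProtein(av, bv, sm, gapOpen, gapExtend)
      seg <- .segmentFromLocal(res, av0, bv, alpha)
      if (is.null(seg)) break
      segLen <- seg$cand_end - seg$cand_start + 1L
      if (segLen < minSegLen || seg$identity < segmentMinIdentity) break
      seg$parent_id <- pid
      cands[[length(cands) + 1L]] <- seg
      av[seg$cand_start:seg$cand_end] <- maskCode
    }
  }
  if (length(cands) == 0L) {
    message("no parental segment reaches identity ", segmentMinIdentity)
    return(structure(list(segments = data.frame(
      parent_id = character(), cand_start = integer(),
      cand_end = integer(), parent_start = integer(),
      parent_end = integer(), identity = numeric(),
      insertions = integer(), deletions = integer(), score = numeric(),
      stringsAsFactors = FALSE),
      alignments = list(), candidate_length = n, covered = logical(n)),
      class = "chimeraDecomposition"))
  }
  # greedy maximum-coverage selection
  covered <- logical(n)
  selected <- integer()
  repeat {
    bestI <- 0L; bestNew <- 0L; bestW <- -Inf
    for (i in setdiff(seq_along(cands), selected)) {
      s <- cands[[i]]
      newCov <- sum(!covered[s$cand_start:s$cand_end])
      w <- s$identity * (s$cand_end - s$cand_start + 1L)
      better <- newCov > bestNew ||
        (newCov == bestNew && newCov > 0L &&
         (w > bestW ||
          (w == bestW && (bestI == 0L ||
             s$parent_id < cands[[bestI]]$parent_id ||
             (s$parent_id == cands[[bestI]]$parent_id &&
              s$cand_start < cands[[bestI]]$cand_start)))))
      if (better) { bestI <- i; bestNew <- newCov; bestW <- w }
    }
    if (bestI == 0L || bestNew == 0L) break
    selected <- c(selected, bestI)
    s <- cands[[bestI]]
    covered[s$cand_start:s$cand_end] <- TRUE
  }
  sel <- cands[selected]
  o <- order(vapply(sel, function(s) as.numeric(s$cand_start), numeric(1)))
  sel <- sel[o]
  segments <- do.call(rbind, lapply(sel, function(s)
    data.frame(parent_id = s$parent_id, cand_start = s$cand_start,
               cand_end = s$cand_end, parent_start = s$parent_start,
               parent_end = s$parent_end, identity = s$identity,
               insertions = s$insertions, deletions = s$deletions,
               score = s$score, stringsAsFactors = FALSE)))
  rownames(segments) <- NULL
  structure(list(segments = segments,
                 alignments = lapply(sel, `[[`, "columns"),
                 candidate_length = n, covered = covered),
            class = "chimeraDecomposition")
}

#' @export
print.chimeraDecomposition <- function(x, ...) {
  cat(sprintf("Chimera decomposition: %d segment(s), %d/%d residues covered\n",
              nrow(x$segments), sum(x$covered), x$candidate_length))
  for (i in seq_len(nrow(x$segments))) {
    s <- x$segments[i, ]
    cat(sprintf("  %d-%d <- %s %d-%d (identity %.3f, ins %d, del %d)\n",
                s$cand_start, s$cand_end, s$parent_id, s$parent_start,
                s$parent_end, s$identity, s$insertions, s$deletions))
  }
  invisible(x)
}

#' Lift parental domain annotations onto a chimeric candidate
#'
#' Maps domain coordinates (e.g. COX11-interaction regions defined on
#' ancestral CMS ORFs) through the segment alignments column by column.
#' A domain annotated with the same `name` on several parents — the
#' chimeric-domain situation, where a region is assembled from two
#' parental proteins across the fusion junction — is merged into a
#' single row reporting every contributing parent. Domain parts falling
#' outside any aligned parent range are unmapped; a fully unmapped
#' domain is reported with `NA` candidate coordinates.
#'
#' @param decomp a `chimeraDecomposition` from [decomposeChimera()].
#' @param domains `data.frame` with columns `parent_id`, `name`,
#'   `start`, `end` (1-based aa positions on the parent).
#' @return `data.frame` with one row per domain `name`: `cand_start`,
#'   `cand_end` (NA when unmapped), `parents` (comma-separated
#'   contributing parents), `mapped_frac` (fraction of annotated parent
#'   residues that map).
#' @export
liftDomains <- function(decomp, domains) {
  need <- c("parent_id", "name", "start", "end")
  if (!all(need %in% names(domains)))
    stop("domains need columns parent_id, name, start, end")
  segs <- decomp$segments
  rows <- lapply(seq_len(nrow(domains)), function(i) {
    d <- domains[i, ]
    hit <- which(segs$parent_id == d$parent_id)
    candPos <- integer()
    total <- d$end - d$start + 1L
    for (si in hit) {
      cols <- decomp$alignments[[si]]
      sel <- cols$parent_pos >= d$start & cols$parent_pos <= d$end &
        cols$cand_pos > 0L & cols$parent_pos > 0L
      candPos <- c(candPos, cols$cand_pos[sel])
    }
    data.frame(name = d$name, parent_id = d$parent_id,
               cand_start = if (length(candPos)) min(candPos) else NA_integer_,
               cand_end = if (length(candPos)) max(candPos) else NA_integer_,
               mapped = length(unique(candPos)), total = total,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  out <- lapply(split(per, per$name), function(g) {
    mapped <- g[!is.na(g$cand_start), , drop = FALSE]
    data.frame(
      name = g$name[1],
      cand_start = if (nrow(mapped)) min(mapped$cand_start) else NA_integer_,
      cand_end = if (nrow(mapped)) max(mapped$cand_end) else NA_integer_,
      parents = paste(sort(unique(mapped$parent_id)), collapse = ","),
      mapped_frac = sum(g$mapped) / sum(g$total),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$name), , drop = FALSE]
}
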