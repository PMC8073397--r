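#' Alignment parameters
#'
#' Parameters for the seed-and-extend local nucleotide aligner and its
#' Karlin-Altschul E-values. Defaults follow the classic ungapped BLASTN
#' regime on near-identical mitogenomes: exact word seeds of 11 nt,
#' +1/-2 match/mismatch, gap open 5 / extend 2 (a gap of length g costs
#' `gapOpen + g * gapExtend`), and the published ungapped Karlin-Altschul
#' constants for +1/-2 (`lambda = 1.28`, `K = 0.46`) per raw-score unit.
#'
#' @param wordSize exact seed length in nt (>= 4).
#' @param match,mismatch match reward (> 0) and mismatch penalty (< 0).
#' @param gapOpen,gapExtend affine gap costs (positive).
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @param evalueMax report only hits with E-value at or below this.
#' @param xdrop ungapped extension stops when the running score falls
#'   this far below the best score seen (raw-score units).
#' @param band maximal diagonal drift allowed when chaining colinear
#'   ungapped blocks across an indel.
#' @param maxChainGap maximal unaligned stretch (bp, each sequence)
#'   bridged between chained blocks.
#' @param maxSeedOcc seeds whose word occurs more often than this in the
#'   subject are skipped (low-complexity guard).
#' @param refineLimit chained hits whose query x subject area is at most
#'   this many DP cells are re-aligned with full affine local DP.
#' @return classed list of validated parameters.
#' @examples
#' p <- alignParams()
#' p$wordSize
#' @export
alignParams <- function(wordSize = 11L, match = 1, mismatch = -2,
                        gapOpen = 5, gapExtend = 2, lambda = 1.28,
                        K = 0.46, evalueMax = 1e-5, xdrop = 20,
                        band = 32L, maxChainGap = 200L, maxSeedOcc = 40L,
                        refineLimit = 1.1e6) {
  stopifnot(wordSize >= 4, match > 0, mismatch < 0, gapOpen >= 0,
            gapExtend > 0, lambda > 0, K > 0, evalueMax > 0, xdrop > 0,
            band >= 1, maxChainGap >= 0)
  structure(list(wordSize = as.integer(wordSize), match = match,
                 mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend, lambda = lambda, K = K,
                 evalueMax = evalueMax, xdrop = xdrop,
                 band = as.integer(band),
                 maxChainGap = as.integer(maxChainGap),
                 maxSeedOcc = as.integer(maxSeedOcc),
                 refineLimit = refineLimit),
            class = "alignParams")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of distinct
#' local alignments of at least this raw score between random sequences
#' of lengths `m` and `n`. Strictly decreasing in `score`, linear in each
#' sequence length.
#'
#' @param rawScore raw alignment score (vectorized).
#' @param m,n query and subject lengths (>= 1).
#' @param params an [alignParams()] object supplying `lambda` and `K`.
#' @return numeric E-value(s).
#' @examples
#' alignEvalue(0, 1000, 1000, alignParams())  # K * m * n = 460000
#' @export
alignEvalue <- function(rawScore, m, n, params = alignParams()) {
  stopifnot(m >= 1, n >= 1)
  params$K * m * n * exp(-params$lambda * rawScore)
}

## ---- internal encodings -------------------------------------------------

.NUC <- c("A", "C", "G", "T", "N")

.nucSubmat <- function(match, mismatch) {
  sm <- matrix(mismatch, 5, 5, dimnames = list(.NUC, .NUC))
  diag(sm) <- match
  sm["N", ] <- mismatch  # N never matches, not even N vs N
  sm[, "N"] <- mismatch
  sm
}

.encodeNuc <- function(x) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], .NUC)
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T,N}")
  v
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      # append a masking letter that nothing may align to
      m <- rbind(cbind(m, `#` = -1000), `#` = c(rep(-1000, ncol(m)), -1000))
      cache <<- m
    }
    cache
  }
})

.encodeAA <- function(x, alphabet) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(v)) stop("sequence contains characters outside the protein ",
                     "alphabet: ", x)
  v
}

# Summarise DP columns (1-based a_idx/b_idx, 0 = gap) into counts.
# ambig: the alphabet's ambiguity letter, which never counts as a match
# ("N" for nucleotides, "X" for proteins).
.columnStats <- function(aIdx, bIdx, aChars, bChars, ambig = "N") {
  gapA <- aIdx == 0L
  gapB <- bIdx == 0L
  both <- !gapA & !gapB
  eq <- both & aChars == bChars & aChars != ambig
  gapcol <- gapA | gapB
  gapopens <- sum(diff(c(FALSE, gapcol)) == 1L)
  list(alnlen = length(aIdx), matches = sum(eq),
       mismatches = sum(both) - sum(eq),
       insertions = sum(gapB),   # a-only columns
       deletions = sum(gapA),    # b-only columns
       gapopens = gapopens)
}

## ---- local nucleotide alignment ----------------------------------------

# Exact shared words between query and subject, as (qpos, spos) pairs
# sorted by (diagonal, spos). Words containing N are skipped.
.kmerSeeds <- function(qseq, sseq, k, maxOcc) {
  m <- nchar(qseq); n <- nchar(sseq)
  if (m < k || n < k)
    return(data.frame(qpos = integer(), spos = integer()))
  qp <- seq_len(m - k + 1L)
  sp <- seq_len(n - k + 1L)
  qk <- substring(qseq, qp, qp + k - 1L)
  sk <- substring(sseq, sp, sp + k - 1L)
  qok <- !grepl("N", qk, fixed = TRUE)
  sok <- !grepl("N", sk, fixed = TRUE)
  tab <- split(sp[sok], sk[sok])
  tab <- tab[lengths(tab) <= maxOcc]
  hitlist <- tab[qk[qok]]
  nhit <- lengths(hitlist)
  qpos <- rep(qp[qok], nhit)
  spos <- unlist(hitlist, use.names = FALSE)
  if (length(qpos) == 0L)
    return(data.frame(qpos = integer(), spos = integer()))
  o <- order(qpos - spos, spos, method = "radix")
  data.frame(qpos = qpos[o], spos = spos[o])
}

# Greedy colinear chaining of ungapped blocks (rows of the matrix from
# cpp_ungapped_extend). Returns a list of integer index vectors. Chains
# whose tail ends too far left of the sweep position can never accept a
# later block (blocks arrive in qstart order) and are retired, keeping
# the active set small.
.chainBlocks <- function(bl, band, maxChainGap) {
  o <- order(bl[, "qstart"], bl[, "sstart"])
  tails <- integer(0)        # row index of each active chain's last block
  chainIds <- integer(0)
  chains <- list()
  for (i in o) {
    qs <- bl[i, "qstart"]; ss <- bl[i, "sstart"]
    live <- bl[tails, "qend"] >= qs - maxChainGap - 1L
    tails <- tails[live]; chainIds <- chainIds[live]
    bestc <- 0L; bestend <- -Inf
    for (ci in seq_along(tails)) {
      t <- tails[ci]
      qgap <- qs - bl[t, "qend"] - 1L
      sgap <- ss - bl[t, "send"] - 1L
      if (qgap >= -50 && qgap <= maxChainGap && sgap >= -50 &&
          sgap <= maxChainGap && abs(qgap - sgap) <= band &&
          bl[t, "qend"] > bestend) {
        bestc <- ci; bestend <- bl[t, "qend"]
      }
    }
    if (bestc > 0L) {
      id <- chainIds[bestc]
      chains[[id]] <- c(chains[[id]], i)
      tails[bestc] <- i
    } else {
      chains[[length(chains) + 1L]] <- i
      tails <- c(tails, i)
      chainIds <- c(chainIds, length(chains))
    }
  }
  chains
}

# Count matches between q[qs..qe] and the same-length s window (ungapped).
.ungappedMatches <- function(qv, sv, qs, qe, ss) {
  if (qe < qs) return(0L)
  a <- qv[qs:qe]; b <- sv[ss:(ss + (qe - qs))]
  sum(a == b & a != 5L)
}

# Evaluate one chain into a single hit record (list of stats).
.chainToHit <- function(chain, bl, qv, sv, qseq, sseq, params) {
  qs0 <- bl[chain[1], "qstart"]; qe0 <- bl[chain[length(chain)], "qend"]
  ss0 <- bl[chain[1], "sstart"]; se0 <- bl[chain[length(chain)], "send"]
  # pad the region so the DP may extend past the X-drop extents
  pad <- params$maxChainGap
  qs <- max(1L, qs0 - pad); qe <- min(length(qv), qe0 + pad)
  ss <- max(1L, ss0 - pad); se <- min(length(sv), se0 + pad)
  qlen <- qe - qs + 1; slen <- se - ss + 1
  if (qlen * slen <= params$refineLimit) {
    # full affine local DP over the chained region
    sm <- .nucSubmat(params$match, params$mismatch)
    res <- cpp_align_affine(qv[qs:qe], sv[ss:se], sm,
                           params$gapOpen, params$gapExtend, TRUE)
    ai <- res$a_idx; bi <- res$b_idx
    if (length(ai) == 0L) return(NULL)
    aCh <- ifelse(ai > 0, .NUC[qv[qs:qe][pmax(ai, 1)]], "-")
    bCh <- ifelse(bi > 0, .NUC[sv[ss:se][pmax(bi, 1)]], "-")
    st <- .columnStats(ai, bi, aCh, bCh)
    apos <- ai[ai > 0]; bpos <- bi[bi > 0]
    return(list(qstart = qs + min(apos) - 1, qend = qs + max(apos) - 1,
                sstart = ss + min(bpos) - 1, send = ss + max(bpos) - 1,
                score = res$score, matches = st$matches,
                mismatches = st$mismatches, gapopens = st$gapopens,
                alnlen = st$alnlen))
  }
  if (length(chain) == 1L) {
    b <- bl[chain, ]
    alnlen <- b[["qend"]] - b[["qstart"]] + 1
    return(list(qstart = b[["qstart"]], qend = b[["qend"]],
                sstart = b[["sstart"]], send = b[["send"]],
                score = b[["score"]], matches = b[["matches"]],
                mismatches = alnlen - b[["matches"]], gapopens = 0,
                alnlen = alnlen))
  }
  # block-sum path: trim block overlaps, align small gap regions exactly
  blocks <- lapply(chain, function(i) as.list(bl[i, ]))
  score <- 0; matches <- 0; mismatches <- 0; gapopens <- 0; alnlen <- 0
  prev <- NULL
  sm <- .nucSubmat(params$match, params$mismatch)
  for (b in blocks) {
    if (!is.null(prev)) {
      trim <- max(prev$qend - b$qstart + 1, prev$send - b$sstart + 1, 0)
      if (trim > 0) {
        lost <- .ungappedMatches(qv, sv, b$qstart, b$qstart + trim - 1,
                                 b$sstart)
        b$qstart <- b$qstart + trim; b$sstart <- b$sstart + trim
        b$matches <- b$matches - lost
        b$score <- b$score - lost * params$match -
          (trim - lost) * params$mismatch
        if (b$qstart > b$qend) { next }
      }
      qgap <- b$qstart - prev$qend - 1
      sgap <- b$sstart - prev$send - 1
      if (qgap > 0 && sgap > 0) {
        g <- cpp_align_affine(qv[(prev$qend + 1):(b$qstart - 1)],
                              sv[(prev$send + 1):(b$sstart - 1)], sm,
                              params$gapOpen, params$gapExtend, FALSE)
        ai <- g$a_idx; bi <- g$b_idx
        aCh <- ifelse(ai > 0, .NUC[qv[(prev$qend + 1):(b$qstart - 1)][pmax(ai, 1)]], "-")
        bCh <- ifelse(bi > 0, .NUC[sv[(prev$send + 1):(b$sstart - 1)][pmax(bi, 1)]], "-")
        st <- .columnStats(ai, bi, aCh, bCh)
        score <- score + g$score
        matches <- matches + st$matches
        mismatches <- mismatches + st$mismatches
        gapopens <- gapopens + st$gapopens
        alnlen <- alnlen + st$alnlen
      } else if (qgap > 0 || sgap > 0) {
        glen <- max(qgap, sgap)
        score <- score - (params$gapOpen + glen * params$gapExtend)
        gapopens <- gapopens + 1
        alnlen <- alnlen + glen
      }
    }
    blen <- b$qend - b$qstart + 1
    score <- score + b$score
    matches <- matches + b$matches
    mismatches <- mismatches + (blen - b$matches)
    alnlen <- alnlen + blen
    prev <- b
  }
  list(qstart = qs0, qend = qe0, sstart = ss0, send = se0, score = score,
       matches = matches, mismatches = mismatches, gapopens = gapopens,
       alnlen = alnlen)
}

.emptyHits <- function() {
  data.frame(qid = character(), sid = character(), strand = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), length = integer(), matches = integer(),
             mismatches = integer(), gapopens = integer(),
             identity = numeric(), score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Seed-and-extend local nucleotide alignment
#'
#' Finds local alignments between a query and a subject genome on both
#' strands: exact shared words seed ungapped X-drop extensions, colinear
#' blocks are chained across small indels (affine DP over the gap
#' regions; chains of moderate size are re-aligned with full affine
#' local DP), and hits are assigned Karlin-Altschul E-values. Only hits
#' with `evalue <= params$evalueMax` are returned. Overlapping hits are
#' pruned: a hit is kept only if less than half of its query span is
#' covered by higher-scoring hits. Circular genomes are aligned in their
#' linearized form, so homology spanning an origin appears as two hits.
#'
#' @param query,subject [MitoGenome-class] objects or nucleotide strings.
#' @param params an [alignParams()] object.
#' @return `data.frame` of hits sorted by `qstart` with columns `qid`,
#'   `sid`, `strand` (+1/-1), `qstart`, `qend`, `sstart`, `send` (subject
#'   forward-strand coordinates, `sstart <= send`), `length` (alignment
#'   columns), `matches`, `mismatches`, `gapopens`, `identity`
#'   (matches / columns), `score`, `evalue`. A query shorter than the
#'   word size yields an empty frame.
#' @seealso [alignEvalue()], [writeHitsTable()]
#' @export
localAlign <- function(query, subject, params = alignParams()) {
  qid <- if (is(query, "MitoGenome")) genomeId(query) else "query"
  sid <- if (is(subject, "MitoGenome")) genomeId(subject) else "subject"
  qseq <- if (is(query, "MitoGenome")) genomeSeq(query) else toupper(query)
  sseq <- if (is(subject, "MitoGenome")) genomeSeq(subject) else toupper(subject)
  if (!nzchar(qseq) || !nzchar(sseq)) stop("empty sequence")
  m <- nchar(qseq); n <- nchar(sseq)
  if (m < params$wordSize) return(.emptyHits())
  qv <- .encodeNuc(qseq)
  hits <- list()
  for (strand in c(1L, -1L)) {
    s2 <- if (strand == 1L) sseq else revComp(sseq)
    seeds <- .kmerSeeds(qseq, s2, params$wordSize, params$maxSeedOcc)
    if (nrow(seeds) == 0L) next
    bl <- cpp_ungapped_extend(qseq, s2, seeds$qpos, seeds$spos,
                              params$wordSize, params$match,
                              params$mismatch, params$xdrop)
    if (nrow(bl) == 0L) next
    # drop blocks far below the single-hit significance score: chance
    # word matches, which would only bloat chaining; any real homology
    # they sat in is bridged by the gap DP between retained blocks
    sig <- log(params$K * m * as.numeric(n) / params$evalueMax) /
      params$lambda
    bl <- bl[bl[, "score"] >= 0.5 * sig, , drop = FALSE]
    if (nrow(bl) == 0L) next
    sv <- .encodeNuc(s2)
    chains <- .chainBlocks(bl, params$band, params$maxChainGap)
    for (ch in chains) {
      h <- .chainToHit(ch, bl, qv, sv, qseq, s2, params)
      if (is.null(h)) next
      if (strand == -1L) {
        tmp <- h$sstart
        h$sstart <- n - h$send + 1L
        h$send <- n - tmp + 1L
      }
      h$strand <- strand
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0L) return(.emptyHits())
  df <- do.call(rbind, lapply(hits, function(h)
    data.frame(qid = qid, sid = sid, strand = h$strand,
               qstart = as.integer(h$qstart), qend = as.integer(h$qend),
               sstart = as.integer(h$sstart), send = as.integer(h$send),
               length = as.integer(h$alnlen),
               matches = as.integer(h$matches),
               mismatches = as.integer(h$mismatches),
               gapopens = as.integer(h$gapopens),
               identity = h$matches / h$alnlen, score = h$score,
               stringsAsFactors = FALSE)))
  df$evalue <- alignEvalue(df$score, m, n, params)
  df <- df[df$evalue <= params$evalueMax, , drop = FALSE]
  if (nrow(df) == 0L) return(.emptyHits())
  # containment pruning: keep a hit only if < 50% of its query span is
  # already covered by higher-scoring hits
  o <- order(-df$score, df$qstart, df$sstart)
  covered <- logical(m)
  keep <- logical(nrow(df))
  for (i in o) {
    span <- df$qstart[i]:df$qend[i]
    if (mean(covered[span]) < 0.5) {
      keep[i] <- TRUE
      covered[span] <- TRUE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$qstart, df$sstart), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write alignment hits as a BLAST-outfmt6-style table
#'
#' Column order mirrors BLAST tabular output (with the raw score in place
#' of a bit score): qid, sid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, score. For minus-strand hits `sstart >
#' send`, following the BLAST convention.
#'
#' @param hits a hit frame from [localAlign()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeHitsTable <- function(hits, path) {
  out <- data.frame(qid = hits$qid, sid = hits$sid,
                    pident = round(100 * hits$identity, 3),
                    length = hits$length, mismatch = hits$mismatches,
                    gapopen = hits$gapopens, qstart = hits$qstart,
                    qend = hits$qend,
                    sstart = ifelse(hits$strand == 1L, hits$sstart,
                                    hits$send),
                    send = ifelse(hits$strand == 1L, hits$send,
                                  hits$sstart),
                    evalue = hits$evalue, score = hits$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

## ---- global protein alignment ------------------------------------------

#' Global protein alignment with affine gaps
#'
#' Optimal Needleman-Wunsch alignment of two protein sequences under an
#' affine gap model (a gap of length g costs `gapOpen + g * gapExtend`;
#' end gaps are penalized). Traceback ties are broken deterministically:
#' diagonal over up (gap in `b`) over left (gap in `a`). Column labels
#' distinguish matches, mismatches and indels; `X` never counts as a
#' match.
#'
#' @param a,b protein sequences over the 20 residues plus `X`.
#' @param substitutionMatrix name of a Biostrings scoring matrix
#'   (default `"BLOSUM62"`) or a numeric matrix with residue dimnames.
#' @param gapOpen,gapExtend affine gap costs (positive).
#' @return list with `score`, `columns` (`data.frame` of `a_pos`,
#'   `b_pos` (0 = gap), `a_char`, `b_char`, `type` in
#'   `match/mismatch/gap_a/gap_b`), `identity` (matches / columns),
#'   `matches`, `insertions` (`a`-only columns), `deletions` (`b`-only
#'   columns), `gapopens`, and the two padded `alignment` strings.
#' @examples
#' globalAlignProtein("MKLV", "MKV")$identity
#' @export
globalAlignProtein <- function(a, b, substitutionMatrix = "BLOSUM62",
                               gapOpen = 10, gapExtend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  sm <- if (is.character(substitutionMatrix)) {
    if (substitutionMatrix != "BLOSUM62")
      stop("only BLOSUM62 is shipped; pass a matrix for other schemes")
    .blosum62()
  } else substitutionMatrix
  alpha <- rownames(sm)
  av <- .encodeAA(a, alpha); bv <- .encodeAA(b, alpha)
  res <- cpp_align_affine(av, bv, sm, gapOpen, gapExtend, FALSE)
  ai <- res$a_idx; bi <- res$b_idx
  aCh <- ifelse(ai > 0, alpha[av[pmax(ai, 1)]], "-")
  bCh <- ifelse(bi > 0, alpha[bv[pmax(bi, 1)]], "-")
  type <- ifelse(ai == 0, "gap_a",
          ifelse(bi == 0, "gap_b",
          ifelse(aCh == bCh & aCh != "X", "match", "mismatch")))
  st <- .columnStats(ai, bi, aCh, bCh, ambig = "X")
  list(score = res$score,
       columns = data.frame(a_pos = ai, b_pos = bi, a_char = aCh,
                            b_char = bCh, type = type,
                            stringsAsFactors = FALSE),
       identity = st$matches / st$alnlen, matches = st$matches,
       insertions = st$insertions, deletions = st$deletions,
       gapopens = st$gapopens,
       alignment = c(a = paste(aCh, collapse = ""),
                     b = paste(bCh, collapse = "")))
}

# Internal: best local protein alignment (Smith-Waterman, affine).
.localAlignProtein <- function(av, bv, sm, gapOpen, gapExtend) {
  cpp_align_affine(av, bv, sm, gapOpen, gapExtend, TRUE)
}
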