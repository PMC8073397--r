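# Candidate diagonals between x and y: offsets j - i (0-based) at which
# some word of length k occurs in both. Words containing N are skipped,
# words occurring more than maxOcc times in either sequence are skipped
# (they would be rediscovered through flanking words of the same run).
.sharedOffsets <- function(x, y, k, maxOcc = 60L, selfSame = FALSE) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx < k || ny < k) return(integer())
  xp <- seq_len(nx - k + 1L)
  xk <- substring(x, xp, xp + k - 1L)
  ok <- !grepl("N", xk, fixed = TRUE)
  if (selfSame) {
    tab <- split(xp[ok], xk[ok])
    tab <- tab[lengths(tab) >= 2L & lengths(tab) <= maxOcc]
    offs <- unlist(lapply(tab, function(p) {
      pr <- utils::combn(p, 2L)
      pr[2L, ] - pr[1L, ]
    }), use.names = FALSE)
  } else {
    yp <- seq_len(ny - k + 1L)
    yk <- substring(y, yp, yp + k - 1L)
    okY <- !grepl("N", yk, fixed = TRUE)
    tabX <- split(xp[ok], xk[ok])
    tabX <- tabX[lengths(tabX) <= maxOcc]
    tabY <- split(yp[okY], yk[okY])
    tabY <- tabY[lengths(tabY) <= maxOcc]
    common <- intersect(names(tabX), names(tabY))
    offs <- unlist(lapply(common, function(w)
      as.vector(outer(tabY[[w]], tabX[[w]], "-"))), use.names = FALSE)
  }
  unique(offs)
}

#' Maximal exact repeats in a (circular) genome
#'
#' Finds all pairs of identical — or, for inverted repeats,
#' reverse-complement identical — substrings of at least `minRepeatLen`
#' bp that cannot be extended on either side (maximal exact repeated
#' pairs). Implementation: word anchoring picks candidate diagonals,
#' which are then swept exactly for maximal equal runs; circular genomes
#' are scanned on the doubled sequence and deduplicated, so repeats
#' crossing the origin are found. `N` never matches. A family of `c`
#' copies yields `choose(c, 2)` pairs; pairs sharing (near-)identical
#' loci are additionally grouped into families, so both counting
#' conventions are available. Self-overlapping tandem pairs are kept and
#' flagged.
#'
#' @param genome a [MitoGenome-class] or nucleotide string (then treated
#'   as circular).
#' @param minRepeatLen minimal repeat length in bp (default 1000; large
#'   repeats in plant mitogenomes are conventionally those > 1 kb).
#' @param includeInverted also search the reverse-complement orientation.
#' @param k anchoring word length (default 31).
#' @return `data.frame` with one row per maximal pair: `start_a`,
#'   `end_a`, `start_b`, `end_b` (1-based inclusive, canonical ordering
#'   `start_a < start_b`; intervals may wrap), `length`, `orientation`
#'   (`direct`/`inverted`), `tandem_overlap` (loci share positions),
#'   `family` (integer id grouping pairs that share a locus).
#' @export
findRepeats <- function(genome, minRepeatLen = 1000L,
                        includeInverted = TRUE, k = 31L) {
  if (!is(genome, "MitoGenome")) genome <- mitoGenome("genome", genome)
  S <- genomeSeq(genome)
  L <- nchar(S)
  circ <- isCircular(genome)
  D <- if (circ) paste0(S, S) else S
  nD <- nchar(D)
  pairs <- list()
  addPair <- function(ga, gb, len, orientation) {
    # canonical genomic starts in 1..L; order by start
    if (gb < ga || (gb == ga && orientation == "inverted")) {
      tmp <- ga; ga <- gb; gb <- tmp
    }
    key <- paste(ga, gb, len, orientation, sep = "/")
    if (!is.null(pairs[[key]])) return(invisible())
    ea <- ((ga + len - 2L) %% L) + 1L
    eb <- ((gb + len - 2L) %% L) + 1L
    pairs[[key]] <<- data.frame(
      start_a = ga, end_a = ea, start_b = gb, end_b = eb, length = len,
      orientation = orientation,
      tandem_overlap = .intervalsOverlap(ga, ea, gb, eb, L),
      stringsAsFactors = FALSE)
    invisible()
  }
  canon <- function(p) if (circ) ((p - 1L) %% L) + 1L else p

  # direct repeats: maximal equal runs between D and D shifted by off.
  # On circular genomes a run truncated at the doubled-sequence boundary
  # is dropped: the same pair recurs untruncated at an echo placement.
  for (off in .sharedOffsets(D, D, k, selfSame = TRUE)) {
    if (circ && off %% L == 0L) next  # the trivial circular identity
    runs <- cpp_diag_runs(D, D, off, minRepeatLen)
    sweepLo <- max(1L, 1L - off); sweepHi <- min(nD, nD - off)
    for (r in seq_len(nrow(runs))) {
      a <- runs[r, "start"]; len <- runs[r, "len"]
      if (circ && (a == sweepLo || a + len - 1L == sweepHi)) next
      if (len > L) len <- L          # cannot exceed one full monomer
      addPair(canon(a), canon(a + off), len, "direct")
    }
  }

  if (includeInverted) {
    Y <- revComp(D)
    for (off in .sharedOffsets(D, Y, k)) {
      runs <- cpp_diag_runs(D, Y, off, minRepeatLen)
      sweepLo <- max(1L, 1L - off); sweepHi <- min(nD, nD - off)
      for (r in seq_len(nrow(runs))) {
        a <- runs[r, "start"]; len <- runs[r, "len"]
        if (circ && (a == sweepLo || a + len - 1L == sweepHi)) next
        if (len > L) len <- L
        # y-run start c (1-based) maps back to D: b = nD - (c+len-1) + 1
        cc <- a + off
        b <- nD - (cc + len - 1L) + 1L
        ga <- canon(a); gb <- canon(b)
        if (ga == gb) next           # a self-palindrome, not a pair
        addPair(ga, gb, len, "inverted")
      }
    }
  }

  if (length(pairs) == 0L)
    return(data.frame(start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      length = integer(), orientation = character(),
                      tandem_overlap = logical(), family = integer(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, unname(pairs))
  # drop doubled-sequence echoes: same unordered locus pair kept once
  keyA <- paste(df$start_a, df$length)
  keyB <- paste(df$start_b, df$length)
  df <- df[!duplicated(paste(pmin(keyA, keyB), pmax(keyA, keyB),
                             df$orientation)), , drop = FALSE]
  df <- df[order(df$start_a, df$start_b, -df$length), , drop = FALSE]
  rownames(df) <- NULL
  df$family <- .repeatFamilies(df, L)
  df
}

# Group pairs into families: union-find over loci; two pairs share a
# family when a locus of one reciprocally overlaps (>= 80%) a locus of
# the other.
.repeatFamilies <- function(df, L) {
  n <- nrow(df)
  if (n == 0L) return(integer())
  loci <- rbind(
    data.frame(pair = seq_len(n), start = df$start_a, end = df$end_a,
               len = df$length),
    data.frame(pair = seq_len(n), start = df$start_b, end = df$end_b,
               len = df$length))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  m <- nrow(loci)
  for (i in seq_len(m)) for (j in seq_len(i - 1L)) {
    if (loci$pair[i] == loci$pair[j]) next
    ov <- .overlapLength(loci$start[i], loci$end[i], loci$start[j],
                         loci$end[j], L)
    if (ov >= 0.8 * max(loci$len[i], loci$len[j]))
      union(loci$pair[i], loci$pair[j])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Wrap-aware overlap length between two intervals.
.overlapLength <- function(s1, e1, s2, e2, L) {
  tot <- 0L
  for (a in .linearPieces(s1, e1, L))
    for (b in .linearPieces(s2, e2, L)) {
      lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
      if (hi >= lo) tot <- tot + (hi - lo + 1L)
    }
  tot
}
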