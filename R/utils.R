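# Internal helpers: wrap-aware interval arithmetic and misc utilities.
# External coordinates are 1-based inclusive; a wrapping interval on a
# circular genome of length L has end < start and length (L-start+1)+end.

#' Length of a (possibly wrapping) interval
#'
#' @param start,end 1-based inclusive endpoints; `end < start` denotes an
#'   interval wrapping the origin of a circular genome.
#' @param L genome length (required for wrapping intervals).
#' @return integer length in bp.
#' @examples
#' intervalLength(259955, 260893)        # 939
#' intervalLength(10, 3, L = 12)         # wraps: 3 + 3
#' @export
intervalLength <- function(start, end, L = NA_integer_) {
  wrap <- end < start
  if (any(wrap) && any(is.na(L)))
    stop("genome length L required for wrapping intervals")
  ifelse(wrap, (L - start + 1L) + end, end - start + 1L)
}

# Decompose an interval into 1 or 2 linear pieces (each a c(start, end)).
.linearPieces <- function(start, end, L) {
  if (end >= start) list(c(start, end))
  else list(c(start, L), c(1L, end))
}

# Wrap-aware position membership: logical vector over 1..L.
.intervalMask <- function(start, end, L) {
  mask <- logical(L)
  for (p in .linearPieces(start, end, L)) mask[p[1]:p[2]] <- TRUE
  mask
}

# Wrap-aware overlap (>= 1 shared position) between two intervals on a
# genome of length L.
.intervalsOverlap <- function(s1, e1, s2, e2, L) {
  for (a in .linearPieces(s1, e1, L))
    for (b in .linearPieces(s2, e2, L))
      if (a[1] <= b[2] && b[1] <= a[2]) return(TRUE)
  FALSE
}

# Extract the sequence of a (possibly wrapping) interval.
.intervalSeq <- function(seq, start, end) {
  L <- nchar(seq)
  paste(vapply(.linearPieces(start, end, L),
               function(p) substr(seq, p[1], p[2]), character(1)),
        collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' `N` complements to `N`.
#' @param x nucleotide string over `A,C,G,T,N`.
#' @return reverse-complemented string.
#' @examples revComp("ACGTN")
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Maximal runs of TRUE in a logical vector, as a matrix (start, end).
.trueRuns <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
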