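#' MitoGenome: a (possibly circular) mitochondrial genome sequence
#'
#' Container for one assembled mitochondrial genome. The sequence is an
#' uppercase nucleotide string over `A,C,G,T,N`; circular genomes are
#' stored linearized at an arbitrary origin, and all interval arithmetic
#' in the package honours wrap-around.
#'
#' @slot id single character identifier.
#' @slot seq uppercase nucleotide string over `A,C,G,T,N`.
#' @slot circular logical; `TRUE` for a circular molecule.
#'
#' @seealso [mitoGenome()], [readGenomeFasta()]
#' @exportClass MitoGenome
setClass("MitoGenome",
  representation(id = "character", seq = "character", circular = "logical")
)

setValidity("MitoGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) != 1L || is.na(object@seq) || !nzchar(object@seq))
    msg <- c(msg, "'seq' must be a single non-empty string")
  else if (grepl("[^ACGTN]", object@seq))
    msg <- c(msg, "'seq' contains characters outside {A,C,G,T,N}")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a MitoGenome
#'
#' @param id genome identifier.
#' @param seq nucleotide string; uppercased, with `U` converted to `T`.
#' @param circular logical; is the molecule circular?
#' @return A [MitoGenome-class] object.
#' @examples
#' g <- mitoGenome("toy", "acgtACGT", circular = FALSE)
#' genomeLength(g)
#' @export
mitoGenome <- function(id, seq, circular = TRUE) {
  seq <- chartr("u", "t", toupper(as.character(seq)))
  seq <- chartr("U", "T", seq)
  new("MitoGenome", id = as.character(id), seq = seq,
      circular = as.logical(circular))
}

#' @describeIn mitoGenome genome identifier accessor
#' @param x a `MitoGenome`.
#' @export
genomeId <- function(x) x@id

#' @describeIn mitoGenome sequence accessor (character scalar)
#' @export
genomeSeq <- function(x) x@seq

#' @describeIn mitoGenome sequence length in bp
#' @export
genomeLength <- function(x) nchar(x@seq)

#' @describeIn mitoGenome is the molecule circular?
#' @export
isCircular <- function(x) x@circular

setMethod("show", "MitoGenome", function(object) {
  cat(sprintf("MitoGenome '%s': %d bp, %s\n", object@id,
              nchar(object@seq),
              if (object@circular) "circular" else "linear"))
})

#' MssSet: mitotype-specific sequences of a query genome
#'
#' Result container for [detectMss()]: the MSS intervals on the query
#' genome (with copy counts from self-alignment) and the presence/absence
#' matrix of every MSS over the query plus the comparison panel.
#'
#' @slot records `data.frame` with columns `id` (M1..Mn in coordinate
#'   order), `start`, `end` (1-based inclusive; `end < start` marks a
#'   wrapping interval), `length`, `copies`.
#' @slot presence logical matrix, rows = MSS ids, columns = genome ids
#'   (query first); `TRUE` = the genome carries the sequence.
#' @slot query id of the query genome.
#' @slot params list of detection parameters.
#'
#' @seealso [detectMss()], [mssRecords()], [presenceMatrix()]
#' @exportClass MssSet
setClass("MssSet",
  representation(records = "data.frame", presence = "matrix",
                 query = "character", params = "list")
)

setValidity("MssSet", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("id", "start", "end", "length", "copies")
  if (!all(need %in% names(rec)))
    msg <- c(msg, "records must have columns id, start, end, length, copies")
  if (nrow(rec) != nrow(object@presence))
    msg <- c(msg, "records and presence row counts differ")
  if (nrow(object@presence) > 0) {
    if (!identical(rownames(object@presence), rec$id))
      msg <- c(msg, "presence rownames must equal record ids")
    qcol <- match(object@query, colnames(object@presence))
    if (is.na(qcol)) msg <- c(msg, "query column missing from presence matrix")
    else if (!all(object@presence[, qcol]))
      msg <- c(msg, "query column of presence matrix must be all TRUE")
    if (any(apply(object@presence, 1L, all) & ncol(object@presence) > 1))
      msg <- c(msg, "an all-TRUE presence row is not mitotype-specific")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn MssSet-class MSS records table accessor
#' @param x an `MssSet`.
#' @export
mssRecords <- function(x) x@records

#' @describeIn MssSet-class presence/absence matrix accessor
#' @export
presenceMatrix <- function(x) x@presence

setMethod("show", "MssSet", function(object) {
  n <- nrow(object@records)
  cat(sprintf("MssSet: %d mitotype-specific sequence(s) on '%s'\n",
              n, object@query))
  if (n > 0) {
    rng <- range(object@records$length)
    cat(sprintf("  lengths %d-%d bp; %d with duplicate copies; panel of %d\n",
                rng[1], rng[2], sum(object@records$copies >= 2),
                ncol(object@presence) - 1L))
  }
})

#' CandidateReport: result of the end-to-end CMS candidate screen
#'
#' @slot orfs `data.frame` of all predicted ORFs with per-filter flags
#'   (`discarded`, `has_tm`, `mss_overlap`, `candidate`).
#' @slot candidates subset of `orfs` surviving every required filter.
#' @slot mss the [MssSet-class] computed against the panel (or `NULL`-like
#'   empty set when no panel was given).
#' @slot tm list of per-ORF transmembrane segment tables.
#' @slot chimera list of per-candidate chimera decompositions (may be empty).
#' @slot params every threshold that affected the output, plus package
#'   version and seed (the report provenance header).
#' @slot log character vector of stage messages.
#' @exportClass CandidateReport
setClass("CandidateReport",
  representation(orfs = "data.frame", candidates = "data.frame",
                 mss = "MssSet", tm = "list", chimera = "list",
                 params = "list", log = "character")
)

#' @describeIn CandidateReport-class surviving candidate table accessor
#' @param x a `CandidateReport`.
#' @export
candidates <- function(x) x@candidates

#' @describeIn CandidateReport-class provenance parameter list accessor
#' @export
screenParams <- function(x) x@params

setMethod("show", "CandidateReport", function(object) {
  cat(sprintf("CandidateReport: %d ORF(s) scanned, %d candidate(s)\n",
              nrow(object@orfs), nrow(object@candidates)))
  if (nrow(object@candidates) > 0) {
    with(object@candidates,
         cat(sprintf("  %s: %d..%d strand %+d, %d aa\n",
                     orf_id, start, end, strand, aa_length), sep = ""))
  }
})

.emptyMssSet <- function(query = "query") {
  rec <- data.frame(id = character(), start = integer(), end = integer(),
                    length = integer(), copies = integer(),
                    stringsAsFactors = FALSE)
  pres <- matrix(logical(), nrow = 0, ncol = 1,
                 dimnames = list(NULL, query))
  new("MssSet", records = rec, presence = pres, query = query,
      params = list())
}
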