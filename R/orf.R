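#' Translate a nucleotide string codon by codon
#'
#' Standard genetic code (plant mitochondria use the standard table).
#' Any codon containing `N` translates to `X`; stop codons translate to
#' `*`.
#'
#' @param codons nucleotide string over `A,C,G,T,N`, length divisible
#'   by 3.
#' @return amino-acid string (one character per codon).
#' @examples
#' translateCodons("ATGTAA")  # "M*"
#' @export
translateCodons <- function(codons) {
  codons <- toupper(codons)
  n <- nchar(codons)
  if (n %% 3L != 0L) stop("length not divisible by 3")
  if (grepl("[^ACGTN]", codons)) stop("characters outside {A,C,G,T,N}")
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  cod <- substring(codons, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[cod])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

# Scan one already-translated frame for maximal ATG..stop ORFs.
# aa: character vector of residues; returns list of (m_idx, stop_idx)
# codon indices, where stop_idx is the index of the stop codon.
.frameOrfs <- function(aa, minCodons) {
  brk <- which(aa == "*" | aa == "X")
  isStop <- aa[brk] == "*"
  out <- list()
  prev <- 0L
  for (bi in seq_along(brk)) {
    b <- brk[bi]
    if (isStop[bi] && b - prev > 1L) {
      seg <- which(aa[(prev + 1L):(b - 1L)] == "M")
      if (length(seg)) {
        mIdx <- prev + seg[1L]          # most upstream ATG: longest ORF
        if (b - mIdx >= minCodons)
          out[[length(out) + 1L]] <- c(mIdx, b)
      }
    }
    prev <- b
  }
  out
}

#' Six-frame ORF prediction on a (circular) genome
#'
#' Reports every maximal ATG-to-stop open reading frame on both strands
#' with at least `minCodons` amino acids of coding sequence (the stop
#' codon is included in the reported interval but excluded from the
#' protein). For nested ATGs sharing a stop only the longest (most
#' upstream ATG) is reported. On circular genomes ORFs crossing the
#' origin are found by scanning the doubled sequence and deduplicating;
#' their intervals wrap (`end < start`). Codons containing `N` terminate
#' scanning without yielding an ORF across them; linear genomes only
#' yield ORFs that end at a genuine stop codon.
#'
#' The default threshold of 70 codons is the screening threshold used for
#' CMS candidate surveys of rice mitogenomes.
#'
#' @param genome a [MitoGenome-class] (or nucleotide string, treated as
#'   circular).
#' @param minCodons minimum protein length in amino acids (default 70).
#' @return `data.frame` sorted by `start` with columns `orf_id`
#'   (`orf<aa_length>_<n>`), `start`, `end` (1-based inclusive, stop
#'   codon included; `end < start` wraps), `strand` (+1/-1), `frame`
#'   (1..3 on the reading strand), `aa_length`, `wraps`, `aa_seq`.
#' @seealso [translateCodons()], [writeOrfProteins()]
#' @export
findOrfs <- function(genome, minCodons = 70L) {
  if (!is(genome, "MitoGenome")) genome <- mitoGenome("genome", genome)
  S <- genomeSeq(genome)
  L <- nchar(S)
  circ <- isCircular(genome)
  res <- list()
  for (strand in c(1L, -1L)) {
    W <- if (strand == 1L) S else revComp(S)
    D <- if (circ) paste0(W, W) else W
    for (f in 1:3) {
      nCod <- (nchar(D) - f + 1L) %/% 3L
      if (nCod < 1L) next
      aaStr <- translateCodons(substr(D, f, f + 3L * nCod - 1L))
      aa <- strsplit(aaStr, "", fixed = TRUE)[[1L]]
      for (orf in .frameOrfs(aa, minCodons)) {
        ntStart <- f + 3L * (orf[1L] - 1L)         # on D (reading strand)
        ntEnd <- f + 3L * orf[2L] - 1L             # incl. stop codon
        span <- ntEnd - ntStart + 1L
        if (circ && (ntStart > L || span > L)) next  # canonical copy only
        aaSeq <- paste(aa[orf[1L]:(orf[2L] - 1L)], collapse = "")
        # map reading-strand coordinates back to the forward strand
        if (strand == 1L) {
          gs <- ntStart
          ge <- if (circ) ((ntEnd - 1L) %% L) + 1L else ntEnd
        } else {
          ps <- ((ntStart - 1L) %% L) + 1L
          pe <- ((ntEnd - 1L) %% L) + 1L
          gs <- L - pe + 1L
          ge <- L - ps + 1L
        }
        res[[length(res) + 1L]] <- data.frame(
          start = gs, end = ge, strand = strand, frame = f,
          aa_length = orf[2L] - orf[1L], wraps = ge < gs,
          aa_seq = aaSeq, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(orf_id = character(), start = integer(),
                      end = integer(), strand = integer(),
                      frame = integer(), aa_length = integer(),
                      wraps = logical(), aa_seq = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, res)
  df <- df[!duplicated(df[c("start", "end", "strand")]), , drop = FALSE]
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  df$orf_id <- sprintf("orf%d_%d", df$aa_length, seq_len(nrow(df)))
  rownames(df) <- NULL
  df[c("orf_id", "start", "end", "strand", "frame", "aa_length", "wraps",
       "aa_seq")]
}

#' Write ORF translations as protein FASTA
#'
#' @param orfs ORF table from [findOrfs()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeOrfProteins <- function(orfs, path) {
  set <- Biostrings::AAStringSet(setNames(orfs$aa_seq, orfs$orf_id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
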