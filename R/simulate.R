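# Random nucleotide sequence with a GC knob.
.randSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

.randProtein <- function(n) {
  paste(c("M", sample(.AA20, n - 1L, replace = TRUE)), collapse = "")
}

# Codons for a protein; for hydrophobic cores, draws from L/I/V/F codons.
.codonsFor <- function(aa) {
  tab <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  vapply(strsplit(aa, "", fixed = TRUE)[[1L]], function(r) {
    cods <- tab[[r]]
    cods[sample.int(length(cods), 1L)]
  }, character(1))
}

# A planted ORF nucleotide sequence: ATG + codons + TAA, with a
# hydrophobic core when tm = TRUE (>= 25 consecutive L/I/V/F residues).
.plantedOrfSeq <- function(aaLength, tm = TRUE) {
  core <- if (tm) paste(sample(c("L", "I", "V", "F"), 25L, replace = TRUE),
                        collapse = "") else ""
  nOther <- aaLength - 1L - nchar(core)
  stopifnot(nOther >= 0L)
  left <- sample.int(nOther + 1L, 1L) - 1L
  aa <- paste0("M",
               paste(sample(.AA20, left, replace = TRUE), collapse = ""),
               core,
               paste(sample(.AA20, nOther - left, replace = TRUE),
                     collapse = ""))
  paste0(paste(.codonsFor(aa), collapse = ""), "TAA")
}

#' Simulate a mitogenome panel with planted mitotype-specific sequences
#'
#' Generates a query genome plus a comparison panel sharing a
#' uniform-random circular backbone. Each entry of `mssSpec` plants one
#' random insertion into the query and into the panel genomes listed in
#' its `presentIn` subset (so that the segment is absent from the
#' remaining panel genomes — a mitotype-specific sequence with a known
#' presence vector). Insertions may carry a planted ORF (optionally with
#' a hydrophobic, transmembrane-like core) and may be duplicated at a
#' second query locus. Insertion sequences are drawn independently of
#' the backbone so planted-truth recovery assertions are sharp; with
#' `cleanOrfs = TRUE` insertion sequences are redrawn until they carry
#' no chance ORF of `orfThreshold` codons, so an end-to-end screen
#' recovers exactly the planted ORFs.
#'
#' @param seed RNG seed; generation is a pure function of
#'   `(seed, arguments)`.
#' @param backboneLen backbone length in bp (>= 10x the largest
#'   insertion).
#' @param nPanel number of panel genomes.
#' @param mssSpec list of specs, each a list with `length` (bp),
#'   `presentIn` (integer indices of panel genomes also carrying it; may
#'   be empty), optional `duplicate` (logical: second query copy),
#'   optional `orf` (list with `aaLength`, `tm`).
#' @param repeatSpec optional list of specs, each a list with `length`
#'   and optional `inverted`, planting an exact extra copy of a backbone
#'   slice into the query.
#' @param cleanOrfs redraw insertions containing chance ORFs (see above).
#' @param orfThreshold codon threshold used by `cleanOrfs`.
#' @param gc backbone GC content.
#' @return list with `query` ([MitoGenome-class]), `panel` (named list
#'   of `MitoGenome`), and `truth`: planted MSS intervals and presence
#'   subsets on query coordinates, planted ORF coordinates, planted
#'   repeat loci, and the seed.
#' @export
simPanel <- function(seed, backboneLen = 1e5, nPanel = 5L,
                     mssSpec = list(), repeatSpec = list(),
                     cleanOrfs = FALSE, orfThreshold = 70L, gc = 0.5) {
  maxIns <- if (length(mssSpec))
    max(vapply(mssSpec, function(s) s$length, numeric(1))) else 0
  stopifnot(backboneLen >= 10 * max(maxIns, 1))
  .withSeed(seed, {
    backbone <- .randSeq(backboneLen, gc)
    nm <- length(mssSpec)
    nr <- length(repeatSpec)
    nAnchor <- nm + sum(vapply(mssSpec, function(s)
      isTRUE(s$duplicate), logical(1))) + nr
    # anchors: distinct backbone positions, spaced and away from origin
    minSpace <- max(2L * maxIns, 2000L)
    lo <- max(2000L, maxIns)
    hi <- backboneLen - lo
    if (nAnchor > 0L) {
      repeat {
        anchors <- sort(sample(lo:hi, nAnchor))
        if (nAnchor == 1L || min(diff(anchors)) >= minSpace) break
      }
    } else anchors <- integer()
    # draw insertion sequences (possibly ORF-bearing, possibly redrawn)
    insSeqs <- character(nm)
    orfOffsets <- rep(NA_integer_, nm)
    orfSeqLens <- rep(NA_integer_, nm)
    for (i in seq_len(nm)) {
      s <- mssSpec[[i]]
      repeat {
        if (!is.null(s$orf)) {
          orfNt <- .plantedOrfSeq(s$orf$aaLength,
                                  tm = !isFALSE(s$orf$tm))
          pad <- s$length - nchar(orfNt)
          stopifnot(pad >= 0L)
          offL <- sample.int(pad + 1L, 1L) - 1L
          insSeqs[i] <- paste0(.randSeq(offL, gc), orfNt,
                               .randSeq(pad - offL, gc))
          orfOffsets[i] <- offL
          orfSeqLens[i] <- nchar(orfNt)
        } else {
          insSeqs[i] <- .randSeq(s$length, gc)
        }
        if (!cleanOrfs) break
        lin <- mitoGenome("ins", insSeqs[i], circular = FALSE)
        found <- findOrfs(lin, minCodons = orfThreshold)
        ok <- if (!is.null(s$orf) && s$orf$aaLength >= orfThreshold) {
          nrow(found) == 1L && found$strand == 1L &&
            found$start == orfOffsets[i] + 1L
        } else nrow(found) == 0L
        if (ok) break
      }
    }
    # repeat insertions: exact copies of backbone slices
    repSeqs <- character(nr)
    repSrc <- vector("list", nr)
    for (i in seq_len(nr)) {
      s <- repeatSpec[[i]]
      src <- sample.int(backboneLen - s$length, 1L)
      piece <- substr(backbone, src, src + s$length - 1L)
      if (isTRUE(s$inverted)) piece <- revComp(piece)
      repSeqs[i] <- piece
      repSrc[[i]] <- c(src = src, len = s$length)
    }
    # assemble: all inserted pieces at their anchors, per genome
    dupIdx <- which(vapply(mssSpec, function(s) isTRUE(s$duplicate),
                           logical(1)))
    pieceSeq <- c(insSeqs, insSeqs[dupIdx], repSeqs)
    pieceKind <- c(rep("mss", nm), rep("dup", length(dupIdx)),
                   rep("repeat", nr))
    pieceMss <- c(seq_len(nm), dupIdx, rep(NA_integer_, nr))
    stopifnot(length(pieceSeq) == nAnchor)
    assemble <- function(useMss) {
      keep <- pieceKind != "mss" & pieceKind != "dup" |
        pieceMss %in% useMss
      parts <- character(0)
      prev <- 1L
      ins <- which(keep)
      for (t in ins) {
        parts <- c(parts, substr(backbone, prev, anchors[t] - 1L),
                   pieceSeq[t])
        prev <- anchors[t]
      }
      paste0(paste(parts, collapse = ""),
             substr(backbone, prev, backboneLen))
    }
    # query carries everything; compute truth coordinates on the query
    offsets <- cumsum(c(0, nchar(pieceSeq)))[seq_len(nAnchor)]
    qStart <- anchors + offsets           # insertion start on query
    qEnd <- qStart + nchar(pieceSeq) - 1L
    querySeq <- assemble(seq_len(nm))
    stopifnot(nchar(querySeq) == backboneLen + sum(nchar(pieceSeq)))
    panel <- vector("list", nPanel)
    for (g in seq_len(nPanel)) {
      carries <- which(vapply(mssSpec, function(s)
        g %in% s$presentIn, logical(1)))
      # duplicate copies are query-only; panel genomes carry one copy
      pieceOk <- (pieceKind == "mss" & pieceMss %in% carries) |
        pieceKind == "repeat"
      parts <- character(0); prev <- 1L
      for (t in which(pieceOk)) {
        parts <- c(parts, substr(backbone, prev, anchors[t] - 1L),
                   pieceSeq[t])
        prev <- anchors[t]
      }
      gs <- paste0(paste(parts, collapse = ""),
                   substr(backbone, prev, backboneLen))
      panel[[g]] <- mitoGenome(sprintf("panel%02d", g), gs)
    }
    names(panel) <- vapply(panel, genomeId, character(1))
    mssTruth <- lapply(seq_len(nm), function(i) {
      t1 <- which(pieceKind == "mss" & pieceMss == i)
      dups <- which(pieceKind == "dup" & pieceMss == i)
      list(id = sprintf("S%d", i), start = unname(qStart[t1]),
           end = unname(qEnd[t1]), length = mssSpec[[i]]$length,
           presentIn = mssSpec[[i]]$presentIn,
           copies = 1L + length(dups),
           dup_start = if (length(dups)) unname(qStart[dups]) else NULL)
    })
    orfTruth <- lapply(which(!is.na(orfOffsets)), function(i) {
      t1 <- which(pieceKind == "mss" & pieceMss == i)
      list(mss = sprintf("S%d", i),
           start = unname(qStart[t1]) + orfOffsets[i],
           end = unname(qStart[t1]) + orfOffsets[i] + orfSeqLens[i] - 1L,
           strand = 1L,
           aa_length = mssSpec[[i]]$orf$aaLength)
    })
    repTruth <- lapply(seq_len(nr), function(i) {
      t1 <- which(pieceKind == "repeat")[i]
      list(src_start = unname(repSrc[[i]]["src"]),
           length = unname(repSrc[[i]]["len"]),
           copy_start = unname(qStart[t1]),
           inverted = isTRUE(repeatSpec[[i]]$inverted))
    })
    list(query = mitoGenome("query", querySeq),
         panel = panel,
         backbone = mitoGenome("backbone", backbone),
         truth = list(seed = seed, mss = mssTruth, orfs = orfTruth,
                      repeats = repTruth))
  })
}

#' Simulate a chimeric fusion protein with known decomposition
#'
#' Builds a candidate protein and two parents so that the candidate is
#' parent 1's N-terminal region fused to parent 2's C-terminal region,
#' with a homologous junction overlap of `junctionOverlap` residues
#' shared by both parents (the recombination signature), `nIndels`
#' residues present in the candidate but deleted from parent 1 (so the
#' decomposition reports them as insertions), and `nMismatches` residue
#' changes in the parent-2 part (planted at the C terminus inward).
#'
#' @param seed RNG seed.
#' @param candLength candidate protein length (default 312 aa).
#' @param breakpoint last candidate residue of the parent-1 segment
#'   (default 202).
#' @param junctionOverlap homologous overlap: the parent-2 segment
#'   starts at `breakpoint - junctionOverlap + 1` (default 6).
#' @param parent1Tail,parent2Head unrelated residues appended to parent 1
#'   / prepended to parent 2 beyond the fused regions.
#' @param nIndels candidate-only residues in the parent-1 segment,
#'   planted at interior positions (a terminal indel would admit an
#'   equally optimal indel-free alignment, leaving the planted truth
#'   unidentifiable).
#' @param nMismatches substitutions distinguishing parent 2.
#' @return list with `candidate`, `parents` (named character vector),
#'   and `truth` (planted breakpoints, parental ranges, edit counts).
#' @export
simFusion <- function(seed, candLength = 312L, breakpoint = 202L,
                      junctionOverlap = 6L, parent1Tail = 40L,
                      parent2Head = 30L, nIndels = 0L, nMismatches = 0L) {
  stopifnot(breakpoint < candLength, junctionOverlap < breakpoint)
  .withSeed(seed, {
    cand <- .randProtein(candLength)
    candV <- strsplit(cand, "", fixed = TRUE)[[1L]]
    # parent 1: candidate 1..breakpoint with nIndels residues deleted,
    # plus an unrelated tail
    p1v <- candV[1:breakpoint]
    if (nIndels > 0L) {
      # interior positions only: an indel at a segment terminus admits an
      # equally optimal indel-free alignment, making the truth ambiguous
      del <- sort(sample(15:(breakpoint - 15L), nIndels))
      p1v <- p1v[-del]
    } else del <- integer()
    p1 <- paste0(paste(p1v, collapse = ""),
                 paste(sample(.AA20, parent1Tail, replace = TRUE),
                       collapse = ""))
    # parent 2: unrelated head plus candidate (breakpoint-ov+1)..end,
    # with nMismatches substitutions (last residue first, inward)
    p2start <- breakpoint - junctionOverlap + 1L
    p2v <- candV[p2start:candLength]
    if (nMismatches > 0L) {
      at <- length(p2v) - seq_len(nMismatches) + 1L
      for (k in at) {
        p2v[k] <- sample(setdiff(.AA20, p2v[k]), 1L)
      }
    }
    p2 <- paste0(paste(sample(.AA20, parent2Head, replace = TRUE),
                       collapse = ""),
                 paste(p2v, collapse = ""))
    list(candidate = cand,
         parents = c(parentA = p1, parentB = p2),
         truth = list(seed = seed, breakpoint = breakpoint,
                      junction_overlap = junctionOverlap,
                      p1_cand_range = c(1L, breakpoint),
                      p1_parent_range = c(1L, breakpoint - nIndels),
                      p1_insertions = nIndels,
                      p1_deleted_positions = del,
                      p2_cand_range = c(p2start, candLength),
                      p2_parent_range = c(parent2Head + 1L,
                                          parent2Head + candLength -
                                            p2start + 1L),
                      p2_mismatches = nMismatches))
  })
}

#' Simulate two-bulk allele counts from a segregating population
#'
#' Emulates bulked-segregant sequencing of two phenotypic extreme pools
#' (e.g. fertile and sterile) of 25 individuals each from a population
#' segregating for one fertility-restorer locus. With `effect = 1`,
#' bulk 1 is fixed for the restorer (donor) allele at `qtlPos` and
#' bulk 2 fixed against it; linkage decays with distance via the Haldane
#' map function at `recombRate` Morgans/bp. With `effect = 0` both bulks
#' are unselected null samples (F2-equivalent segregation). Read depths
#' are Poisson around `depthMean` (or exactly `depthMean` with
#' `depthModel = "fixed"`), and read counts binomial at the bulk allele
#' frequency.
#'
#' @param seed RNG seed.
#' @param nSnps number of SNP sites.
#' @param chromLen chromosome length in bp.
#' @param depthMean mean sequencing depth per bulk.
#' @param bulkSize individuals per bulk (default 25).
#' @param qtlPos position of the planted restorer locus.
#' @param recombRate Morgans per bp (default 4e-8, i.e. 4 cM/Mb, a
#'   typical rice euchromatic rate).
#' @param effect 1 = fixed-vs-fixed selection at the locus, 0 = null.
#' @param depthModel `"poisson"` or `"fixed"`.
#' @param chrom chromosome name.
#' @return list with `counts` (allele-count `data.frame` in the
#'   [readAlleleCounts()] layout) and `truth` (`qtl_pos`, `effect`,
#'   `seed`).
#' @export
simBulkseq <- function(seed, nSnps = 2000L, chromLen = 25e6,
                       depthMean = 50, bulkSize = 25L, qtlPos = 12.5e6,
                       recombRate = 4e-8, effect = 1,
                       depthModel = c("poisson", "fixed"),
                       chrom = "chr10") {
  depthModel <- match.arg(depthModel)
  stopifnot(qtlPos >= 1, qtlPos <= chromLen, effect %in% c(0, 1))
  .withSeed(seed, {
    pos <- sort(sample.int(chromLen, nSnps))
    r <- 0.5 * (1 - exp(-2 * recombRate * abs(pos - qtlPos)))
    nAll <- 2L * bulkSize
    if (effect == 1) {
      # bulk1 individuals RR at the locus: each of 2N haplotypes carries
      # the donor allele at a linked SNP with prob 1 - r; bulk2 rr: prob r
      x1 <- rbinom(nSnps, nAll, 1 - r)
      x2 <- rbinom(nSnps, nAll, r)
    } else {
      x1 <- rbinom(nSnps, nAll, 0.5)
      x2 <- rbinom(nSnps, nAll, 0.5)
    }
    f1 <- x1 / nAll; f2 <- x2 / nAll
    d1 <- if (depthModel == "poisson") rpois(nSnps, depthMean)
      else rep(as.integer(depthMean), nSnps)
    d2 <- if (depthModel == "poisson") rpois(nSnps, depthMean)
      else rep(as.integer(depthMean), nSnps)
    a1 <- rbinom(nSnps, d1, f1)
    a2 <- rbinom(nSnps, d2, f2)
    counts <- data.frame(chrom = chrom, pos = pos,
                         ref_count_bulk1 = d1 - a1, alt_count_bulk1 = a1,
                         ref_count_bulk2 = d2 - a2, alt_count_bulk2 = a2,
                         stringsAsFactors = FALSE)
    list(counts = counts,
         truth = list(seed = seed, qtl_pos = qtlPos, effect = effect,
                      chrom_len = chromLen, bulk_size = bulkSize))
  })
}

#' Write a truth list as JSON
#'
#' @param truth a truth list from one of the simulators.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
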