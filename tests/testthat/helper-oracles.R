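# Independent brute-force oracles used to validate the optimized
# implementations, plus small fixture builders. These deliberately take
# different algorithmic routes from the package code.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# an ORF of naa amino acids from random non-stop codons (ATG ... TAA)
rand_orf <- function(naa) {
  gc <- Biostrings::GENETIC_CODE
  ok <- names(gc)[gc != "*" ]
  paste0("ATG", paste(sample(ok, naa - 1L, TRUE), collapse = ""), "TAA")
}

rand_protein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, TRUE), collapse = "")
}

# point-mutate + indel a sequence (keeps high identity to the original)
mutate_dna <- function(s, nsub = 5, nindel = 1) {
  v <- strsplit(s, "")[[1]]
  for (i in sample(length(v), nsub))
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  for (k in seq_len(nindel)) {
    p <- sample(length(v) - 3L, 1)
    if (stats::runif(1) < 0.5)
      v <- append(v, sample(c("A", "C", "G", "T"), sample(3, 1), TRUE), p)
    else v <- v[-(p:(p + sample(2, 1)))]
  }
  paste(v, collapse = "")
}

# Smith-Waterman / Needleman-Wunsch reference scores via Biostrings.
sw_oracle_score <- function(a, b, match = 1, mismatch = -2,
                            gapOpen = 5, gapExtend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gapOpen,
    gapExtension = gapExtend))
}

nw_oracle_score <- function(a, b, gapOpen = 10, gapExtend = 1) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = e$BLOSUM62, gapOpening = gapOpen,
    gapExtension = gapExtend))
}

# Brute-force six-frame ORF scan: walk codon by codon from every ATG on
# both strands of the (doubled, for circular) sequence; report the
# longest ORF per stop, deduplicated by genomic coordinates.
oracle_orfs <- function(seq, circular = TRUE, minCodons = 70) {
  L <- nchar(seq)
  found <- list()
  for (strand in c(1L, -1L)) {
    W <- if (strand == 1L) seq else MitoCMS::revComp(seq)
    D <- if (circular) paste0(W, W) else W
    v <- strsplit(D, "")[[1]]
    nD <- length(v)
    codon_at <- function(p) paste(v[p:(p + 2L)], collapse = "")
    gc <- Biostrings::GENETIC_CODE
    for (p in seq_len(nD - 2L)) {
      if (codon_at(p) != "ATG") next
      # walk to the stop
      q <- p
      good <- TRUE
      repeat {
        if (q + 2L > nD) { good <- FALSE; break }
        cod <- codon_at(q)
        aa <- if (grepl("N", cod)) "X" else unname(gc[cod])
        if (aa == "X") { good <- FALSE; break }
        if (aa == "*") break
        q <- q + 3L
      }
      if (!good) next
      aaLen <- (q - p) / 3L
      if (aaLen < minCodons) next
      ntStart <- p; ntEnd <- q + 2L
      if (circular && (ntStart > L || ntEnd - ntStart + 1L > L)) next
      # is there an upstream ATG sharing this stop? then skip (not maximal)
      up <- p - 3L
      maximal <- TRUE
      while (up >= 1L) {
        cod <- codon_at(up)
        aa <- if (grepl("N", cod)) "X" else unname(gc[cod])
        if (aa == "*" || aa == "X") break
        if (cod == "ATG") { maximal <- FALSE; break }
        up <- up - 3L
      }
      if (!maximal) next
      if (strand == 1L) {
        gs <- ntStart
        ge <- if (circular) ((ntEnd - 1L) %% L) + 1L else ntEnd
      } else {
        ps <- ((ntStart - 1L) %% L) + 1L
        pe <- ((ntEnd - 1L) %% L) + 1L
        gs <- L - pe + 1L
        ge <- L - ps + 1L
      }
      found[[sprintf("%d/%d/%d", gs, ge, strand)]] <-
        c(start = gs, end = ge, strand = strand, aa = aaLen)
    }
  }
  out <- do.call(rbind, unname(found))
  if (is.null(out)) out <- matrix(numeric(), ncol = 4,
                                  dimnames = list(NULL, c("start", "end",
                                                          "strand", "aa")))
  out[order(out[, "start"], out[, "end"], out[, "strand"]), ,
      drop = FALSE]
}

# Naive UPGMA recomputing every cluster distance as the plain average of
# original leaf-pair distances (no incremental update formula).
oracle_upgma_newick <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  strings <- labs
  heights <- rep(0, length(labs))
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      dd <- mean(d[clusters[[j]], clusters[[i]], drop = FALSE])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        ii <- i; jj <- j
        if (min(clusters[[j]]) > min(clusters[[i]])) { ii <- j; jj <- i }
        best <- list(d = dd, i = ii, j = jj, key = key)
      }
    }
    h <- best$d / 2
    i <- best$i; j <- best$j   # j has the smaller min label
    s <- sprintf("(%s:%g,%s:%g)", strings[j], h - heights[j],
                 strings[i], h - heights[i])
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    strings[j] <- s
    heights[j] <- h
    clusters[[i]] <- NULL
    strings <- strings[-i]
    heights <- heights[-i]
  }
  paste0(strings[1], ";")
}

# Exhaustive maximal exact repeat finder for linear sequences: sweep
# every offset, vectorized equality, no word anchoring.
oracle_repeats_linear <- function(seq, minLen) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  out <- list()
  for (d in seq_len(n - 1L)) {
    if (n - d < minLen) break
    eq <- v[1:(n - d)] == v[(1 + d):n] & v[1:(n - d)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= minLen)) {
      out[[length(out) + 1L]] <- c(a = starts[k], b = starts[k] + d,
                                   len = r$lengths[k])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(numeric(), ncol = 3,
                                  dimnames = list(NULL, c("a", "b", "len")))
  res[order(res[, "a"], res[, "b"]), , drop = FALSE]
}

# Plain per-window averaging oracle for the delta SNP-index.
oracle_window_means <- function(stats, starts, windowBp) {
  vapply(starts, function(s0) {
    sel <- !stats$filtered & stats$pos >= s0 & stats$pos <= s0 + windowBp - 1
    if (!any(sel)) return(NA_real_)
    mean(stats$delta[sel])
  }, numeric(1))
}

write_fasta_raw <- function(lines, path) {
  writeLines(lines, path)
  path
}
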