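#' SNP-index of a sequenced bulk
#'
#' Fraction of reads carrying the alternate (donor-parent) allele,
#' `alt / (ref + alt)`. Sites below `minDepth` total reads are not an
#' error: they return `NA` (flagged, to be excluded downstream).
#'
#' @param refCount,altCount non-negative read counts (vectorized).
#' @param minDepth minimal total depth for a usable site (default 10).
#' @return numeric vector in `[0, 1]`, `NA` where depth < `minDepth`.
#' @examples
#' snpIndex(5, 5)    # 0.5
#' snpIndex(10, 0)   # 0.0
#' @export
snpIndex <- function(refCount, altCount, minDepth = 10L) {
  depth <- refCount + altCount
  idx <- ifelse(depth >= minDepth, altCount / depth, NA_real_)
  idx
}

#' Per-SNP delta SNP-index table
#'
#' Computes both bulk SNP-indices and their difference
#' `delta = index_bulk1 - index_bulk2` for every site of an allele-count
#' table (see [readAlleleCounts()] for the format). Swapping the bulks
#' negates `delta` exactly.
#'
#' @param table allele-count `data.frame`.
#' @param minDepth minimal per-bulk depth; shallower sites get `NA`
#'   indices and are flagged `filtered`.
#' @return `data.frame` with `chrom`, `pos`, `depth1`, `depth2`,
#'   `index_bulk1`, `index_bulk2`, `delta`, `filtered`.
#' @export
snpStats <- function(table, minDepth = 10L) {
  d1 <- table$ref_count_bulk1 + table$alt_count_bulk1
  d2 <- table$ref_count_bulk2 + table$alt_count_bulk2
  i1 <- snpIndex(table$ref_count_bulk1, table$alt_count_bulk1, minDepth)
  i2 <- snpIndex(table$ref_count_bulk2, table$alt_count_bulk2, minDepth)
  data.frame(chrom = table$chrom, pos = table$pos, depth1 = d1,
             depth2 = d2, index_bulk1 = i1, index_bulk2 = i2,
             delta = i1 - i2, filtered = is.na(i1) | is.na(i2),
             stringsAsFactors = FALSE)
}

#' Sliding-window mean delta SNP-index
#'
#' Tiles each chromosome with windows of `windowBp` every `stepBp` and
#' averages the per-SNP delta SNP-index within each window. Windows
#' without usable SNPs are reported with `n_snps = 0` and `NA` mean.
#'
#' @param stats per-SNP table from [snpStats()] (or an allele-count
#'   table, converted on the fly).
#' @param windowBp window width in bp (default 2 Mb).
#' @param stepBp window step in bp (default 50 kb).
#' @param chromLen optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome.
#' @return `data.frame` with `chrom`, `start`, `end`, `mid`, `n_snps`,
#'   `mean_delta`, `median_depth` (median over SNPs of the smaller bulk
#'   depth; used to pick the matching simulated confidence band).
#' @seealso [nullConfidence()], [attachConfidence()], [callQtl()]
#' @export
deltaWindows <- function(stats, windowBp = 2e6, stepBp = 5e4,
                         chromLen = NULL) {
  if (!"delta" %in% names(stats)) stats <- snpStats(stats)
  out <- list()
  for (ch in unique(stats$chrom)) {
    s <- stats[stats$chrom == ch & !stats$filtered, , drop = FALSE]
    len <- if (!is.null(chromLen) && ch %in% names(chromLen))
      chromLen[[ch]] else max(stats$pos[stats$chrom == ch])
    starts <- seq(1, max(1, len - 1), by = stepBp)
    ends <- pmin(starts + windowBp - 1, len)
    n <- length(starts)
    nsnp <- integer(n); msum <- numeric(n); dep <- rep(NA_real_, n)
    for (w in seq_len(n)) {
      inw <- s$pos >= starts[w] & s$pos <= ends[w]
      nsnp[w] <- sum(inw)
      msum[w] <- if (nsnp[w]) mean(s$delta[inw]) else NA_real_
      dep[w] <- if (nsnp[w]) median(pmin(s$depth1[inw], s$depth2[inw]))
        else NA_real_
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            mid = (starts + ends) / 2, n_snps = nsnp,
                            mean_delta = msum, median_depth = dep,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulated null confidence bands for the delta SNP-index
#'
#' Monte-Carlo bands under the null hypothesis of no QTL. Per
#' simulation, each bulk's allele frequency is obtained by sampling
#' `bulkSize` genotypes from the null segregation ratio (F2-equivalent
#' 1:2:1, i.e. per-individual allele dose 0/0.5/1 — equivalently
#' `2*bulkSize` independent alleles at frequency 1/2; BC1-equivalent
#' 1:1 heterozygote:homozygote is also available), then read counts are
#' drawn binomially at the given depth for each bulk independently. The
#' `alpha/2` and `1 - alpha/2` quantiles of the simulated delta define
#' the band per depth.
#'
#' @param depths integer vector of read depths (one band per unique
#'   depth; both bulks simulated at that depth).
#' @param bulkSize individuals per bulk (default 25).
#' @param nSims simulations per depth (>= 1000; default 10000).
#' @param population `"F2"` (1:2:1) or `"BC1"` (1:1 Aa:aa).
#' @param seed RNG seed for reproducibility.
#' @return `data.frame` with `depth`, `ci95_lo`, `ci95_hi`, `ci99_lo`,
#'   `ci99_hi`.
#' @export
nullConfidence <- function(depths, bulkSize = 25L, nSims = 10000L,
                           population = c("F2", "BC1"), seed = 1L) {
  population <- match.arg(population)
  stopifnot(nSims >= 1000L)
  depths <- sort(unique(round(depths)))
  depths <- depths[!is.na(depths) & depths >= 1]
  .withSeed(seed, {
    rows <- lapply(depths, function(d) {
      freq <- function() {
        if (population == "F2")
          rbinom(nSims, 2L * bulkSize, 0.5) / (2L * bulkSize)
        else  # BC1: genotypes Aa:aa 1:1, per-individual dose 0.5 or 0
          rbinom(nSims, bulkSize, 0.5) * 0.5 / bulkSize
      }
      i1 <- rbinom(nSims, d, freq()) / d
      i2 <- rbinom(nSims, d, freq()) / d
      delta <- i1 - i2
      q <- quantile(delta, c(0.025, 0.975, 0.005, 0.995), names = FALSE)
      data.frame(depth = d, ci95_lo = q[1], ci95_hi = q[2],
                 ci99_lo = q[3], ci99_hi = q[4])
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

#' Attach simulated confidence bands to delta windows
#'
#' Simulates [nullConfidence()] bands at each unique rounded
#' `median_depth` occurring in the window table and joins them on.
#'
#' @param windows window table from [deltaWindows()].
#' @inheritParams nullConfidence
#' @return `windows` with `ci95_lo`, `ci95_hi`, `ci99_lo`, `ci99_hi`
#'   columns (`NA` for empty windows).
#' @export
attachConfidence <- function(windows, bulkSize = 25L, nSims = 10000L,
                             population = "F2", seed = 1L) {
  dep <- round(windows$median_depth)
  bands <- nullConfidence(dep[!is.na(dep)], bulkSize = bulkSize,
                          nSims = nSims, population = population,
                          seed = seed)
  j <- match(dep, bands$depth)
  windows$ci95_lo <- bands$ci95_lo[j]
  windows$ci95_hi <- bands$ci95_hi[j]
  windows$ci99_lo <- bands$ci99_lo[j]
  windows$ci99_hi <- bands$ci99_hi[j]
  windows
}

#' Call QTL regions from banded windows
#'
#' Maximal runs of consecutive non-empty windows whose mean delta
#' SNP-index lies outside the simulated 95% band, annotated with whether
#' any window also exceeds the 99% band, and with the window of largest
#' absolute delta as the peak.
#'
#' @param windows window table with bands, from [attachConfidence()].
#' @return `data.frame` with `chrom`, `start`, `end`, `peak_mid`,
#'   `n_windows`, `sig99`.
#' @export
callQtl <- function(windows) {
  need <- c("ci95_lo", "ci95_hi", "ci99_lo", "ci99_hi")
  if (!all(need %in% names(windows)))
    stop("windows lack confidence bands; run attachConfidence() first")
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_mid = numeric(),
                      n_windows = integer(), sig99 = logical(),
                      stringsAsFactors = FALSE)
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    outside <- !is.na(w$mean_delta) & w$n_snps > 0 &
      (w$mean_delta < w$ci95_lo | w$mean_delta > w$ci95_hi)
    if (!any(outside)) next
    runs <- .trueRuns(outside)
    for (r in seq_len(nrow(runs))) {
      rows <- runs[r, "start"]:runs[r, "end"]
      sub <- w[rows, , drop = FALSE]
      peak <- sub$mid[which.max(abs(sub$mean_delta))]
      sig99 <- any(sub$mean_delta < sub$ci99_lo |
                   sub$mean_delta > sub$ci99_hi, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(sub$start), end = max(sub$end),
        peak_mid = peak, n_windows = length(rows), sig99 = sig99,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
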