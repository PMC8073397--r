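# Kyte-Doolittle hydropathy scale (J Mol Biol 157:105-132 values).
.KD <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
         X =  0.0)

#' Per-position Kyte-Doolittle hydropathy
#'
#' @param aaSeq protein sequence (20 residues plus `X`; `X` scores 0).
#' @return numeric vector of per-residue hydropathy values.
#' @export
hydropathyProfile <- function(aaSeq) {
  v <- .KD[strsplit(toupper(aaSeq), "", fixed = TRUE)[[1L]]]
  if (anyNA(v)) stop("sequence contains characters outside the protein ",
                     "alphabet")
  unname(v)
}

#' Hydropathy-window transmembrane segment prediction
#'
#' Sliding-window transmembrane segment caller: every window of
#' `window` residues whose mean Kyte-Doolittle hydropathy reaches
#' `threshold` marks its span as membrane-embedded; overlapping spans
#' are merged into maximal segments. This is a deterministic hydropathy
#' method; the candidate screen only consumes presence/absence of at
#' least one called segment, not helix counts or topology.
#'
#' @param aaSeq protein sequence.
#' @param window window length in residues (default 19, the classic
#'   transmembrane-helix span).
#' @param threshold minimal window mean hydropathy (default 1.6, the
#'   Kyte-Doolittle cutoff suggestive of a membrane-spanning segment).
#' @return `data.frame` with one row per called segment: `start`, `end`
#'   (1-based residue positions), `mean_hydropathy` (mean over the
#'   segment). A sequence shorter than `window` yields an empty frame
#'   with a warning.
#' @examples
#' predictTm(strrep("L", 30))   # one fully hydrophobic segment
#' predictTm(strrep("D", 30))   # none
#' @export
predictTm <- function(aaSeq, window = 19L, threshold = 1.6) {
  empty <- data.frame(start = integer(), end = integer(),
                      mean_hydropathy = numeric())
  prof <- hydropathyProfile(aaSeq)
  n <- length(prof)
  if (n < window) {
    warning("sequence shorter than window; no segments called")
    return(empty)
  }
  cs <- c(0, cumsum(prof))
  wmean <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  hit <- wmean >= threshold
  if (!any(hit)) return(empty)
  runs <- .trueRuns(hit)
  segs <- data.frame(start = runs[, "start"],
                     end = runs[, "end"] + window - 1L)
  segs$mean_hydropathy <- vapply(seq_len(nrow(segs)), function(i)
    mean(prof[segs$start[i]:segs$end[i]]), numeric(1))
  segs
}
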