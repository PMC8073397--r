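#' Configuration for the CMS candidate screen
#'
#' Bundles and validates every threshold of [runScreen()]. The defaults
#' mirror the canonical candidate screen on rice mitogenomes: ORFs of at
#' least 70 codons; ORFs discarded when a single local-alignment hit to
#' the fertile reference genome covers at least `discardCoverage` of the
#' ORF at identity above `identityDiscard` (E-value at most
#' `evalueMax`); transmembrane-segment presence required; MSS overlap
#' annotated and optionally required (off by default — a candidate need
#' not overlap a mitotype-specific sequence, the flag is reported either
#' way).
#'
#' @param query,reference [MitoGenome-class] objects or FASTA paths
#'   (first record used): the CMS genome screened and the fertile
#'   reference whose shared ORFs are discarded.
#' @param panel list of [MitoGenome-class] or a multi-FASTA path: the
#'   comparison panel for MSS detection (may be empty).
#' @param minCodons ORF length threshold in codons (default 70).
#' @param identityDiscard reference-identity above which a covered ORF
#'   is discarded (default 0.99).
#' @param discardCoverage fraction of the ORF a single reference hit
#'   must cover to discard it (default 0.95).
#' @param evalueMax alignment E-value ceiling (default 1e-5).
#' @param requireTm require at least one predicted transmembrane segment.
#' @param requireMssOverlap require overlap with at least one MSS.
#' @param tmWindow,tmThreshold hydropathy window and cutoff for
#'   [predictTm()].
#' @param minMssLen,mergeGap,presenceFrac,identityMin MSS thresholds,
#'   see [detectMss()].
#' @param params an [alignParams()].
#' @param parents optional named vector of parental proteins for chimera
#'   decomposition of surviving candidates.
#' @param seed seed recorded in the provenance header (the screen itself
#'   is deterministic).
#' @return classed list `screenConfig`.
#' @export
screenConfig <- function(query, reference, panel = list(),
                         minCodons = 70L, identityDiscard = 0.99,
                         discardCoverage = 0.95, evalueMax = 1e-5,
                         requireTm = TRUE, requireMssOverlap = FALSE,
                         tmWindow = 19L, tmThreshold = 1.6,
                         minMssLen = 100L, mergeGap = 50L,
                         presenceFrac = 0.8, identityMin = 0.90,
                         params = alignParams(), parents = NULL,
                         seed = 1L) {
  loadG <- function(x, what) {
    if (is(x, "MitoGenome")) return(x)
    if (is.character(x) && length(x) == 1L && file.exists(x))
      return(readGenomeFasta(x)[[1L]])
    stop(what, " must be a MitoGenome or an existing FASTA path")
  }
  query <- loadG(query, "query")
  reference <- loadG(reference, "reference")
  if (is.character(panel)) panel <- readGenomeFasta(panel)
  stopifnot(identityDiscard > 0, identityDiscard <= 1,
            discardCoverage > 0, discardCoverage <= 1,
            evalueMax > 0, minCodons >= 1, presenceFrac > 0,
            presenceFrac <= 1, identityMin > 0, identityMin <= 1)
  params$evalueMax <- evalueMax
  structure(list(query = query, reference = reference, panel = panel,
                 minCodons = as.integer(minCodons),
                 identityDiscard = identityDiscard,
                 discardCoverage = discardCoverage,
                 evalueMax = evalueMax, requireTm = requireTm,
                 requireMssOverlap = requireMssOverlap,
                 tmWindow = as.integer(tmWindow),
                 tmThreshold = tmThreshold,
                 minMssLen = as.integer(minMssLen),
                 mergeGap = as.integer(mergeGap),
                 presenceFrac = presenceFrac, identityMin = identityMin,
                 params = params, parents = parents,
                 seed = as.integer(seed)),
            class = "screenConfig")
}

# Fraction of an ORF covered by a single hit's query interval,
# wrap-aware on the ORF side.
.orfHitCoverage <- function(orfStart, orfEnd, hitStart, hitEnd, L) {
  tot <- 0L
  for (p in .linearPieces(orfStart, orfEnd, L)) {
    lo <- max(p[1], hitStart); hi <- min(p[2], hitEnd)
    if (hi >= lo) tot <- tot + (hi - lo + 1L)
  }
  tot / intervalLength(orfStart, orfEnd, L)
}

#' Run the end-to-end CMS candidate screen
#'
#' Pipeline: [findOrfs()] on the query; discard ORFs shared with the
#' fertile reference (a single [localAlign()] hit covering at least
#' `discardCoverage` of the ORF at identity above `identityDiscard`);
#' [predictTm()] on every translation; [detectMss()] against the panel
#' plus [annotateMssOverlaps()]; candidates are the surviving ORFs
#' passing the required flags; optional [decomposeChimera()] of each
#' candidate against supplied parental proteins. Deterministic; every
#' threshold is recorded in the report's provenance parameters. Note
#' that transcript-level evidence (expression of the candidate in the
#' sterile cytoplasm) is a wet-lab filter this screen can flag but not
#' apply.
#'
#' @param config a [screenConfig()].
#' @return a [CandidateReport-class].
#' @export
runScreen <- function(config) {
  stopifnot(inherits(config, "screenConfig"))
  cfg <- config
  L <- genomeLength(cfg$query)
  logs <- character()
  say <- function(...) logs <<- c(logs, sprintf(...))

  stage <- "orf_scan"
  orfs <- tryCatch(findOrfs(cfg$query, cfg$minCodons),
                   error = function(e) stop("stage ", stage, ": ",
                                            conditionMessage(e)))
  say("orf_scan: %d ORFs >= %d codons", nrow(orfs), cfg$minCodons)

  stage <- "reference_discard"
  refHits <- tryCatch(localAlign(cfg$query, cfg$reference, cfg$params),
                      error = function(e) stop("stage ", stage, ": ",
                                               conditionMessage(e)))
  strong <- refHits[refHits$identity > cfg$identityDiscard &
                    refHits$evalue <= cfg$evalueMax, , drop = FALSE]
  orfs$discarded <- vapply(seq_len(nrow(orfs)), function(i) {
    any(vapply(seq_len(nrow(strong)), function(h)
      .orfHitCoverage(orfs$start[i], orfs$end[i], strong$qstart[h],
                      strong$qend[h], L) >= cfg$discardCoverage,
      logical(1)))
  }, logical(1))
  say("reference_discard: %d of %d ORFs discarded (identity > %.2f, coverage >= %.2f)",
      sum(orfs$discarded), nrow(orfs), cfg$identityDiscard,
      cfg$discardCoverage)

  stage <- "tm_prediction"
  tm <- lapply(orfs$aa_seq, function(aa)
    suppressWarnings(predictTm(aa, cfg$tmWindow, cfg$tmThreshold)))
  names(tm) <- orfs$orf_id
  orfs$has_tm <- vapply(tm, nrow, integer(1)) > 0L
  say("tm_prediction: %d ORFs with >= 1 segment", sum(orfs$has_tm))

  stage <- "mss_detection"
  if (length(cfg$panel) > 0L) {
    mss <- detectMss(cfg$query, cfg$panel, cfg$params, cfg$minMssLen,
                     cfg$mergeGap, cfg$presenceFrac, cfg$identityMin)
    ov <- annotateMssOverlaps(orfs, mss, L)
    orfs$mss_ids <- vapply(ov, paste, character(1), collapse = ",")
    orfs$mss_overlap <- lengths(ov) > 0L
    dup <- findMssDuplicates(mss)
    orfs$mss_duplicated <- vapply(ov, function(ids)
      any(ids %in% dup$id), logical(1))
    say("mss_detection: %d MSSs, %d duplicated", nrow(mssRecords(mss)),
        nrow(dup))
  } else {
    mss <- .emptyMssSet(genomeId(cfg$query))
    orfs$mss_ids <- ""
    orfs$mss_overlap <- FALSE
    orfs$mss_duplicated <- FALSE
    say("mss_detection: skipped (no panel)")
  }

  orfs$candidate <- !orfs$discarded &
    (!cfg$requireTm | orfs$has_tm) &
    (!cfg$requireMssOverlap | orfs$mss_overlap)
  cand <- orfs[orfs$candidate, , drop = FALSE]
  say("screen: %d candidate(s)", nrow(cand))

  stage <- "chimera"
  chim <- list()
  if (!is.null(cfg$parents) && nrow(cand) > 0L) {
    for (i in seq_len(nrow(cand))) {
      chim[[cand$orf_id[i]]] <-
        suppressMessages(decomposeChimera(cand$aa_seq[i], cfg$parents))
    }
    say("chimera: decomposed %d candidate(s) against %d parent(s)",
        nrow(cand), length(cfg$parents))
  }

  provenance <- list(
    package = "MitoCMS", version = as.character(packageVersion("MitoCMS")),
    query = genomeId(cfg$query), reference = genomeId(cfg$reference),
    panel = vapply(cfg$panel, genomeId, character(1)),
    minCodons = cfg$minCodons, identityDiscard = cfg$identityDiscard,
    discardCoverage = cfg$discardCoverage, evalueMax = cfg$evalueMax,
    requireTm = cfg$requireTm, requireMssOverlap = cfg$requireMssOverlap,
    tmWindow = cfg$tmWindow, tmThreshold = cfg$tmThreshold,
    minMssLen = cfg$minMssLen, mergeGap = cfg$mergeGap,
    presenceFrac = cfg$presenceFrac, identityMin = cfg$identityMin,
    align = unclass(cfg$params), seed = cfg$seed,
    expression_filter = "not applied (requires transcript evidence)")

  new("CandidateReport", orfs = orfs, candidates = cand, mss = mss,
      tm = tm, chimera = chim, params = provenance, log = logs)
}

#' Write the screen report files
#'
#' Emits, with stable ordering and no timestamps (a rerun with the same
#' configuration is byte-identical): `orfs.tsv` (all ORFs with flags),
#' `candidates.tsv`, `mss.tsv`, `presence_matrix.tsv` (the
#' machine-readable grey/white presence figure, 0/1 cells),
#' `tm_segments.tsv`, and `report.json` (provenance header plus
#' candidate details).
#'
#' @param report a [CandidateReport-class].
#' @param outdir output directory, created if needed.
#' @return named character vector of file paths, invisibly.
#' @export
renderReports <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2L) != 0L) stop("unwritable directory: ", outdir)
  p <- function(f) file.path(outdir, f)
  orfTab <- function(df) {
    if (nrow(df) == 0L)
      return(data.frame(id = character(), start = integer(),
                        end = integer(), strand = integer(),
                        type = character(), attributes = character()))
    data.frame(id = df$orf_id, start = df$start, end = df$end,
               strand = df$strand, type = "ORF",
               attributes = sprintf(
                 "aa_length=%d;discarded=%s;has_tm=%s;mss=%s;candidate=%s",
                 df$aa_length, df$discarded, df$has_tm, df$mss_ids,
                 df$candidate),
               stringsAsFactors = FALSE)
  }
  writeFeatureTable(orfTab(report@orfs), p("orfs.tsv"))
  writeFeatureTable(orfTab(report@candidates), p("candidates.tsv"))
  rec <- mssRecords(report@mss)
  mssTab <- if (nrow(rec)) data.frame(
    id = rec$id, start = rec$start, end = rec$end, strand = 1L,
    type = "MSS", attributes = sprintf("length=%d;copies=%d",
                                       rec$length, rec$copies),
    stringsAsFactors = FALSE) else NULL
  writeFeatureTable(mssTab, p("mss.tsv"))
  pm <- presenceMatrix(report@mss)
  pmInt <- matrix(as.integer(pm), nrow = nrow(pm), ncol = ncol(pm),
                  dimnames = dimnames(pm))
  pmOut <- cbind(data.frame(id = if (nrow(pm)) rownames(pm) else character(),
                            stringsAsFactors = FALSE),
                 as.data.frame(pmInt, check.names = FALSE))
  write.table(pmOut, p("presence_matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tmRows <- do.call(rbind, lapply(names(report@tm), function(id) {
    s <- report@tm[[id]]
    if (nrow(s) == 0L) return(NULL)
    data.frame(orf_id = id, start = s$start, end = s$end,
               mean_hydropathy = s$mean_hydropathy,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tmRows))
    tmRows <- data.frame(orf_id = character(), start = integer(),
                         end = integer(), mean_hydropathy = numeric())
  write.table(tmRows, p("tm_segments.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  json <- list(
    provenance = report@params,
    log = report@log,
    candidates = if (nrow(report@candidates)) {
      df <- report@candidates
      lapply(seq_len(nrow(df)), function(i) {
        ci <- list(orf_id = df$orf_id[i], start = df$start[i],
                   end = df$end[i], strand = df$strand[i],
                   aa_length = df$aa_length[i],
                   mss = df$mss_ids[i],
                   mss_duplicated = df$mss_duplicated[i],
                   tm_segments = report@tm[[df$orf_id[i]]])
        if (df$orf_id[i] %in% names(report@chimera))
          ci$chimera <- report@chimera[[df$orf_id[i]]]$segments
        ci
      })
    } else list())
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(c(orfs = p("orfs.tsv"), candidates = p("candidates.tsv"),
              mss = p("mss.tsv"),
              presence_matrix = p("presence_matrix.tsv"),
              tm_segments = p("tm_segments.tsv"),
              report = p("report.json")))
}
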