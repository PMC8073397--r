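#' Read mitochondrial genomes from a FASTA file
#'
#' Reads a multi-record FASTA file into a list of [MitoGenome-class]
#' objects. Sequences are uppercased and `U` is converted to `T`; any
#' character outside `A,C,G,T,N` is a format error reported with its
#' position. Record order is preserved; duplicate ids and empty files are
#' errors. Record ids are the first whitespace-delimited token of the
#' header line.
#'
#' @param path path to a FASTA file.
#' @param circular logical, recycled over records; whether each molecule
#'   is circular (plant mitogenomes usually assemble as circles).
#' @return list of [MitoGenome-class] objects, named by id.
#' @seealso [writeGenomeFasta()]
#' @export
readGenomeFasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate id '",
         ids[duplicated(ids)][1], "'")
  circular <- rep_len(circular, length(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    s <- chartr("U", "T", s)
    s <- gsub("[ \t\r\n]", "", s)
    if (!nzchar(s)) stop("FASTA format error: empty sequence for '",
                         ids[i], "'")
    bad <- regexpr("[^ACGTN]", s)
    if (bad > 0)
      stop(sprintf(
        "FASTA format error: illegal character '%s' at position %d of '%s'",
        substr(s, bad, bad), bad, ids[i]))
    out[[i]] <- mitoGenome(ids[i], s, circular[i])
  }
  names(out) <- ids
  out
}

#' Write mitochondrial genomes to FASTA
#'
#' Round-trips with [readGenomeFasta()] on ids and sequence content.
#'
#' @param genomes a [MitoGenome-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genomes, path) {
  if (is(genomes, "MitoGenome")) genomes <- list(genomes)
  seqs <- vapply(genomes, genomeSeq, character(1))
  ids <- vapply(genomes, genomeId, character(1))
  set <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a two-bulk allele-count table
#'
#' Reads the tab-separated per-SNP allele counts for two sequenced bulks
#' (e.g. fertile and sterile pools of a segregating population). Required
#' columns: `chrom`, `pos`, `ref_count_bulk1`, `alt_count_bulk1`,
#' `ref_count_bulk2`, `alt_count_bulk2`. Positions must be strictly
#' increasing within each chromosome and counts non-negative. Rows with
#' zero total depth in either bulk are retained but flagged in the
#' logical columns `zero_depth_bulk1` / `zero_depth_bulk2`.
#'
#' @param path path to a TSV file with a header row.
#' @return `data.frame` with the six required columns (typed) plus the
#'   two zero-depth flags.
#' @export
readAlleleCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref_count_bulk1", "alt_count_bulk1",
            "ref_count_bulk2", "alt_count_bulk2")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("allele-count format error: missing column(s) ",
         paste(miss, collapse = ", "))
  tab <- tab[need]
  for (cc in need[-1]) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v)) stop("allele-count format error: non-numeric '", cc, "'")
    tab[[cc]] <- v
  }
  cnt <- need[3:6]
  if (any(unlist(tab[cnt]) < 0))
    stop("allele-count format error: negative count")
  for (ch in unique(tab$chrom)) {
    p <- tab$pos[tab$chrom == ch]
    if (any(diff(p) <= 0))
      stop("allele-count format error: positions not strictly increasing ",
           "within ", ch)
  }
  tab$zero_depth_bulk1 <- tab$ref_count_bulk1 + tab$alt_count_bulk1 == 0
  tab$zero_depth_bulk2 <- tab$ref_count_bulk2 + tab$alt_count_bulk2 == 0
  tab
}

#' Write a feature table
#'
#' Writes labeled intervals as a TSV with columns `id`, `start`, `end`,
#' `strand`, `type`, `attributes`, 1-based inclusive, ordered stably by
#' `(start, end, id)`. An empty feature set yields a header-only file.
#'
#' @param features `data.frame` with at least `id`, `start`, `end`;
#'   missing `strand`/`type`/`attributes` are filled with `+1` / `""`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  cols <- c("id", "start", "end", "strand", "type", "attributes")
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(id = character(), start = integer(),
                           end = integer(), strand = integer(),
                           type = character(), attributes = character())
  } else {
    if (!all(c("id", "start", "end") %in% names(features)))
      stop("features need columns id, start, end")
    if (is.null(features$strand)) features$strand <- 1L
    if (is.null(features$type)) features$type <- ""
    if (is.null(features$attributes)) features$attributes <- ""
    features <- features[cols]
    o <- order(features$start, features$end, features$id, method = "radix")
    features <- features[o, , drop = FALSE]
  }
  write.table(features, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
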