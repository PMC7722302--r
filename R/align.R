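#' Map small RNA reads to a genome (ungapped, mismatch-tolerant)
#'
#' Finds every ungapped placement of each read on either strand of the
#' genome with at most `max_mismatch` substitutions. `N` in the read or the
#' genome never matches and counts as a mismatch at its position.
#' Mismatches falling in the last two read positions (3'-most, in read
#' orientation) are reported separately as putative non-template 3'
#' additions (`mm_tail3`); all other mismatches are internal
#' (`mm_internal`).
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of read
#'   sequences (5' to 3'). Names become `read_id`; unnamed reads are given
#'   ids `read1, read2, ...`. All reads must be at least
#'   `4 * (max_mismatch + 1)` nt (always satisfied by QC-passed reads of
#'   >= 18 nt at the default).
#' @param genome named character vector or [Biostrings::DNAStringSet] of
#'   contig sequences.
#' @param max_mismatch maximum substitutions allowed per placement
#'   (default 3).
#'
#' @return a `data.frame` with one row per hit: `read_id`, `contig`,
#'   `start` (0-based), `end` (exclusive), `strand` (`"+"`/`"-"`),
#'   `mm_internal`, `mm_tail3`, `mm_total`.
#' @seealso [besthit_filter()]
#' @export
map_reads <- function(reads, genome, max_mismatch = 3) {
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  reads <- toupper(reads)
  genome <- toupper(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  if (length(reads) == 0)
    return(data.frame(read_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), mm_internal = integer(),
                      mm_tail3 = integer(), mm_total = integer(),
                      stringsAsFactors = FALSE))
  lens <- nchar(reads)
  if (any(lens < 4L * (max_mismatch + 1L)))
    stop("reads shorter than 4*(max_mismatch+1) nt are not supported")
  h <- .cpp_map_reads(unname(reads), unname(genome), as.integer(max_mismatch))
  data.frame(read_id = ids[h$read],
             contig = names(genome)[h$contig],
             start = h$start,
             end = h$start + lens[h$read],
             strand = ifelse(h$plus == 1L, "+", "-"),
             mm_internal = h$mm_internal,
             mm_tail3 = h$mm_tail3,
             mm_total = h$mm_total,
             stringsAsFactors = FALSE)
}

#' Best-hit filtering of genomic placements
#'
#' Per read: (1) keep only hits whose total mismatch count equals the
#' read's minimum; (2) among those, discard hits with more than one
#' internal mismatch or more than two non-template 3' nucleotides. Reads
#' whose hits are all discarded become unmapped (no rows returned).
#'
#' @param hits hit table as returned by [map_reads()].
#' @param max_internal maximum internal mismatches per retained hit
#'   (default 1).
#' @param max_tail3 maximum 3'-terminal (non-template) mismatches per
#'   retained hit (default 2).
#' @return the retained subset of `hits`, with an added column `n_hits`
#'   giving each read's number of surviving placements.
#' @export
besthit_filter <- function(hits, max_internal = 1, max_tail3 = 2) {
  if (nrow(hits) == 0) {
    hits$n_hits <- integer(0)
    return(hits)
  }
  best <- stats::ave(hits$mm_total, hits$read_id, FUN = min)
  keep <- hits$mm_total == best &
    hits$mm_internal <= max_internal &
    hits$mm_tail3 <= max_tail3
  out <- hits[keep, , drop = FALSE]
  if (nrow(out)) {
    out$n_hits <- as.integer(stats::ave(rep(1L, nrow(out)), out$read_id,
                                        FUN = sum))
  } else {
    out$n_hits <- integer(0)
  }
  rownames(out) <- NULL
  out
}

# GRanges view of a hit table
hits_granges <- function(hits) {
  GenomicRanges::GRanges(
    seqnames = hits$contig,
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
}

#' Write a hit table as headered TSV
#'
#' @param hits hit table from [map_reads()] or [besthit_filter()].
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
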