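#' Filter raw small RNA reads and collapse to unique sequences
#'
#' Applies the five raw-read filter criteria in a fixed order, attributing
#' each rejected read to its first failing rule:
#'
#' 1. `q10`: more than `max_q10` (default 4) bases with quality below 10;
#' 2. `q13`: more than `max_q13` (default 6) bases with quality below 13;
#' 3. `homopolymer`: a single nucleotide makes up at least
#'    `homopolymer_frac` (default 0.9) of the insert;
#' 4. `adapter5`: the read contains the 5' adapter (first
#'    `adapter_match` bases), when `adapter5` is supplied;
#' 5. `no_adapter3`: no exact match of the first `adapter_match`
#'    (default 8) bases of the 3' adapter anywhere in the read (the
#'    leftmost match defines the insert);
#' 6. `no_insert`: trimmed insert length 0;
#' 7. `too_short`: trimmed insert shorter than `min_length` (default 18 nt).
#'
#' Quality rules are evaluated on the full read; the 3' adapter is trimmed
#' before the length check. Kept reads are collapsed to unique insert
#' sequences with counts.
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 string), e.g. the `reads` element of [simulate_library()] or
#'   the result of [read_fastq()].
#' @param adapter3 3' adapter sequence (required, at least `adapter_match`
#'   nt).
#' @param adapter5 optional 5' adapter sequence; when `NULL` the
#'   `adapter5` rule is skipped.
#' @param max_q10,max_q13 quality rule thresholds (counts of low-quality
#'   bases allowed).
#' @param homopolymer_frac insert fraction of a single nucleotide at or
#'   above which a read is discarded.
#' @param adapter_match number of adapter prefix bases requiring an exact
#'   match.
#' @param min_length minimum insert length after trimming.
#' @return a list of class `filter_result`:
#'   * `kept`: data.frame `seq_id` (`seq{i}_x{count}`), `sequence`, `count`,
#'     `length` of collapsed unique inserts, ordered by decreasing count;
#'   * `read_ids`: list mapping each kept sequence to its source read ids;
#'   * `report`: list with `input_count`, `kept_count` and `rejected`
#'     (named counts per rule). `kept_count + sum(rejected)` always equals
#'     `input_count`.
#' @export
filter_reads <- function(reads, adapter3, adapter5 = NULL,
                         max_q10 = 4, max_q13 = 6, homopolymer_frac = 0.9,
                         adapter_match = 8, min_length = 18) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  adapter3 <- toupper(adapter3)
  if (nchar(adapter3) < adapter_match)
    stop("adapter3 must supply at least ", adapter_match, " bases")
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len))
    stop("sequence/quality length mismatch for read ",
         reads$read_id[which(bad_len)[1]])

  rules <- c("q10", "q13", "homopolymer", "adapter5", "no_adapter3",
             "no_insert", "too_short")
  n <- nrow(reads)
  if (n == 0) {
    return(structure(list(
      kept = data.frame(seq_id = character(0), sequence = character(0),
                        count = integer(0), length = integer(0),
                        stringsAsFactors = FALSE),
      read_ids = list(),
      report = list(input_count = 0L, kept_count = 0L,
                    rejected = setNames(rep(0L, length(rules)), rules))),
      class = "filter_result"))
  }

  seqs <- toupper(reads$sequence)
  quals <- lapply(reads$quality, function(q) utf8ToInt(q) - 33L)

  n_below <- function(cut) vapply(quals, function(q) sum(q < cut), 0L)
  fail <- matrix(FALSE, n, length(rules), dimnames = list(NULL, rules))
  fail[, "q10"] <- n_below(10L) > max_q10
  fail[, "q13"] <- n_below(13L) > max_q13

  # locate the 3' adapter: leftmost exact match of its first
  # adapter_match bases; insert = read prefix before the match
  a3 <- substr(adapter3, 1, adapter_match)
  m <- regexpr(a3, seqs, fixed = TRUE)
  has_a3 <- m > 0L
  insert <- ifelse(has_a3, substr(seqs, 1L, m - 1L), seqs)
  ilen <- nchar(insert)

  nz <- ilen > 0L
  homop <- rep(FALSE, n)
  if (any(nz)) {
    f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(insert[nz]),
                                     DNA)
    homop[nz] <- apply(f, 1, max) / ilen[nz] >= homopolymer_frac
  }
  fail[, "homopolymer"] <- homop

  if (!is.null(adapter5)) {
    adapter5 <- toupper(adapter5)
    if (nchar(adapter5) < adapter_match)
      stop("adapter5 must supply at least ", adapter_match, " bases")
    a5 <- substr(adapter5, 1, adapter_match)
    fail[, "adapter5"] <- grepl(a5, seqs, fixed = TRUE)
  }
  fail[, "no_adapter3"] <- !has_a3
  fail[, "no_insert"] <- has_a3 & ilen == 0L
  fail[, "too_short"] <- has_a3 & ilen > 0L & ilen < min_length

  # first-failing-rule attribution
  first_fail <- apply(fail, 1, function(x) {
    w <- which(x)
    if (length(w)) w[1] else 0L
  })
  rejected <- setNames(
    vapply(seq_along(rules), function(r) sum(first_fail == r), 0L), rules)
  keep <- first_fail == 0L

  kept_ins <- insert[keep]
  kept_ids <- reads$read_id[keep]
  tab <- sort(table(kept_ins), decreasing = TRUE)
  kept <- data.frame(
    sequence = names(tab), count = as.integer(tab),
    stringsAsFactors = FALSE)
  kept$length <- nchar(kept$sequence)
  kept$seq_id <- sprintf("seq%d_x%d", seq_len(nrow(kept)), kept$count)
  kept <- kept[, c("seq_id", "sequence", "count", "length")]
  read_ids <- split(kept_ids, factor(kept_ins, levels = names(tab)))
  names(read_ids) <- kept$seq_id

  structure(list(kept = kept, read_ids = read_ids,
                 report = list(input_count = n,
                               kept_count = as.integer(sum(keep)),
                               rejected = rejected)),
            class = "filter_result")
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file, optionally gzipped.
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = unname(as.character(x)),
             quality = unname(as.character(S4Vectors::mcols(x)$qualities)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a simulated library to FASTQ (and its truth labels to TSV)
#'
#' @param sim a `synthetic_library` from [simulate_library()].
#' @param fastq_path output FASTQ path; a `.gz` suffix triggers gzip
#'   compression.
#' @param truth_path optional TSV path for the per-read truth labels.
#' @return `fastq_path`, invisibly.
#' @export
write_library <- function(sim, fastq_path, truth_path = NULL) {
  stopifnot(inherits(sim, "synthetic_library"))
  x <- Biostrings::DNAStringSet(sim$reads$sequence)
  names(x) <- sim$reads$read_id
  q <- Biostrings::BStringSet(sim$reads$quality)
  Biostrings::writeXStringSet(
    x, fastq_path, format = "fastq", qualities = q,
    compress = grepl("\\.gz$", fastq_path))
  if (!is.null(truth_path))
    write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fastq_path)
}

#' Write collapsed kept reads as FASTA
#'
#' Headers follow the `>seq{i}_x{count}` convention.
#'
#' @param filtered a `filter_result` from [filter_reads()].
#' @param path output FASTA path.
#' @export
write_collapsed_fasta <- function(filtered, path) {
  stopifnot(inherits(filtered, "filter_result"))
  x <- Biostrings::DNAStringSet(filtered$kept$sequence)
  names(x) <- filtered$kept$seq_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a filter report as JSON
#'
#' @param filtered a `filter_result` from [filter_reads()].
#' @param path output JSON path.
#' @export
write_filter_report <- function(filtered, path) {
  stopifnot(inherits(filtered, "filter_result"))
  jsonlite::write_json(filtered$report, path, auto_unbox = TRUE)
  invisible(path)
}
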