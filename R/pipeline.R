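#' Run the small RNA profiling pipeline on one library
#'
#' Convenience wrapper chaining the stages: QC filtering and collapsing
#' ([filter_reads()]), genome mapping and best-hit filtering
#' ([map_reads()], [besthit_filter()]), the annotation cascade
#' ([classify_reads()]) with class fractions and repeat orientation
#' accounting, and the piRNA diagnostics (candidate selection, 5' U
#' fraction and ping-pong profile on the unannotated candidate fraction,
#' cluster prediction on all candidates).
#'
#' @param reads read table (`read_id`, `sequence`, `quality`), e.g. from
#'   [simulate_library()] or [read_fastq()].
#' @param genome `DNAStringSet` of the genome.
#' @param refs a [reference_set()].
#' @param adapter3,adapter5 adapter sequences for [filter_reads()].
#' @param max_mismatch mapping mismatch budget (default 3).
#' @param pimax maximum piRNA length for cluster prediction (default 35).
#' @return a list with elements `filter` (filter_result), `hits`
#'   (best-hit table), `classified`, `counts` (per collapsed sequence),
#'   `fractions`, `length_profile`, `repeat_orientation`, `candidates`
#'   (read ids), `u1` (5' U share of unannotated candidates), `pingpong`
#'   (profile on unannotated candidates), `clusters` (GRanges).
#' @export
profile_library <- function(reads, genome, refs,
                            adapter3, adapter5 = NULL,
                            max_mismatch = 3, pimax = 35) {
  flt <- filter_reads(reads, adapter3 = adapter3, adapter5 = adapter5)
  seqs <- setNames(flt$kept$sequence, flt$kept$seq_id)
  counts <- setNames(flt$kept$count, flt$kept$seq_id)
  hits <- besthit_filter(map_reads(seqs, genome, max_mismatch))
  classified <- classify_reads(hits, refs)
  cand <- select_candidates(classified, max_len = pimax)
  none_cand <- intersect(cand,
                         classified$read_id[classified$major == "none"])
  cand_hits <- hits[hits$read_id %in% cand, , drop = FALSE]
  none_hits <- hits[hits$read_id %in% none_cand, , drop = FALSE]
  clusters <- predict_clusters(cand_hits, seqs, counts, pimax = pimax)
  list(filter = flt,
       hits = hits,
       classified = classified,
       counts = counts,
       fractions = class_fractions(classified, counts),
       length_profile = length_profile(classified, counts),
       repeat_orientation = repeat_orientation_counts(hits, classified,
                                                      refs, counts),
       candidates = cand,
       u1 = u1_fraction(seqs[none_cand], counts[none_cand]),
       pingpong = pingpong_profile(none_hits, counts),
       pingpong_matrix = pingpong_matrix(none_hits, counts),
       clusters = clusters,
       cluster_share = cluster_share(cand_hits, clusters, genome, counts))
}
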