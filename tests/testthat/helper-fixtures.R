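# small shared fixtures built in code

tiny_genome <- function(seed = 7, ...) {
  build_genome(genome_spec(contig_count = 1, contig_length = 30000,
                           mirna_hairpin_count = 3, trna_count = 2,
                           rrna_count = 1, mrna_count = 2,
                           repeat_family_count = 2, repeat_copies = 3,
                           pirna_cluster_count = 1,
                           pirna_cluster_length = 3000,
                           rng_seed = seed, ...))
}

# a cluster-only genome for piRNA statistics runs
cluster_genome <- function(seed = 3) {
  build_genome(genome_spec(contig_count = 1, contig_length = 12000,
                           mirna_hairpin_count = 0, trna_count = 0,
                           rrna_count = 0, mrna_count = 0,
                           repeat_family_count = 0, repeat_copies = 0,
                           pirna_cluster_count = 1,
                           pirna_cluster_length = 5000,
                           rng_seed = seed))
}

pirna_only_mix <- c(miRNA = 0, tRF = 0, rRF = 0, mRNA = 0, "repeat" = 0,
                    piRNA = 1)

# hit table straight from truth coordinates (each simulated read placed at
# its origin); independent of the mapper
truth_hits <- function(sim) {
  t <- sim$truth[sim$truth$class != "artifact", , drop = FALSE]
  data.frame(read_id = t$read_id, contig = t$contig, start = t$start,
             end = t$end, strand = t$strand, mm_internal = 0L,
             mm_tail3 = 0L, mm_total = 0L, n_hits = 1L,
             stringsAsFactors = FALSE)
}

unit_counts <- function(hits) {
  ids <- unique(hits$read_id)
  setNames(rep(1, length(ids)), ids)
}

# map collapsed kept sequences back to per-read truth classes
truth_vs_label <- function(sim, flt, classified) {
  seq_of_read <- rep(names(flt$read_ids), lengths(flt$read_ids))
  names(seq_of_read) <- unlist(flt$read_ids)
  tr <- sim$truth[sim$truth$class != "artifact", , drop = FALSE]
  expected <- c(miRNA = "miRNA", tRF = "tRF", rRF = "rRF", mRNA = "mRNA",
                "repeat" = "repeat", piRNA = "none")[tr$class]
  observed <- classified$major[match(seq_of_read[tr$read_id],
                                     classified$read_id)]
  data.frame(truth = tr$class, expected = expected, observed = observed,
             stringsAsFactors = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# insert portion (adapter stripped) of each simulated read, via truth length
sub_adapter <- function(sim) {
  len <- sim$truth$length[match(sim$reads$read_id, sim$truth$read_id)]
  substr(sim$reads$sequence, 1, len)
}
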