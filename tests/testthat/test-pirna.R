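mk_hit <- function(id, start, end, strand = "+", contig = "chr",
                   n_hits = 1L) {
  data.frame(read_id = id, contig = contig, start = start, end = end,
             strand = strand, mm_internal = 0L, mm_tail3 = 0L,
             mm_total = 0L, n_hits = n_hits, stringsAsFactors = FALSE)
}

test_that("candidate selection excludes annotated reads and short/long reads", {
  cl <- data.frame(
    read_id = c("mi", "pi", "rep", "short", "long"),
    major = c("miRNA", "none", "repeat", "none", "none"),
    length = c(22L, 32L, 30L, 23L, 36L),
    stringsAsFactors = FALSE)
  expect_setequal(select_candidates(cl), c("pi", "rep"))
})

test_that("u1_fraction is the count-weighted 5' T share", {
  expect_equal(u1_fraction(c("TAA", "TCC")), 1)
  expect_equal(u1_fraction(c("TAA", "GCC"), counts = c(3, 1)), 0.75)
})

test_that("single-strand data gives a zero profile with undefined background", {
  h <- rbind(mk_hit("a", 100, 130), mk_hit("b", 109, 139))
  pp <- pingpong_profile(h)
  expect_true(all(pp$mass == 0))
  expect_true(pp$undefined_background)
  expect_true(all(pp$z == 0))
})

test_that("a constructed 6-read case matches the all-pairs oracle", {
  # plus 5' ends at 10 (x2 reads), 40; minus 5' ends at 19, 49, 20
  h <- rbind(mk_hit("p1", 10, 40), mk_hit("p2", 10, 42),
             mk_hit("p3", 40, 70),
             mk_hit("m1", 0, 20, "-"), mk_hit("m2", 20, 50, "-"),
             mk_hit("m3", 0, 21, "-"))
  counts <- c(p1 = 2, p2 = 1, p3 = 1, m1 = 1, m2 = 3, m3 = 2)
  pp <- pingpong_profile(h, counts)
  expect_equal(pp$mass, oracle_pingpong(h, counts))
  # overlap 10: plus@10 (mass 3) x minus@19 (mass 1), plus@40 x minus@49 (3)
  expect_equal(pp$mass[10], 3 * 1 + 1 * 3)
  # overlap 11: plus@10 (mass 3) x minus@20 (mass 2)
  expect_equal(pp$mass[11], 6)
})

test_that("profile mass equals the brute-force oracle on a simulated library", {
  g <- cluster_genome()
  sim <- simulate_library(g, library_spec(total_reads = 800,
                                          class_mix = pirna_only_mix,
                                          pingpong_fraction = 0.3,
                                          rng_seed = 31))
  h <- truth_hits(sim)
  counts <- unit_counts(h)
  pp <- pingpong_profile(h, counts)
  expect_equal(pp$mass, oracle_pingpong(h, counts))
  expect_equal(which.max(pp$z), 10L)
  expect_gt(pp$z[10], 3.3)
})

test_that("the ping-pong matrix is zero without 10-nt pairs and symmetric with them", {
  h0 <- rbind(mk_hit("a", 100, 131), mk_hit("b", 120, 152, "-"))
  expect_true(all(pingpong_matrix(h0) == 0))
  # planted 31/32 pair: plus read 31 nt with 5' at 100, minus read 32 nt
  # with 5' at 109
  h <- rbind(mk_hit("a", 100, 131), mk_hit("b", 78, 110, "-"))
  m <- pingpong_matrix(h)
  expect_equal(m["31", "32"], 1)
  expect_equal(m["32", "31"], 1)
  expect_equal(sum(m), 2)
  expect_equal(m, t(m))
})

test_that("clusters are recovered on planted loci and absent elsewhere", {
  g <- build_genome(genome_spec(contig_count = 2, contig_length = 20000,
                                mirna_hairpin_count = 0, trna_count = 0,
                                rrna_count = 0, mrna_count = 0,
                                repeat_family_count = 0, repeat_copies = 0,
                                pirna_cluster_count = 1,
                                pirna_cluster_length = 5000, rng_seed = 37))
  sim <- simulate_library(g, library_spec(total_reads = 500,
                                          class_mix = pirna_only_mix,
                                          rng_seed = 37))
  h <- truth_hits(sim)
  seqs <- setNames(sub_adapter(sim), sim$reads$read_id)
  clu <- predict_clusters(h, seqs)
  expect_equal(length(clu), 1L)
  truth <- g$features[g$features$class == "pirna_cluster"]
  expect_equal(as.character(GenomicRanges::seqnames(clu)),
               as.character(GenomicRanges::seqnames(truth)))
  j <- interval_jaccard(GenomicRanges::start(clu), GenomicRanges::end(clu),
                        GenomicRanges::start(truth),
                        GenomicRanges::end(truth))
  expect_gte(j, 0.9)
  expect_gte(clu$u1_fraction, 0.5)
})

test_that("cluster prediction is invariant to read input order", {
  g <- cluster_genome()
  sim <- simulate_library(g, library_spec(total_reads = 400,
                                          class_mix = pirna_only_mix,
                                          rng_seed = 41))
  h <- truth_hits(sim)
  seqs <- setNames(sub_adapter(sim), sim$reads$read_id)
  c1 <- predict_clusters(h, seqs)
  set.seed(1)
  c2 <- predict_clusters(h[sample.int(nrow(h)), ], seqs)
  expect_equal(granges_df(c1), granges_df(c2))
})

test_that("merging cluster lists equals the sweep-line union oracle", {
  g1 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(1, 500), c(400, 900)))
  g2 <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(350, 2000), c(600, 2400)))
  g3 <- GenomicRanges::GRanges("c2", IRanges::IRanges(10, 50))
  # identical lists are unchanged
  expect_equal(granges_df(merge_clusters(list(g3, g3))), granges_df(g3))
  # disjoint lists concatenate
  expect_equal(granges_df(merge_clusters(list(g1[1], g3))),
               rbind(granges_df(g1[1]), granges_df(g3)))
  # staggered overlaps follow the sweep-line union
  merged <- merge_clusters(list(g1, g2, g3))
  want <- oracle_sweep_union(rbind(granges_df(g1), granges_df(g2),
                                   granges_df(g3)))
  got <- granges_df(merged)
  rownames(want) <- rownames(got) <- NULL
  expect_equal(got, want)
  # idempotent and commutative
  expect_equal(granges_df(merge_clusters(list(merged))), got)
  expect_equal(granges_df(merge_clusters(list(g2, g3, g1))), got)
})

test_that("cluster_share reports read and genome fractions", {
  expect_equal(
    unname(cluster_share(mk_hit("a", 10, 42), GenomicRanges::GRanges(),
                         c(chr = strrep("A", 1000)))),
    c(0, 0))
  # all reads inside one cluster covering 1% of the genome
  h <- rbind(mk_hit("a", 100, 132), mk_hit("b", 150, 181))
  clu <- GenomicRanges::GRanges("chr", IRanges::IRanges(91, 190))
  cs <- cluster_share(h, clu, setNames(10000, "chr"))
  expect_equal(cs[["pirna_fraction_in_clusters"]], 1)
  expect_equal(cs[["genome_fraction_covered"]], 0.01)
})
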