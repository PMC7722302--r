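test_that("a featureless spec yields a plain random genome with empty annotation", {
  spec <- genome_spec(contig_count = 2, contig_length = 5000,
                      mirna_hairpin_count = 0, trna_count = 0,
                      rrna_count = 0, mrna_count = 0,
                      repeat_family_count = 0, repeat_copies = 0,
                      pirna_cluster_count = 0, rng_seed = 1)
  g <- build_genome(spec)
  expect_length(g$features, 0)
  expect_equal(Biostrings::width(g$genome), c(5000, 5000))
})

test_that("genome building is deterministic for a fixed seed", {
  g1 <- tiny_genome(seed = 42)
  g2 <- tiny_genome(seed = 42)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(g1$features), as.data.frame(g2$features))
  g3 <- tiny_genome(seed = 43)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("planted features are complete and non-overlapping", {
  g <- build_genome(genome_spec(contig_count = 1, contig_length = 100000,
                                mirna_hairpin_count = 10, trna_count = 5,
                                rrna_count = 0, mrna_count = 0,
                                repeat_family_count = 0, repeat_copies = 0,
                                pirna_cluster_count = 3,
                                pirna_cluster_length = 5000, rng_seed = 5))
  f <- g$features[g$features$class != "utr3"]
  expect_length(f, 18)
  # interval-overlap oracle: sort by start, assert each start > previous end
  df <- data.frame(start = GenomicRanges::start(f),
                   end = GenomicRanges::end(f))
  df <- df[order(df$start), ]
  expect_true(all(df$start[-1] > df$end[-nrow(df)]))
})

test_that("requesting more features than fit raises a sizing error", {
  expect_error(build_genome(genome_spec(contig_count = 1,
                                        contig_length = 3000,
                                        pirna_cluster_count = 2,
                                        pirna_cluster_length = 5000)),
               "deficit")
})

test_that("library simulation is deterministic and byte-stable", {
  g <- tiny_genome()
  lib <- library_spec(total_reads = 500, rng_seed = 9)
  s1 <- simulate_library(g, lib)
  s2 <- simulate_library(g, lib)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_library(s1, f1); write_library(s2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("an empty library gives empty FASTQ and truth", {
  g <- tiny_genome()
  s <- simulate_library(g, library_spec(total_reads = 0))
  expect_equal(nrow(s$reads), 0)
  expect_equal(nrow(s$truth), 0)
})

test_that("u1_fraction = 1 forces 5' T on every piRNA read", {
  g <- cluster_genome()
  s <- simulate_library(g, library_spec(total_reads = 2000,
                                        class_mix = pirna_only_mix,
                                        u1_fraction = 1,
                                        pingpong_fraction = 0.3,
                                        rng_seed = 2))
  first <- substr(sub_adapter(s), 1, 1)
  expect_true(all(first == "T"))
})

test_that("class composition matches the mix within 3 binomial sigma", {
  g <- tiny_genome()
  lib <- library_spec(total_reads = 20000, rng_seed = 21)
  s <- simulate_library(g, lib)
  tab <- table(s$truth$class)
  for (cl in names(lib$class_mix)) {
    p <- lib$class_mix[[cl]]
    expect_lt(abs(tab[[cl]] - 20000 * p), 3 * sqrt(20000 * p * (1 - p)))
  }
})

test_that("nonzero mix for a class absent from the truth errors", {
  g <- cluster_genome()
  expect_error(simulate_library(g, library_spec(total_reads = 10)),
               "absent")
})

test_that("every genuine read's origin lies inside a feature of its class", {
  g <- tiny_genome()
  s <- simulate_library(g, library_spec(total_reads = 4000, rng_seed = 5))
  t <- s$truth[s$truth$class != "artifact", ]
  f <- g$features
  fidx <- match(t$feature_id, f$feature_id)
  expect_false(anyNA(fidx))
  fs <- GenomicRanges::start(f)[fidx] - 1L
  fe <- GenomicRanges::end(f)[fidx]
  expect_true(all(t$start >= fs & t$end <= fe))
  # and the feature class corresponds to the read class
  cls_map <- c(miRNA = "mirna_hairpin", tRF = "trna", rRF = "rrna",
               mRNA = "mrna", "repeat" = "repeat", piRNA = "pirna_cluster")
  expect_true(all(f$class[fidx] == cls_map[t$class]))
})

test_that("ping-pong pairs overlap by exactly 10 nt at their 5' ends", {
  g <- cluster_genome()
  s <- simulate_library(g, library_spec(total_reads = 1000,
                                        class_mix = pirna_only_mix,
                                        pingpong_fraction = 0.5,
                                        rng_seed = 4))
  t <- s$truth
  prim <- t[t$subtype == "pingpong_primary", ]
  sec <- t[t$subtype == "pingpong_secondary", ]
  expect_equal(nrow(prim), nrow(sec))
  expect_gt(nrow(prim), 100)
  # simulate_library shuffles reads, so pairing order is lost; verify the
  # 5'-position multisets instead: each primary 5' end p has a secondary
  # partner whose 5' end sits at p + 9
  expect_equal(sort(prim$start + 9L), sort(sec$end - 1L))
})

test_that("5' tRFs share the mature tRNA 5' terminus", {
  g <- tiny_genome()
  s <- simulate_library(g, library_spec(
    total_reads = 2000,
    class_mix = c(miRNA = 0, tRF = 1, rRF = 0, mRNA = 0, "repeat" = 0,
                  piRNA = 0),
    trf_type_mix = c(trf5 = 1, trf3 = 0, other = 0), rng_seed = 6))
  t <- s$truth
  f <- g$features
  fidx <- match(t$feature_id, f$feature_id)
  five <- ifelse(as.character(GenomicRanges::strand(f))[fidx] == "+",
                 GenomicRanges::start(f)[fidx] - 1L,
                 GenomicRanges::end(f)[fidx] - 1L)
  read5 <- ifelse(t$strand == "+", t$start, t$end - 1L)
  expect_true(all(read5 == five))
})

test_that("genome and library exporters write the documented formats", {
  g <- tiny_genome()
  d <- file.path(tempdir(), "synthout")
  write_genome(g, d)
  fa <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(as.character(fa), as.character(g$genome))
  bed <- read.table(file.path(d, "features.bed"), sep = "\t")
  expect_equal(nrow(bed), length(g$features))
  expect_equal(bed$V3 - bed$V2, GenomicRanges::width(g$features))
  expect_true(all(bed$V6 %in% c("+", "-", ".")))
  hp <- Biostrings::readDNAStringSet(file.path(d, "hairpins.fa"))
  expect_equal(length(hp), sum(g$features$class == "mirna_hairpin"))
  mr <- Biostrings::readDNAStringSet(file.path(d, "mrna.fa"))
  expect_true(all(grepl("utr3=401-600", names(mr))))

  sim <- simulate_library(g, library_spec(total_reads = 200, rng_seed = 8))
  fq <- file.path(d, "lib.fastq.gz")
  tsv <- file.path(d, "truth.tsv")
  write_library(sim, fq, tsv)
  back <- read_fastq(fq)
  expect_equal(back, sim$reads)
  truth <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(truth), 200)
})
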