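#' Specification of a synthetic toy genome
#'
#' Describes a random genome with planted small-RNA source features:
#' miRNA hairpins (22-nt arms, 15-nt loop, the 3' arm a reverse complement
#' of the 5' arm carrying 3 interior substitutions so the two arms are
#' distinguishable by an ungapped mapper), mature tRNAs (72 nt), rRNAs
#' (120 nt), mRNAs (600 nt, the final 200 nt annotated as 3' UTR),
#' multi-copy repeat families (200-nt consensus, copies planted in both
#' orientations; the last family is recorded with unknown orientation) and
#' intergenic piRNA clusters. Planted features never overlap and every
#' feature is recorded in the truth annotation.
#'
#' @param contig_count,contig_length number and length (nt) of contigs.
#' @param mirna_hairpin_count,trna_count,rrna_count,mrna_count number of
#'   planted features of each class (across all contigs).
#' @param repeat_family_count,repeat_copies repeat families and copies per
#'   family.
#' @param pirna_cluster_count,pirna_cluster_length intergenic piRNA
#'   cluster loci and their length (nt).
#' @param rng_seed integer seed; identical specs give byte-identical
#'   genomes and annotations.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(contig_count = 2, contig_length = 50000,
                        mirna_hairpin_count = 8, trna_count = 6,
                        rrna_count = 2, mrna_count = 6,
                        repeat_family_count = 3, repeat_copies = 5,
                        pirna_cluster_count = 2, pirna_cluster_length = 5000,
                        rng_seed = 1) {
  spec <- list(contig_count = as.integer(contig_count),
               contig_length = as.integer(contig_length),
               mirna_hairpin_count = as.integer(mirna_hairpin_count),
               trna_count = as.integer(trna_count),
               rrna_count = as.integer(rrna_count),
               mrna_count = as.integer(mrna_count),
               repeat_family_count = as.integer(repeat_family_count),
               repeat_copies = as.integer(repeat_copies),
               pirna_cluster_count = as.integer(pirna_cluster_count),
               pirna_cluster_length = as.integer(pirna_cluster_length),
               rng_seed = as.integer(rng_seed))
  counts <- unlist(spec[3:10])
  if (any(counts < 0) || spec$contig_count < 1 || spec$contig_length < 1)
    stop("all genome_spec counts must be >= 0 and dimensions positive")
  structure(spec, class = "genome_spec")
}

HAIRPIN_ARM <- 22L
HAIRPIN_LOOP <- 15L
HAIRPIN_LEN <- 2L * HAIRPIN_ARM + HAIRPIN_LOOP # 59
TRNA_LEN <- 72L
RRNA_LEN <- 120L
MRNA_LEN <- 600L
UTR3_LEN <- 200L
REPEAT_LEN <- 200L

random_dna <- function(n) {
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

# non-overlapping 1-based start positions for features of the given widths
# on a contig of length len; min_gap exceeds the read-clustering distance
# used downstream so planted features produce unambiguous, separable loci
place_intervals <- function(len, widths, min_gap = 250L) {
  n <- length(widths)
  if (n == 0) return(integer(0))
  need <- sum(widths) + min_gap * (n + 1L)
  if (need > len)
    stop(sprintf(
      "contig too short to host requested features: need %d nt, have %d (deficit %d nt)",
      need, len, need - len))
  extra <- len - need
  props <- diff(sort(c(0, runif(n), 1)))[seq_len(n)]
  gaps <- min_gap + floor(props * extra)
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + widths[i]
  }
  starts
}

#' Build a synthetic genome with planted features and truth annotation
#'
#' @param spec a [genome_spec()].
#' @return a list of class `synthetic_genome` with elements
#'   * `genome`: [Biostrings::DNAStringSet] of contigs,
#'   * `features`: [GenomicRanges::GRanges] truth annotation with metadata
#'     columns `feature_id`, `class` (one of `mirna_hairpin`, `trna`,
#'     `rrna`, `mrna`, `utr3`, `repeat`, `pirna_cluster`), `family` and
#'     `orientation` (repeats), and 0-based half-open mature/star arm
#'     coordinates (`mature_start`, `mature_end`, `star_start`,
#'     `star_end`) for hairpins,
#'   * `spec`: the input spec.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$rng_seed, build_genome_impl(spec))
}

build_genome_impl <- function(spec) {
  feats <- data.frame(class = character(0), width = integer(0),
                      family = character(0), stringsAsFactors = FALSE)
  add <- function(class, n, width, family = NA_character_) {
    if (n > 0)
      feats <<- rbind(feats, data.frame(
        class = class, width = width,
        family = if (length(family) == 1) rep(family, n) else family,
        stringsAsFactors = FALSE))
  }
  # the hairpin feature interval includes the 2-nt 3' overhang template of
  # the star read, as miRNA precursor annotations do
  add("mirna_hairpin", spec$mirna_hairpin_count, HAIRPIN_LEN + 2L)
  add("trna", spec$trna_count, TRNA_LEN)
  add("rrna", spec$rrna_count, RRNA_LEN)
  add("mrna", spec$mrna_count, MRNA_LEN)
  if (spec$repeat_family_count > 0 && spec$repeat_copies > 0) {
    fam <- rep(paste0("repfam", seq_len(spec$repeat_family_count)),
               each = spec$repeat_copies)
    add("repeat", length(fam), REPEAT_LEN, fam)
  }
  add("pirna_cluster", spec$pirna_cluster_count, spec$pirna_cluster_length)

  contigs <- vapply(seq_len(spec$contig_count),
                    function(i) random_dna(spec$contig_length), "")
  names(contigs) <- paste0("contig", seq_len(spec$contig_count))

  if (nrow(feats) == 0) {
    return(structure(list(genome = Biostrings::DNAStringSet(contigs),
                          features = GenomicRanges::GRanges(),
                          spec = spec),
                     class = "synthetic_genome"))
  }

  # spread features over contigs round-robin, shuffled within contig
  feats <- feats[sample.int(nrow(feats)), , drop = FALSE]
  feats$contig <- names(contigs)[1L + (seq_len(nrow(feats)) - 1L) %%
                                   spec$contig_count]
  feats$start <- NA_integer_
  for (ct in names(contigs)) {
    i <- which(feats$contig == ct)
    if (length(i))
      feats$start[i] <- place_intervals(spec$contig_length, feats$width[i])
  }
  feats$end <- feats$start + feats$width - 1L
  feats$strand <- "+"
  feats$orientation <- NA_character_
  feats$mature_start <- NA_integer_; feats$mature_end <- NA_integer_
  feats$star_start <- NA_integer_; feats$star_end <- NA_integer_

  cseq <- lapply(contigs, function(s) strsplit(s, "")[[1]])

  consensus <- lapply(seq_len(spec$repeat_family_count),
                      function(i) strsplit(random_dna(REPEAT_LEN), "")[[1]])
  unknown_family <- if (spec$repeat_family_count > 0)
    paste0("repfam", spec$repeat_family_count) else NA_character_
  fam_seen <- integer(0)

  counters <- c(mirna_hairpin = 0L, trna = 0L, rrna = 0L, mrna = 0L,
                "repeat" = 0L, pirna_cluster = 0L)
  feats$feature_id <- NA_character_

  for (i in seq_len(nrow(feats))) {
    cls <- feats$class[i]
    counters[cls] <- counters[cls] + 1L
    ct <- feats$contig[i]
    a <- feats$start[i]
    if (cls == "mirna_hairpin") {
      feats$feature_id[i] <- paste0("mir", counters[cls])
      arm1 <- cseq[[ct]][a:(a + HAIRPIN_ARM - 1L)]
      arm2 <- rev(chartr("ACGT", "TGCA", arm1))
      mut <- sample(6:18, 3) # interior positions of the 3' arm (1-based)
      for (m in mut) arm2[m] <- sample(setdiff(DNA, arm2[m]), 1)
      b1 <- a + HAIRPIN_ARM + HAIRPIN_LOOP
      cseq[[ct]][b1:(b1 + HAIRPIN_ARM - 1L)] <- arm2
      # 0-based half-open read-producing arms; the star read carries the
      # canonical 2-nt 3' overhang of the miRNA/miRNA* duplex, extending
      # 2 nt past the hairpin interval
      feats$mature_start[i] <- a - 1L
      feats$mature_end[i] <- a - 1L + HAIRPIN_ARM
      b2 <- b1 + HAIRPIN_ARM # 1-based position just past the 3' arm
      feats$star_start[i] <- feats$mature_start[i] + (b2 - 1L) + 2L -
        feats$mature_end[i]
      feats$star_end[i] <- (b2 - 1L) + 2L
    } else if (cls == "trna") {
      feats$feature_id[i] <- paste0("trna", counters[cls])
      feats$strand[i] <- if (counters[cls] %% 2L == 0L) "-" else "+"
    } else if (cls == "rrna") {
      feats$feature_id[i] <- paste0("rrna", counters[cls])
    } else if (cls == "mrna") {
      feats$feature_id[i] <- paste0("mrna", counters[cls])
    } else if (cls == "repeat") {
      fam <- feats$family[i]
      fidx <- as.integer(sub("repfam", "", fam))
      k <- (fam_seen[fam] <- if (is.na(fam_seen[fam])) 1L else
        fam_seen[[fam]] + 1L)
      ori <- if (k %% 2L == 0L) "-" else "+"
      copy <- consensus[[fidx]]
      if (ori == "-") copy <- rev(chartr("ACGT", "TGCA", copy))
      cseq[[ct]][a:(a + REPEAT_LEN - 1L)] <- copy
      feats$strand[i] <- ori
      feats$orientation[i] <-
        if (identical(fam, unknown_family)) "unknown" else ori
      feats$feature_id[i] <- paste0(fam, "_c", k)
    } else if (cls == "pirna_cluster") {
      feats$feature_id[i] <- paste0("cluster", counters[cls])
    }
  }

  # 3' UTR sub-intervals of mRNAs as separate truth rows
  m <- feats[feats$class == "mrna", , drop = FALSE]
  if (nrow(m)) {
    u <- m
    u$class <- "utr3"
    u$start <- m$end - UTR3_LEN + 1L
    u$feature_id <- sub("^mrna", "utr3_", m$feature_id)
    u$family <- m$feature_id
    feats <- rbind(feats, u)
  }

  contigs <- vapply(cseq, paste, "", collapse = "")
  gr <- GenomicRanges::GRanges(
    seqnames = factor(feats$contig, levels = names(contigs)),
    ranges = IRanges::IRanges(start = feats$start, end = feats$end),
    strand = feats$strand,
    feature_id = feats$feature_id, class = feats$class,
    family = feats$family, orientation = feats$orientation,
    mature_start = feats$mature_start, mature_end = feats$mature_end,
    star_start = feats$star_start, star_end = feats$star_end)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  structure(list(genome = Biostrings::DNAStringSet(contigs),
                 features = gr, spec = spec),
            class = "synthetic_genome")
}

#' Specification of a synthetic small-RNA library
#'
#' Defines the statistical structure of one sequencing library: total read
#' count, class composition, the 5'-uridine fraction and ping-pong pair
#' fraction of piRNA reads, the antisense:sense ratio of repeat-derived
#' reads, per-class read length distributions, and the rates at which
#' quality-control artifacts of each kind are added. Defaults reflect the
#' library structure of a planarian head-regeneration small RNA dataset:
#' two length peaks near 22 nt (miRNA) and 32/33 nt (piRNA/tRF), about
#' 77.5 percent 5' uridine among piRNAs, and a 2.45-fold antisense excess
#' among repeat-derived reads.
#'
#' Ping-pong secondary reads automatically carry A at position 10 whenever
#' their primary partner starts with U, because position 10 of the
#' secondary pairs position 1 of the primary in a perfect 10-nt 5' overlap;
#' no separate 10A switch exists.
#'
#' @param total_reads number of genuine (non-artifact) reads.
#' @param class_mix named proportions over
#'   `c("miRNA","tRF","rRF","mRNA","repeat","piRNA")`, summing to 1.
#' @param u1_fraction probability that a piRNA read starts with T.
#' @param pingpong_fraction fraction of piRNA reads emitted as
#'   opposite-strand pairs whose 5' ends overlap by exactly 10 nt.
#' @param antisense_repeat_fold antisense:sense ratio for repeat reads
#'   drawn from known-orientation repeat copies.
#' @param length_profile named list, class -> named probability vector over
#'   read lengths (18-40 nt).
#' @param artifact_rates named rates (per `total_reads`) of reads planted to
#'   violate exactly one QC rule; names from
#'   `c("q10","q13","homopolymer","adapter5","no_adapter3","no_insert","too_short")`.
#' @param mirna_star_fraction fraction of miRNA reads drawn from the star
#'   arm rather than the mature arm.
#' @param trf_type_mix proportions of tRF reads emitted as 5' tRFs, 3' tRFs
#'   and internal fragments.
#' @param adapter3,adapter5 adapter sequences; `adapter3` is appended to
#'   every clean read.
#' @param rng_seed integer seed.
#' @return an object of class `library_spec`.
#' @export
library_spec <- function(total_reads = 50000,
                         class_mix = c(miRNA = 0.13, tRF = 0.13, rRF = 0.04,
                                       mRNA = 0.05, "repeat" = 0.21,
                                       piRNA = 0.44),
                         u1_fraction = 0.775,
                         pingpong_fraction = 0.25,
                         antisense_repeat_fold = 2.45,
                         length_profile = default_length_profile(),
                         artifact_rates = c(q10 = 0, q13 = 0,
                                            homopolymer = 0, adapter5 = 0,
                                            no_adapter3 = 0, no_insert = 0,
                                            too_short = 0),
                         mirna_star_fraction = 0.2,
                         trf_type_mix = c(trf5 = 0.9, trf3 = 0.05,
                                          other = 0.05),
                         adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                         adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                         rng_seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1")
  if (u1_fraction < 0 || u1_fraction > 1 ||
      pingpong_fraction < 0 || pingpong_fraction > 1)
    stop("u1_fraction and pingpong_fraction must lie in [0, 1]")
  for (p in length_profile)
    if (abs(sum(p) - 1) > 1e-9) stop("length distributions must sum to 1")
  rules <- c("q10", "q13", "homopolymer", "adapter5", "no_adapter3",
             "no_insert", "too_short")
  rates <- setNames(rep(0, length(rules)), rules)
  rates[names(artifact_rates)] <- artifact_rates
  structure(list(total_reads = as.integer(total_reads),
                 class_mix = class_mix, u1_fraction = u1_fraction,
                 pingpong_fraction = pingpong_fraction,
                 antisense_repeat_fold = antisense_repeat_fold,
                 length_profile = length_profile,
                 artifact_rates = rates,
                 mirna_star_fraction = mirna_star_fraction,
                 trf_type_mix = trf_type_mix / sum(trf_type_mix),
                 adapter3 = toupper(adapter3),
                 adapter5 = toupper(adapter5),
                 rng_seed = as.integer(rng_seed)),
            class = "library_spec")
}

#' @rdname library_spec
#' @export
default_length_profile <- function() {
  unif <- function(a, b) {
    n <- b - a + 1
    setNames(rep(1 / n, n), a:b)
  }
  list(miRNA = c("21" = 0.2, "22" = 0.6, "23" = 0.2),
       tRF = c("30" = 0.25, "31" = 0.25, "32" = 0.3, "33" = 0.2),
       rRF = unif(20, 30),
       mRNA = unif(19, 30),
       "repeat" = unif(28, 34),
       piRNA = unif(30, 34)) # uniform over the 30-34 nt piRNA window
}

sample_length <- function(profile, n) {
  lens <- as.integer(names(profile))
  if (length(lens) == 1L) rep(lens, n) else sample(lens, n, TRUE, profile)
}

#' Simulate a truth-labelled small RNA library
#'
#' Draws reads from the planted features of a synthetic genome according to
#' a [library_spec()]: class counts are multinomial in `class_mix`; piRNA
#' reads start with T at rate `u1_fraction` (achieved by choosing genomic 5'
#' positions, so genuine reads are always exact genome substrings);
#' `pingpong_fraction` of piRNA reads come as opposite-strand pairs with
#' exactly 10 nt 5' overlap; repeat reads are antisense to their repeat at
#' odds `antisense_repeat_fold`:1; 5' tRFs share the mature tRNA 5'
#' terminus. Each clean read is emitted as insert + 3' adapter with Q30
#' throughout; artifact reads violate exactly one QC rule each. Inserts
#' that would by chance trip a QC rule (adapter k-mer content,
#' near-homopolymer composition) are re-drawn so that planted artifact
#' counts are exact.
#'
#' @param genome a `synthetic_genome` from [build_genome()].
#' @param lib a [library_spec()].
#' @return a list of class `synthetic_library` with
#'   * `reads`: data.frame `read_id`, `sequence`, `quality` (Phred+33),
#'   * `truth`: data.frame `read_id`, `class`, `subtype`, `feature_id`,
#'     `contig`, `start` (0-based), `end` (exclusive), `strand`, `length`
#'     describing the insert origin (coordinates `NA` for artifacts).
#' @export
simulate_library <- function(genome, lib) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(lib, "library_spec"))
  with_seed(lib$rng_seed, simulate_library_impl(genome, lib))
}

simulate_library_impl <- function(genome, lib) {
  feats <- genome$features
  gchar <- as.character(genome$genome)
  a3_8 <- substr(lib$adapter3, 1, 8)
  a5_8 <- substr(lib$adapter5, 1, 8)

  feature_class <- c(miRNA = "mirna_hairpin", tRF = "trna", rRF = "rrna",
                     mRNA = "mrna", "repeat" = "repeat",
                     piRNA = "pirna_cluster")
  active <- names(lib$class_mix)[lib$class_mix > 0]
  missing <- active[!feature_class[active] %in% unique(feats$class)]
  if (lib$total_reads > 0 && length(missing))
    stop("nonzero class_mix for classes absent from the truth annotation: ",
         paste(missing, collapse = ", "))

  seqs_clean <- function(s) {
    ok <- !grepl(a3_8, s, fixed = TRUE) & !grepl(a5_8, s, fixed = TRUE)
    nz <- nchar(s) > 0
    if (any(ok & nz)) {
      f <- Biostrings::letterFrequency(
        Biostrings::DNAStringSet(s[ok & nz]), DNA)
      ok[ok & nz] <- apply(f, 1, max) / nchar(s[ok & nz]) < 0.9
    }
    ok
  }
  # a fixed-position source feature is usable only if none of its reads can
  # contain an adapter k-mer
  region_clean <- function(s) {
    !grepl(a3_8, s, fixed = TRUE) & !grepl(a5_8, s, fixed = TRUE) &
      !grepl(a3_8, revcomp_chr(s), fixed = TRUE) &
      !grepl(a5_8, revcomp_chr(s), fixed = TRUE)
  }
  fsub <- function(cl) feats[feats$class == cl]
  region_seq <- function(gr, pad5 = 0L, pad3 = 0L) {
    substring(gchar[as.character(GenomicRanges::seqnames(gr))],
              GenomicRanges::start(gr) - pad5,
              GenomicRanges::end(gr) + pad3)
  }

  rows <- list()
  if (lib$total_reads > 0) {
    n_cls <- as.integer(rmultinom(1, lib$total_reads, lib$class_mix)[, 1])
    names(n_cls) <- names(lib$class_mix)

    ## --- miRNA reads -----------------------------------------------------
    if (n_cls[["miRNA"]] > 0) {
      hp <- fsub("mirna_hairpin")
      hp <- hp[region_clean(region_seq(hp, pad3 = 2L))]
      if (!length(hp)) stop("no usable miRNA hairpins")
      n <- n_cls[["miRNA"]]
      pick <- sample.int(length(hp), n, replace = TRUE)
      star <- runif(n) < lib$mirna_star_fraction
      len <- sample_length(lib$length_profile$miRNA, n)
      start <- ifelse(star, hp$star_start[pick], hp$mature_start[pick])
      end <- ifelse(star, hp$star_end[pick], hp$mature_start[pick] + len)
      rows$mirna <- data.frame(
        class = "miRNA", subtype = ifelse(star, "star", "mature"),
        feature_id = hp$feature_id[pick],
        contig = as.character(GenomicRanges::seqnames(hp))[pick],
        start = start, end = end, strand = "+", stringsAsFactors = FALSE)
    }

    ## --- tRF reads -------------------------------------------------------
    if (n_cls[["tRF"]] > 0) {
      tr <- fsub("trna")
      tr <- tr[region_clean(region_seq(tr))]
      if (!length(tr)) stop("no usable tRNAs")
      n <- n_cls[["tRF"]]
      pick <- sample.int(length(tr), n, replace = TRUE)
      type <- sample(c("tRF-5p", "tRF-3p", "tRF-other"), n, TRUE,
                     lib$trf_type_mix)
      len <- sample_length(lib$length_profile$tRF, n)
      ts <- GenomicRanges::start(tr)[pick] - 1L
      te <- GenomicRanges::end(tr)[pick]
      tstrand <- as.character(GenomicRanges::strand(tr))[pick]
      w <- te - ts
      off <- integer(n) # 5'-end offset from the mature 5' terminus
      off[type == "tRF-3p"] <- (w - len)[type == "tRF-3p"]
      io <- type == "tRF-other"
      if (any(io))
        off[io] <- 3L + floor(runif(sum(io)) * (w[io] - len[io] - 5L))
      start <- ifelse(tstrand == "+", ts + off, te - off - len)
      rows$trf <- data.frame(
        class = "tRF", subtype = type, feature_id = tr$feature_id[pick],
        contig = as.character(GenomicRanges::seqnames(tr))[pick],
        start = start, end = start + len, strand = tstrand,
        stringsAsFactors = FALSE)
    }

    ## --- rRF / mRNA fragments (position re-drawable) ----------------------
    frag <- function(cl, fclass, n) {
      if (n == 0) return(NULL)
      fr <- fsub(fclass)
      pick <- sample.int(length(fr), n, replace = TRUE)
      len <- sample_length(lib$length_profile[[cl]], n)
      fs <- GenomicRanges::start(fr)[pick] - 1L
      fe <- GenomicRanges::end(fr)[pick]
      start <- fs + floor(runif(n) * (fe - fs - len + 1L))
      data.frame(class = cl, subtype = NA_character_,
                 feature_id = fr$feature_id[pick],
                 contig = as.character(GenomicRanges::seqnames(fr))[pick],
                 start = start, end = start + len,
                 strand = as.character(GenomicRanges::strand(fr))[pick],
                 fs = fs, fe = fe, stringsAsFactors = FALSE)
    }
    rows$rrf <- frag("rRF", "rrna", n_cls[["rRF"]])
    rows$mrna <- frag("mRNA", "mrna", n_cls[["mRNA"]])

    ## --- repeat reads ----------------------------------------------------
    if (n_cls[["repeat"]] > 0) {
      rp <- fsub("repeat")
      rp <- rp[region_clean(region_seq(rp))]
      if (!length(rp)) stop("no usable repeat copies")
      n <- n_cls[["repeat"]]
      pick <- sample.int(length(rp), n, replace = TRUE)
      len <- sample_length(lib$length_profile[["repeat"]], n)
      ori <- rp$orientation[pick]
      rstrand <- as.character(GenomicRanges::strand(rp))[pick]
      p_anti <- lib$antisense_repeat_fold / (1 + lib$antisense_repeat_fold)
      anti <- runif(n) < p_anti
      known <- ori != "unknown"
      sub <- ifelse(known, ifelse(anti, "antisense", "sense"), "unknown")
      strand <- ifelse(known,
                       ifelse(anti, chartr("+-", "-+", rstrand), rstrand),
                       sample(c("+", "-"), n, replace = TRUE))
      fs <- GenomicRanges::start(rp)[pick] - 1L
      fe <- GenomicRanges::end(rp)[pick]
      start <- fs + floor(runif(n) * (fe - fs - len + 1L))
      rows$rep <- data.frame(
        class = "repeat", subtype = sub, feature_id = rp$feature_id[pick],
        contig = as.character(GenomicRanges::seqnames(rp))[pick],
        start = start, end = start + len, strand = strand,
        stringsAsFactors = FALSE)
    }

    ## --- piRNA reads -----------------------------------------------------
    if (n_cls[["piRNA"]] > 0)
      rows$pirna <- simulate_pirna_reads(n_cls[["piRNA"]],
                                         fsub("pirna_cluster"), gchar, lib)
  }

  base_cols <- c("class", "subtype", "feature_id", "contig", "start",
                 "end", "strand")
  rows <- lapply(rows, function(d) if (is.null(d)) NULL else d[base_cols])
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(0), subtype = character(0),
               feature_id = character(0), contig = character(0),
               start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)

  # extract inserts (vectorized), then fix rare unclean ones by re-drawing
  # positions within the same feature (movable classes only)
  seqs <- character(nrow(truth))
  if (nrow(truth)) {
    seqs <- substring(gchar[truth$contig], truth$start + 1L, truth$end)
    neg <- truth$strand == "-"
    if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
    movable <- truth$class %in% c("rRF", "mRNA", "piRNA")
    bad <- which(!seqs_clean(seqs) & movable)
    fidx <- setNames(seq_along(feats), feats$feature_id)
    for (i in bad) {
      f <- feats[fidx[truth$feature_id[i]]]
      len <- truth$end[i] - truth$start[i]
      fs <- GenomicRanges::start(f) - 1L
      fe <- GenomicRanges::end(f)
      for (tries in 1:50) {
        truth$start[i] <- fs + floor(runif(1) * (fe - fs - len + 1L))
        truth$end[i] <- truth$start[i] + len
        s <- substring(gchar[truth$contig[i]], truth$start[i] + 1L,
                       truth$end[i])
        if (truth$strand[i] == "-") s <- revcomp_chr(s)
        if (seqs_clean(s)) break
      }
      seqs[i] <- s
    }
  }

  q30 <- function(n) strrep(rawToChar(as.raw(30L + 33L)), n)
  reads <- if (length(seqs)) data.frame(
    sequence = paste0(seqs, lib$adapter3),
    quality = q30(nchar(seqs) + nchar(lib$adapter3)),
    stringsAsFactors = FALSE)
  else data.frame(sequence = character(0), quality = character(0),
                  stringsAsFactors = FALSE)

  art_counts <- round(lib$artifact_rates * lib$total_reads)
  art <- make_artifacts(art_counts, lib, seqs_clean)
  if (nrow(art$reads)) {
    reads <- rbind(reads, art$reads)
    truth <- rbind(truth, art$truth)
  }

  if (nrow(reads)) {
    ord <- sample.int(nrow(reads))
    reads <- reads[ord, , drop = FALSE]
    truth <- truth[ord, , drop = FALSE]
    ids <- sprintf("r%06d", seq_len(nrow(reads)))
    reads <- cbind(read_id = ids, reads, stringsAsFactors = FALSE)
    truth <- cbind(read_id = ids, truth, stringsAsFactors = FALSE)
    truth$length <- ifelse(is.na(truth$start), NA_integer_,
                           truth$end - truth$start)
    rownames(reads) <- rownames(truth) <- NULL
  } else {
    reads <- data.frame(read_id = character(0), sequence = character(0),
                        quality = character(0), stringsAsFactors = FALSE)
    truth <- data.frame(read_id = character(0), class = character(0),
                        subtype = character(0), feature_id = character(0),
                        contig = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        length = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(reads = reads, truth = truth, lib = lib),
            class = "synthetic_library")
}

# piRNA read positions: 5'-end bases chosen to honour u1_fraction, a subset
# emitted as 10-nt 5'-overlap opposite-strand pairs
simulate_pirna_reads <- function(n, clusters, gchar, lib) {
  n_pair <- floor(round(lib$pingpong_fraction * n) / 2)
  n_single <- n - 2L * n_pair

  cinfo <- lapply(seq_along(clusters), function(i) {
    ct <- as.character(GenomicRanges::seqnames(clusters))[i]
    s0 <- GenomicRanges::start(clusters)[i] - 1L
    e0 <- GenomicRanges::end(clusters)[i]
    b <- strsplit(substring(gchar[ct], s0 + 1L, e0), "")[[1]]
    list(contig = ct, s0 = s0, npos = e0 - s0, b = b,
         fid = clusters$feature_id[i],
         is_t = which(b == "T"), not_t = which(b != "T"),
         is_a = which(b == "A"), not_a = which(b != "A"))
  })

  out <- list()
  if (n_single > 0) {
    pick <- sample.int(length(cinfo), n_single, replace = TRUE)
    len <- sample_length(lib$length_profile$piRNA, n_single)
    strand <- sample(c("+", "-"), n_single, replace = TRUE)
    u1 <- runif(n_single) < lib$u1_fraction
    start <- integer(n_single)
    for (j in seq_len(n_single)) {
      ci <- cinfo[[pick[j]]]
      set <- if (strand[j] == "+") {
        if (u1[j]) ci$is_t else ci$not_t
      } else {
        if (u1[j]) ci$is_a else ci$not_a
      }
      # rejection-sample the 5' position against the cluster boundary
      p <- NA_integer_
      for (t in 1:40) {
        cand <- set[sample.int(length(set), 1L)]
        fits <- if (strand[j] == "+") cand <= ci$npos - len[j] + 1L
        else cand >= len[j]
        if (fits) { p <- cand; break }
      }
      if (is.na(p)) p <- if (strand[j] == "+") 1L else len[j]
      start[j] <- if (strand[j] == "+") ci$s0 + p - 1L else
        ci$s0 + p - len[j]
    }
    out$single <- data.frame(
      class = "piRNA", subtype = "primary",
      feature_id = vapply(cinfo[pick], `[[`, "", "fid"),
      contig = vapply(cinfo[pick], `[[`, "", "contig"),
      start = start, end = start + len, strand = strand,
      stringsAsFactors = FALSE)
  }
  if (n_pair > 0) {
    pick <- sample.int(length(cinfo), n_pair, replace = TRUE)
    l1 <- sample_length(lib$length_profile$piRNA, n_pair)
    l2 <- sample_length(lib$length_profile$piRNA, n_pair)
    u1a <- runif(n_pair) < lib$u1_fraction
    u1b <- runif(n_pair) < lib$u1_fraction
    p1 <- integer(n_pair)
    for (j in seq_len(n_pair)) {
      ci <- cinfo[[pick[j]]]
      # primary plus-strand 5' at offset p, secondary minus-strand 5' at
      # p + 9; both reads must stay inside the cluster
      lo <- max(1L, l2[j] - 9L)
      hi <- ci$npos - max(l1[j], 10L) + 1L
      set <- if (u1a[j]) ci$is_t else ci$not_t
      p <- NA_integer_
      for (t in 1:60) {
        cand <- set[sample.int(length(set), 1L)]
        if (cand < lo || cand > hi) next
        sec_t <- ci$b[cand + 9L] == "A"
        if (sec_t == u1b[j]) { p <- cand; break }
        if (t > 40L) { p <- cand; break } # relax the secondary condition
      }
      if (is.na(p)) p <- lo
      p1[j] <- p
    }
    s0 <- vapply(cinfo[pick], `[[`, 0L, "s0")
    ct <- vapply(cinfo[pick], `[[`, "", "contig")
    fid <- vapply(cinfo[pick], `[[`, "", "fid")
    prim_start <- s0 + p1 - 1L
    sec_start <- s0 + p1 + 9L - l2
    out$pp <- data.frame(
      class = "piRNA",
      subtype = rep(c("pingpong_primary", "pingpong_secondary"),
                    each = n_pair),
      feature_id = c(fid, fid), contig = c(ct, ct),
      start = c(prim_start, sec_start),
      end = c(prim_start + l1, sec_start + l2),
      strand = rep(c("+", "-"), each = n_pair),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}


make_artifacts <- function(counts, lib, seqs_clean) {
  qc <- function(q, n) strrep(rawToChar(as.raw(q + 33L)), n)
  rand_insert <- function(len) {
    repeat {
      s <- random_dna(len)
      if (seqs_clean(s)) return(s)
    }
  }
  seqs <- character(0); quals <- character(0); sub <- character(0)
  emit <- function(rule, sequence, quality) {
    seqs <<- c(seqs, sequence); quals <<- c(quals, quality)
    sub <<- c(sub, rule)
  }
  for (rule in names(counts)) {
    for (i in seq_len(counts[[rule]])) {
      ins <- rand_insert(25L)
      full <- paste0(ins, lib$adapter3)
      n <- nchar(full)
      if (rule == "q10") {
        q <- rep(30L, n); q[sample.int(n, 5L)] <- 9L
        emit(rule, full, intToUtf8(q + 33L))
      } else if (rule == "q13") {
        q <- rep(30L, n); q[sample.int(n, 7L)] <- 12L
        emit(rule, full, intToUtf8(q + 33L))
      } else if (rule == "homopolymer") {
        s <- paste0(strrep("A", 25L), lib$adapter3)
        emit(rule, s, qc(30L, nchar(s)))
      } else if (rule == "adapter5") {
        s <- paste0(lib$adapter5, ins, lib$adapter3)
        emit(rule, s, qc(30L, nchar(s)))
      } else if (rule == "no_adapter3") {
        emit(rule, ins, qc(30L, nchar(ins)))
      } else if (rule == "no_insert") {
        emit(rule, lib$adapter3, qc(30L, nchar(lib$adapter3)))
      } else if (rule == "too_short") {
        s <- paste0(rand_insert(17L), lib$adapter3)
        emit(rule, s, qc(30L, nchar(s)))
      }
    }
  }
  k <- length(sub)
  list(reads = data.frame(sequence = seqs, quality = quals,
                          stringsAsFactors = FALSE),
       truth = data.frame(class = rep("artifact", k),
                          subtype = sub,
                          feature_id = rep(NA_character_, k),
                          contig = rep(NA_character_, k),
                          start = rep(NA_integer_, k),
                          end = rep(NA_integer_, k),
                          strand = rep(NA_character_, k),
                          stringsAsFactors = FALSE))
}

#' Write a synthetic genome and its truth annotation to disk
#'
#' Writes the genome as FASTA, the truth annotation as BED6 (0-based
#' half-open, strand in column 6) and one FASTA per reference class
#' (hairpins, mature tRNAs, rRNAs, mRNAs with their 3' UTR sub-interval
#' noted in the header).
#'
#' @param genome a `synthetic_genome` from [build_genome()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(genome$genome, file.path(dir, "genome.fa"))
  f <- genome$features
  bed <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(f)),
    start = GenomicRanges::start(f) - 1L,
    end = GenomicRanges::end(f),
    name = f$feature_id,
    score = 0L,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(f))))
  write.table(bed, file.path(dir, "features.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  feature_seq <- function(sub) {
    s <- Biostrings::DNAStringSet(substring(
      as.character(genome$genome)[as.character(
        GenomicRanges::seqnames(sub))],
      GenomicRanges::start(sub), GenomicRanges::end(sub)))
    neg <- as.character(GenomicRanges::strand(sub)) == "-"
    s[neg] <- Biostrings::reverseComplement(s[neg])
    names(s) <- sub$feature_id
    s
  }
  class_files <- c(mirna_hairpin = "hairpins", trna = "trna", rrna = "rrna")
  for (k in names(class_files)) {
    sub <- f[f$class == k]
    if (length(sub))
      Biostrings::writeXStringSet(
        feature_seq(sub), file.path(dir, paste0(class_files[[k]], ".fa")))
  }
  mrna <- f[f$class == "mrna"]
  if (length(mrna)) {
    s <- feature_seq(mrna)
    w <- GenomicRanges::width(mrna)
    names(s) <- sprintf("%s utr3=%d-%d", mrna$feature_id,
                        w - UTR3_LEN + 1L, w)
    Biostrings::writeXStringSet(s, file.path(dir, "mrna.fa"))
  }
  invisible(dir)
}
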