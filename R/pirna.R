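#' Select candidate piRNA reads
#'
#' Candidates are mapped reads of 24-35 nt whose annotation cascade label
#' is `none` or `repeat` (everything assignable to miRNA/tRNA/rRNA/mRNA is
#' excluded). The lower bound is configurable; the window upper end equals
#' the maximum expected piRNA length.
#'
#' @param classified output of [classify_reads()] (columns `read_id`,
#'   `major`, `length`).
#' @param min_len,max_len inclusive read length window (defaults 24 and
#'   35 nt).
#' @return character vector of candidate `read_id`s.
#' @export
select_candidates <- function(classified, min_len = 24, max_len = 35) {
  classified$read_id[classified$major %in% c("none", "repeat") &
                       classified$length >= min_len &
                       classified$length <= max_len]
}

#' 5' uridine (1U) fraction
#'
#' Read-count-weighted share of sequences whose first base is T.
#'
#' @param seqs character vector of candidate read sequences (5' to 3').
#' @param counts read counts parallel to `seqs` (default 1 each).
#' @return a proportion in `[0, 1]` (`NaN` on empty input).
#' @export
u1_fraction <- function(seqs, counts = NULL) {
  if (is.null(counts)) counts <- rep(1, length(seqs))
  sum(counts[substr(seqs, 1, 1) == "T"]) / sum(counts)
}

# 5'-end position/weight tables per contig and strand from a hit table
five_prime_table <- function(hits, counts) {
  w <- counts[hits$read_id]
  pos5 <- ifelse(hits$strand == "+", hits$start, hits$end - 1L)
  data.frame(contig = hits$contig, strand = hits$strand, pos5 = pos5,
             w = w, len = hits$end - hits$start, stringsAsFactors = FALSE)
}

#' Ping-pong 5'-overlap profile with Z-scores
#'
#' For each overlap `o` in `1..max_overlap`, accumulates the pair mass
#' `n_o` = sum over opposite-strand 5'-position pairs at overlap `o` of
#' (read mass at the plus-strand 5' position) x (read mass at the
#' minus-strand 5' position). A plus-strand 5' end at `p` and a
#' minus-strand 5' end at `p + o - 1` overlap by `o` nt. The Z-score of
#' each overlap is computed against the mean and sample standard deviation
#' of all other overlaps. With fewer than two overlaps carrying mass the
#' background is undefined: all Z are reported as 0 and
#' `undefined_background` is set.
#'
#' @param hits hit table of candidate reads (best-hit-filtered).
#' @param counts optional named read counts per `read_id`.
#' @param max_overlap largest 5' overlap scored (default 30).
#' @return a list of class `pingpong_profile`: `overlap`, `mass`, `z`
#'   (parallel numeric vectors) and `undefined_background` flag.
#' @export
pingpong_profile <- function(hits, counts = NULL, max_overlap = 30) {
  counts <- resolve_counts(counts, unique(hits$read_id))
  n_o <- setNames(numeric(max_overlap), seq_len(max_overlap))
  if (nrow(hits)) {
    fp <- five_prime_table(hits, counts)
    for (ct in unique(fp$contig)) {
      p <- fp[fp$contig == ct & fp$strand == "+", ]
      m <- fp[fp$contig == ct & fp$strand == "-", ]
      if (!nrow(p) || !nrow(m)) next
      pw <- tapply(p$w, p$pos5, sum)
      mw <- tapply(m$w, m$pos5, sum)
      ppos <- as.integer(names(pw))
      mpos <- as.integer(names(mw))
      for (o in seq_len(max_overlap)) {
        i <- match(ppos + o - 1L, mpos)
        hit <- !is.na(i)
        if (any(hit))
          n_o[o] <- n_o[o] + sum(as.numeric(pw[hit]) * as.numeric(mw[i[hit]]))
      }
    }
  }
  undefined <- sum(n_o > 0) < 2
  z <- numeric(max_overlap)
  if (!undefined) {
    for (o in seq_len(max_overlap)) {
      bg <- n_o[-o]
      s <- sd(bg)
      z[o] <- if (s > 0) (n_o[o] - mean(bg)) / s else 0
    }
  }
  structure(list(overlap = seq_len(max_overlap), mass = unname(n_o),
                 z = z, undefined_background = undefined),
            class = "pingpong_profile")
}

#' Ping-pong length-combination matrix
#'
#' Accumulates pair mass for read pairs with exactly 10 nt 5' overlap into
#' a symmetric length x length matrix (mass of a pair with lengths `(a, b)`
#' is added at both `(a, b)` and `(b, a)`).
#'
#' @param hits hit table of candidate reads.
#' @param counts optional named read counts per `read_id`.
#' @param lengths length range of the matrix (default 18-40 nt).
#' @param overlap the diagnostic 5' overlap (default 10 nt).
#' @return numeric matrix `lengths x lengths`.
#' @export
pingpong_matrix <- function(hits, counts = NULL, lengths = 18:40,
                            overlap = 10) {
  counts <- resolve_counts(counts, unique(hits$read_id))
  m <- matrix(0, length(lengths), length(lengths),
              dimnames = list(lengths, lengths))
  if (!nrow(hits)) return(m)
  fp <- five_prime_table(hits, counts)
  for (ct in unique(fp$contig)) {
    p <- fp[fp$contig == ct & fp$strand == "+", ]
    q <- fp[fp$contig == ct & fp$strand == "-", ]
    if (!nrow(p) || !nrow(q)) next
    # aggregate by (5' position, length)
    pa <- stats::aggregate(w ~ pos5 + len, p, sum)
    qa <- stats::aggregate(w ~ pos5 + len, q, sum)
    key <- match(pa$pos5 + overlap - 1L, qa$pos5)
    for (i in which(!is.na(key))) {
      js <- which(qa$pos5 == pa$pos5[i] + overlap - 1L)
      for (j in js) {
        la <- as.character(pa$len[i]); lb <- as.character(qa$len[j])
        if (la %in% rownames(m) && lb %in% rownames(m)) {
          mass <- pa$w[i] * qa$w[j]
          m[la, lb] <- m[la, lb] + mass
          m[lb, la] <- m[lb, la] + mass
        }
      }
    }
  }
  m
}

#' Predict piRNA clusters by sliding-window read density
#'
#' Scans each contig with 1-kb windows (100-nt step) of normalized
#' candidate read mass, where each read contributes its count divided by
#' its number of genomic placements. A window qualifies if its mass is at
#' least `min_mass` and it looks piRNA-like: 5' U fraction >= 0.5 or at
#' least 75 percent of its read mass within `[size_min, pimax]` nt.
#' Overlapping or adjacent qualifying windows are merged, merged intervals
#' are trimmed to the span of their supporting reads, and clusters shorter
#' than `min_cluster_length` are dropped.
#'
#' @param hits hit table of candidate reads (best-hit-filtered; `n_hits`
#'   column used for 1/placement weighting when present).
#' @param seqs named character vector of read sequences (names =
#'   `read_id`), used for the 5' U criterion.
#' @param counts optional named read counts per `read_id`.
#' @param pimax maximum piRNA length for the size criterion (default 35).
#' @param window,step sliding window geometry in nt.
#' @param min_mass minimum normalized read mass per qualifying window.
#' @param min_u1,min_size_frac the piRNA-likeness thresholds.
#' @param size_min lower end of the size window (default 24 nt).
#' @param min_cluster_length minimum reported cluster length (default
#'   1000 nt).
#' @return [GenomicRanges::GRanges] of clusters with metadata `mass`,
#'   `u1_fraction` and `size_fraction_in_range`.
#' @export
predict_clusters <- function(hits, seqs, counts = NULL, pimax = 35,
                             window = 1000, step = 100, min_mass = 10,
                             min_u1 = 0.5, min_size_frac = 0.75,
                             size_min = 24, min_cluster_length = 1000) {
  out <- GenomicRanges::GRanges()
  if (!nrow(hits)) return(out)
  counts <- resolve_counts(counts, unique(hits$read_id))
  nh <- if (!is.null(hits$n_hits)) hits$n_hits else
    as.integer(table(hits$read_id)[hits$read_id])
  w <- counts[hits$read_id] / nh
  u1 <- substr(seqs[hits$read_id], 1, 1) == "T"
  len <- hits$end - hits$start
  in_size <- len >= size_min & len <= pimax

  res <- list()
  for (ct in unique(hits$contig)) {
    i <- which(hits$contig == ct)
    pos <- hits$start[i]
    starts <- seq(0L, max(pos), by = step)
    qual <- logical(length(starts))
    for (k in seq_along(starts)) {
      j <- i[pos >= starts[k] & pos < starts[k] + window]
      if (!length(j)) next
      mass <- sum(w[j])
      if (mass < min_mass) next
      u1f <- sum(w[j][u1[j]]) / mass
      szf <- sum(w[j][in_size[j]]) / mass
      qual[k] <- u1f >= min_u1 || szf >= min_size_frac
    }
    if (!any(qual)) next
    win <- IRanges::IRanges(start = starts[qual] + 1L,
                            width = window)
    merged <- IRanges::reduce(win, min.gapwidth = 1L)
    for (k in seq_along(merged)) {
      j <- i[hits$start[i] + 1L >= IRanges::start(merged)[k] &
               hits$start[i] + 1L <= IRanges::end(merged)[k]]
      if (!length(j)) next
      lo <- min(hits$start[j]) + 1L
      hi <- max(hits$end[j])
      if (hi - lo + 1L < min_cluster_length) next
      mass <- sum(w[j])
      res[[length(res) + 1L]] <- data.frame(
        contig = ct, start = lo, end = hi, mass = mass,
        u1_fraction = sum(w[j][u1[j]]) / mass,
        size_fraction_in_range = sum(w[j][in_size[j]]) / mass,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(out)
  df <- do.call(rbind, res)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(df$start, df$end), strand = "*",
    mass = df$mass, u1_fraction = df$u1_fraction,
    size_fraction_in_range = df$size_fraction_in_range)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Merge piRNA cluster sets across libraries
#'
#' Takes the union of the genomic intervals: clusters from any libraries
#' that overlap (or touch) coalesce into one locus. Idempotent and
#' commutative.
#'
#' @param cluster_list list of cluster GRanges (e.g. one per timepoint).
#' @return GRanges of merged loci.
#' @export
merge_clusters <- function(cluster_list) {
  grs <- lapply(cluster_list, function(g) {
    GenomicRanges::granges(GenomicRanges::GRanges(g))
  })
  lv <- unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
  grs <- lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
  all <- do.call(c, grs)
  if (!length(all)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(all, ignore.strand = TRUE)
}

#' Cluster share of piRNA candidates and of the genome
#'
#' @param hits candidate hit table (1/placement weighting as in
#'   [predict_clusters()]).
#' @param clusters cluster GRanges.
#' @param genome `DNAStringSet` (or named lengths) of the genome.
#' @param counts optional named read counts per `read_id`.
#' @return named numeric vector: `pirna_fraction_in_clusters` and
#'   `genome_fraction_covered`.
#' @export
cluster_share <- function(hits, clusters, genome, counts = NULL) {
  glen <- if (is(genome, "DNAStringSet")) sum(Biostrings::width(genome))
  else if (is.character(genome)) sum(nchar(genome))
  else sum(as.numeric(genome))
  if (!length(clusters) || !nrow(hits))
    return(c(pirna_fraction_in_clusters = 0, genome_fraction_covered = 0))
  counts <- resolve_counts(counts, unique(hits$read_id))
  nh <- if (!is.null(hits$n_hits)) hits$n_hits else
    as.integer(table(hits$read_id)[hits$read_id])
  w <- counts[hits$read_id] / nh
  ov <- GenomicRanges::findOverlaps(hits_granges(hits),
                                    GenomicRanges::GRanges(clusters),
                                    type = "within", ignore.strand = TRUE)
  inside <- unique(S4Vectors::queryHits(ov))
  c(pirna_fraction_in_clusters = sum(w[inside]) / sum(w),
    genome_fraction_covered =
      sum(IRanges::width(GenomicRanges::reduce(
        GenomicRanges::GRanges(clusters), ignore.strand = TRUE))) / glen)
}

#' Write clusters as BED6 plus a TSV of cluster statistics
#'
#' @param clusters cluster GRanges from [predict_clusters()].
#' @param bed_path BED6 output path (0-based half-open, strand column 6).
#' @param tsv_path optional TSV with mass and 1U fraction per cluster.
#' @export
write_clusters <- function(clusters, bed_path, tsv_path = NULL) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters) - 1L,
    end = GenomicRanges::end(clusters),
    name = paste0("cluster", seq_along(clusters)),
    score = 0L,
    strand = ".", stringsAsFactors = FALSE)
  write.table(df, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path)) {
    stats <- cbind(df[c("chrom", "start", "end", "name")],
                   as.data.frame(S4Vectors::mcols(clusters)))
    write.table(stats, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(bed_path)
}
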