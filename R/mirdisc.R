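#' De novo miRNA locus discovery
#'
#' Clusters aligned reads (pooled over libraries, mapped at up to 2
#' mismatches) into loci separated by more than `max_gap` nt, then accepts
#' a locus as a miRNA gene iff
#'
#' * its total read support is at least `min_support`,
#' * at least `min_strand_bias` of the locus read mass lies on one strand,
#' * the (weighted) dominant read length is 20-24 nt,
#' * a star partner exists: a second read-supported interval on the major
#'   strand whose genomic position forms a duplex with the mature arm in
#'   the register implied by a 2-nt 3' overhang at both duplex ends,
#' * the heuristic hairpin pairing score over that duplex (Watson-Crick
#'   plus G:U, fraction of paired positions) is at least `min_paired`, and
#' * mature plus star reads carry at least `min_arm_fraction` of the locus
#'   read mass (a precision requirement that rejects diffuse read piles
#'   whose interval pairs are complementary by chance).
#'
#' The mature arm is the most abundant read interval on the major strand.
#'
#' @param hits best-hit-filtered hit table from a <= 2 mismatch mapping.
#' @param genome `DNAStringSet` of the genome.
#' @param counts optional named read counts per `read_id`.
#' @param max_gap maximum gap joining reads into one locus (default
#'   200 nt).
#' @param min_support minimum locus read mass (default 10).
#' @param min_strand_bias minimum major-strand mass fraction (default 0.8).
#' @param min_paired minimum duplex pairing fraction (default 0.6).
#' @param min_arm_fraction minimum share of locus read mass on the mature
#'   plus star intervals (default 0.5).
#' @param dominant_lengths acceptable dominant read lengths (default
#'   20:24).
#' @return data.frame of accepted loci: `locus_id`, `contig`, `start`,
#'   `end` (0-based half-open), `strand`, `mature_start`, `mature_end`,
#'   `star_start`, `star_end`, `pairing_score`, `strand_bias`,
#'   `read_support`, `name` (filled by [assign_names()], `NA` here).
#' @export
find_mirna_loci <- function(hits, genome, counts = NULL, max_gap = 200,
                            min_support = 10, min_strand_bias = 0.8,
                            min_paired = 0.6, min_arm_fraction = 0.5,
                            dominant_lengths = 20:24) {
  empty <- data.frame(locus_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mature_start = integer(0),
                      mature_end = integer(0), star_start = integer(0),
                      star_end = integer(0), pairing_score = numeric(0),
                      strand_bias = numeric(0), read_support = numeric(0),
                      name = character(0), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  counts <- resolve_counts(counts, unique(hits$read_id))
  w <- counts[hits$read_id]

  hgr <- hits_granges(hits)
  loci <- GenomicRanges::reduce(hgr, min.gapwidth = max_gap + 1L,
                                ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(hgr, loci, ignore.strand = TRUE)
  locus_of <- rep(NA_integer_, nrow(hits))
  locus_of[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)

  res <- list()
  for (k in seq_along(loci)) {
    idx <- which(locus_of == k)
    mass <- sum(w[idx])
    if (mass < min_support) next
    # strand bias
    plus_mass <- sum(w[idx][hits$strand[idx] == "+"])
    bias <- max(plus_mass, mass - plus_mass) / mass
    if (bias < min_strand_bias) next
    major <- if (plus_mass >= mass - plus_mass) "+" else "-"
    midx <- idx[hits$strand[idx] == major]
    # dominant read length
    lens <- hits$end[midx] - hits$start[midx]
    lmass <- tapply(w[midx], lens, sum)
    dom_len <- as.integer(names(lmass)[which.max(lmass)])
    if (!dom_len %in% dominant_lengths) next
    # distinct read intervals on the major strand, by decreasing mass
    key <- paste(hits$start[midx], hits$end[midx])
    imass <- tapply(w[midx], key, sum)
    ints <- do.call(rbind, strsplit(names(imass), " "))
    ints <- data.frame(start = as.integer(ints[, 1]),
                       end = as.integer(ints[, 2]),
                       mass = as.numeric(imass))
    ints <- ints[order(-ints$mass), , drop = FALSE]
    mature <- ints[1, ]
    gseq <- strsplit(genome[[as.character(
      GenomicRanges::seqnames(loci))[k]]], "")[[1]]
    star <- NULL
    score <- NA_real_
    for (j in utils::head(seq_len(nrow(ints))[-1], 50L)) {
      cand <- ints[j, ]
      # arms must be disjoint
      if (cand$start < mature$end && mature$start < cand$end) next
      s <- duplex_pairing_score(gseq, mature, cand, major)
      if (!is.na(s) && s >= min_paired) {
        star <- cand; score <- s; break
      }
    }
    if (is.null(star)) next
    if ((mature$mass + star$mass) / mass < min_arm_fraction) next
    ct <- as.character(GenomicRanges::seqnames(loci))[k]
    res[[length(res) + 1L]] <- data.frame(
      contig = ct,
      start = GenomicRanges::start(loci)[k] - 1L,
      end = GenomicRanges::end(loci)[k],
      strand = major,
      mature_start = mature$start, mature_end = mature$end,
      star_start = star$start, star_end = star$end,
      pairing_score = score, strand_bias = bias, read_support = mass,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out <- cbind(locus_id = paste0("locus", seq_len(nrow(out))), out,
               name = NA_character_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# pairing fraction of the duplex formed by two same-strand arm intervals
# (0-based half-open) in the register implied by 2-nt 3' overhangs; both
# arms are ungapped, pairing = Watson-Crick or G:U
duplex_pairing_score <- function(gseq, a, b, strand) {
  # order arms by genome position
  up <- if (a$start <= b$start) a else b
  dn <- if (a$start <= b$start) b else a
  npair <- min(up$end - up$start, dn$end - dn$start) - 2L
  if (npair < 1L) return(NA_real_)
  if (strand == "+") {
    # transcript 5' arm is upstream; its 5' base (up$start) pairs the
    # downstream arm base two inside from that arm's 3' end (dn$end - 3,
    # 0-based), leaving 2-nt 3' overhangs on both reads
    i <- seq_len(npair) - 1L
    x <- gseq[up$start + 1L + i]
    y <- gseq[dn$end - 2L - i]
  } else {
    # transcript 5' arm is the downstream interval; mirror register
    i <- seq_len(npair) - 1L
    x <- gseq[dn$end - i]
    y <- gseq[up$start + 3L + i]
  }
  mean(bases_pair(x, y))
}

#' Assign names to discovered miRNA loci by hairpin homology
#'
#' Each locus sequence is locally aligned against a set of known hairpins
#' (match +2, mismatch -3, blastn-like gap penalties). The best hit names
#' the locus if its Karlin-Altschul E-value is below `max_evalue`
#' (ungapped parameters, search space = query length x total database
#' length); otherwise the locus is `novel-k` in locus order.
#'
#' @param loci locus table from [find_mirna_loci()].
#' @param genome `DNAStringSet` of the genome (locus sequences are
#'   extracted from it).
#' @param known_hairpins named `DNAStringSet` (or named character) of known
#'   hairpin sequences; may be empty.
#' @param max_evalue homology threshold (default 1e-6).
#' @return `loci` with `name` filled in and an `evalue` column.
#' @export
assign_names <- function(loci, genome, known_hairpins,
                         max_evalue = 1e-6) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.character(known_hairpins))
    known_hairpins <- Biostrings::DNAStringSet(known_hairpins)
  loci$evalue <- NA_real_
  if (nrow(loci) == 0) return(loci)
  novel <- 0L
  lambda <- karlin_lambda(match = 2, mismatch = -3)
  K <- 0.41 # ungapped Karlin-Altschul K for +2/-3 at uniform base content
  db_len <- sum(Biostrings::width(known_hairpins))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in seq_len(nrow(loci))) {
    q <- substr(genome[[loci$contig[i]]], loci$start[i] + 1L, loci$end[i])
    best_e <- Inf; best_name <- NA_character_
    if (length(known_hairpins) && nchar(q)) {
      al <- Biostrings::pairwiseAlignment(
        rep(q, length(known_hairpins)), known_hairpins,
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
      s <- max(al)
      best_e <- K * nchar(q) * db_len * exp(-lambda * s)
      best_name <- names(known_hairpins)[which.max(al)]
    }
    if (is.finite(best_e) && best_e < max_evalue) {
      loci$name[i] <- best_name
      loci$evalue[i] <- best_e
    } else {
      novel <- novel + 1L
      loci$name[i] <- paste0("novel-", novel)
      loci$evalue[i] <- if (is.finite(best_e)) best_e else NA_real_
    }
  }
  loci
}

# ungapped Karlin-Altschul lambda for a match/mismatch score scheme at
# uniform base composition: solves sum p_ij exp(lambda s_ij) = 1
karlin_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 10))$root
}
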