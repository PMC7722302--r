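#' Reference feature sets for small RNA classification
#'
#' Bundles the reference intervals the annotation cascade classifies
#' against. All components are [GenomicRanges::GRanges] (1-based, with
#' strand): `mirna` (hairpin loci), `trna` (mature tRNAs; the interval ends
#' are the mature 5'/3' termini), `rrna`, `mrna` (with a `utr3` companion
#' set of 3' UTR sub-intervals) and `repeats` (metadata column
#' `orientation` in `"+"`, `"-"`, `"unknown"`).
#'
#' @param mirna,trna,rrna,mrna,utr3,repeats GRanges per class; empty
#'   GRanges by default.
#' @return a list of class `reference_set`.
#' @export
reference_set <- function(mirna = GenomicRanges::GRanges(),
                          trna = GenomicRanges::GRanges(),
                          rrna = GenomicRanges::GRanges(),
                          mrna = GenomicRanges::GRanges(),
                          utr3 = GenomicRanges::GRanges(),
                          repeats = GenomicRanges::GRanges()) {
  if (length(repeats) && is.null(repeats$orientation))
    repeats$orientation <- as.character(GenomicRanges::strand(repeats))
  structure(list(mirna = mirna, trna = trna, rrna = rrna, mrna = mrna,
                 utr3 = utr3, repeats = repeats),
            class = "reference_set")
}

#' Derive a reference set from a synthetic genome's truth annotation
#'
#' @param genome a `synthetic_genome` from [build_genome()].
#' @return a [reference_set()].
#' @export
as_reference_set <- function(genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  f <- genome$features
  pick <- function(cl) f[f$class == cl]
  reference_set(mirna = pick("mirna_hairpin"), trna = pick("trna"),
                rrna = pick("rrna"), mrna = pick("mrna"),
                utr3 = pick("utr3"), repeats = pick("repeat"))
}

CLASS_PRECEDENCE <- c("miRNA", "tRF", "rRF", "mRNA", "repeat")

# reads (hit GRanges) overlapping a reference with >= frac of the read
# inside the feature; returns the hit rows and matched feature indices
overlap_hits <- function(hgr, ref, frac = 0.5) {
  if (length(ref) == 0 || length(hgr) == 0)
    return(data.frame(hit = integer(0), feat = integer(0)))
  ov <- GenomicRanges::findOverlaps(hgr, ref, ignore.strand = TRUE)
  if (!length(ov)) return(data.frame(hit = integer(0), feat = integer(0)))
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(hgr)[q], IRanges::ranges(ref)[s]))
  keep <- w >= frac * IRanges::width(hgr)[q]
  data.frame(hit = q[keep], feat = s[keep])
}

#' Classify mapped reads by the annotation cascade
#'
#' Each mapped read receives exactly one class label: the
#' highest-precedence class (miRNA > tRNA > rRNA > mRNA > repeat > none)
#' overlapped by any of its retained hits, where overlap requires at least
#' `min_overlap` of the read length inside the feature. tRF reads are
#' sub-typed against the mature tRNA termini ([type_trf()]); repeat reads
#' are sub-typed sense/antisense/unknown by comparing the hit strand with
#' the repeat orientation.
#'
#' @param hits best-hit-filtered hit table ([besthit_filter()]).
#' @param refs a [reference_set()].
#' @param min_overlap minimum fraction of the read inside the feature
#'   (default 0.5).
#' @return data.frame with one row per mapped read: `read_id`, `major`
#'   (miRNA/tRF/rRF/mRNA/repeat/none), `sub` (tRF-5p/tRF-3p/tRF-other for
#'   tRFs, sense/antisense/unknown for repeats, `NA` otherwise),
#'   `feature_id` of the assigning feature when available, and `length`.
#' @export
classify_reads <- function(hits, refs, min_overlap = 0.5) {
  stopifnot(inherits(refs, "reference_set"))
  for (ref in refs)
    validate_reference(ref)
  ids <- unique(hits$read_id)
  out <- data.frame(read_id = ids, major = "none", sub = NA_character_,
                    feature_id = NA_character_, stringsAsFactors = FALSE)
  len <- hits$end - hits$start
  out$length <- len[match(ids, hits$read_id)]
  if (nrow(hits) == 0) return(out[0, ])
  hgr <- hits_granges(hits)
  ridx <- match(hits$read_id, ids)

  refmap <- list(miRNA = refs$mirna, tRF = refs$trna, rRF = refs$rrna,
                 mRNA = refs$mrna, "repeat" = refs$repeats)
  unassigned <- rep(TRUE, length(ids))
  for (cl in CLASS_PRECEDENCE) {
    if (!any(unassigned)) break
    ov <- overlap_hits(hgr, refmap[[cl]], min_overlap)
    if (!nrow(ov)) next
    ov <- ov[unassigned[ridx[ov$hit]], , drop = FALSE]
    if (!nrow(ov)) next
    # widest overlap decides the assigning feature for each read
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(hgr)[ov$hit],
      IRanges::ranges(refmap[[cl]])[ov$feat]))
    ord <- order(ridx[ov$hit], -w)
    ov <- ov[ord, , drop = FALSE]
    firsts <- !duplicated(ridx[ov$hit])
    r <- ridx[ov$hit[firsts]]
    f <- ov$feat[firsts]
    h <- ov$hit[firsts]
    out$major[r] <- cl
    out$feature_id[r] <- refmap[[cl]]$feature_id[f]
    if (cl == "tRF") {
      out$sub[r] <- type_trf(hits[h, , drop = FALSE], refmap[[cl]][f])
    } else if (cl == "repeat") {
      ori <- refmap[[cl]]$orientation[f]
      hs <- hits$strand[h]
      out$sub[r] <- ifelse(ori == "unknown", "unknown",
                           ifelse(hs == ori, "sense", "antisense"))
    }
    unassigned[r] <- FALSE
  }
  out
}

validate_reference <- function(ref) {
  if (length(ref) && any(GenomicRanges::start(ref) < 1))
    stop("reference interval off contig")
  invisible(TRUE)
}

#' Type a tRNA fragment against the mature tRNA termini
#'
#' A read is `tRF-5p` if its 5' end lies within +/- 1 nt of the mature
#' tRNA's 5' terminus (on the tRNA's strand), `tRF-3p` analogously at the
#' 3' terminus, otherwise `tRF-other`. Reads antisense to the tRNA are
#' always `tRF-other`.
#'
#' @param hits hit table rows (one per read) overlapping the tRNAs.
#' @param trna GRanges of the mature tRNAs, parallel to `hits`.
#' @return character vector of tRF types.
#' @export
type_trf <- function(hits, trna) {
  tstrand <- as.character(GenomicRanges::strand(trna))
  ts0 <- GenomicRanges::start(trna) - 1L # 0-based mature 5'/3' ends
  te0 <- GenomicRanges::end(trna) - 1L
  five_term <- ifelse(tstrand == "+", ts0, te0)
  three_term <- ifelse(tstrand == "+", te0, ts0)
  read5 <- ifelse(hits$strand == "+", hits$start, hits$end - 1L)
  read3 <- ifelse(hits$strand == "+", hits$end - 1L, hits$start)
  ifelse(hits$strand != tstrand, "tRF-other",
         ifelse(abs(read5 - five_term) <= 1L, "tRF-5p",
                ifelse(abs(read3 - three_term) <= 1L, "tRF-3p",
                       "tRF-other")))
}

#' Read-count accounting of repeat-derived small RNAs by orientation
#'
#' Accumulates read counts (not unique sequences) of repeat-class reads by
#' the relation between hit strand and repeat orientation. Multi-mapping
#' reads distribute their count equally over their repeat-overlapping
#' hits; repeats of unknown orientation are counted as `unknown`.
#'
#' @param hits best-hit-filtered hit table.
#' @param classified output of [classify_reads()].
#' @param refs a [reference_set()].
#' @param counts optional named vector of read counts per `read_id`
#'   (default 1 each).
#' @param min_overlap overlap fraction as in [classify_reads()].
#' @return list with `total` (named counts `sense`/`antisense`/`unknown`)
#'   and `per_family` (data.frame `family`, `sense`, `antisense`,
#'   `unknown`).
#' @export
repeat_orientation_counts <- function(hits, classified, refs, counts = NULL,
                                      min_overlap = 0.5) {
  stopifnot(inherits(refs, "reference_set"))
  counts <- resolve_counts(counts, classified$read_id)
  rep_reads <- classified$read_id[classified$major == "repeat"]
  zero <- c(sense = 0, antisense = 0, unknown = 0)
  if (!length(rep_reads) || !length(refs$repeats))
    return(list(total = zero,
                per_family = data.frame(family = character(0), sense = numeric(0),
                                        antisense = numeric(0),
                                        unknown = numeric(0))))
  h <- hits[hits$read_id %in% rep_reads, , drop = FALSE]
  ov <- overlap_hits(hits_granges(h), refs$repeats, min_overlap)
  if (!nrow(ov)) return(list(total = zero, per_family = NULL))
  rid <- h$read_id[ov$hit]
  n_ov <- table(rid)
  w <- counts[rid] / as.numeric(n_ov[rid])
  ori <- refs$repeats$orientation[ov$feat]
  fam <- refs$repeats$family[ov$feat]
  if (is.null(fam)) fam <- refs$repeats$feature_id[ov$feat]
  rel <- ifelse(ori == "unknown", "unknown",
                ifelse(h$strand[ov$hit] == ori, "sense", "antisense"))
  total <- zero
  agg <- tapply(w, rel, sum)
  total[names(agg)] <- agg
  pf <- as.data.frame.matrix(
    tapply(w, list(fam, rel), sum, default = 0))
  for (col in names(zero)) if (is.null(pf[[col]])) pf[[col]] <- 0
  per_family <- data.frame(family = rownames(pf),
                           sense = pf$sense, antisense = pf$antisense,
                           unknown = pf$unknown, stringsAsFactors = FALSE)
  list(total = total, per_family = per_family)
}

resolve_counts <- function(counts, ids) {
  if (is.null(counts)) return(setNames(rep(1, length(ids)), ids))
  stopifnot(!is.null(names(counts)))
  counts
}

#' Per-class shares of mapped reads
#'
#' @param classified output of [classify_reads()].
#' @param counts optional named read counts per `read_id` (default 1);
#'   supply collapsed-sequence counts to weight by reads rather than
#'   unique sequences.
#' @return named numeric vector of class shares (miRNA, tRF, rRF, mRNA,
#'   repeat, none) summing to 1 over mapped reads.
#' @export
class_fractions <- function(classified, counts = NULL) {
  counts <- resolve_counts(counts, classified$read_id)
  classes <- c(CLASS_PRECEDENCE, "none")
  w <- counts[classified$read_id]
  tot <- sum(w)
  shares <- setNames(numeric(length(classes)), classes)
  if (tot == 0) return(shares)
  agg <- tapply(w, factor(classified$major, levels = classes), sum,
                default = 0)
  shares[names(agg)] <- agg / tot
  shares
}

#' Class-by-length profile of mapped reads
#'
#' @param classified output of [classify_reads()] (must carry `length`).
#' @param counts optional named read counts per `read_id`.
#' @param lengths length range reported (default 18-40 nt; reads outside
#'   are clamped into the terminal bins).
#' @return numeric matrix class x length; row sums equal per-class read
#'   counts.
#' @export
length_profile <- function(classified, counts = NULL, lengths = 18:40) {
  counts <- resolve_counts(counts, classified$read_id)
  classes <- c(CLASS_PRECEDENCE, "none")
  w <- counts[classified$read_id]
  l <- pmin(pmax(classified$length, min(lengths)), max(lengths))
  m <- tapply(w, list(factor(classified$major, levels = classes),
                      factor(l, levels = lengths)), sum, default = 0)
  m[is.na(m)] <- 0
  m
}
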