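# Independent reference implementations ("oracles") used to validate the
# package's algorithms. These deliberately use different algorithms from
# the implementation: exhaustive scans, pairwise enumeration, naive
# agglomeration, closed forms.

oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

# exhaustive sliding-window Hamming-distance mapper (both strands);
# N never matches anything
oracle_map <- function(reads, genome, max_mm = 3) {
  rows <- list()
  ids <- names(reads)
  for (ci in seq_along(genome)) {
    g <- strsplit(genome[[ci]], "")[[1]]
    G <- length(g)
    for (ri in seq_along(reads)) {
      r <- reads[[ri]]
      L <- nchar(r)
      if (G < L) next
      nwin <- G - L + 1L
      for (strand in c("+", "-")) {
        q <- strsplit(if (strand == "+") r else oracle_revcomp(r), "")[[1]]
        mm <- matrix(FALSE, L, nwin)
        for (k in seq_len(L)) {
          gk <- g[k:(k + nwin - 1L)]
          mm[k, ] <- gk != q[k] | gk == "N" | q[k] == "N"
        }
        tot <- colSums(mm)
        tail_rows <- if (strand == "+") c(L - 1L, L) else c(1L, 2L)
        tails <- colSums(mm[tail_rows, , drop = FALSE])
        ok <- which(tot <= max_mm)
        if (length(ok))
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = ids[ri], contig = names(genome)[ci],
            start = ok - 1L, end = ok - 1L + L, strand = strand,
            mm_internal = tot[ok] - tails[ok], mm_tail3 = tails[ok],
            mm_total = tot[ok], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mm_internal = integer(0),
                      mm_tail3 = integer(0), mm_total = integer(0)))
  do.call(rbind, rows)
}

# per-read best-hit rule applied to an oracle hit table
oracle_besthit <- function(hits, max_internal = 1, max_tail3 = 2) {
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$read_id),
                        function(i) {
    b <- i[hits$mm_total[i] == min(hits$mm_total[i])]
    b[hits$mm_internal[b] <= max_internal & hits$mm_tail3[b] <= max_tail3]
  }))
  hits[sort(keep), , drop = FALSE]
}

canon_hits <- function(h) {
  h <- h[c("read_id", "contig", "start", "end", "strand", "mm_internal",
           "mm_tail3", "mm_total")]
  h <- h[order(h$read_id, h$contig, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# all-pairs ping-pong overlap enumeration
oracle_pingpong <- function(hits, counts, max_o = 30) {
  n_o <- numeric(max_o)
  w <- counts[hits$read_id]
  p5 <- ifelse(hits$strand == "+", hits$start, hits$end - 1L)
  for (ct in unique(hits$contig)) {
    ip <- which(hits$contig == ct & hits$strand == "+")
    im <- which(hits$contig == ct & hits$strand == "-")
    for (i in ip) {
      o <- p5[im] - p5[i] + 1L
      sel <- which(o >= 1L & o <= max_o)
      for (s in sel) n_o[o[s]] <- n_o[o[s]] + w[i] * w[im[s]]
    }
  }
  n_o
}

# sweep-line interval union (1-based inclusive intervals, merging touching
# intervals)
oracle_sweep_union <- function(df) {
  out <- list()
  for (ct in sort(unique(df$contig))) {
    x <- df[df$contig == ct, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    cs <- x$start[1]; ce <- x$end[1]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= ce + 1L) ce <- max(ce, x$end[i])
      else {
        out[[length(out) + 1L]] <- data.frame(contig = ct, start = cs,
                                              end = ce)
        cs <- x$start[i]; ce <- x$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(contig = ct, start = cs, end = ce)
  }
  do.call(rbind, out)
}

granges_df <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

# O(n^3) average-linkage (UPGMA) agglomeration returning the cophenetic
# distance matrix; ties broken by lowest index pair
oracle_average_linkage_cophenetic <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  coph <- matrix(0, n, n)
  cl <- lapply(seq_len(n), identity)
  while (length(cl) > 1) {
    best <- c(Inf, NA, NA)
    k <- length(cl)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dd <- mean(dm[cl[[i]], cl[[j]]])
      if (dd < best[1] - 1e-12) best <- c(dd, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[cl[[i]], cl[[j]]] <- best[1]
    coph[cl[[j]], cl[[i]]] <- best[1]
    cl[[i]] <- c(cl[[i]], cl[[j]])
    cl[[j]] <- NULL
  }
  coph
}

# textbook pooled-variance two-sample t statistic
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# closed-form 2x2 Pearson chi-square
oracle_chisq_2x2 <- function(a, b, c, d) {
  o <- matrix(c(a, c, b, d), 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  uni <- (e1 - s1 + 1) + (e2 - s2 + 1) - inter
  inter / uni
}
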