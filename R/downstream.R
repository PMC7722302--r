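#' Seed-based miRNA target scanning on 3' UTRs
#'
#' A site is reported where the miRNA seed (positions 2-8, a 7-mer) pairs
#' the UTR perfectly in antiparallel orientation - Watson-Crick throughout,
#' with up to `seed_gu_max` G:U wobbles tolerated and no mismatch - and the
#' total duplex score over the full-length ungapped extension reaches
#' `min_score`. Scoring: Watson-Crick +5, G:U +2, mismatch -3 per position,
#' with seed positions weighted twice (a 22-nt perfect duplex scores 145);
#' miRNA positions extending past the UTR end contribute 0.
#'
#' @param mirnas named character vector of miRNA sequences (5' to 3', DNA
#'   alphabet).
#' @param utrs named character vector of 3' UTR sequences (5' to 3').
#' @param min_score minimum duplex score for a reported site (default 140).
#' @param seed_gu_max G:U wobbles tolerated in the seed (default 1).
#' @return data.frame `mirna_id`, `mrna_id`, `start`, `end` (1-based UTR
#'   coordinates of the seed match), `n_gu` (wobbles in the seed) and
#'   `score`. Attribute `skipped` counts miRNA/UTR combinations skipped
#'   for missing sequence.
#' @export
scan_targets <- function(mirnas, utrs, min_score = 140, seed_gu_max = 1) {
  out <- list()
  skipped <- 0L
  for (mi in names(mirnas)) {
    mseq <- strsplit(toupper(mirnas[[mi]]), "")[[1]]
    if (length(mseq) < 8) { skipped <- skipped + 1L; next }
    for (ui in names(utrs)) {
      useq <- strsplit(toupper(utrs[[ui]]), "")[[1]]
      nu <- length(useq)
      if (nu < 7) { skipped <- skipped + 1L; next }
      # seed scan: miRNA position 2+k pairs UTR position j+6-k
      wc <- matrix(FALSE, nu - 6L, 7L)
      gu <- matrix(FALSE, nu - 6L, 7L)
      for (k in 0:6) {
        mb <- mseq[2L + k]
        ub <- useq[(7L - k):(nu - k)]
        wc[, k + 1L] <- ub == chartr("ACGT", "TGCA", mb)
        gu[, k + 1L] <- (mb == "G" & ub == "T") | (mb == "T" & ub == "G")
      }
      n_wc <- rowSums(wc)
      n_gu <- rowSums(gu)
      hit <- which(n_wc + n_gu == 7L & n_gu <= seed_gu_max)
      for (j in hit) {
        sc <- duplex_score(mseq, useq, j)
        if (sc >= min_score)
          out[[length(out) + 1L]] <- data.frame(
            mirna_id = mi, mrna_id = ui, start = j, end = j + 6L,
            n_gu = n_gu[j], score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna_id = character(0), mrna_id = character(0),
               start = integer(0), end = integer(0), n_gu = integer(0),
               score = numeric(0), stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  res
}

# full-length ungapped duplex score in the register set by a seed match at
# UTR position j (1-based): miRNA position i pairs UTR position j + 8 - i
duplex_score <- function(mseq, useq, j) {
  i <- seq_along(mseq)
  u <- j + 8L - i
  ok <- u >= 1L & u <= length(useq)
  mb <- mseq[ok]; ub <- useq[u[ok]]
  wc <- ub == chartr("ACGT", "TGCA", mb)
  gu <- (mb == "G" & ub == "T") | (mb == "T" & ub == "G")
  per <- ifelse(wc, 5, ifelse(gu, 2, -3))
  weight <- ifelse(i[ok] >= 2L & i[ok] <= 8L, 2, 1)
  sum(per * weight)
}

#' Chi-square statistic of a 2x2 table
#'
#' Closed-form Pearson statistic without continuity correction.
#'
#' @param a,b,c,d cell counts (rows: set 1 / set 2; columns: with/without).
#' @return list `chi_square`, `p` (df = 1), `expected` (2x2 matrix).
#' @export
chisq_2x2 <- function(a, b, c, d) {
  o <- matrix(c(a, c, b, d), 2)
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  x2 <- sum((o - e)^2 / e)
  list(chi_square = x2, p = pchisq(x2, df = 1, lower.tail = FALSE),
       expected = e)
}

#' GO term enrichment by chi-square with Bonferroni correction
#'
#' For every term annotated to any gene, tests the 2x2 table (target genes
#' with/without the term vs non-target background genes with/without) by an
#' uncorrected Pearson chi-square. Terms with any expected cell below
#' `min_expected` are flagged and excluded from testing. Significance uses
#' the strict Bonferroni level `alpha / n_tested`.
#'
#' @param targets character vector of target gene ids.
#' @param background character vector of background gene ids (target genes
#'   are removed from it).
#' @param gene2term data.frame with columns `gene`, `term`.
#' @param alpha family-wise error level (default 0.05).
#' @param min_expected minimum expected cell count for a testable term
#'   (default 5).
#' @return data.frame per term: `term`, `a`, `b`, `c`, `d`, `tested`,
#'   `chi_square`, `p`, `bonferroni_alpha`, `significant`, sorted by `p`.
#' @export
go_enrichment <- function(targets, background, gene2term, alpha = 0.05,
                          min_expected = 5) {
  targets <- unique(targets)
  background <- setdiff(unique(background), targets)
  terms <- sort(unique(gene2term$term))
  by_term <- split(gene2term$gene, gene2term$term)
  n_t <- length(targets); n_b <- length(background)
  rows <- lapply(terms, function(tm) {
    g <- by_term[[tm]]
    a <- sum(targets %in% g); b <- n_t - a
    c_ <- sum(background %in% g); d <- n_b - c_
    res <- chisq_2x2(a, b, c_, d)
    tested <- all(res$expected >= min_expected)
    data.frame(term = tm, a = a, b = b, c = c_, d = d, tested = tested,
               chi_square = if (tested) res$chi_square else NA_real_,
               p = if (tested) res$p else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_tested <- sum(out$tested)
  out$bonferroni_alpha <- if (n_tested > 0) alpha / n_tested else NA_real_
  out$significant <- out$tested & !is.na(out$p) &
    out$p < out$bonferroni_alpha
  out[order(out$p), , drop = FALSE]
}

#' Target-site enrichment on regeneration-associated genes
#'
#' Compares the number of target sites that a miRNA set places on
#' regeneration-associated genes vs all other genes, against a control
#' miRNA set, by a 2x2 chi-square.
#'
#' @param sites site table from [scan_targets()].
#' @param phenotype_mirnas,control_mirnas miRNA id sets.
#' @param regen_genes ids of regeneration-associated genes.
#' @return list: `table` (2x2 counts), `chi_square`, `p`, `verdict` in
#'   `c("enriched", "not-enriched", "not-testable")`.
#' @export
regen_target_comparison <- function(sites, phenotype_mirnas,
                                    control_mirnas, regen_genes) {
  cnt <- function(set, on) {
    sum(sites$mirna_id %in% set &
          (sites$mrna_id %in% regen_genes) == on)
  }
  a <- cnt(phenotype_mirnas, TRUE); b <- cnt(phenotype_mirnas, FALSE)
  c_ <- cnt(control_mirnas, TRUE); d <- cnt(control_mirnas, FALSE)
  tab <- matrix(c(a, c_, b, d), 2,
                dimnames = list(c("phenotype", "control"),
                                c("regen", "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, chi_square = NA_real_, p = NA_real_,
                verdict = "not-testable"))
  res <- chisq_2x2(a, b, c_, d)
  enr <- a / (a + b) > c_ / (c_ + d) && res$p < 0.05
  list(table = tab, chi_square = res$chi_square, p = res$p,
       verdict = if (enr) "enriched" else "not-enriched")
}

#' Classify a knockdown animal's photoreceptor phenotype
#'
#' Categories, in order of precedence: `lesion/lysed` (flag dominates),
#' `no-PR` (0 photoreceptors), `cyclopia` (1), then for paired
#' photoreceptors `irregular-paired` iff the two surface areas differ by
#' more than `tol` relative to the smaller one (100 vs 140 square units is
#' a 40 percent difference, hence irregular), or the photoreceptor
#' distance relative to head diameter deviates by more than `tol` from the
#' control average, or the surrounding white region is absent; otherwise
#' `regular-paired`. All geometric rules are scale-invariant.
#'
#' @param record list or one-row data.frame with `pr_count`, `area_left`,
#'   `area_right`, `distance`, `head_diameter`, `white_region_present`,
#'   `lesion_or_lysed`.
#' @param control_summary list with `mean_dist_ratio`: control mean of
#'   distance / head diameter (see [control_summary()]).
#' @param tol relative deviation threshold (default 1/3).
#' @return one of `"regular-paired"`, `"irregular-paired"`, `"cyclopia"`,
#'   `"no-PR"`, `"lesion/lysed"`.
#' @export
classify_phenotype <- function(record, control_summary, tol = 1 / 3) {
  r <- as.list(record)
  if (isTRUE(r$lesion_or_lysed)) return("lesion/lysed")
  if (r$pr_count == 0) return("no-PR")
  if (r$pr_count == 1) return("cyclopia")
  area_dev <- if (r$area_left == r$area_right) 0 else
    abs(r$area_left - r$area_right) / min(r$area_left, r$area_right)
  dist_dev <- abs(r$distance / r$head_diameter -
                    control_summary$mean_dist_ratio) /
    control_summary$mean_dist_ratio
  if (area_dev > tol || dist_dev > tol || !isTRUE(r$white_region_present))
    return("irregular-paired")
  "regular-paired"
}

#' Control-group summary for phenotype classification
#'
#' @param records data.frame of control (scrambled) animals with paired
#'   photoreceptors: columns as in [classify_phenotype()].
#' @return list with `mean_dist_ratio` (mean distance / head diameter) and
#'   `mean_area` (mean of per-animal mean photoreceptor areas).
#' @export
control_summary <- function(records) {
  paired <- records[records$pr_count == 2, , drop = FALSE]
  list(mean_dist_ratio = mean(paired$distance / paired$head_diameter),
       mean_area = mean((paired$area_left + paired$area_right) / 2))
}

#' Photoreceptor size statistics for one knockdown condition
#'
#' Compares per-animal mean photoreceptor surface areas of a knockdown arm
#' against controls: relative mean area, pooled-variance two-sample t
#' statistic (two-tailed), and the ratio of variances of the relative
#' photoreceptor distances (knockdown / control), reported descriptively.
#'
#' @param condition,control data.frames of paired-photoreceptor animals
#'   with columns `area_left`, `area_right`, `distance`, `head_diameter`.
#' @param welch if `TRUE`, use the Welch t-test instead of the pooled
#'   (Student) form.
#' @return list: `relative_area`, `t`, `df`, `p`,
#'   `distance_variance_ratio`, `n` (condition/control sample sizes).
#' @export
pr_stats <- function(condition, control, welch = FALSE) {
  parea <- function(d) (d$area_left + d$area_right) / 2
  pdist <- function(d) d$distance / d$head_diameter
  x <- parea(condition); y <- parea(control)
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 paired-photoreceptor animals per arm")
  tt <- t.test(x, y, var.equal = !welch)
  list(relative_area = mean(x) / mean(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       distance_variance_ratio = var(pdist(condition)) /
         var(pdist(control)),
       n = c(condition = length(x), control = length(y)))
}

#' Tabulate phenotype category fractions per condition
#'
#' @param records data.frame of animals with a `condition` column plus the
#'   [classify_phenotype()] fields.
#' @param control_condition name of the control arm used for the
#'   irregularity reference (default `"scrambled"`).
#' @return data.frame of per-condition category fractions.
#' @export
phenotype_summary <- function(records, control_condition = "scrambled") {
  ctrl <- control_summary(
    records[records$condition == control_condition, , drop = FALSE])
  cats <- c("regular-paired", "irregular-paired", "cyclopia", "no-PR",
            "lesion/lysed")
  records$category <- vapply(seq_len(nrow(records)), function(i)
    classify_phenotype(records[i, ], ctrl), "")
  tab <- table(records$condition,
               factor(records$category, levels = cats))
  frac <- sweep(tab, 1, rowSums(tab), "/")
  data.frame(condition = rownames(frac),
             as.data.frame.matrix(frac), check.names = FALSE,
             stringsAsFactors = FALSE)
}
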