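#' Build a per-class RPM expression matrix across timepoints
#'
#' Counts are scaled to reads per million reads of the same small RNA
#' class within each library (so each column sums to 1e6 before entity
#' filtering), then entities never reaching `min_rpm` in any timepoint are
#' removed.
#'
#' @param counts data.frame with columns `entity`, `timepoint`, `count`
#'   (all counts of one class: miRNA genes, source tRNAs or piRNA cluster
#'   loci).
#' @param timepoints column order of the matrix (default
#'   `c("0h","24h","72h","120h")`).
#' @param min_rpm entity filter: kept iff RPM >= `min_rpm` in at least one
#'   timepoint (default 100).
#' @return numeric matrix entity x timepoint of RPM values.
#' @export
build_matrix <- function(counts, timepoints = c("0h", "24h", "72h", "120h"),
                         min_rpm = 100) {
  stopifnot(all(c("entity", "timepoint", "count") %in% names(counts)))
  m <- tapply(counts$count,
              list(factor(counts$entity, levels = unique(counts$entity)),
                   factor(counts$timepoint, levels = timepoints)),
              sum, default = 0)
  m[is.na(m)] <- 0
  tot <- colSums(m)
  rpm <- sweep(m, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  rpm[apply(rpm, 1, max) >= min_rpm, , drop = FALSE]
}

#' Row Z-scores of an expression matrix
#'
#' Rows are centred and scaled to unit standard deviation; constant rows
#' (sd 0) get all-zero Z-scores and are flagged.
#'
#' @param m numeric matrix.
#' @return list with `z` (matrix) and `constant` (logical vector per row).
#' @export
row_zscores <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  constant <- s == 0
  z <- (m - mu) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  list(z = z, constant = constant)
}

#' Hierarchical clustering of expression profiles (Pearson distance,
#' average linkage)
#'
#' Rows and columns are clustered by average-linkage agglomeration on the
#' distance `d(x, y) = 1 - r(x, y)` (Pearson correlation). The two
#' clusters below the final row merge define the groups; `group-a` is the
#' cluster with the higher mean row Z-score at the reference timepoint
#' (24 h by default, the early regeneration response).
#'
#' @param m RPM matrix from [build_matrix()] (>= 2 rows).
#' @param reference_timepoint column used to orient the two groups
#'   (default `"24h"`).
#' @return a list of class `dendro_groups`: `groups` (named factor
#'   `group-a`/`group-b` per entity), `row_tree`, `col_tree` (hclust),
#'   `row_order`, `col_order`, `z` (row Z-score matrix), `constant`
#'   (flagged all-constant rows).
#' @export
cluster_rows <- function(m, reference_timepoint = "24h") {
  if (nrow(m) < 2)
    stop("clustering requires at least 2 retained entities")
  dr <- pearson_dist(m)
  row_tree <- hclust(dr, method = "average")
  col_tree <- if (ncol(m) >= 2)
    hclust(pearson_dist(t(m)), method = "average") else NULL
  cut <- cutree(row_tree, k = 2)
  zs <- row_zscores(m)
  ref <- if (reference_timepoint %in% colnames(m)) reference_timepoint
  else colnames(m)[min(2, ncol(m))]
  mean_z <- tapply(zs$z[, ref], cut, mean)
  a <- as.integer(names(mean_z)[which.max(mean_z)])
  groups <- factor(ifelse(cut == a, "group-a", "group-b"),
                   levels = c("group-a", "group-b"))
  names(groups) <- rownames(m)
  structure(list(groups = groups, row_tree = row_tree, col_tree = col_tree,
                 row_order = row_tree$order,
                 col_order = if (is.null(col_tree)) seq_len(ncol(m))
                 else col_tree$order,
                 z = zs$z, constant = zs$constant),
            class = "dendro_groups")
}

# 1 - Pearson correlation distance over matrix rows; constant rows are
# assigned the maximal distance 2 to anything non-identical
pearson_dist <- function(m) {
  s <- apply(m, 1, sd)
  r <- suppressWarnings(cor(t(m)))
  r[is.na(r)] <- -1
  const <- which(s == 0)
  for (i in const) for (j in const)
    if (identical(unname(m[i, ]), unname(m[j, ]))) r[i, j] <- 1
  diag(r) <- 1
  as.dist(1 - r)
}

#' Select upregulated candidate entities
#'
#' A candidate rises at least `fold`-fold after amputation (maximum
#' post-amputation RPM vs the 0 h RPM; entities silent at 0 h but
#' expressed later count as upregulated) and has a mean RPM across all
#' timepoints of at least `min_mean_rpm`.
#'
#' @param m RPM matrix from [build_matrix()]; first column is the 0 h
#'   baseline.
#' @param fold minimum fold change (default 2).
#' @param min_mean_rpm minimum mean expression (default 100).
#' @param baseline name of the baseline column (default the first).
#' @return character vector of selected entity names.
#' @export
select_upregulated <- function(m, fold = 2, min_mean_rpm = 100,
                               baseline = colnames(m)[1]) {
  post <- m[, setdiff(colnames(m), baseline), drop = FALSE]
  peak <- apply(post, 1, max)
  base <- m[, baseline]
  up <- ifelse(base == 0, peak > 0, peak >= fold * base)
  rownames(m)[up & rowMeans(m) >= min_mean_rpm]
}

#' Write an expression matrix (and optional groups) as TSV
#'
#' @param m matrix from [build_matrix()] or a Z-score matrix.
#' @param path output TSV.
#' @param groups optional `dendro_groups` whose assignment column is
#'   appended.
#' @export
write_matrix_tsv <- function(m, path, groups = NULL) {
  df <- data.frame(entity = rownames(m), m, check.names = FALSE)
  if (!is.null(groups))
    df$group <- as.character(groups$groups[rownames(m)])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
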