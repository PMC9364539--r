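# Array-level quality control by three outlier criteria, plus transcript
# cluster (TC-ID) filtering and best-probe-per-gene selection.

boxplot_flag <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  x > q[2] + 1.5 * (q[2] - q[1])
}

#' Mean inter-array distance score per sample
#'
#' For each array the score is the mean Euclidean distance between its
#' expression column and every other array's column. Arrays are flagged by
#' the boxplot rule (score > Q3 + 1.5 IQR).
#'
#' @param dataset an `ExpressionDataset` with at least 3 samples.
#' @return data.frame: sample_id, distance_score, flagged.
#' @export
score_array_distance <- function(dataset) {
  n <- n_samples(dataset)
  if (n < 3) stop("array distance score needs >= 3 samples")
  d <- as.matrix(dist(t(dataset$values)))
  score <- rowSums(d) / (n - 1)
  data.frame(sample_id = dataset$sample_ids, distance_score = unname(score),
             flagged = unname(boxplot_flag(score)), stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov statistic of each array against the pooled intensities
#'
#' `K_a` is the supremum distance between the ECDF of one array's intensities
#' and the ECDF of all intensities pooled (the array under test included).
#' Flagged by the boxplot rule.
#'
#' @param dataset an `ExpressionDataset` with at least 2 samples.
#' @return data.frame: sample_id, ks_stat, flagged.
#' @export
score_array_ks <- function(dataset) {
  if (n_samples(dataset) < 2) stop("KS score needs >= 2 samples")
  v <- dataset$values
  pooled <- sort(as.numeric(v))
  npool <- length(pooled)
  ks <- vapply(seq_len(ncol(v)), function(j) {
    x <- sort(v[, j])
    # both ECDFs are right-continuous steps jumping only at pooled points,
    # so the sup is attained on this grid; findInterval handles ties
    Fi <- findInterval(pooled, x) / length(x)
    Fp <- findInterval(pooled, pooled) / npool
    max(abs(Fi - Fp))
  }, numeric(1))
  data.frame(sample_id = dataset$sample_ids, ks_stat = ks,
             flagged = unname(boxplot_flag(ks)), stringsAsFactors = FALSE)
}

#' Hoeffding's D statistic per array on MA-plot coordinates
#'
#' For each array, with `m` the per-gene median across arrays, Hoeffding's D
#' measures dependence between `A = (x + m)/2` and `M = x - m`. A clean array
#' has no intensity-dependent bias (M independent of A, D near 0); arrays
#' with `D > threshold` are flagged.
#'
#' Classical rank statistic with midranks for ties:
#' `D = 30 * ((n-2)(n-3) D1 + D2 - 2(n-2) D3) / (n(n-1)(n-2)(n-3)(n-4))`
#' where `D1 = sum (Q-1)(Q-2)`, `D2 = sum (R-1)(R-2)(S-1)(S-2)`,
#' `D3 = sum (R-2)(S-2)(Q-1)` and `Q_i` is the bivariate rank.
#'
#' @param dataset an `ExpressionDataset` with at least 5 features.
#' @param threshold flag threshold on D (default 0.15).
#' @return data.frame: sample_id, hoeffding_stat, flagged.
#' @export
score_array_hoeffding <- function(dataset, threshold = 0.15) {
  if (n_features(dataset) < 5) stop("Hoeffding's D needs >= 5 features")
  v <- dataset$values
  m <- apply(v, 1, median)
  d <- vapply(seq_len(ncol(v)), function(j) {
    hoeffding_d((v[, j] + m) / 2, v[, j] - m)
  }, numeric(1))
  data.frame(sample_id = dataset$sample_ids, hoeffding_stat = d,
             flagged = d > threshold, stringsAsFactors = FALSE)
}

#' Hoeffding's D between two vectors
#'
#' @param x,y paired numeric vectors, length >= 5.
#' @return Hoeffding's D (in \[-0.5, 1\] up to ties).
#' @export
hoeffding_d <- function(x, y) {
  n <- length(x)
  if (n < 5 || length(y) != n) stop("Hoeffding's D needs paired n >= 5")
  R <- rank(x)  # midranks
  S <- rank(y)
  # bivariate rank with tie weights 1/2 per tied coordinate (1/4 both tied)
  Q <- vapply(seq_len(n), function(i) {
    cx <- (x < x[i]) + 0.5 * (x == x[i])
    cy <- (y < y[i]) + 0.5 * (y == y[i])
    sum(cx * cy) - 0.25  # remove self term (0.5 * 0.5)
  }, numeric(1)) + 1
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Run all three QC criteria and drop triple-flagged arrays
#'
#' An array is removed only when all three criteria (inter-array distance,
#' KS against pooled intensities, Hoeffding's D on MA coordinates) flag it as
#' an outlier.
#'
#' @param dataset an `ExpressionDataset`.
#' @param hoeffding_threshold threshold passed to [score_array_hoeffding()].
#' @return list: `dataset` (survivors), `qc` (per-sample report: the three
#'   statistics, three flags, `removed`).
#' @export
remove_outlier_arrays <- function(dataset, hoeffding_threshold = 0.15) {
  sd_ <- score_array_distance(dataset)
  sk <- score_array_ks(dataset)
  sh <- score_array_hoeffding(dataset, hoeffding_threshold)
  qc <- data.frame(sample_id = dataset$sample_ids,
                   distance_score = sd_$distance_score,
                   ks_stat = sk$ks_stat,
                   hoeffding_stat = sh$hoeffding_stat,
                   flag_distance = sd_$flagged,
                   flag_ks = sk$flagged,
                   flag_hoeffding = sh$flagged,
                   stringsAsFactors = FALSE)
  qc$removed <- qc$flag_distance & qc$flag_ks & qc$flag_hoeffding
  keep <- !qc$removed
  list(dataset = subset_dataset(dataset, samples = which(keep)), qc = qc)
}

#' Filter TC-IDs by expression level and pick one probe per gene
#'
#' A feature is kept iff its median expression exceeds the mean of all
#' feature medians, or its per-sample expression exceeds that mean-of-medians
#' in strictly more than `median_fraction` of samples (default 0.125, the
#' one-founder-in-eight allowance for strains carrying low/no-expression
#' alleles). Among surviving features sharing a gene symbol, the one with the
#' highest expression is selected so each gene is represented by a unique
#' TC-ID.
#'
#' @param dataset an `ExpressionDataset`.
#' @param median_fraction exceedance fraction for the second rule.
#' @param selection how "highest expression" is measured for probe selection:
#'   mean (default), median, or max across samples. Ties break by
#'   lexicographic TC-ID.
#' @param mean_of_medians optionally, a fixed threshold to use instead of the
#'   mean of this dataset's feature medians (e.g. to re-apply a filter fitted
#'   on a larger dataset).
#' @return list: `dataset` (one feature per gene), `report` (per-feature:
#'   median expression, both rule flags, `selected_for_gene`), and
#'   `mean_of_medians`.
#' @export
filter_tcids <- function(dataset, median_fraction = 0.125,
                         selection = c("mean", "median", "max"),
                         mean_of_medians = NULL) {
  selection <- match.arg(selection)
  v <- dataset$values
  med <- apply(v, 1, median)
  mom <- if (is.null(mean_of_medians)) mean(med) else mean_of_medians
  pass_median <- med > mom
  frac_above <- rowMeans(v > mom)
  pass_fraction <- frac_above > median_fraction
  keep <- pass_median | pass_fraction

  level <- switch(selection,
                  mean = rowMeans(v),
                  median = med,
                  max = apply(v, 1, max))
  selected <- logical(nrow(v))
  kidx <- which(keep)
  if (length(kidx)) {
    ord <- kidx[order(dataset$gene_symbols[kidx], -level[kidx],
                      dataset$feature_ids[kidx])]
    first <- ord[!duplicated(dataset$gene_symbols[ord])]
    selected[first] <- TRUE
  }
  report <- data.frame(feature_id = dataset$feature_ids,
                       gene_symbol = dataset$gene_symbols,
                       median_expression = unname(med),
                       frac_above_mom = unname(frac_above),
                       pass_median_rule = unname(pass_median),
                       pass_fraction_rule = unname(pass_fraction),
                       selected_for_gene = selected,
                       stringsAsFactors = FALSE)
  list(dataset = subset_dataset(dataset, features = which(selected)),
       report = report, mean_of_medians = mom)
}
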