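# Robust gene-phenotype association: biweight midcorrelation with Student-t
# p-values honouring pairwise-complete sample counts.

bicor_weights <- function(x) {
  medx <- median(x)
  madx <- median(abs(x - medx))  # unscaled MAD, per the bicor definition
  if (madx == 0) return(NULL)    # caller falls back to Pearson standardization
  u <- (x - medx) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- (x - medx) * w
  s <- sqrt(sum(xt^2))
  if (s == 0) return(NULL)
  xt / s
}

pearson_std <- function(x) {
  xc <- x - mean(x)
  s <- sqrt(sum(xc^2))
  if (s == 0) stop("correlation undefined: constant vector")
  xc / s
}

#' Biweight midcorrelation
#'
#' Robust correlation based on median/MAD weighting: with `u_i =
#' (x_i - med_x) / (9 mad_x)` and weights `w_i = (1 - u_i^2)^2 1[|u_i| < 1]`,
#' each vector is centred at its median, weighted and normalized, and the
#' correlation is the inner product of the two weighted vectors. A vector
#' whose MAD is zero falls back to Pearson standardization; a vector constant
#' under both schemes is an error.
#'
#' @param x,y paired finite numeric vectors, length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("bicor needs paired vectors of length >= 3")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("bicor needs finite values; subset to complete pairs first")
  xs <- bicor_weights(x); if (is.null(xs)) xs <- pearson_std(x)
  ys <- bicor_weights(y); if (is.null(ys)) ys <- pearson_std(y)
  r <- sum(xs * ys)
  max(-1, min(1, r))
}

#' Two-sided Student p-value for a correlation
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' `|r| = 1` returns `p = 0` (flagged upstream, not an error).
#'
#' @param r correlation value(s).
#' @param n number(s) of observations, `>= 3`.
#' @return two-sided p-value(s).
#' @export
student_p <- function(r, n) {
  if (any(n < 3)) stop("student_p needs n >= 3")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  tt <- r[ok] * sqrt((n[ok] - 2) / (1 - r[ok]^2))
  if (length(n) == 1) n <- rep(n, length(r))
  p[ok] <- 2 * pt(-abs(tt), df = n[ok] - 2)
  p
}

#' Correlate every gene with every phenotype by bicor
#'
#' Uses pairwise-complete observations per gene x trait (expression has no
#' missing values after validation, so completeness is driven by the
#' phenotype). Traits with fewer than 3 complete pairs yield NA rows with a
#' reason. Both nominal and BH-adjusted p-value columns are emitted; the
#' significance flag is nominal `p < 0.05`, the screening convention for
#' "correlated with body fat %".
#'
#' @param dataset a filtered `ExpressionDataset`.
#' @param phenotypes data.frame keyed by sample_id with numeric trait columns.
#' @param traits optional character vector restricting which traits to use.
#' @param alpha nominal significance threshold for the flag (default 0.05).
#' @return data.frame: feature_id, gene_symbol, trait, bicor, n_obs, p_value,
#'   p_adj_bh (within trait), significant, reason.
#' @export
correlate_expression_with_traits <- function(dataset, phenotypes,
                                             traits = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(phenotypes), "sample_id" %in% names(phenotypes))
  if (is.null(traits))
    traits <- setdiff(names(phenotypes),
                      "sample_id")[vapply(phenotypes[setdiff(names(phenotypes),
                                                             "sample_id")],
                                          is.numeric, logical(1))]
  idx <- match(dataset$sample_ids, phenotypes$sample_id)
  out <- vector("list", length(traits))
  for (k in seq_along(traits)) {
    tr <- traits[k]
    y <- phenotypes[[tr]][idx]
    ok <- !is.na(y)
    nobs <- sum(ok)
    G <- n_features(dataset)
    if (nobs < 3) {
      out[[k]] <- data.frame(feature_id = dataset$feature_ids,
                             gene_symbol = dataset$gene_symbols, trait = tr,
                             bicor = NA_real_, n_obs = nobs, p_value = NA_real_,
                             p_adj_bh = NA_real_, significant = NA,
                             reason = "fewer than 3 complete pairs",
                             stringsAsFactors = FALSE)
      next
    }
    ys <- bicor_weights(y[ok]); if (is.null(ys)) ys <- pearson_std(y[ok])
    r <- apply(dataset$values[, ok, drop = FALSE], 1, function(x) {
      xs <- bicor_weights(x); if (is.null(xs)) xs <- pearson_std(x)
      max(-1, min(1, sum(xs * ys)))
    })
    p <- student_p(r, rep(nobs, G))
    out[[k]] <- data.frame(feature_id = dataset$feature_ids,
                           gene_symbol = dataset$gene_symbols, trait = tr,
                           bicor = unname(r), n_obs = nobs, p_value = p,
                           p_adj_bh = p.adjust(p, "BH"),
                           significant = p < alpha, reason = "",
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
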