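# Per-gene linear models with empirical-Bayes variance moderation, DEG calls
# by diet (moderated t) and strain (moderated F), and hypergeometric gene-set
# over-representation.

#' Build the shared design matrix for differential expression
#'
#' Treatment coding with the first strain, the HP diet and the first week as
#' reference levels, so positive diet coefficients mean higher expression on
#' the HS diet. The same additive design (strain + diet + week) serves both
#' DEG families.
#'
#' @param metadata per-sample metadata (strain, diet, week).
#' @param include optional subset of terms, default `c("strain","diet","week")`.
#' @return list: `X` (design matrix), `diet_col`, `strain_cols`, `terms`.
#' @export
make_design <- function(metadata, include = c("strain", "diet", "week")) {
  md <- metadata
  md$strain <- factor(md$strain)
  md$diet <- factor(md$diet, levels = VALID_DIETS)
  md$week <- factor(md$week)
  if (any(include == "diet") && nlevels(droplevels(md$diet)) < 2)
    stop("both diet levels must be present")
  if (any(include == "strain") && nlevels(md$strain) < 2)
    stop("at least 2 strains required")
  fml <- stats::as.formula(paste("~", paste(include, collapse = " + ")))
  X <- model.matrix(fml, data = md)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  list(X = X,
       diet_col = grep("^diet", colnames(X)),
       strain_cols = grep("^strain", colnames(X)),
       terms = include)
}

#' Least-squares fits for every gene under a common design
#'
#' One QR decomposition of the design is shared across genes:
#' `beta = (X'X)^-1 X'y`, residual variance `s2 = RSS / (n - rank)`, and the
#' unscaled coefficient standard deviations are the square roots of the
#' diagonal of `(X'X)^-1`.
#'
#' @param dataset an `ExpressionDataset`.
#' @param design a [make_design()] result (or any full-rank matrix in `X`).
#' @return list: `coefficients` (genes x p), `sigma2`, `df_residual`,
#'   `stdev_unscaled` (genes x p), `cov_unscaled` (`(X'X)^-1`), `design`.
#' @export
fit_gene_models <- function(dataset, design) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (n != n_samples(dataset)) stop("design rows must match samples")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (n <= p) stop("no residual degrees of freedom (n <= rank)")
  Y <- t(dataset$values)                    # samples x genes
  qrX <- qr(X)
  B <- qr.coef(qrX, Y)                      # p x genes
  res <- qr.resid(qrX, Y)
  rss <- colSums(res^2)
  df <- n - p
  XtXinv <- chol2inv(chol(crossprod(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  sdu <- sqrt(diag(XtXinv))
  list(coefficients = t(B),
       sigma2 = rss / df,
       df_residual = rep(df, ncol(Y)),
       stdev_unscaled = matrix(sdu, ncol(Y), p, byrow = TRUE,
                               dimnames = list(dataset$feature_ids,
                                               colnames(X))),
       cov_unscaled = XtXinv,
       design = design,
       feature_ids = dataset$feature_ids,
       gene_symbols = dataset$gene_symbols)
}

#' Invert the trigamma function
#'
#' Monotone Newton inversion of `trigamma` on (0, Inf); used when matching
#' moments of log residual variances to a scaled inverse chi-square prior.
#'
#' @param y positive value(s) of trigamma(x).
#' @return x with trigamma(x) = y.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (it in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Fits a scaled inverse chi-square prior `s0^2, d0` to the residual
#' variances by moment matching on `e_g = log s_g^2 - digamma(d/2) +
#' log(d/2)`: `trigamma(d0/2) = var(e) - trigamma(d/2)` (Newton inversion)
#' and `log s0^2 = mean(e) + digamma(d0/2) - log(d0/2)`. When the observed
#' spread is no larger than expected under equal true variances the prior
#' degrees of freedom are infinite and every posterior variance equals the
#' pooled value. Posterior: `s~2_g = (d0 s0^2 + d s2_g) / (d0 + d)`.
#'
#' @param fits a [fit_gene_models()] result (>= 2 genes, positive df).
#' @return `fits` augmented with `d0`, `s02`, `s2_post`, `df_total`.
#' @export
ebayes_moderate <- function(fits) {
  s2 <- fits$sigma2
  d <- fits$df_residual
  if (length(s2) < 2) stop("moderation needs >= 2 genes")
  if (any(d <= 0)) stop("moderation needs positive residual df")
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- var(e)
  gap <- evar - mean(trigamma(d / 2))
  if (is.na(gap) || gap <= 0) {
    d0 <- Inf
    s02 <- mean(s2)         # pooled variance: equal-df arithmetic mean
    s2_post <- rep(s02, length(s2))
  } else {
    d0 <- 2 * trigamma_inverse(gap)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  }
  fits$d0 <- d0
  fits$s02 <- s02
  fits$s2_post <- s2_post
  fits$df_total <- d + d0
  fits
}

de_table <- function(fits, stat, p, coef_col = NULL, alpha = 0.05,
                     stat_name = "t") {
  tb <- data.frame(feature_id = fits$feature_ids,
                   gene_symbol = fits$gene_symbols,
                   stringsAsFactors = FALSE)
  if (!is.null(coef_col)) tb$coef <- fits$coefficients[, coef_col]
  tb[[stat_name]] <- stat
  tb$p_value <- p
  tb$p_adj <- p.adjust(p, "BH")
  tb$de <- tb$p_adj < alpha
  attr(tb, "d0") <- fits$d0
  attr(tb, "s02") <- fits$s02
  tb
}

#' Call genes differentially expressed by diet (moderated t)
#'
#' Moderated t on the diet (HS vs HP) coefficient of the shared additive
#' design, BH adjustment across genes, DEG flag at adjusted `p < alpha`.
#'
#' @param dataset an `ExpressionDataset` with both diets.
#' @param design optional [make_design()] result; built from the metadata
#'   (strain + diet + week) if omitted.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame: feature_id, gene_symbol, coef (log2 HS - HP), t,
#'   p_value, p_adj, de; attributes d0, s02.
#' @export
call_diet_degs <- function(dataset, design = NULL, alpha = 0.05) {
  if (is.null(design)) design <- make_design(dataset$metadata)
  if (length(design$diet_col) != 1) stop("design must contain one diet column")
  fits <- ebayes_moderate(fit_gene_models(dataset, design))
  j <- design$diet_col
  tstat <- fits$coefficients[, j] /
    (fits$stdev_unscaled[, j] * sqrt(fits$s2_post))
  p <- 2 * pt(-abs(tstat), df = fits$df_total)
  de_table(fits, unname(tstat), unname(p), coef_col = j, alpha = alpha)
}

#' Call genes differentially expressed by strain (moderated F)
#'
#' Joint moderated F over the S-1 strain coefficients:
#' `F = (b' V^-1 b / r) / s~2` with `V` the strain block of `(X'X)^-1`, on
#' `(r, d + d0)` degrees of freedom.
#'
#' @inheritParams call_diet_degs
#' @return data.frame: feature_id, gene_symbol, F, p_value, p_adj, de.
#' @export
call_strain_degs <- function(dataset, design = NULL, alpha = 0.05) {
  if (is.null(design)) design <- make_design(dataset$metadata)
  cols <- design$strain_cols
  if (!length(cols)) stop("design has no strain columns")
  tab <- table(dataset$metadata$strain)
  if (any(tab < 1)) stop("every strain needs at least one sample")
  fits <- ebayes_moderate(fit_gene_models(dataset, design))
  V <- fits$cov_unscaled[cols, cols, drop = FALSE]
  L <- chol(V)
  B <- fits$coefficients[, cols, drop = FALSE]     # genes x r
  # quadratic form b' V^-1 b via backsolve against chol factor
  Q <- colSums(backsolve(L, t(B), transpose = TRUE)^2)
  r <- length(cols)
  Fstat <- (Q / r) / fits$s2_post
  p <- pf(Fstat, r, fits$df_total, lower.tail = FALSE)
  de_table(fits, unname(Fstat), unname(p), alpha = alpha, stat_name = "F")
}

#' One-sided hypergeometric over-representation test
#'
#' For each gene set: overlap `k` of DEGs with the set restricted to the
#' universe, `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, BH column,
#' and "gene richness" `k / K`.
#'
#' @param deg_symbols character vector of DEG symbols (subset of universe).
#' @param universe_symbols character vector, the tested gene universe.
#' @param gene_sets a [read_gene_sets()] collection (or named list with
#'   `genes` elements).
#' @param alpha adjusted-p threshold for the enrichment flag.
#' @return data.frame: set_id, description, k, K, n_deg, N, richness,
#'   p_value, p_adj, enriched.
#' @export
overrepresentation_test <- function(deg_symbols, universe_symbols, gene_sets,
                                    alpha = 0.05) {
  universe <- unique(toupper(trimws(universe_symbols)))
  deg <- unique(toupper(trimws(deg_symbols)))
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(deg, universe)))
    stop("DEG symbols must be a subset of the universe")
  N <- length(universe); n <- length(deg)
  rows <- lapply(names(gene_sets), function(id) {
    gs <- intersect(gene_sets[[id]]$genes, universe)
    K <- length(gs)
    k <- length(intersect(gs, deg))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id,
               description = gene_sets[[id]]$description,
               k = k, K = K, n_deg = n, N = N,
               richness = if (K > 0) k / K else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p_value, "BH")
  res$enriched <- res$p_adj < alpha
  res[order(res$p_value), ]
}
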