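# Broad-sense heritability from ANOVA mean squares (intraclass correlation
# r_I and coefficient of genetic determination g^2), diet intraclass
# correlation, distribution comparisons, and REML variance partitioning into
# proportions of variance (POV).

#' Between- and within-group mean squares with covariate adjustment
#'
#' Fits an additive linear model with the covariates entered before the
#' grouping factor and takes the sequential (type I) sum of squares for the
#' group term, so MSB is the covariate-adjusted between-group mean square and
#' MSW the residual mean square. Also returns the effective replicate count
#' `n0 = (N - sum(n_g^2)/N) / (G - 1)` for unbalanced group sizes.
#'
#' @param y numeric response (one gene's expression).
#' @param meta per-sample metadata data.frame.
#' @param group name of the grouping column (e.g. `"strain"` or `"diet"`).
#' @param covariates character vector of covariate columns entered first.
#' @return list: `msb`, `msw`, `n0`, `df_between`, `df_within`.
#' @export
strain_mean_squares <- function(y, meta, group = "strain",
                                covariates = c("diet", "week")) {
  g <- factor(meta[[group]])
  if (nlevels(droplevels(g)) < 2) stop("need >= 2 levels of ", group)
  counts <- table(droplevels(g))
  if (any(counts < 1)) stop("a ", group, " level has 0 samples")
  N <- length(y)
  Glev <- length(counts)
  if (N - Glev < 1) stop("need replicates beyond the number of ", group, " levels")
  covariates <- covariates[vapply(covariates, function(cv)
    nlevels(droplevels(factor(meta[[cv]]))) > 1, logical(1))]
  md <- meta
  for (cv in covariates) md[[cv]] <- factor(md[[cv]])
  md$.group <- g
  rhs <- paste(c(covariates, ".group"), collapse = " + ")
  fit <- lm(stats::as.formula(paste("y ~", rhs)), data = cbind(md, y = y))
  an <- anova(fit)
  gi <- match(".group", rownames(an))
  msb <- an[gi, "Mean Sq"]
  msw <- an["Residuals", "Mean Sq"]
  n0 <- (N - sum(counts^2) / N) / (Glev - 1)
  list(msb = msb, msw = msw, n0 = n0,
       df_between = an[gi, "Df"], df_within = an["Residuals", "Df"])
}

#' Intraclass correlation from mean squares
#'
#' `r_I = (MSB - MSW) / (MSB + (n0 - 1) MSW)`; approximates the proportion of
#' variation between groups. Negative values are legal (within-group
#' variation exceeding between-group). `MSW = 0` returns 1 carrying a
#' `"flag"` attribute.
#'
#' @param msb,msw between/within mean squares.
#' @param n0 effective replicates per group (> 1).
#' @return intraclass correlation (<= 1).
#' @export
intraclass_r <- function(msb, msw, n0) {
  stopifnot(n0 > 1)
  if (msw == 0) return(structure(1, flag = "MSW zero"))
  (msb - msw) / (msb + (n0 - 1) * msw)
}

#' Coefficient of genetic determination from mean squares
#'
#' `g^2 = (MSB - MSW) / (MSB + (2 n0 - 1) MSW)`: the denominator doubles the
#' additive genetic term to account for inbreeding, so `g^2 < r_I` whenever
#' `MSB > MSW`.
#'
#' @inheritParams intraclass_r
#' @return coefficient of genetic determination (<= 1).
#' @export
genetic_determination_g2 <- function(msb, msw, n0) {
  stopifnot(n0 > 1)
  if (msw == 0) return(structure(1, flag = "MSW zero"))
  (msb - msw) / (msb + (2 * n0 - 1) * msw)
}

#' Diet intraclass correlation from the full additive model
#'
#' Intraclass correlation with diet as the grouping factor and strain + week
#' as covariates, quantifying the share of expression variation between
#' diets.
#'
#' @param y one gene's expression.
#' @param meta per-sample metadata with both diets present.
#' @return diet ICC.
#' @export
diet_icc <- function(y, meta) {
  if (length(unique(meta$diet)) < 2) stop("both diets must be present")
  ms <- strain_mean_squares(y, meta, group = "diet",
                            covariates = c("strain", "week"))
  intraclass_r(ms$msb, ms$msw, ms$n0)
}

# Shared-design fast path: sequential strain SS for every gene at once.
# MSB(group last) = (RSS_reduced - RSS_full) / df_group.
seq_ms_all <- function(values, meta, group, covariates) {
  md <- meta
  for (cv in c(covariates, group)) md[[cv]] <- droplevels(factor(md[[cv]]))
  counts <- table(md[[group]])
  if (any(counts < 1) || length(counts) < 2)
    stop("each ", group, " level needs >= 1 sample and >= 2 levels")
  covariates <- covariates[vapply(covariates,
                                  function(cv) nlevels(md[[cv]]) > 1, logical(1))]
  rhs_red <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  Xr <- model.matrix(stats::as.formula(paste("~", rhs_red)), md)
  Xf <- model.matrix(stats::as.formula(paste("~", rhs_red, "+", group)), md)
  qf <- qr(Xf); qrr <- qr(Xr)
  Y <- t(values)
  rss_f <- colSums(qr.resid(qf, Y)^2)
  rss_r <- colSums(qr.resid(qrr, Y)^2)
  df_b <- qf$rank - qrr$rank
  df_w <- nrow(Xf) - qf$rank
  N <- nrow(Xf)
  n0 <- (N - sum(counts^2) / N) / (length(counts) - 1)
  list(msb = (rss_r - rss_f) / df_b, msw = rss_f / df_w, n0 = n0,
       df_between = df_b, df_within = df_w)
}

#' Per-gene heritability table across the full, HP and HS models
#'
#' For every gene: `r_I` and `g^2` from (1) the full additive model (strain
#' with diet + week covariates, both diets), (2) the HP-only model (strain
#' with week covariate), (3) the HS-only model; plus the diet ICC from the
#' full additive model (diet grouped, strain + week covariates).
#'
#' @param dataset a filtered `ExpressionDataset` with both diets.
#' @return data.frame with one row per gene: msb/msw per model, n0s, `ri_full`,
#'   `ri_hp`, `ri_hs`, `g2_full`, `g2_hp`, `g2_hs`, `diet_icc`.
#' @export
heritability_all <- function(dataset) {
  meta <- dataset$metadata
  if (length(unique(meta$diet)) < 2) stop("both diets must be present")
  v <- dataset$values
  full <- seq_ms_all(v, meta, "strain", c("diet", "week"))
  hp <- meta$diet == "HP"; hs <- meta$diet == "HS"
  m_hp <- seq_ms_all(v[, hp, drop = FALSE], meta[hp, ], "strain", "week")
  m_hs <- seq_ms_all(v[, hs, drop = FALSE], meta[hs, ], "strain", "week")
  dicc <- seq_ms_all(v, meta, "diet", c("strain", "week"))
  ri <- function(m) (m$msb - m$msw) / (m$msb + (m$n0 - 1) * m$msw)
  g2 <- function(m) (m$msb - m$msw) / (m$msb + (2 * m$n0 - 1) * m$msw)
  data.frame(feature_id = dataset$feature_ids,
             gene_symbol = dataset$gene_symbols,
             msb_full = full$msb, msw_full = full$msw, n0_full = full$n0,
             ri_full = ri(full), g2_full = g2(full),
             ri_hp = ri(m_hp), g2_hp = g2(m_hp),
             ri_hs = ri(m_hs), g2_hs = g2(m_hs),
             msb_diet = dicc$msb, msw_diet = dicc$msw, n0_diet = dicc$n0,
             diet_icc = ri(dicc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summary statistics of heritability estimates per gene group
#'
#' Produces the familiar summary layout (mean +/- SE, median, Q1, Q3, min,
#' max) for each heritability metric and each gene group (e.g. all expressed
#' genes, diet DEGs, strain DEGs).
#'
#' @param herit a [heritability_all()] table.
#' @param groups named list of feature-id vectors; default a single group
#'   `all` with every gene.
#' @param metrics columns of `herit` to summarize.
#' @return data.frame: metric, group, n, mean, se, median, q1, q3, min, max.
#' @export
summarize_heritability <- function(herit,
                                   groups = list(all = herit$feature_id),
                                   metrics = c("ri_full", "ri_hp", "ri_hs",
                                               "g2_full", "g2_hp", "g2_hs",
                                               "diet_icc")) {
  rows <- list()
  for (m in metrics) for (g in names(groups)) {
    x <- herit[[m]][herit$feature_id %in% groups[[g]]]
    x <- x[!is.na(x)]
    if (!length(x)) next
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(metric = m, group = g, n = length(x), mean = mean(x),
                 se = sd(x) / sqrt(length(x)), median = q[2], q1 = q[1],
                 q3 = q[3], min = min(x), max = max(x),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Compare two g-squared distributions
#'
#' Two-sided Mann-Whitney U (normal approximation with tie correction) and
#' two-sample Kolmogorov-Smirnov test, as used to ask whether diet-specific
#' heritability distributions differ.
#'
#' @param g2_a,g2_b numeric vectors (length >= 2 each).
#' @return list: `mwu_stat`, `mwu_p`, `ks_stat`, `ks_p`.
#' @export
compare_g2_distributions <- function(g2_a, g2_b) {
  if (length(g2_a) < 2 || length(g2_b) < 2) stop("need >= 2 values per group")
  mw <- suppressWarnings(wilcox.test(g2_a, g2_b, exact = FALSE))
  ks <- suppressWarnings(ks.test(g2_a, g2_b))
  list(mwu_stat = unname(mw$statistic), mwu_p = mw$p.value,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

# ---- REML variance partitioning --------------------------------------------

# Precompute the random-effect structure shared by all genes. The REML
# objective is evaluated in the reduced random-effects space: with
# Z = [Z_strain Z_diet Z_interaction] (n x m) and Gamma = diag(gamma by
# block), V0 = I + Z Gamma Z' has log|V0| = log|S| and
# u' V0^-1 v = u'v - (g .* Z'u)' S^-1 (g .* Z'v)
# where S = I_m + (g g') .* Z'Z and g = sqrt(gamma by column)
# (Woodbury identity and the matrix determinant lemma), so each evaluation
# costs one m x m Cholesky instead of an n x n one.
pov_structure <- function(meta) {
  s <- factor(meta$strain)
  d <- factor(meta$diet)
  sd_ <- interaction(s, d, drop = TRUE)
  Z <- cbind(model.matrix(~ 0 + s), model.matrix(~ 0 + d),
             model.matrix(~ 0 + sd_))
  block <- rep(1:3, c(nlevels(s), nlevels(d), nlevels(sd_)))
  list(Z = Z, block = block, ZtZ = crossprod(Z),
       Zt1 = colSums(Z), n = nrow(Z), s = s, d = d, sd = sd_)
}

# Method-of-moments (expected mean squares) starting values; balanced formulas
# applied with average cell counts, truncated at a small positive floor.
pov_mom_start <- function(y, str) {
  a <- nlevels(str$s); b <- nlevels(str$d)
  r <- str$n / (a * b)
  an <- tryCatch(suppressWarnings(anova(lm(y ~ str$s * str$d))),
                 error = function(e) NULL)
  if (is.null(an) || nrow(an) < 4 || !is.finite(an["Residuals", "Mean Sq"]))
    return(c(0.3, 0.1, 0.1))
  mse <- an["Residuals", "Mean Sq"]
  ms_i <- an[3, "Mean Sq"]; ms_s <- an[1, "Mean Sq"]; ms_d <- an[2, "Mean Sq"]
  v_i <- max(0, (ms_i - mse) / r)
  v_s <- max(0, (ms_s - ms_i) / (r * b))
  v_d <- max(0, (ms_d - ms_i) / (r * a))
  pmax(c(v_s, v_d, v_i) / max(mse, 1e-12), 1e-4)
}

reml_objective <- function(gamma, qs, str) {
  g <- sqrt(pmax(gamma, 0)[str$block])  # numeric gradients can probe below 0
  S <- tcrossprod(g) * str$ZtZ
  diag(S) <- diag(S) + 1
  C <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(C)) return(1e10)
  logdet <- 2 * sum(log(diag(C)))
  A <- backsolve(C, cbind(g * qs$Zty, g * str$Zt1), transpose = TRUE)
  yvy <- qs$yty - sum(A[, 1]^2)
  xvy <- qs$oty - sum(A[, 1] * A[, 2])
  xvx <- str$n - sum(A[, 2]^2)
  q <- yvy - xvy^2 / xvx
  if (q <= 0 || xvx <= 0) return(1e10)
  (str$n - 1) * log(q) + logdet + log(xvx)
}

reml_quadforms <- function(y, str) {
  list(Zty = as.numeric(crossprod(str$Z, y)), yty = sum(y * y), oty = sum(y))
}

#' REML variance components and proportions of variance for one gene
#'
#' Random-effects model with strain, diet and strain x diet all random:
#' profiled REML over the three variance ratios with non-negativity box
#' constraints and three starts (a method-of-moments start plus two spread
#' alternates), convergence tolerance 1e-8. POV for each term is its variance
#' divided by the sum of all four components (residual included), times 100.
#'
#' @param y one gene's expression.
#' @param meta per-sample metadata (>= 2 strains, both diets).
#' @param structure optionally a precomputed [pov_structure()]-style object
#'   (reused across genes by [partition_variance_all()]).
#' @return one-row data.frame: sigma2_strain, sigma2_diet,
#'   sigma2_interaction, sigma2_resid, pov_strain, pov_diet,
#'   pov_interaction, pov_resid, converged.
#' @export
partition_variance <- function(y, meta, structure = NULL) {
  str <- if (is.null(structure)) pov_structure(meta) else structure
  if (nlevels(str$s) < 2 || nlevels(str$d) < 2)
    stop("need >= 2 strains and both diets")
  qs <- reml_quadforms(y, str)
  starts <- list(pov_mom_start(y, str), c(0.5, 0.5, 0.5), c(0.05, 0.05, 0.05))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, reml_objective, qs = qs, str = str, method = "L-BFGS-B",
            lower = 0, upper = 1e6,
            control = list(factr = 1e-8 / .Machine$double.eps, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$convergence != 0) {
      # line searches can fail on the flat boundary; polish derivative-free
      nm <- tryCatch(optim(pmax(fit$par, 0), reml_objective, qs = qs,
                           str = str, method = "Nelder-Mead",
                           control = list(reltol = 1e-10, maxit = 500)),
                     error = function(e) NULL)
      if (!is.null(nm) && nm$value <= fit$value) fit <- nm
    }
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    return(data.frame(sigma2_strain = NA_real_, sigma2_diet = NA_real_,
                      sigma2_interaction = NA_real_, sigma2_resid = NA_real_,
                      pov_strain = NA_real_, pov_diet = NA_real_,
                      pov_interaction = NA_real_, pov_resid = NA_real_,
                      converged = FALSE))
  }
  gamma <- pmax(best$par, 0)   # L-BFGS-B can stop a rounding error below 0
  # parsimony tie-break: with one observation per cell the interaction is
  # confounded with the residual and the profiled REML surface is flat along
  # that trade-off; prefer the zero-interaction point when it fits as well
  if (gamma[3] > 0) {
    # the confounded direction scales the whole covariance: the equivalent
    # zero-interaction point has the other ratios divided by (1 + gamma_int)
    g0 <- c(gamma[1:2] / (1 + gamma[3]), 0)
    if (reml_objective(g0, qs, str) <= best$value + 1e-6) gamma <- g0
  }
  # recover sigma2_e at the optimum
  g <- sqrt(gamma[str$block])
  S <- tcrossprod(g) * str$ZtZ
  diag(S) <- diag(S) + 1
  C <- chol(S)
  A <- backsolve(C, cbind(g * qs$Zty, g * str$Zt1), transpose = TRUE)
  yvy <- qs$yty - sum(A[, 1]^2)
  xvy <- qs$oty - sum(A[, 1] * A[, 2])
  xvx <- str$n - sum(A[, 2]^2)
  q <- yvy - xvy^2 / xvx
  s2e <- q / (str$n - 1)
  s2 <- c(gamma * s2e, s2e)
  pov <- 100 * s2 / sum(s2)
  data.frame(sigma2_strain = s2[1], sigma2_diet = s2[2],
             sigma2_interaction = s2[3], sigma2_resid = s2[4],
             pov_strain = pov[1], pov_diet = pov[2], pov_interaction = pov[3],
             pov_resid = pov[4], converged = best$convergence == 0)
}

#' REML variance partitioning for every gene
#'
#' @param dataset an `ExpressionDataset`.
#' @param features optional subset of feature ids.
#' @return data.frame, one row per gene, columns as [partition_variance()]
#'   plus feature_id and gene_symbol.
#' @export
partition_variance_all <- function(dataset, features = NULL) {
  if (!is.null(features)) dataset <- subset_dataset(dataset, features = features)
  str <- pov_structure(dataset$metadata)
  rows <- lapply(seq_len(n_features(dataset)), function(g)
    partition_variance(dataset$values[g, ], structure = str))
  out <- do.call(rbind, rows)
  cbind(data.frame(feature_id = dataset$feature_ids,
                   gene_symbol = dataset$gene_symbols,
                   stringsAsFactors = FALSE), out)
}

#' Mean variance components and POV per gene group
#'
#' @param pov a [partition_variance_all()] table.
#' @param groups named list of feature-id vectors.
#' @return data.frame: group, mean variance and mean POV per term.
#' @export
summarize_pov <- function(pov, groups = list(all = pov$feature_id)) {
  rows <- lapply(names(groups), function(g) {
    sub <- pov[pov$feature_id %in% groups[[g]] & pov$converged, , drop = FALSE]
    data.frame(group = g, n = nrow(sub),
               var_strain = mean(sub$sigma2_strain),
               pov_strain = mean(sub$pov_strain),
               var_diet = mean(sub$sigma2_diet),
               pov_diet = mean(sub$pov_diet),
               var_interaction = mean(sub$sigma2_interaction),
               pov_interaction = mean(sub$pov_interaction),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
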