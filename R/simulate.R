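# Synthetic Collaborative-Cross-like expression data with known ground truth.
#
# Per-gene model (log2 scale), sample i, gene g:
#   y_gi = mu_g + a_{g,strain(i)} + beta_g * 1[diet(i) = HS]
#        + c_{g,strain(i),diet(i)} + w_{g,week(i)} + lambda_g * F_{m(g),i} + e_gi
# a ~ N(0, sigma2_strain_g), c ~ N(0, sigma2_interaction_g),
# w ~ N(0, sigma2_batch_g), e ~ N(0, sigma2_resid_g); module factors F are
# standard normal per sample. The adiposity phenotype is built from the module
# factors: body_fat_pct_i = baseline + sum_m gamma_m F_mi + delta * 1[HS] + noise.

#' Build a simulation configuration
#'
#' Defaults are sized to the study design this generator emulates: 22
#' recombinant-inbred strains x 2 diets (HP / HS) x 3 replicates (132 arrays
#' before QC), 4 husbandry-week batches, and a variance-component regime in
#' which strain variance dominates diet and strain-x-diet interaction
#' (0.069 / 0.007 / 0.004 on the log2 scale, residual 0.148).
#'
#' The two-level diet contrast is simulated as a fixed shift
#' `beta_g = sign_g * sqrt(2 * sigma2_diet_g)`, so that a variance-component
#' estimate of the diet term recovers `sigma2_diet` in expectation
#' (E\[MSB_diet\] = sigma2_e + n * sum((d_j - dbar)^2)/(J - 1) with J = 2).
#'
#' Per-gene variance components default to a strain-dominant regime
#' (strain 0.069, interaction 0.004, batch 0.005, residual 0.148 on the log2
#' scale); 15% of genes carry a diet shift of variance scale 0.045, so the
#' average diet variance over all genes is about 0.007 -- strain variance an
#' order of magnitude above diet and interaction, as observed in
#' strain-dominant liver expression.
#'
#' @param n_strains,reps_per_cell,n_weeks,n_genes design dimensions.
#' @param mu per-gene baseline intensity (recycled).
#' @param sigma2_strain,sigma2_diet,sigma2_interaction,sigma2_batch,sigma2_resid
#'   per-gene variance components (scalars or length-`n_genes` vectors).
#' @param diet_affected_frac fraction of genes carrying a nonzero diet shift
#'   (the rest get `sigma2_diet = 0`).
#' @param modules `NULL` or a list with parallel vectors `sizes` (genes per
#'   module), `loadings` (lambda, shared within a module), `gamma` (loading of
#'   the module factor onto body fat %), and optionally `diet_frac`
#'   (per-module fraction of member genes with a diet shift; `NA` = use the
#'   global `diet_affected_frac`) and `strain_cor` (share of the module
#'   factor's variance carried by a strain-level component, default 0.5:
#'   co-expression modules in inbred panels are typically strain-driven, so
#'   part of the shared factor is a per-strain draw common to both diets; the
#'   remainder is sample-level and centered within strain). Ground-truth ICCs
#'   account for the factor's strain share.
#' @param pheno list: `baseline` (percent), `delta` (HS diet shift on body
#'   fat %), `noise_sd`.
#' @param founder_null list: `gene_fraction`, `strain_fraction`, `shift` for
#'   [inject_founder_nulls()] applied inside [simulate_dataset()].
#' @param duplicate list: `fraction`, `attenuation`, `noise_sd` for
#'   [add_duplicate_tcids()] applied inside [simulate_dataset()].
#' @param seed integer RNG seed; same seed gives bit-identical output.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 22, reps_per_cell = 3, n_weeks = 4,
                       n_genes = 2000, mu = 8,
                       sigma2_strain = 0.069, sigma2_diet = 0.045,
                       sigma2_interaction = 0.004, sigma2_batch = 0.005,
                       sigma2_resid = 0.148,
                       diet_affected_frac = 0.15,
                       modules = NULL,
                       pheno = list(baseline = 25, delta = 6, noise_sd = 3),
                       founder_null = list(gene_fraction = 0,
                                           strain_fraction = 3 / 22, shift = 4),
                       duplicate = list(fraction = 0, attenuation = 0.6,
                                        noise_sd = 0.3),
                       seed = 1) {
  cfg <- list(n_strains = n_strains, n_diets = 2L, reps_per_cell = reps_per_cell,
              n_weeks = n_weeks, n_genes = n_genes, mu = mu,
              sigma2_strain = sigma2_strain, sigma2_diet = sigma2_diet,
              sigma2_interaction = sigma2_interaction,
              sigma2_batch = sigma2_batch, sigma2_resid = sigma2_resid,
              diet_affected_frac = diet_affected_frac, modules = modules,
              pheno = pheno, founder_null = founder_null, duplicate = duplicate,
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_strains >= 2, cfg$reps_per_cell >= 1, cfg$n_weeks >= 1,
            cfg$n_genes >= 1)
  for (nm in c("sigma2_strain", "sigma2_diet", "sigma2_interaction",
               "sigma2_batch", "sigma2_resid"))
    if (any(cfg[[nm]] < 0)) stop(nm, " must be >= 0")
  stopifnot(cfg$diet_affected_frac >= 0, cfg$diet_affected_frac <= 1)
  if (!is.null(cfg$modules)) {
    stopifnot(length(cfg$modules$sizes) == length(cfg$modules$loadings),
              length(cfg$modules$sizes) == length(cfg$modules$gamma))
    if (sum(cfg$modules$sizes) > cfg$n_genes)
      stop("module sizes sum exceeds n_genes")
    if (!is.null(cfg$modules$strain_cor) &&
        any(cfg$modules$strain_cor < 0 | cfg$modules$strain_cor > 1))
      stop("modules$strain_cor must be in [0, 1]")
  }
  stopifnot(cfg$founder_null$gene_fraction >= 0,
            cfg$founder_null$gene_fraction <= 1,
            cfg$founder_null$strain_fraction >= 0,
            cfg$founder_null$strain_fraction <= 1,
            cfg$duplicate$fraction >= 0, cfg$duplicate$fraction <= 1)
  if (cfg$duplicate$fraction > 0 && cfg$duplicate$attenuation >= 1)
    stop("duplicate attenuation must be < 1")
  invisible(cfg)
}

recycle_genes <- function(x, G) {
  if (length(x) == 1) rep(x, G)
  else if (length(x) == G) as.numeric(x)
  else stop("per-gene parameter must have length 1 or n_genes")
}

#' Simulate a CC-like expression dataset with ground truth
#'
#' Draw order under the single seeded generator (documented so outputs are
#' reproducible): (1a) strain-level module-factor components, (1b)
#' sample-level module-factor components, (2) strain effects, (3) interaction
#' effects, (4) batch effects, (5) diet-affected gene selection and effect
#' signs, (6) residuals, (7) phenotype noise, (8) founder-null gene/strain
#' selection, (9) duplicate TC-ID selection and noise.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an [expression_dataset()]), `phenotypes`
#'   (data.frame: sample_id, body_fat_pct, lean_pct, heat_production), and
#'   `truth` (ground truth: per-gene components, true ICC, module labels and
#'   loadings, diet effects, module factors, phenotype coefficients,
#'   founder-null and duplicate records).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  S <- config$n_strains; R <- config$reps_per_cell; W <- config$n_weeks
  G <- config$n_genes
  N <- S * 2L * R

  strain <- rep(sprintf("CC%03d", seq_len(S)), each = 2L * R)
  diet <- rep(rep(c("HP", "HS"), each = R), times = S)
  week <- sprintf("W%d", rep_len(seq_len(W), N))
  sample_id <- sprintf("M%04d", seq_len(N))
  meta <- data.frame(sample_id = sample_id, strain = strain, diet = diet,
                     week = week, stringsAsFactors = FALSE)

  mu <- recycle_genes(config$mu, G)
  s2s <- recycle_genes(config$sigma2_strain, G)
  s2d <- recycle_genes(config$sigma2_diet, G)
  s2i <- recycle_genes(config$sigma2_interaction, G)
  s2b <- recycle_genes(config$sigma2_batch, G)
  s2e <- recycle_genes(config$sigma2_resid, G)

  # module membership: first sum(sizes) genes, consecutive blocks
  module <- integer(G)
  lambda <- numeric(G)
  M <- 0L
  if (!is.null(config$modules)) {
    sizes <- config$modules$sizes
    M <- length(sizes)
    idx <- 1L
    for (m in seq_len(M)) {
      module[idx:(idx + sizes[m] - 1L)] <- m
      lambda[idx:(idx + sizes[m] - 1L)] <- config$modules$loadings[m]
      idx <- idx + sizes[m]
    }
  }

  # (1) module factors, unit variance per sample:
  #   F_mi = sqrt(h_m) * S_{m,strain(i)} + sqrt(1 - h_m) * E_mi
  # (1a) the strain-level component S is one standard-normal draw per strain,
  # shared by both diets, carrying the factor's strain_cor share h_m;
  # (1b) the sample-level component E is centered within strain and rescaled,
  # so it adds no between-strain variance. The factor's strain variance
  # (lambda^2 h) is therefore exact in the ground truth and identical in the
  # two diet subsets.
  h_m <- if (M > 0) {
    sc <- config$modules$strain_cor
    if (is.null(sc)) rep(0.5, M) else rep_len(sc, M)
  } else numeric(0)
  factors <- matrix(0, 0, N)
  if (M > 0) {
    si0 <- rep(seq_len(S), each = 2L * R)
    Sfac <- matrix(rnorm(M * S), M, S)
    E <- matrix(rnorm(M * N), M, N)
    if (2L * R >= 2L) {
      for (m in seq_len(M)) {
        em <- tapply(E[m, ], si0, mean)
        E[m, ] <- (E[m, ] - em[si0]) * sqrt(2 * R / (2 * R - 1))
      }
    }
    factors <- sqrt(h_m) * Sfac[, si0, drop = FALSE] + sqrt(1 - h_m) * E
    colnames(factors) <- sample_id
  }
  # (2) strain effects
  a <- matrix(rnorm(G * S), G, S) * sqrt(s2s)
  # (3) strain x diet interaction effects
  cc <- matrix(rnorm(G * S * 2L), G, S * 2L) * sqrt(s2i)
  # (4) batch (week) effects
  w <- matrix(rnorm(G * W), G, W) * sqrt(s2b)
  # (5) diet-affected selection and signs
  affected <- runif(G) < diet_frac_per_gene(config, module)
  s2d[!affected] <- 0
  beta <- ifelse(runif(G) < 0.5, 1, -1) * sqrt(2 * s2d)
  # (6) residuals
  e <- matrix(rnorm(G * N), G, N) * sqrt(s2e)

  si <- match(strain, unique(strain))
  di <- as.integer(diet == "HS")
  wi <- match(week, sprintf("W%d", seq_len(W)))
  cell <- (si - 1L) * 2L + di + 1L

  y <- mu + a[, si, drop = FALSE] + outer(beta, di) +
    cc[, cell, drop = FALSE] + w[, wi, drop = FALSE] + e
  if (M > 0) {
    inmod <- module > 0
    y[inmod, ] <- y[inmod, , drop = FALSE] +
      lambda[inmod] * factors[module[inmod], , drop = FALSE]
  }
  dimnames(y) <- list(sprintf("TC%07d", seq_len(G)), sample_id)

  feature_ids <- rownames(y)
  gene_symbols <- sprintf("GENE%05d", seq_len(G))

  # (7) phenotype
  gamma <- if (M > 0) config$modules$gamma else numeric(0)
  bf <- config$pheno$baseline + config$pheno$delta * di +
    rnorm(N, 0, config$pheno$noise_sd)
  if (M > 0) bf <- bf + as.numeric(crossprod(factors, gamma))
  phen <- data.frame(sample_id = sample_id,
                     body_fat_pct = bf,
                     lean_pct = 70 - bf + rnorm(N, 0, 1),
                     heat_production = rnorm(N, 3.5, 0.3),
                     stringsAsFactors = FALSE)

  ds <- expression_dataset(y, feature_ids, gene_symbols, meta)
  truth <- list(
    genes = local({
      h_g <- ifelse(module > 0, h_m[pmax(module, 1)], 0)
      s2s_tot <- s2s + lambda^2 * h_g          # factor strain share included
      s2e_tot <- s2e + lambda^2 * (1 - h_g)
      data.frame(feature_id = feature_ids, gene_symbol = gene_symbols,
                 module = module, lambda = lambda, factor_strain_cor = h_g,
                 diet_effect = beta,
                 sigma2_strain = s2s_tot, sigma2_diet = s2d,
                 sigma2_interaction = s2i, sigma2_batch = s2b,
                 sigma2_resid = s2e_tot,
                 true_icc = ifelse(s2s_tot + s2i + s2e_tot > 0,
                                   s2s_tot / (s2s_tot + s2i + s2e_tot), 0),
                 stringsAsFactors = FALSE)
    }),
    factors = factors,
    pheno_coef = c(config$pheno, list(gamma = gamma)),
    founder_null = list(genes = character(0), strains = character(0)),
    duplicates = data.frame(original = character(0), duplicate = character(0)),
    config = config)

  # (8) founder-null injection
  fn <- config$founder_null
  if (fn$gene_fraction > 0) {
    inj <- inject_founder_nulls(ds, fn$gene_fraction, fn$strain_fraction, fn$shift)
    ds <- inj$dataset
    truth$founder_null <- list(genes = inj$genes, strains = inj$strains)
  }
  # (9) duplicate TC-IDs
  dup <- config$duplicate
  if (dup$fraction > 0) {
    dd <- add_duplicate_tcids(ds, dup$fraction, dup$attenuation, dup$noise_sd)
    ds <- dd$dataset
    truth$duplicates <- dd$map
  }

  list(dataset = ds, phenotypes = phen, truth = truth)
}

#' Study-scale simulation config with co-expression structure
#'
#' The full-pipeline emulation of a 22-strain, two-diet liver study: the
#' [sim_config()] variance regime plus a size-graded hierarchy of
#' co-expression modules covering about 60% of the genes (ten modules from
#' 17% of genes down to 1.7% at the default size), within-module
#' correlations between about 0.45 and 0.65, per-module diet-responsive
#' fractions spanning 0 to 0.5, three module factors loading onto body
#' fat %, founder-null alleles injected into 2% of genes, and duplicate
#' TC-IDs for 5% of genes.
#'
#' @param n_genes number of genes (module sizes scale proportionally;
#'   modules that would fall below 21 genes are dropped).
#' @param seed RNG seed.
#' @return a [sim_config()].
#' @export
cc_study_config <- function(n_genes = 2000, seed = 1) {
  base_other <- 0.069 + 0.004 + 0.005 + 0.148   # non-factor variance, approx.
  size_frac <- c(0.17, 0.12, 0.087, 0.06, 0.047, 0.037, 0.03, 0.023,
                 0.02, 0.017)
  sizes <- round(size_frac * n_genes)
  keep <- sizes >= 21
  sizes <- sizes[keep]
  k <- length(sizes)
  target_cor <- rep_len(c(0.45, 0.5, 0.55, 0.5, 0.6, 0.55, 0.5, 0.6, 0.65,
                          0.6), k)
  gamma <- numeric(k)
  gamma[1] <- 2
  if (k >= 2) gamma[2] <- -1.5
  if (k >= 5) gamma[5] <- 0.8
  sim_config(
    n_genes = n_genes,
    modules = list(sizes = sizes,
                   loadings = sqrt(target_cor / (1 - target_cor) * base_other),
                   gamma = gamma,
                   diet_frac = rep_len(c(0.5, 0.3, 0.15, 0.05, 0), k)),
    founder_null = list(gene_fraction = 0.02, strain_fraction = 3 / 22,
                        shift = 4),
    duplicate = list(fraction = 0.05, attenuation = 0.6, noise_sd = 0.3),
    seed = seed)
}

diet_frac_per_gene <- function(config, module) {
  frac <- rep(config$diet_affected_frac, length(module))
  if (!is.null(config$modules) && !is.null(config$modules$diet_frac)) {
    mf <- config$modules$diet_frac
    for (m in seq_along(mf))
      if (!is.na(mf[m])) frac[module == m] <- mf[m]
  }
  frac
}

#' Shift selected genes down in selected strains (founder-null alleles)
#'
#' Emulates strains that inherited a low/no-expression allele from one
#' founder: for a random fraction of genes, expression is shifted down by
#' `shift` log2 units in a random fraction of strains only.
#'
#' @param dataset an `ExpressionDataset`.
#' @param gene_fraction fraction of genes to affect.
#' @param strain_fraction fraction of strains carrying the null allele.
#' @param shift downward shift in log2 units.
#' @return list: `dataset` (modified), `genes` (affected feature ids),
#'   `strains` (affected strain labels).
#' @export
inject_founder_nulls <- function(dataset, gene_fraction, strain_fraction, shift) {
  stopifnot(gene_fraction >= 0, gene_fraction <= 1,
            strain_fraction >= 0, strain_fraction <= 1)
  strains <- unique(dataset$metadata$strain)
  ng <- round(gene_fraction * n_features(dataset))
  ns <- max(if (gene_fraction > 0) 1L else 0L, round(strain_fraction * length(strains)))
  if (ng == 0) return(list(dataset = dataset, genes = character(0),
                           strains = character(0)))
  gsel <- sort(sample.int(n_features(dataset), ng))
  ssel <- sort(sample(strains, ns))
  cols <- dataset$metadata$strain %in% ssel
  v <- dataset$values
  v[gsel, cols] <- v[gsel, cols] - shift
  list(dataset = expression_dataset(v, dataset$feature_ids,
                                    dataset$gene_symbols, dataset$metadata),
       genes = dataset$feature_ids[gsel], strains = ssel)
}

#' Append attenuated duplicate TC-IDs for a fraction of genes
#'
#' For each chosen gene a second TC-ID is appended carrying
#' `attenuation * signal` plus fresh Gaussian noise, under the same gene
#' symbol. Because `attenuation < 1` the duplicate probe sits lower on the
#' intensity scale, so best-probe-per-gene selection should retain the
#' original.
#'
#' @param dataset an `ExpressionDataset`.
#' @param fraction fraction of genes to duplicate.
#' @param attenuation multiplicative signal attenuation, must be `< 1`.
#' @param noise_sd sd of the fresh noise added to the duplicate probe.
#' @return list: `dataset` (with appended features), `map` (data.frame
#'   original / duplicate feature ids).
#' @export
add_duplicate_tcids <- function(dataset, fraction, attenuation, noise_sd = 0.3) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction > 0 && attenuation >= 1) stop("attenuation must be < 1")
  ng <- round(fraction * n_features(dataset))
  if (ng == 0) return(list(dataset = dataset,
                           map = data.frame(original = character(0),
                                            duplicate = character(0))))
  gsel <- sort(sample.int(n_features(dataset), ng))
  orig <- dataset$values[gsel, , drop = FALSE]
  dupv <- attenuation * orig +
    matrix(rnorm(length(orig), 0, noise_sd), nrow(orig), ncol(orig))
  dup_ids <- paste0(dataset$feature_ids[gsel], "_B")
  v <- rbind(dataset$values, dupv)
  fid <- c(dataset$feature_ids, dup_ids)
  sym <- c(dataset$gene_symbols, dataset$gene_symbols[gsel])
  rownames(v) <- fid
  list(dataset = expression_dataset(v, fid, sym, dataset$metadata),
       map = data.frame(original = dataset$feature_ids[gsel],
                        duplicate = dup_ids, stringsAsFactors = FALSE))
}

#' Simulate expression with approximate scale-free co-expression topology
#'
#' Single latent factor with heterogeneous, heavy-tailed gene loadings:
#' `x_i = w_i f + sqrt(1 - w_i^2) e_i`, where `w_i = v_i^(1/beta0)` and `v_i`
#' is drawn from a truncated Pareto density on `[v_min, 1]` with tail exponent
#' `gamma_tail`. Network connectivity at soft power `beta0` is then
#' proportional to `v_i`, i.e. power-law distributed, giving a high
#' scale-free fit index around `beta0`.
#'
#' @param n_genes,n_samples dimensions.
#' @param beta0 design soft power (default 5).
#' @param gamma_tail Pareto tail exponent (default 2.5).
#' @param v_min lower truncation of the connectivity weight (default 0.02).
#' @param seed RNG seed.
#' @return an `ExpressionDataset` (metadata filled with a trivial design).
#' @export
simulate_scale_free_expression <- function(n_genes = 600, n_samples = 132,
                                           beta0 = 5, gamma_tail = 2.5,
                                           v_min = 0.02, seed = 1) {
  set.seed(seed)
  u <- runif(n_genes)
  # inverse CDF of p(v) ~ v^(-gamma) truncated to [v_min, 1]
  g1 <- 1 - gamma_tail
  v <- (v_min^g1 + u * (1 - v_min^g1))^(1 / g1)
  wl <- v^(1 / beta0)
  f <- rnorm(n_samples)
  x <- outer(wl, f) + sqrt(1 - wl^2) * matrix(rnorm(n_genes * n_samples),
                                              n_genes, n_samples)
  x <- x + 8
  meta <- data.frame(sample_id = sprintf("M%04d", seq_len(n_samples)),
                     strain = rep_len(sprintf("CC%03d", 1:22), n_samples),
                     diet = rep_len(c("HP", "HS"), n_samples),
                     week = rep_len(sprintf("W%d", 1:4), n_samples),
                     stringsAsFactors = FALSE)
  expression_dataset(x, sprintf("TC%07d", seq_len(n_genes)),
                     sprintf("GENE%05d", seq_len(n_genes)), meta)
}

#' Write ground truth tables for test harnesses
#'
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param dir output directory.
#' @return invisibly, paths written.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gp <- file.path(dir, "ground_truth_genes.tsv")
  write.table(truth$genes, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  pp <- file.path(dir, "provenance.json")
  cfg <- truth$config
  cfg$modules <- if (is.null(cfg$modules)) NULL else cfg$modules
  jsonlite::write_json(unclass(cfg), pp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(genes = gp, provenance = pp))
}
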