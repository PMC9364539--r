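# Weighted co-expression network construction and module analysis:
# soft-threshold selection by scale-free fit, unsigned Pearson adjacency,
# signed TOM, average-linkage clustering with a dynamic hybrid tree cut,
# module merging, eigengenes, and module-trait statistics.

MODULE_COLOR_NAMES <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue")

#' Network construction configuration
#'
#' @param powers candidate soft-threshold powers (positive integers).
#' @param rsq_target scale-free fit threshold for choosing the power.
#' @param beta fixed soft power; `NULL` chooses by [pick_soft_threshold()].
#' @param min_module_size smallest allowed module (grey excepted).
#' @param deep_split split sensitivity 0..4 (higher cuts deeper).
#' @param merge_cut_height eigengene-dissimilarity threshold for merging.
#' @return a list of class `network_config`.
#' @export
network_config <- function(powers = 1:20, rsq_target = 0.9, beta = NULL,
                           min_module_size = 20, deep_split = 2,
                           merge_cut_height = 0.15) {
  stopifnot(all(powers > 0), all(powers == round(powers)),
            rsq_target > 0, rsq_target < 1,
            deep_split %in% 0:4, min_module_size >= 2,
            merge_cut_height > 0, merge_cut_height < 1)
  structure(list(powers = powers, rsq_target = rsq_target, beta = beta,
                 min_module_size = min_module_size, deep_split = deep_split,
                 merge_cut_height = merge_cut_height),
            class = "network_config")
}

scale_free_fit <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) stop("degenerate connectivity: too few distinct values")
  br <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  kmean <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- !is.na(kmean) & freq > 0 & kmean > 0
  if (sum(ok) < 3) stop("degenerate connectivity bins")
  lx <- log10(kmean[ok]); ly <- log10(freq[ok])
  fit <- lm(ly ~ lx)
  r2 <- summary(fit)$r.squared
  slope <- unname(coef(fit)[2])
  c(signed_rsq = -sign(slope) * r2, slope = slope)
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed,
#' per-gene connectivity `k_i = sum_j a_ij` computed, `k` binned into 10
#' equal-width bins, and `log10` mean frequency regressed on `log10` mean
#' `k`. The signed fit index is `-sign(slope) * R^2`; the chosen power is the
#' lowest one reaching `rsq_target`, falling back with a warning to the power
#' of maximal fit when none crosses.
#'
#' @param dataset an `ExpressionDataset` (>= 20 genes).
#' @param config a [network_config()].
#' @return list: `table` (power, signed_rsq, slope, mean_k, median_k, max_k),
#'   `beta` (chosen power), `reached_target`.
#' @export
pick_soft_threshold <- function(dataset, config = network_config()) {
  if (n_features(dataset) < 20) stop("soft-threshold selection needs >= 20 genes")
  r <- cor(t(dataset$values))
  if (anyNA(r)) stop("constant gene rows give undefined correlations")
  absr <- abs(r)
  rows <- lapply(config$powers, function(b) {
    a <- absr^b
    k <- rowSums(a) - 1
    sf <- scale_free_fit(k)
    data.frame(power = b, signed_rsq = unname(sf["signed_rsq"]),
               slope = unname(sf["slope"]), mean_k = mean(k),
               median_k = median(k), max_k = max(k))
  })
  tb <- do.call(rbind, rows)
  hit <- which(tb$signed_rsq >= config$rsq_target)
  if (length(hit)) {
    beta <- tb$power[hit[1]]
    reached <- TRUE
  } else {
    beta <- tb$power[which.max(tb$signed_rsq)]
    reached <- FALSE
    warning("no power reached signed R^2 >= ", config$rsq_target,
            "; using power of maximal fit (", beta, ")")
  }
  list(table = tb, beta = beta, reached_target = reached)
}

#' Unsigned adjacency matrix
#'
#' `a_ij = |cor_Pearson(i, j)|^beta`, diagonal 1.
#'
#' @param dataset an `ExpressionDataset`.
#' @param beta soft-threshold power (>= 1).
#' @return symmetric genes x genes matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(dataset, beta) {
  stopifnot(beta >= 1)
  r <- cor(t(dataset$values))
  if (anyNA(r)) stop("constant gene rows give undefined correlations")
  a <- abs(r)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' With `l_ij = sum_{u != i,j} a_iu a_uj` and connectivity
#' `k_i = sum_{u != i} a_iu`:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, `TOM_ii = 1`.
#' For a nonnegative (unsigned) adjacency the signed and unsigned TOM
#' formulas coincide; nonnegativity is asserted on input. The output is
#' checked per run for symmetry, unit diagonal, range \[0, 1\], and numerator
#' dominance `TOM_ij >= a_ij / (min(k_i, k_j) + 1 - a_ij)`.
#'
#' @param adj symmetric adjacency with unit diagonal, entries in \[0, 1\].
#' @return the TOM, same shape.
#' @export
tom_similarity <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(adj < 0)) stop("adjacency entries must be nonnegative")
  if (max(abs(diag(adj) - 1)) > 1e-12) stop("adjacency diagonal must be 1")
  A <- adj
  diag(A) <- 0
  L <- A %*% A                 # (i,j): sum_u a_iu a_uj with u != i, j on offdiag
  k <- rowSums(A)
  denom <- outer(k, k, pmin) + 1 - A
  tom <- (L + A) / denom
  diag(tom) <- 1
  stopifnot(isSymmetric(unname(tom), tol = 1e-8),
            min(tom) >= -1e-12, max(tom) <= 1 + 1e-12,
            all(tom - A / denom >= -1e-12))
  tom[tom < 0] <- 0; tom[tom > 1] <- 1
  tom
}

#' Detect modules on a dendrogram by a dynamic hybrid tree cut
#'
#' Stage 1: average-linkage branches of the TOM dissimilarity dendrogram are
#' decomposed at a cut height placed at a deepSplit-controlled quantile of
#' the merge-height range; connected branches of at least `min_module_size`
#' genes become modules. Stage 2 (PAM-like): each unassigned gene joins the
#' nearest module if its average dissimilarity to that module's members is
#' below the module's radius (the maximum member-to-module average
#' dissimilarity). Leftover genes get label 0 (grey). Modules are numbered
#' 1..M by decreasing size.
#'
#' @param tom a TOM from [tom_similarity()].
#' @param config a [network_config()].
#' @return integer vector of per-gene labels (0 = unassigned), named by the
#'   TOM dimnames if present.
#' @export
cluster_and_cut <- function(tom, config = network_config()) {
  n <- nrow(tom)
  if (n < config$min_module_size) {
    warning("fewer genes than min_module_size; all genes left unassigned")
    return(setNames(integer(n), rownames(tom)))
  }
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  # cut height as a deepSplit-controlled fraction of the top merge height;
  # referencing the maximum (not the range) keeps the cut stable when a few
  # tight branches merge at unusually low heights
  fr <- c(0.95, 0.97, 0.99, 0.995, 0.999)
  h <- fr[config$deep_split + 1] * max(hc$height)
  raw <- cutree(hc, h = h)
  sizes <- table(raw)
  mods <- as.integer(names(sizes)[sizes >= config$min_module_size])
  labels <- integer(n)
  for (m in seq_along(mods)) labels[raw == mods[m]] <- m

  if (any(labels > 0) && any(labels == 0)) {
    # PAM-like stage on the TOM dissimilarity
    M <- max(labels)
    radius <- numeric(M)
    avg_to_mod <- matrix(0, n, M)
    for (m in seq_len(M)) {
      mem <- which(labels == m)
      avg_to_mod[, m] <- rowMeans(diss[, mem, drop = FALSE])
      # member-to-module average excludes the gene itself
      within <- (rowSums(diss[mem, mem, drop = FALSE])) / (length(mem) - 1)
      radius[m] <- if (length(mem) > 1) max(within) else 0
    }
    for (g in which(labels == 0)) {
      m <- which.min(avg_to_mod[g, ])
      if (avg_to_mod[g, m] < radius[m]) labels[g] <- m
    }
  }
  relabel_by_size(setNames(labels, rownames(tom)))
}

relabel_by_size <- function(labels) {
  sizes <- table(labels[labels > 0])
  if (!length(sizes)) return(labels)
  ord <- as.integer(names(sort(sizes, decreasing = TRUE)))
  new <- integer(length(labels))
  for (m in seq_along(ord)) new[labels == ord[m]] <- m
  setNames(new, names(labels))
}

#' Module label to color name
#'
#' Arbitrary color names for module labels in the field's reporting
#' convention, largest module first; 0 maps to "grey".
#'
#' @param labels integer module labels.
#' @return character vector of color names.
#' @export
module_colors <- function(labels) {
  cols <- c("grey", rep_len(MODULE_COLOR_NAMES, max(1, max(labels))))
  cols[labels + 1]
}

#' Module eigengenes
#'
#' For each module the member genes are z-scored per gene and the first
#' principal component across samples (unit-norm left singular vector) is the
#' eigengene. Sign is oriented so the eigengene correlates positively with
#' the module's average standardized expression. Variance explained is the
#' leading singular value's share of total variance.
#'
#' @param dataset the `ExpressionDataset` the labels were computed on.
#' @param labels per-gene integer labels (0 = unassigned).
#' @return object of class `ModuleSet`: `labels`, `eigengenes` (samples x
#'   modules), `var_explained`, `sizes`, `colors`, `sample_ids`.
#' @export
module_eigengenes <- function(dataset, labels) {
  M <- max(labels)
  if (M < 1) stop("no modules to summarize")
  n <- n_samples(dataset)
  me <- matrix(NA_real_, n, M,
               dimnames = list(dataset$sample_ids, paste0("ME", seq_len(M))))
  ve <- numeric(M)
  for (m in seq_len(M)) {
    mem <- which(labels == m)
    Z <- scale(t(dataset$values[mem, , drop = FALSE]))  # samples x genes
    sv <- svd(Z, nu = 1, nv = 0)
    e <- sv$u[, 1]
    avg <- rowMeans(Z)
    if (sum(e * avg) < 0) e <- -e
    me[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(labels = labels, eigengenes = me, var_explained = ve,
                 sizes = as.integer(table(factor(labels, levels = seq_len(M)))),
                 colors = module_colors(seq_len(M)),
                 sample_ids = dataset$sample_ids),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d modules (sizes %s), %d genes unassigned\n",
              ncol(x$eigengenes),
              paste(x$sizes, collapse = ", "), sum(x$labels == 0)))
  invisible(x)
}

#' Merge modules with highly correlated eigengenes
#'
#' Eigengenes are clustered at dissimilarity `1 - cor(ME)` (average linkage);
#' clusters joined below `cut_height` are merged, eigengenes recomputed, and
#' the procedure iterated to a fixed point.
#'
#' @param dataset the `ExpressionDataset` the labels were computed on.
#' @param labels per-gene integer labels.
#' @param cut_height merge threshold on eigengene dissimilarity.
#' @return merged labels, renumbered by decreasing module size.
#' @export
merge_close_modules <- function(dataset, labels, cut_height = 0.15) {
  repeat {
    M <- max(labels)
    if (M < 2) return(labels)
    ms <- module_eigengenes(dataset, labels)
    d <- 1 - cor(ms$eigengenes)
    hc <- hclust(as.dist(d), method = "average")
    grp <- cutree(hc, h = cut_height)
    if (max(grp) == M) return(labels)        # nothing merged
    new <- labels
    for (m in seq_len(M)) new[labels == m] <- grp[m]
    labels <- relabel_by_size(new)
  }
}

#' Spearman correlations between module eigengenes and phenotypes
#'
#' @param module_set a [module_eigengenes()] result.
#' @param phenotypes data.frame keyed by sample_id with numeric traits.
#' @param alpha significance threshold for the flag.
#' @return data.frame: module, color, trait, rho, n_obs, p_value, significant.
#' @export
module_trait_correlation <- function(module_set, phenotypes, alpha = 0.05) {
  idx <- match(module_set$sample_ids, phenotypes$sample_id)
  traits <- setdiff(names(phenotypes), "sample_id")
  traits <- traits[vapply(phenotypes[traits], is.numeric, logical(1))]
  rows <- list()
  for (m in seq_len(ncol(module_set$eigengenes))) {
    e <- module_set$eigengenes[, m]
    if (sd(e) == 0) stop("constant module eigengene")
    for (tr in traits) {
      y <- phenotypes[[tr]][idx]
      ok <- !is.na(y)
      ct <- suppressWarnings(cor.test(e[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      rows[[length(rows) + 1L]] <-
        data.frame(module = m, color = module_colors(m), trait = tr,
                   rho = unname(ct$estimate), n_obs = sum(ok),
                   p_value = ct$p.value,
                   significant = ct$p.value < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Diet and strain effects on module eigengenes
#'
#' Per eigengene: two-group Wilcoxon rank-sum p for HP vs HS, and
#' Kruskal-Wallis p across strains.
#'
#' @param module_set a [module_eigengenes()] result.
#' @param metadata per-sample metadata aligned with the eigengenes.
#' @return data.frame: module, color, wilcoxon_diet_p, kruskal_strain_p.
#' @export
me_group_tests <- function(module_set, metadata) {
  stopifnot(identical(as.character(metadata$sample_id), module_set$sample_ids))
  diet <- factor(metadata$diet, levels = VALID_DIETS)
  strain <- factor(metadata$strain)
  if (any(table(diet) == 0)) stop("both diets need observations")
  rows <- lapply(seq_len(ncol(module_set$eigengenes)), function(m) {
    e <- module_set$eigengenes[, m]
    w <- suppressWarnings(wilcox.test(e[diet == "HP"], e[diet == "HS"],
                                      exact = FALSE))
    k <- kruskal.test(e, strain)
    data.frame(module = m, color = module_colors(m),
               wilcoxon_diet_p = w$p.value, kruskal_strain_p = k$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export the network as a plain edge list
#'
#' Upper-triangle gene pairs with their TOM weight and a flag for weights at
#' or above `threshold`, for external visualization tools.
#'
#' @param tom a TOM with gene ids as dimnames.
#' @param threshold weight flag threshold.
#' @param keep_below if `FALSE` (default) only flagged edges are written.
#' @return data.frame: gene1, gene2, weight, above_threshold.
#' @export
export_edge_list <- function(tom, threshold = 0.1, keep_below = FALSE) {
  ut <- upper.tri(tom)
  idx <- which(ut, arr.ind = TRUE)
  w <- tom[ut]
  ids <- rownames(tom)
  out <- data.frame(gene1 = ids[idx[, 1]], gene2 = ids[idx[, 2]], weight = w,
                    above_threshold = w >= threshold, stringsAsFactors = FALSE)
  if (!keep_below) out <- out[out$above_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full network branch: power, adjacency, TOM, modules, eigengenes
#'
#' @param dataset a filtered `ExpressionDataset`.
#' @param config a [network_config()]; if `config$beta` is `NULL` the power
#'   is chosen by [pick_soft_threshold()].
#' @return list: `beta`, `soft_threshold` (table or NULL), `labels` (after
#'   merging), `module_set`, `tom`.
#' @export
detect_modules <- function(dataset, config = network_config()) {
  st <- NULL
  beta <- config$beta
  if (is.null(beta)) {
    st <- pick_soft_threshold(dataset, config)
    beta <- st$beta
  }
  adj <- adjacency_matrix(dataset, beta)
  tom <- tom_similarity(adj)
  labels <- cluster_and_cut(tom, config)
  if (max(labels) >= 2)
    labels <- merge_close_modules(dataset, labels, config$merge_cut_height)
  ms <- if (max(labels) >= 1) module_eigengenes(dataset, labels) else NULL
  list(beta = beta, soft_threshold = st$table, labels = labels,
       module_set = ms, tom = tom)
}
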