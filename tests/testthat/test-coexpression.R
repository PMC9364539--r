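planted_blocks <- function(seed = 5) {
  simulate_dataset(sim_config(
    n_genes = 740, sigma2_strain = 0, sigma2_diet = 0, diet_affected_frac = 0,
    sigma2_interaction = 0, sigma2_batch = 0, sigma2_resid = 0.3,
    modules = list(sizes = c(80, 80, 80), loadings = rep(sqrt(0.7), 3),
                   gamma = c(2, 0, 0)), seed = seed))
}

test_that("adjacency is |cor|^beta, exactly", {
  # construct two genes with exact correlation -0.5
  x <- rnorm(40); x <- (x - mean(x)) / sd(x)
  u <- rnorm(40); u <- residuals(lm(u ~ x)); u <- u / sd(u)
  y <- -x + sqrt(3) * u
  ds <- make_toy_dataset(rbind(x, y, x + 0.1 * u), meta = make_meta(40))
  a <- adjacency_matrix(ds, 5)
  expect_equal(a[1, 2], 0.5^5, tolerance = 1e-12)
  expect_equal(a[1, 2], 0.03125, tolerance = 1e-12)
  # beta = 1 reduces to |cor|
  a1 <- adjacency_matrix(ds, 1)
  expect_equal(unname(a1), abs(unname(cor(t(ds$values)))), tolerance = 1e-12)
  # element-wise oracle on a random 30-gene matrix
  set.seed(1)
  ds2 <- make_toy_dataset(matrix(rnorm(30 * 20), 30, 20),
                          meta = make_meta(20))
  expect_equal(unname(adjacency_matrix(ds2, 6)),
               oracle_adjacency(ds2$values, 6), tolerance = 1e-12)
  ds3 <- make_toy_dataset(rbind(rep(1, 10), rnorm(10)), meta = make_meta(10))
  expect_error(suppressWarnings(adjacency_matrix(ds3, 5)), "constant")
})

test_that("TOM closed forms and brute-force oracle agree", {
  # 2-gene network: TOM_12 = a_12
  a2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(tom_similarity(a2)[1, 2], 0.4, tolerance = 1e-12)
  # complete graph saturates at 1
  a4 <- matrix(1, 4, 4)
  expect_true(all(tom_similarity(a4) == 1))
  # random 20-node adjacency vs the O(n^3) oracle
  set.seed(2)
  r <- matrix(runif(400), 20)
  a <- (r + t(r)) / 2
  diag(a) <- 1
  expect_equal(unname(tom_similarity(a)), oracle_tom(a), tolerance = 1e-12)
  # structural checks
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("dynamic cut recovers planted blocks and leaves noise grey", {
  s <- planted_blocks()
  tr <- s$truth$genes
  net <- detect_modules(s$dataset, network_config(beta = 5))
  planted <- tr$module > 0
  expect_gte(adjusted_rand_index(net$labels[planted], tr$module[planted]),
             0.9)
  expect_gte(mean(net$labels[!planted] == 0), 0.95)
})

test_that("degenerate clustering inputs behave as documented", {
  # a single homogeneous block collapses to one module
  s <- simulate_dataset(sim_config(
    n_genes = 60, sigma2_strain = 0, sigma2_diet = 0, diet_affected_frac = 0,
    sigma2_interaction = 0, sigma2_batch = 0, sigma2_resid = 0.3,
    modules = list(sizes = 60, loadings = sqrt(0.7), gamma = 1), seed = 7))
  net <- detect_modules(s$dataset, network_config(beta = 5))
  expect_equal(max(net$labels), 1)
  # i.i.d. noise: everything grey
  sN <- simulate_dataset(sim_config(
    n_genes = 300, sigma2_strain = 0, sigma2_diet = 0, diet_affected_frac = 0,
    sigma2_interaction = 0, sigma2_batch = 0, sigma2_resid = 1, seed = 8))
  netN <- detect_modules(sN$dataset, network_config(beta = 5))
  expect_gte(mean(netN$labels == 0), 0.95)
  # fewer genes than the minimum module size
  tiny <- subset_dataset(sN$dataset, features = 1:10)
  tomt <- tom_similarity(adjacency_matrix(tiny, 5))
  expect_warning(lab <- cluster_and_cut(tomt, network_config()), "fewer genes")
  expect_true(all(lab == 0))
})

test_that("network labels are deterministic and permutation consistent", {
  s <- planted_blocks(9)
  ds <- s$dataset
  n1 <- detect_modules(ds, network_config(beta = 5))
  n2 <- detect_modules(ds, network_config(beta = 5))
  expect_identical(n1$labels, n2$labels)
  set.seed(10)
  perm <- sample(n_features(ds))
  dsp <- subset_dataset(ds, features = perm)
  np <- detect_modules(dsp, network_config(beta = 5))
  # same partition after permuting gene order (labels may be renamed)
  expect_equal(adjusted_rand_index(np$labels, n1$labels[perm]), 1)
})

test_that("eigengenes summarize modules with oriented first PCs", {
  s <- planted_blocks(11)
  net <- detect_modules(s$dataset, network_config(beta = 5))
  ms <- net$module_set
  # planted single-factor module: eigengene tracks the factor
  lab_of_mod1 <- as.integer(names(which.max(table(
    net$labels[s$truth$genes$module == 1]))))
  expect_gte(abs(cor(ms$eigengenes[, lab_of_mod1], s$truth$factors[1, ])),
             0.95)
  # identical member genes: variance explained 1, ME tracks the profile
  prof <- rnorm(24)
  dsI <- make_toy_dataset(matrix(rep(prof, each = 5), 5, 24) ,
                          meta = make_meta(24))
  msI <- module_eigengenes(dsI, setNames(rep(1L, 5), dsI$feature_ids))
  expect_equal(msI$var_explained[1], 1, tolerance = 1e-10)
  expect_gt(cor(msI$eigengenes[, 1], prof), 0.999)
  # flipping all member genes flips the eigengene (deterministic orientation)
  dsF <- make_toy_dataset(-dsI$values, meta = make_meta(24))
  msF <- module_eigengenes(dsF, setNames(rep(1L, 5), dsF$feature_ids))
  expect_equal(msF$eigengenes[, 1], -msI$eigengenes[, 1], tolerance = 1e-10)
  # single-gene module: eigengene proportional to that gene's z-score
  ds1 <- make_toy_dataset(rbind(prof, rnorm(24) + 5), meta = make_meta(24))
  ms1 <- module_eigengenes(ds1, setNames(c(1L, 0L), ds1$feature_ids))
  z <- scale(prof)[, 1]
  expect_equal(abs(cor(ms1$eigengenes[, 1], z)), 1, tolerance = 1e-10)
})

test_that("close modules merge, distant ones persist", {
  # one factor split across two labels: eigengene correlation near 1
  set.seed(12)
  f1 <- rnorm(60); f3 <- rnorm(60)
  v <- rbind(t(sapply(1:20, function(i) f1 + rnorm(60, 0, 0.3))),
             t(sapply(1:20, function(i) f1 + rnorm(60, 0, 0.3))),
             t(sapply(1:20, function(i) f3 + rnorm(60, 0, 0.3))))
  ds <- make_toy_dataset(v, meta = make_meta(60))
  labels <- setNames(rep(1:3, each = 20), ds$feature_ids)
  merged <- merge_close_modules(ds, labels, cut_height = 0.15)
  expect_equal(max(merged), 2)
  # the two split halves share a label; the independent factor stays apart
  expect_equal(length(unique(merged[1:40])), 1)
  expect_false(merged[41] == merged[1])
  # orthogonal eigengenes: nothing merges
  un <- merge_close_modules(ds, setNames(c(rep(1L, 40), rep(2L, 20)),
                                         ds$feature_ids), 0.15)
  expect_equal(max(un), 2)
})

test_that("module-trait correlation finds the planted ME-phenotype link", {
  s <- planted_blocks(13)
  net <- detect_modules(s$dataset, network_config(beta = 5))
  mt <- module_trait_correlation(net$module_set, s$phenotypes)
  bf <- mt[mt$trait == "body_fat_pct", ]
  lab1 <- as.integer(names(which.max(table(
    net$labels[s$truth$genes$module == 1]))))
  expect_equal(which.max(abs(bf$rho)), match(lab1, bf$module))
  # Spearman rho is invariant to monotone trait transforms
  ph2 <- s$phenotypes
  ph2$body_fat_pct <- exp(ph2$body_fat_pct / 10)
  mt2 <- module_trait_correlation(net$module_set, ph2)
  expect_equal(mt2$rho[mt2$trait == "body_fat_pct"], bf$rho,
               tolerance = 1e-12)
})

test_that("eigengene group tests separate diet from strain effects", {
  # module 1 diet-responsive, module 2 strain-driven
  cfg <- sim_config(n_genes = 500, seed = 14, sigma2_strain = 0.03,
                    sigma2_batch = 0, sigma2_interaction = 0,
                    sigma2_diet = 0.3, diet_affected_frac = 0,
                    modules = list(sizes = c(60, 60),
                                   loadings = c(0.6, 0.6), gamma = c(0, 0),
                                   diet_frac = c(1, 0),
                                   strain_cor = c(0, 0.8)))
  s <- simulate_dataset(cfg)
  net <- detect_modules(s$dataset, network_config(beta = 5))
  ms <- net$module_set
  tests <- me_group_tests(ms, s$dataset$metadata)
  tr <- s$truth$genes
  lab1 <- as.integer(names(which.max(table(net$labels[tr$module == 1]))))
  lab2 <- as.integer(names(which.max(table(net$labels[tr$module == 2]))))
  expect_lt(tests$wilcoxon_diet_p[tests$module == lab1], 0.01)
  expect_lt(tests$kruskal_strain_p[tests$module == lab2], 0.01)
  expect_gt(tests$wilcoxon_diet_p[tests$module == lab2], 0.05)
})

test_that("soft threshold selection on scale-free data is self consistent", {
  sf <- simulate_scale_free_expression(600, 132, beta0 = 5, seed = 2)
  st <- pick_soft_threshold(sf, network_config())
  expect_true(st$reached_target)
  crossing <- st$table$power[st$table$signed_rsq >= 0.9]
  expect_equal(st$beta, min(crossing))
  # mean connectivity decreases monotonically in the power
  expect_true(all(diff(st$table$mean_k) < 0))
  # pure noise: no crossing, argmax fallback with a warning
  set.seed(9)
  noise <- make_toy_dataset(matrix(rnorm(200 * 30), 200, 30),
                            meta = make_meta(30))
  expect_warning(stn <- pick_soft_threshold(noise, network_config()),
                 "maximal fit")
  expect_false(stn$reached_target)
  # two perfectly correlated genes: degenerate bins
  x <- rnorm(30)
  dup <- make_toy_dataset(rbind(rep(0, 30), matrix(rep(x, 24), 24, 30,
                                                   byrow = TRUE))[-1, ],
                          meta = make_meta(30))
  expect_error(pick_soft_threshold(dup, network_config()), "degenerate")
})

test_that("edge list export preserves weights and threshold flags", {
  s <- planted_blocks(15)
  sub <- subset_dataset(s$dataset, features = 1:30)
  tom <- tom_similarity(adjacency_matrix(sub, 5))
  el <- export_edge_list(tom, threshold = 0.05, keep_below = TRUE)
  expect_equal(nrow(el), choose(30, 2))
  i <- match(el$gene1[10], rownames(tom))
  j <- match(el$gene2[10], rownames(tom))
  expect_equal(el$weight[10], tom[i, j])
  expect_true(all(el$above_threshold == (el$weight >= 0.05)))
})
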