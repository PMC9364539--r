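test_that("inter-array distance score flags a globally shifted array", {
  set.seed(1)
  v <- matrix(rnorm(200, 8, 0.2), 20, 10)
  v[, 4] <- v[, 4] + 10
  ds <- make_toy_dataset(v, meta = make_meta(10))
  sc <- score_array_distance(ds)
  # brute-force mean pairwise Euclidean distance for the shifted column
  d4 <- mean(sapply(setdiff(1:10, 4), function(j)
    sqrt(sum((v[, 4] - v[, j])^2))))
  expect_equal(sc$distance_score[4], d4, tolerance = 1e-12)
  expect_true(sc$flagged[4])
  expect_equal(which.max(sc$distance_score), 4)

  same <- make_toy_dataset(matrix(rep(1:5, 4), 5, 4), meta = make_meta(4))
  sc2 <- score_array_distance(same)
  expect_true(all(sc2$distance_score == 0))
  expect_false(any(sc2$flagged))

  two <- make_toy_dataset(matrix(1:10, 5, 2), meta = make_meta(2))
  expect_error(score_array_distance(two), ">= 3 samples")
})

test_that("per-array KS statistic against pooled intensities", {
  set.seed(2)
  v <- matrix(rnorm(600, 8), 60, 10)
  v[, 7] <- rnorm(60, 11)       # drawn from a +3-shifted distribution
  ds <- make_toy_dataset(v, meta = make_meta(10))
  sc <- score_array_ks(ds)
  expect_equal(which.max(sc$ks_stat), 7)
  # agree with a sup-scan oracle over all pooled values
  for (j in c(1, 7)) {
    expect_equal(sc$ks_stat[j], oracle_ks_sup(v[, j], as.numeric(v)),
                 tolerance = 1e-12)
  }
  # identical columns: equal and minimal K_a for all
  same <- make_toy_dataset(matrix(rep(rnorm(30), 4), 30, 4),
                           meta = make_meta(4))
  sc2 <- score_array_ks(same)
  expect_true(all(abs(sc2$ks_stat - sc2$ks_stat[1]) < 1e-12))
  # single-gene dataset is degenerate but legal
  one <- make_toy_dataset(matrix(c(1, 1, 2, 3), 1, 4), meta = make_meta(4))
  expect_true(all(is.finite(score_array_ks(one)$ks_stat)))
})

test_that("Hoeffding's D detects intensity-dependent bias on MA coordinates", {
  set.seed(3)
  base <- rnorm(50, 8, 2)
  v <- sapply(1:8, function(j) base + rnorm(50, 0, 0.05))
  # array with M = 0.5 A exactly: x - m = 0.25 (x + m)  =>  x = (5/3) m
  v[, 3] <- apply(v, 1, median) * 5 / 3
  ds <- make_toy_dataset(v, meta = make_meta(8))
  sc <- score_array_hoeffding(ds)
  expect_true(sc$flagged[3])
  expect_gt(sc$hoeffding_stat[3], max(sc$hoeffding_stat[-3]))

  four <- make_toy_dataset(matrix(rnorm(16), 4, 4), meta = make_meta(4))
  expect_error(score_array_hoeffding(four), ">= 5")
  expect_error(hoeffding_d(1:4, 1:4), ">= 5")
})

test_that("hoeffding_d agrees with the rank-definition oracle", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- if (i %% 2) rnorm(n) else x + rnorm(n, 0, 0.5)
    if (i %% 3 == 0) x <- round(x)   # exercise midranks under ties
    expect_equal(hoeffding_d(x, y), oracle_hoeffding(x, y),
                 tolerance = 1e-12)
  }
})

test_that("arrays are removed only when all three criteria flag them", {
  set.seed(5)
  base <- rnorm(60, 8, 2)
  v <- sapply(1:10, function(j) base + rnorm(60, 0, 0.1))
  # a triple outlier: strong multiplicative distortion gives large distance,
  # a shifted intensity distribution, and A-M dependence all at once
  v[, 2] <- base * 2
  ds <- make_toy_dataset(v, meta = make_meta(10))
  out <- remove_outlier_arrays(ds)
  expect_true(out$qc$removed[2])
  expect_equal(n_samples(out$dataset), 9)
  expect_identical(out$dataset$metadata$sample_id, out$dataset$sample_ids)
  expect_true(all(out$qc$removed ==
                  (out$qc$flag_distance & out$qc$flag_ks & out$qc$flag_hoeffding)))

  # an array flagged by two criteria but not Hoeffding's is retained
  v2 <- sapply(1:10, function(j) base + rnorm(60, 0, 0.1))
  v2[, 5] <- v2[, 5] + 3          # additive shift: distance + KS, but M ~ const
  ds2 <- make_toy_dataset(v2, meta = make_meta(10))
  out2 <- remove_outlier_arrays(ds2)
  expect_true(out2$qc$flag_distance[5] && out2$qc$flag_ks[5])
  expect_false(out2$qc$removed[5])
  expect_equal(n_samples(out2$dataset), 10)
})

test_that("TC-ID filter applies the median and exceedance rules exactly", {
  # hand-enumerated toy: medians {10, 0}, mean of medians 5
  v <- rbind(rep(10, 8), c(rep(0, 7), 6))       # gene 2: 1/8 samples above 5
  ds <- make_toy_dataset(v, symbols = c("GA", "GB"), meta = make_meta(8))
  f <- filter_tcids(ds)
  expect_true(f$report$pass_median_rule[1])
  expect_false(f$report$pass_median_rule[2])
  expect_false(f$report$pass_fraction_rule[2])   # 1/8 = 0.125 not > 0.125
  expect_equal(f$dataset$feature_ids, "TC001")

  # 2/8 samples above the mean of medians passes the strict > 12.5% rule
  v2 <- rbind(rep(10, 8), c(rep(0, 6), 6, 6))
  ds2 <- make_toy_dataset(v2, symbols = c("GA", "GB"), meta = make_meta(8))
  f2 <- filter_tcids(ds2)
  expect_true(f2$report$pass_fraction_rule[2])
  expect_equal(n_features(f2$dataset), 2)

  # identical features: median == mean of medians, rule 1 strict > fails,
  # fraction of samples above is 0, so everything is dropped
  v3 <- matrix(5, 3, 8)
  ds3 <- make_toy_dataset(v3, meta = make_meta(8))
  f3 <- filter_tcids(ds3)
  expect_equal(n_features(f3$dataset), 0)
})

test_that("best probe per gene is the highest-mean TC-ID, ties lexicographic", {
  # low-intensity padding genes keep the mean-of-medians below the probes
  pad <- rbind(rep(0, 6), rep(0, 6))
  v <- rbind(rep(8.0, 6), rep(7.9, 6), rep(7.9, 6), pad)
  ds <- make_toy_dataset(v, symbols = c("GX", "GX", "GY", "GZ1", "GZ2"),
                         meta = make_meta(6))
  f <- filter_tcids(ds)
  expect_setequal(f$dataset$feature_ids, c("TC001", "TC003"))
  # tie within a gene breaks to the lexicographically first TC-ID
  v2 <- rbind(rep(8, 6), rep(8, 6), pad)
  ds2 <- make_toy_dataset(v2, symbols = c("GX", "GX", "GZ1", "GZ2"),
                          meta = make_meta(6))
  f2 <- filter_tcids(ds2)
  expect_equal(f2$dataset$feature_ids, "TC001")
})

test_that("filter is idempotent on well-separated intensity populations", {
  ds <- make_bimodal_dataset()
  f1 <- filter_tcids(ds)
  f2 <- filter_tcids(f1$dataset)
  expect_identical(f2$dataset$feature_ids, f1$dataset$feature_ids)
  expect_identical(f2$dataset$values, f1$dataset$values)
})

test_that("founder-null genes pass the filter, globally suppressed genes fail", {
  ds <- make_bimodal_dataset(n_expr = 40, n_unexpr = 20, n_samp = 22)
  v <- ds$values
  # founder-null emulation: one expressed gene suppressed in 3/22 samples
  v[5, 1:3] <- v[5, 1:3] - 6
  # globally suppressed gene: below threshold everywhere
  v[6, ] <- v[6, ] - 6
  ds2 <- make_toy_dataset(v, meta = make_meta(22))
  f <- filter_tcids(ds2)
  expect_true("TC005" %in% f$dataset$feature_ids)
  expect_false("TC006" %in% f$dataset$feature_ids)
})
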