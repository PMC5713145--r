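test_that("pooling concatenates members once each and validates ids", {
  a <- make_axis_ds("a", 1:10)
  b <- make_axis_ds("b", 5:14)
  pool <- pool_observations(c("a", "b"), list(a = a, b = b))
  expect_equal(nrow(pool), 20)
  expect_equal(sort(unique(pool$dataset)), c("a", "b"))
  expect_error(pool_observations(c("a", "a"), list(a = a)),
               "duplicate", class = "mx_validation_error")
  expect_error(pool_observations(c("a", "zz"), list(a = a, b = b)),
               "zz", class = "mx_validation_error")
})

test_that("intensity merging matches hand values and the brute-force oracle", {
  one <- make_axis_ds("one", 5L, intensity = 100, sigma = 10)
  m1 <- merge_intensities(pool_observations("one", list(one = one)))
  expect_equal(m1$i_mean, 100)
  expect_equal(m1$sigma, 10)
  expect_equal(m1$multiplicity, 1L)

  a <- make_axis_ds("a", 5L, intensity = 100, sigma = 10)
  b <- make_axis_ds("b", 5L, intensity = 200, sigma = 10)
  m2 <- merge_intensities(pool_observations(c("a", "b"), list(a = a, b = b)))
  expect_equal(m2$i_mean, 150)
  expect_equal(m2$sigma, 10 / sqrt(2))
  expect_equal(m2$multiplicity, 2L)

  # random pools vs per-key accumulation
  set.seed(21)
  for (rep in 1:5) {
    ks <- sample(1:8, 30, replace = TRUE)
    ds <- make_axis_ds("r", ks, intensity = rnorm(30, 100, 20),
                       sigma = runif(30, 0.5, 3))
    pool <- pool_observations("r", list(r = ds))
    m <- merge_intensities(pool)
    oracle <- brute_merge(pool$key, pool$intensity, pool$sigma)
    expect_equal(m$i_mean, oracle$i_mean)
    expect_equal(m$sigma, oracle$sigma)
    expect_equal(m$multiplicity, oracle$multiplicity)
  }
})

test_that("merging is invariant to observation and dataset order", {
  set.seed(4)
  a <- make_axis_ds("a", sample(1:6, 20, TRUE), intensity = rnorm(20, 100),
                    sigma = runif(20, 1, 2))
  b <- make_axis_ds("b", sample(3:9, 15, TRUE), intensity = rnorm(15, 100),
                    sigma = runif(15, 1, 2))
  m_ab <- merge_intensities(pool_observations(c("a", "b"), list(a = a, b = b)))
  m_ba <- merge_intensities(pool_observations(c("b", "a"), list(a = a, b = b)))
  expect_equal(m_ab, m_ba, ignore_attr = TRUE)
  perm <- sample(nrow(a$observations))
  a2 <- partial_dataset("a", a$cell, 1, a$observations[perm, ])
  m_p <- merge_intensities(pool_observations(c("a", "b"), list(a = a2, b = b)))
  expect_equal(m_ab, m_p, ignore_attr = TRUE)
})

test_that("R factors match hand computation and the doublet identities", {
  mkpool <- function(key, i) data.frame(key = key, intensity = i)
  # identical observations: all three zero
  rf0 <- r_factors(mkpool(c(1, 1, 2, 2), c(5, 5, 9, 9)))
  expect_equal(rf0$r_merge, 0)
  expect_equal(rf0$r_meas, 0)
  # one group {90, 110}: 20/200, times sqrt(2), times 1
  rf <- r_factors(mkpool(c(1, 1), c(90, 110)))
  expect_equal(rf$r_merge, 0.1)
  expect_equal(rf$r_meas, 0.1 * sqrt(2))
  expect_equal(rf$r_pim, 0.1)
  # singletons excluded entirely
  rf2 <- r_factors(mkpool(c(1, 1, 2), c(90, 110, 1e6)))
  expect_equal(rf2$r_merge, 0.1)
  expect_equal(rf2$n_groups, 1L)
  # all singleton: undefined, not zero
  expect_true(is.na(r_factors(mkpool(1:4, 1:4))$r_merge))
  # doublet-only pools: r_meas = sqrt(2) r_merge, r_pim = r_merge
  set.seed(8)
  key <- rep(1:50, each = 2)
  rfd <- r_factors(mkpool(key, rnorm(100, 100, 10)))
  expect_equal(rfd$r_meas, sqrt(2) * rfd$r_merge)
  expect_equal(rfd$r_pim, rfd$r_merge)
  # random pools vs brute force; r_pim <= r_meas
  for (rep in 1:5) {
    key <- sample(1:20, 100, replace = TRUE)
    i <- rnorm(100, 100, 15)
    rf <- r_factors(mkpool(key, i))
    oracle <- brute_r_factors(key, i)
    expect_equal(rf$r_merge, oracle$r_merge)
    expect_equal(rf$r_meas, oracle$r_meas)
    expect_equal(rf$r_pim, oracle$r_pim)
    expect_lte(rf$r_pim, rf$r_meas)
  }
})

test_that("CC1/2 is 1 without noise, seeded, and matches its expectation", {
  mkpool <- function(key, i) data.frame(key = key, intensity = i)
  # noise-free: all observations of a group identical
  key <- rep(1:30, each = 3)
  expect_equal(as.numeric(cc_half(mkpool(key, rep(rnorm(30, 100, 30),
                                                  each = 3)))), 1)
  # determinism under a fixed seed; the caller's RNG stream is untouched
  p <- mkpool(rep(1:100, each = 2), rnorm(200, 100, 10))
  set.seed(99); before <- runif(1)
  set.seed(99)
  v1 <- cc_half(p, seed = 7)
  v2 <- cc_half(p, seed = 7)
  expect_identical(v1, v2)
  expect_equal(runif(1), before)
  # analytic expectation: halves of doublets around true values correlate at
  # var_sig / (var_sig + var_noise)
  set.seed(12)
  truth <- rnorm(3000, 0, 2)
  p2 <- mkpool(rep(1:3000, each = 2), rep(truth, each = 2) + rnorm(6000))
  expect_equal(as.numeric(cc_half(p2, seed = 2)), 4 / 5, tolerance = 0.03)
  # undefined below two usable groups
  expect_true(is.na(cc_half(mkpool(c(1, 1, 2), c(1, 2, 3)))))
})

test_that("sigAno matches hand values and the null baseline", {
  sim <- simulate_experiment(small_config(n_classes = 1,
                                          datasets_per_class = 4,
                                          anomalous_signal = 0))
  pool <- pool_observations(names(sim$datasets), sim$datasets,
                            anomalous = TRUE)
  merged <- merge_intensities(pool)
  # hand value: I+ = 120 (3), I- = 100 (4) -> 20 / 5
  fake <- merged[1, ]
  fake$i_plus <- 120; fake$sigma_plus <- 3
  fake$i_minus <- 100; fake$sigma_minus <- 4
  fake$n_plus <- fake$n_minus <- 1L; fake$centric <- FALSE
  expect_equal(as.numeric(sig_ano(fake)), 4)
  fake$i_minus <- 120; fake$sigma_minus <- 3
  expect_equal(as.numeric(sig_ano(fake)), 0)
  expect_error(sig_ano(merge_intensities(pool_observations(
    names(sim$datasets), sim$datasets))), class = "mx_validation_error")
})

test_that("shelled statistics are conserved and complete data score 1.0", {
  # noise-free, full-coverage, single-observation dataset
  cfg <- small_config(n_classes = 1, datasets_per_class = 2, noise_level = 0,
                      within_cc = 1, wedge_fraction = 1, multiplicity = 1,
                      cell_jitter = 0)
  sim <- simulate_experiment(cfg)
  pool <- pool_observations(names(sim$datasets), sim$datasets)
  st <- merge_statistics(pool, d_min = cfg$d_min, n_shells = 6)
  expect_true(all(abs(st$shells$completeness - 1) < 1e-12))
  expect_equal(st$overall$completeness, 1)
  expect_equal(sum(st$shells$n_unique), st$overall$n_unique)
  expect_equal(sum(st$shells$n_total), st$overall$n_total)
  expect_equal(st$overall$multiplicity, 2, tolerance = 1e-12)
  expect_equal(st$overall$cc_half, 1, tolerance = 1e-9)
  expect_equal(st$overall$r_merge, 0, tolerance = 1e-12)

  # a noisy pool keeps the r_pim <= r_meas ordering in every shell
  sim2 <- simulate_experiment(small_config(n_classes = 1,
                                           datasets_per_class = 8))
  st2 <- merge_statistics(pool_observations(names(sim2$datasets),
                                            sim2$datasets), n_shells = 5)
  ok <- is.finite(st2$shells$r_meas)
  expect_true(all(st2$shells$r_pim[ok] <= st2$shells$r_meas[ok]))
  expect_true(all(st2$shells$completeness >= 0 &
                    st2$shells$completeness <= 1))
})

test_that("selective merging beats indiscriminate merging on synthetic classes", {
  sim <- simulate_experiment(small_config(seed = 31))
  tree <- average_linkage(build_distance_matrix(sim$datasets))
  sel <- cut_clusters(tree, threshold_by_growth(tree), "largest")
  pure <- pool_observations(sel$clusters[[1]], sim$datasets)
  all_in <- pool_observations(names(sim$datasets), sim$datasets)
  expect_gt(as.numeric(cc_half(pure, 1)), as.numeric(cc_half(all_in, 1)))
  expect_lt(r_factors(pure)$r_meas, r_factors(all_in)$r_meas)
})
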