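# Evaluation machinery: distances, subsampling, CDF interpolation,
# Bland-Altman, pairwise correlation.

test_that("distance_to_population is the mean absolute difference", {
  expect_equal(distance_to_population(c(1, 2), c(0, 0)), 1.5)
  expect_equal(distance_to_population(c(3, 3, 3), c(3, 3, 3)), 0)
  expect_equal(distance_to_population(c(1, 2, 3) + 0.7, c(1, 2, 3)), 0.7)
  # pairwise-complete dropping
  expect_equal(distance_to_population(c(1, NA, 5), c(0, 0, NA)), 1)
  expect_error(distance_to_population(c(NA, NA), c(1, 2)), "overlapping")
  # pseudometric on a fixed feature set: symmetry and triangle inequality
  withr::with_seed(21, {
    a <- rnorm(30); b <- rnorm(30); c <- rnorm(30)
    expect_equal(distance_to_population(a, b), distance_to_population(b, a))
    expect_lte(distance_to_population(a, c),
               distance_to_population(a, b) + distance_to_population(b, c))
  })
})

test_that("subsample_donors draws seeded donor subsets and scores them", {
  withr::with_seed(5, {
    mat <- matrix(rnorm(20 * 8, sd = 0.5), nrow = 20,
                  dimnames = list(sprintf("P%02d", 1:20), paste0("d", 1:8)))
  })
  tbl <- ratios_long(mat)
  tr <- subsample_donors(tbl, k = 4, trials = 6, penalty = 20, seed = 13)
  tr2 <- subsample_donors(tbl, k = 4, trials = 6, penalty = 20, seed = 13)
  expect_identical(tr$donors, tr2$donors)  # same seed, same draws
  expect_equal(nrow(tr), 6)
  expect_true(all(purrr::map_int(tr$donors, ~ length(unique(.x))) == 4))
  # per-trial values match a direct recomputation
  ids <- tr$donors[[1]]
  sub <- mat[, ids]
  expect_equal(unname(tr$raw_means[[1]]), unname(rowMeans(sub)))
  p1 <- apply(sub, 1, one_sample_t_pvalue, m0 = 0)
  expect_equal(unname(tr$scaled_values[[1]]),
               unname(rowMeans(sub) * 20^(-p1)), tolerance = 1e-12)
  pop <- rowMeans(mat)
  expect_equal(tr$raw_distance[1],
               mean(abs(rowMeans(sub) - pop)), tolerance = 1e-12)
  expect_error(subsample_donors(tbl, k = 9, trials = 2, seed = 1), "exceed")
})

test_that("a full-cohort draw reproduces the population exactly", {
  withr::with_seed(6, {
    mat <- matrix(rnorm(10 * 5), nrow = 10,
                  dimnames = list(paste0("P", 1:10), paste0("d", 1:5)))
  })
  tr <- subsample_donors(ratios_long(mat), k = 5, trials = 1, seed = 2)
  expect_equal(unname(tr$raw_means[[1]]), unname(rowMeans(mat)))
  expect_equal(tr$raw_distance, 0)
})

test_that("normalize_distances sets the mean raw distance to one", {
  tr <- tibble::tibble(trial = 1:2, raw_distance = c(2, 4),
                       scaled_distance = c(1, 2))
  out <- normalize_distances(tr)
  expect_equal(out$raw_distance, c(2 / 3, 4 / 3))
  expect_equal(out$scaled_distance, c(1 / 3, 2 / 3))
  expect_equal(mean(out$raw_distance), 1)
  # idempotent: normalising an already-normalised table changes nothing
  expect_equal(normalize_distances(out), out)
  one <- normalize_distances(tibble::tibble(raw_distance = 2,
                                            scaled_distance = 1))
  expect_equal(c(one$raw_distance, one$scaled_distance), c(1, 0.5))
  expect_error(normalize_distances(tibble::tibble(raw_distance = 0,
                                                  scaled_distance = 0)))
})

test_that("interpolate_cdf picks the nearest ECDF position, lower on ties", {
  out <- interpolate_cdf(c(1, 2, 3, 4), increments = 101)
  expect_equal(nrow(out), 101)
  # positions are i/n = 0.25, 0.5, 0.75, 1; target 0.6 is nearest 0.5 -> 2
  expect_equal(out$value[out$position == 0.6], 2)
  # exhaustive nearest-position oracle over the whole grid
  pos <- (1:4) / 4
  oracle <- vapply(out$position, function(t) {
    d <- abs(pos - t)
    c(1, 2, 3, 4)[which(d == min(d))[1]]  # lower position on ties
  }, numeric(1))
  expect_equal(out$value, oracle)
  # constant input maps every increment to that constant
  expect_true(all(interpolate_cdf(rep(7, 5))$value == 7))
  # monotone and bounded by the data range
  withr::with_seed(31, x <- rnorm(57))
  cdf <- interpolate_cdf(x)
  expect_true(all(diff(cdf$value) >= 0))
  expect_gte(min(cdf$value), min(x))
  expect_lte(max(cdf$value), max(x))
  expect_error(interpolate_cdf(numeric(0)))
})

test_that("bland_altman returns mean difference and limits of agreement", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(unlist(ba0[, 1:3])), c(0, 0, 0))
  # d = {-1, 1}: sd = sqrt(2), limits at +/- 1.96 * sqrt(2)
  ba <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_high, 2.772, tolerance = 1e-3)
  expect_equal(ba$loa_low, -ba$loa_high)
  # limits always bracket the mean difference
  withr::with_seed(41, {
    a <- rnorm(100); b <- a + rnorm(100, sd = 0.2)
    x <- bland_altman(a, b)
    expect_lte(x$loa_low, x$mean_difference)
    expect_gte(x$loa_high, x$mean_difference)
  })
  expect_error(bland_altman(1, 1))
  expect_error(bland_altman(c(1, NA), c(NA, 2)))
  expect_equal(tidy(ba)$mean_difference, 0)
})

test_that("pairwise_correlation tags inside/outside pairs on shared features", {
  withr::with_seed(51, {
    shared_truth <- rnorm(1000)
    t1 <- tibble::tibble(feature_id = sprintf("F%04d", 1:1000),
                         value = shared_truth + rnorm(1000, sd = 0.5))
    t2 <- tibble::tibble(feature_id = sprintf("F%04d", 1:1000),
                         value = shared_truth + rnorm(1000, sd = 0.5))
    t3 <- tibble::tibble(feature_id = sprintf("F%04d", 1:1000),
                         value = rnorm(1000))
  })
  out <- pairwise_correlation(list(a = t1, b = t2, c = t3),
                              groups = c("AD", "AD", "ALS"))
  expect_equal(nrow(out), 3)
  ab <- dplyr::filter(out, table_a == "a", table_b == "b")
  expect_equal(ab$relation, "inside")
  expect_gt(ab$r, 0.5)  # shared ground truth correlates
  # independent noise pairs: null-correlation bound 3/sqrt(n)
  ac <- dplyr::filter(out, table_b == "c")
  expect_true(all(ac$relation == "outside"))
  expect_true(all(abs(ac$r) < 0.1))
  # a table against itself correlates perfectly
  self <- pairwise_correlation(list(x = t1, y = t1), groups = c("g", "g"))
  expect_equal(self$r, 1)
  # too little overlap yields a flagged null
  tiny <- pairwise_correlation(
    list(x = t1[1:2, ], y = t1[1:2, ]), groups = c("g", "g")
  )
  expect_true(is.na(tiny$r))
  expect_equal(tiny$n_shared, 2)
})

test_that("scaling improves cross-study correlation for shared-truth pairs", {
  # two small-n studies of the same disease share true effects; scaling
  # suppresses their independent noise, so their correlation rises
  wins <- 0L
  for (seed in 1:8) {
    c1 <- generate_cohort(n_features = 300, n_control = 10, n_case = 5,
                          affected_fraction = 0.3, effect_log2 = 1,
                          noise_sd_log2 = 0.6, seed = seed)
    c2 <- generate_cohort(n_features = 300, n_control = 10, n_case = 5,
                          affected_fraction = 0.3, effect_log2 = 1,
                          noise_sd_log2 = 0.6, seed = seed + 1000,
                          truth = c1$truth)  # shared truth, independent noise
    s1 <- percept_table(abundance_ratios(c1$data), penalty = 20)
    s2 <- percept_table(abundance_ratios(c2$data), penalty = 20)
    raw <- pairwise_correlation(
      list(a = dplyr::transmute(s1, feature_id, value = m1),
           b = dplyr::transmute(s2, feature_id, value = m1)),
      groups = c("g", "g")
    )$r
    scaled <- pairwise_correlation(
      list(a = dplyr::transmute(s1, feature_id, value = V),
           b = dplyr::transmute(s2, feature_id, value = V)),
      groups = c("g", "g")
    )$r
    if (scaled > raw) wins <- wins + 1L
  }
  expect_gte(wins, 5)
})
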