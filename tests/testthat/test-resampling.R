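test_that("identical seed and parameters give bit-identical results", {
  pair <- make_simple_model(5, 3, 3)
  for (m in c("permutation", "independent", "hybrid", "fl")) {
    r1 <- cooccur_test(pair, "A", "B", m, iterations = 500, seed = 7)
    r2 <- cooccur_test(pair, "A", "B", m, iterations = 500, seed = 7)
    expect_identical(r1, r2)
  }
  # and the caller's RNG stream is untouched
  set.seed(99)
  before <- .Random.seed
  invisible(cooccur_test(pair, "A", "B", "hybrid", iterations = 50,
                         seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("p-value arithmetic and reporting of zero exceedances", {
  pair <- make_simple_model(3)
  r <- cooccur_test(pair, "A", "B", "permutation", iterations = 1000,
                    seed = 2)
  expect_equal(r$p_value, r$exceed / r$iterations)
  expect_gte(r$exceed, 0)
  expect_lte(r$exceed, r$iterations)
  expect_equal(format_pvalue(0, 5000), "< 2e-04")
  expect_equal(format_pvalue(0, 1e5), "< 1e-05")
})

test_that("observed statistic of zero gives p-value one", {
  pair <- make_simple_model(0, 3, 3)
  for (m in c("permutation", "independent", "hybrid", "fl")) {
    r <- cooccur_test(pair, "A", "B", m, iterations = 200, seed = 5)
    expect_equal(r$observed, 0)
    expect_equal(r$p_value, 1, label = m)
  }
})

test_that("permutation null matches exhaustive enumeration on a toy pool", {
  # 2 overlapped pairs: C(4,2) = 6 splits, 4 of which score >= 2
  model <- make_simple_model(2)
  null <- enum_perm_null(bf_dense_matrix(model), 2)
  p_exact <- mean(null >= 2)
  expect_equal(p_exact, 2 / 3)
  r <- cooccur_test(model, "A", "B", "permutation", iterations = 20000,
                    seed = 31, keep_null = TRUE)
  expect_lt(abs(r$p_value - p_exact), mc_tol(p_exact, r$iterations))
  # the whole null distribution agrees, not just the tail
  for (s in unique(null))
    expect_lt(abs(mean(r$null_sample == s) - mean(null == s)),
              mc_tol(mean(null == s), r$iterations))
})

test_that("independent null matches exhaustive enumeration on a toy pool", {
  # 2 overlapped pairs: all C(4,2)^2 = 36 ordered draw pairs
  model <- make_simple_model(2)
  null <- enum_indep_null(bf_dense_matrix(model), 2, 2)
  p_exact <- mean(null >= 2)
  expect_equal(p_exact, 34 / 36)
  r <- cooccur_test(model, "A", "B", "independent", iterations = 20000,
                    seed = 32, keep_null = TRUE)
  expect_lt(abs(r$p_value - p_exact), mc_tol(p_exact, r$iterations))
  for (s in unique(null))
    expect_lt(abs(mean(r$null_sample == s) - mean(null == s)),
              mc_tol(mean(null == s) + 1e-3, r$iterations))
})

test_that("hybrid with no overlapped pool follows the limiting pmf", {
  model <- make_simple_model(0, 6, 6)
  r <- cooccur_test(model, "A", "B", "hybrid", iterations = 20000,
                    seed = 33, keep_null = TRUE)
  k <- 0:6
  expected <- hybrid_limit_pmf(k, 6, 6)
  counts <- tabulate(r$null_sample + 1, nbins = 7)
  chi <- suppressWarnings(stats::chisq.test(counts, p = expected))
  expect_gt(chi$p.value, 1e-4)
})

test_that("hybrid with no singleton pool degenerates to permutation", {
  model <- make_simple_model(6)
  rh <- cooccur_test(model, "A", "B", "hybrid", iterations = 10000,
                     seed = 34, keep_null = TRUE)
  rp <- cooccur_test(model, "A", "B", "permutation", iterations = 10000,
                     seed = 35, keep_null = TRUE)
  ks <- suppressWarnings(stats::ks.test(rh$null_sample, rp$null_sample))
  expect_gt(ks$p.value, 1e-4)
  expect_lt(abs(rh$p_value - rp$p_value),
            mc_tol(perm_pvalue_simple(6, 6, 6), 10000) * 2)
})

test_that("FL on a two-factor dataset is the permutation test", {
  model <- make_simple_model(4, 2, 5)
  rf <- cooccur_test(model, "A", "B", "fl", iterations = 5000, seed = 36)
  rp <- cooccur_test(model, "A", "B", "permutation", iterations = 5000,
                     seed = 36)
  # same draws, same seed: identical exceedance count
  expect_identical(rf$exceed, rp$exceed)
})

test_that("Monte-Carlo permutation agrees with the analytic p-value", {
  for (params in list(c(2, 4, 4), c(5, 10, 10), c(5, 20, 20))) {
    m <- params[1]; n_a <- params[2]; n_b <- params[3]
    model <- make_simple_model(m, n_a - m, n_b - m)
    r <- cooccur_test(model, "A", "B", "permutation", iterations = 20000,
                      seed = 40 + m)
    p <- perm_pvalue_simple(m, n_a, n_b)
    expect_lt(abs(r$p_value - p), mc_tol(p, r$iterations),
              label = sprintf("m=%d nA=%d nB=%d", m, n_a, n_b))
  }
})

test_that("p-value is invariant to factor order", {
  model <- make_simple_model(6, 2, 4)
  for (m in c("permutation", "independent", "hybrid", "fl")) {
    rab <- cooccur_test(model, "A", "B", m, iterations = 10000, seed = 50)
    rba <- cooccur_test(model, "B", "A", m, iterations = 10000, seed = 51)
    expect_equal(rab$observed, rba$observed)
    expect_lt(abs(rab$p_value - rba$p_value),
              2 * mc_tol(max(rab$p_value, 0.01), 10000), label = m)
  }
})

test_that("an iteration budget can be split and merged", {
  model <- make_simple_model(5, 3, 3)
  base_seed <- 60
  parts <- lapply(1:4, function(k)
    cooccur_test(model, "A", "B", "hybrid", iterations = 2500,
                 seed = base_seed + k))
  merged <- merge_cooccur_tests(parts)
  expect_equal(merged$iterations, 10000)
  expect_equal(merged$exceed, sum(vapply(parts, `[[`, 0L, "exceed")))
  expect_equal(merged$p_value, merged$exceed / 10000)
  whole <- cooccur_test(model, "A", "B", "hybrid", iterations = 10000,
                        seed = base_seed)
  expect_lt(abs(merged$p_value - whole$p_value),
            2 * mc_tol(max(whole$p_value, 0.01), 10000))
  expect_error(merge_cooccur_tests(parts[[1]],
    cooccur_test(model, "A", "B", "permutation", iterations = 100,
                 seed = 1)), "different tests")
})

test_that("survey stage screens out clear negatives and can be bypassed", {
  disjoint <- make_simple_model(0, 5, 5)
  r <- cooccur_test(disjoint, "A", "B", "hybrid", iterations = 5000,
                    seed = 70, survey_iterations = 100)
  expect_true(r$screened)
  expect_equal(r$iterations, 100)
  expect_equal(r$p_value, 1)
  # cutoff = 1 always proceeds to the full run
  r2 <- cooccur_test(disjoint, "A", "B", "hybrid", iterations = 5000,
                     seed = 70, survey_iterations = 100, survey_cutoff = 1)
  expect_false(r2$screened)
  expect_equal(r2$iterations, 5000)
  # a strong co-occurrence passes the survey into the full run
  r3 <- cooccur_test(make_simple_model(10), "A", "B", "hybrid",
                     iterations = 5000, seed = 71,
                     survey_iterations = 100)
  expect_false(r3$screened)
  expect_equal(r3$iterations, 5000)
})

test_that("empty joint pool is rejected", {
  empty <- list(binding_profile(data.frame(contig = character(0),
                                           start = integer(0),
                                           end = integer(0)), "A"),
                binding_profile(data.frame(contig = character(0),
                                           start = integer(0),
                                           end = integer(0)), "B"))
  expect_error(cooccur_test(empty, "A", "B", "permutation",
                            iterations = 10), "empty joint pool")
})
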