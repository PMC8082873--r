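test_that("qmCV matches hand values and is scale-free", {
  X <- rbind(c(0.4, 0.6), c(0.6, 0.4))
  pr <- qmcv_direct(X)
  expect_equal(pr$qmcv_direct, 100 * sd(c(0.4, 0.6)) / 0.5)
  expect_equal(pr$per_taxon_cv$cv, rep(sd(c(0.4, 0.6)) / 0.5, 2))
  expect_equal(qmcv_direct(rbind(X[1, ], X[1, ]))$qmcv_direct, 0)
  expect_equal(qmcv_direct(100 * X)$qmcv_direct, pr$qmcv_direct)
  expect_error(qmcv_direct(X[1, , drop = FALSE]), class = "mockval_insufficient_replication")
})

test_that("qmcv_from_mvar is the closed-form conversion", {
  expect_equal(qmcv_from_mvar(0, 5), 0)
  expect_equal(qmcv_from_mvar(0.0016, 16), 1)
  expect_error(qmcv_from_mvar(-1, 5), class = "mockval_invalid_input")
})

test_that("variance decomposition reproduces the brute-force sums of squares", {
  m <- rbind(c(0.4, 0.6), c(0.6, 0.4), c(0.3, 0.7), c(0.7, 0.3))
  g <- c("a", "a", "b", "b")
  vd <- decompose_variance(m, group = g)
  # both group centers are [0.5, 0.5], so the between SS vanishes
  expect_equal(vd$tss_between, 0, tolerance = 1e-12)
  tss_w_oracle <-
    2 * oracle_dA_pairwise(c(0.4, 0.6), c(0.5, 0.5))^2 +
    2 * oracle_dA_pairwise(c(0.3, 0.7), c(0.5, 0.5))^2
  expect_equal(vd$tss_within, tss_w_oracle, tolerance = 1e-9)
  expect_true(vd$truncated)
  expect_equal(vd$var_between, 0)
  # identical measurements: everything is zero
  flat <- rbind(m[1, ], m[1, ], m[1, ], m[1, ])
  vd0 <- decompose_variance(flat, group = g)
  expect_equal(vd0$tss_between + vd0$tss_within, 0, tolerance = 1e-20)
  expect_error(decompose_variance(m, group = c("a", "a", "a", "a")),
    class = "mockval_invalid_input"
  )
  expect_error(decompose_variance(m[1:3, ], group = c("a", "a", "b")),
    class = "mockval_insufficient_replication"
  )
})

test_that("TSS additivity holds against the total SS about the grand center", {
  set.seed(121)
  for (i in 1:10) {
    p <- sample(2:4, 1); n <- sample(2:4, 1); D <- sample(3:6, 1)
    m <- rcomp_set(p * n, D)
    g <- rep(paste0("g", seq_len(p)), each = n)
    vd <- decompose_variance(m, group = g)
    expect_equal(vd$tss_between + vd$tss_within, oracle_total_ss(m), tolerance = 1e-6)
  }
})

test_that("sums of squares agree with vegan's distance-based decomposition", {
  skip_if_not_installed("vegan")
  set.seed(131)
  m <- rcomp_set(12, 6)
  g <- rep(c("a", "b", "c"), each = 4)
  vd <- decompose_variance(m, group = g)
  z <- clr(m)
  ad <- vegan::adonis2(dist(z) ~ g, permutations = 2)
  expect_equal(vd$tss_between, ad$SumOfSqs[1], tolerance = 1e-8)
  expect_equal(vd$tss_within, ad$SumOfSqs[2], tolerance = 1e-8)
})

test_that("simulated variance components are recovered and null betweens truncate", {
  set.seed(141)
  truth <- make_ground_truth(D = 20)
  model <- measurement_model(sigma_within = 0.03, sigma_between = 0.1)
  D <- 20
  true_w <- 0.03^2 * (D - 1)  # clr projection removes one df per taxon vector
  true_b <- 0.1^2 * (D - 1)
  est <- t(replicate(100, {
    st <- simulate_hierarchy(truth, model, p = 10, n = 2)
    vd <- decompose_variance(st$abundance, st$metadata, "group")
    c(w = vd$var_within, b = vd$var_between)
  }))
  expect_lt(abs(mean(est[, "w"]) - true_w) / true_w, 0.15)
  expect_lt(abs(mean(est[, "b"]) - true_b) / true_b, 0.15)

  null_model <- measurement_model(sigma_within = 0.05, sigma_between = 0)
  raw <- replicate(100, {
    st <- simulate_hierarchy(truth, null_model, p = 5, n = 2)
    vd <- decompose_variance(st$abundance, st$metadata, "group")
    vd$var_between_raw
  })
  expect_gte(mean(raw < 0), 0.4)  # negative raw estimates are common under the null
  expect_lt(abs(mean(raw)), 3 * sd(raw) / sqrt(100) + 1e-4)
})

test_that("upper confidence bounds behave like the chi-square construction", {
  set.seed(151)
  truth <- make_ground_truth(D = 10)
  st <- simulate_hierarchy(truth, measurement_model(sigma_within = 0.05, sigma_between = 0.05),
    p = 10, n = 2
  )
  vd <- decompose_variance(st$abundance, st$metadata, "group")
  cb <- upper_confidence_bound(vd)
  expect_true(all(cb$upper >= cb$estimate))
  # within bound equals the textbook formula
  expect_equal(
    cb$upper[cb$component == "within"],
    vd$df_within * vd$ms_within / qchisq(0.05, vd$df_within)
  )
  # more replication tightens the bound (ratio to estimate shrinks)
  st2 <- simulate_hierarchy(truth, measurement_model(sigma_within = 0.05, sigma_between = 0.05),
    p = 10, n = 6
  )
  vd2 <- decompose_variance(st2$abundance, st2$metadata, "group")
  cb2 <- upper_confidence_bound(vd2)
  ratio1 <- cb$upper[1] / cb$estimate[1]
  ratio2 <- cb2$upper[1] / cb2$estimate[1]
  expect_lt(ratio2, ratio1)
  # level 0.5 with large df: bound close to the point estimate
  cb_half <- upper_confidence_bound(vd2, level = 0.5)
  expect_equal(cb_half$upper[1], cb_half$estimate[1], tolerance = 0.05)
})

test_that("unbalanced designs error unless the harmonic-mean option is chosen", {
  set.seed(161)
  m <- rcomp_set(5, 4)
  g <- c("a", "a", "a", "b", "b")
  expect_error(decompose_variance(m, group = g), class = "mockval_invalid_input")
  vd <- decompose_variance(m, group = g, unbalanced = "harmonic")
  expect_equal(vd$n, 1 / mean(1 / c(3, 2)))
})

test_that("pairwise distance summaries match direct Aitchison distances", {
  set.seed(171)
  m <- rcomp_set(5, 4)
  rownames(m) <- paste0("s", 1:5)
  g <- c("a", "a", "a", "b", "b")
  pd <- pairwise_distance_summary(m, stratifier = g)
  expect_equal(nrow(pd), choose(3, 2) + choose(2, 2))
  for (k in seq_len(nrow(pd))) {
    i <- match(pd$sample_1[k], rownames(m))
    j <- match(pd$sample_2[k], rownames(m))
    expect_equal(pd$distance[k], aitchison_distance(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  # duplicated sample gives a zero distance; singleton strata warn
  m2 <- rbind(m[1, ], m[1, ], m[2, ])
  rownames(m2) <- c("x1", "x2", "y1")
  expect_warning(
    pd2 <- pairwise_distance_summary(m2, stratifier = c("a", "a", "b")),
    "singleton"
  )
  expect_equal(pd2$distance, 0)
})

test_that("qmCV from the ANOVA within-component matches pooled direct qmCV for pure noise", {
  set.seed(181)
  truth <- make_ground_truth(D = 20)
  model <- measurement_model(sigma_within = 0.05, sigma_between = 0)
  st <- simulate_hierarchy(truth, model, p = 6, n = 10)
  vd <- decompose_variance(st$abundance, st$metadata, "group")
  pooled <- sapply(split(seq_len(60), st$metadata$group), function(idx) {
    qmcv_direct(as_matrix_rows(st$abundance, idx))$qmcv_direct
  })
  expect_lt(abs(vd$qmcv_within - mean(pooled)) / mean(pooled), 0.15)
})
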