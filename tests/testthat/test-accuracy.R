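test_that("gmAFD matches hand values, is symmetric, kappa-invariant, and >= 1", {
  x <- c(0.5, 0.5)
  expect_equal(gmafd(x, x), 1)
  y <- c(0.25, 0.75)
  prof <- afd_profile(x, y)
  expect_equal(prof$afd, c(2, 1.5))
  expect_equal(prof$gmafd[1], sqrt(3))
  expect_equal(max_afd(x, y), 2)
  set.seed(71)
  for (i in 1:25) {
    D <- sample(3:9, 1)
    a <- rcomp(D); b <- rcomp(D)
    expect_equal(gmafd(a, b), gmafd(b, a))
    expect_equal(gmafd(100 * a, b), gmafd(a, b), tolerance = 1e-12)
    expect_gte(gmafd(a, b), 1)
  }
  expect_gt(gmafd(rcomp(5), rcomp(5)), 1)  # equality only at identity
  expect_error(gmafd(c(0.5, 0, 0.5), c(1, 1, 1) / 3), class = "mockval_invalid_input")
})

test_that("trueness is the gmAFD of the compositional mean; accuracy is per replicate", {
  truth <- c(a = 0.3, b = 0.3, c = 0.4)
  X <- rbind(truth, truth)
  colnames(X) <- names(truth)
  expect_equal(trueness(X, truth), 1)
  # a single measurement's accuracy equals its trueness
  one <- rbind(rcomp(3))
  colnames(one) <- names(truth)
  expect_equal(accuracy_each(one, truth)$accuracy, trueness(one, truth))
  # symmetric +/- clr perturbations cancel at the center
  d <- c(0.1, -0.05, -0.05)
  xp <- closure(truth * exp(d))
  xm <- closure(truth * exp(-d))
  pair <- rbind(xp, xm)
  colnames(pair) <- names(truth)
  expect_equal(trueness(pair, truth), 1, tolerance = 1e-9)
  expect_gt(accuracy_each(pair, truth)$accuracy[1], 1)
})

test_that("threshold evaluation reproduces the pass/fail semantics", {
  cfg <- threshold_config("dna_mock")
  expect_true(evaluate_thresholds(1.06, 1.3, cfg)$pass_gmafd)
  expect_false(evaluate_thresholds(1.24, 1.3, cfg)$pass_gmafd)
  expect_true(evaluate_thresholds(1.15, 1.5, cfg)$pass)   # at the bound passes
  cell <- threshold_config("cell_mock")
  expect_equal(c(cell$gmafd_max, cell$maxafd_max), c(1.55, 3.1))
  expect_error(threshold_config("custom"), class = "mockval_configuration_error")
  expect_error(
    threshold_config("custom", gmafd_max = 2, maxafd_max = 1.5),
    class = "mockval_configuration_error"
  )
})

test_that("GC-bias slope recovers noiseless log-linear bias and reporting transform", {
  gc <- c(40, 50, 60)
  x <- closure(2^(-0.02 * gc))
  fit <- gc_bias_slope(x, gc)
  expect_equal(fit$slope, -0.02, tolerance = 1e-12)
  expect_equal(fit$fold_per_10pct, 2^(-0.2), tolerance = 1e-12)
  expect_equal(fit$n_pairs, 3)
  expect_equal(gc_bias_slope(rep(1 / 3, 3), gc)$slope, 0)
  # fold_per_10pct = 1.14 corresponds to slope log2(1.14)/10
  s <- log2(1.14) / 10
  y <- closure(2^(s * gc))
  expect_equal(gc_bias_slope(y, gc)$fold_per_10pct, 1.14, tolerance = 1e-9)
  # ordered pairs are redundant: slope from the (j,i) duplicates is identical
  set.seed(81)
  ab <- rcomp(6)
  gcp <- runif(6, 30, 65)
  pr <- combn(6, 2)
  r <- log2(ab[pr[1, ]] / ab[pr[2, ]]); d <- gcp[pr[1, ]] - gcp[pr[2, ]]
  full <- sum(c(r, -r) * c(d, -d)) / sum(c(d, -d)^2)
  expect_equal(gc_bias_slope(ab, gcp)$slope, full, tolerance = 1e-12)
  expect_error(gc_bias_slope(ab, rep(50, 6)), class = "mockval_degenerate_design")
})

test_that("GC-bias slope is unbiased under symmetric taxon noise", {
  set.seed(91)
  truth <- make_ground_truth(D = 10)
  est <- replicate(200, {
    m <- simulate_measurement(truth, measurement_model(gc_slope = -0.02, sigma_within = 0.1))
    gc_bias_slope(m, truth$gc_percent)$slope
  })
  expect_lt(abs(mean(est) - (-0.02)), 3 * sd(est) / sqrt(200) + 1e-4)
})

test_that("fragmentation bias is a per-position Aitchison distance averaged over cycles", {
  bf <- simulate_base_frequencies(15, perturbation_sd = 0, seed = 1)
  expect_equal(fragmentation_bias(bf$observed, bf$expected)$bias, 0)
  # single position against a uniform expectation, brute force via clr
  obs <- tibble::tibble(position = 1, A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  fb <- fragmentation_bias(obs, rep(0.25, 4), cycles = 1)
  expect_equal(fb$bias, oracle_dA_pairwise(c(0.3, 0.2, 0.2, 0.3), rep(0.25, 4)), tolerance = 1e-9)
  # doubling the clr perturbation doubles the distance
  base <- c(0.3, 0.2, 0.2, 0.3)
  z <- log(base) - mean(log(base))
  obs2 <- closure(exp(2 * z + log(0.25)))
  fb2 <- fragmentation_bias(
    tibble::tibble(position = 1, A = obs2[1], C = obs2[2], G = obs2[3], T = obs2[4]),
    rep(0.25, 4),
    cycles = 1
  )
  expect_equal(fb2$bias, 2 * fb$bias, tolerance = 1e-9)
  expect_error(fragmentation_bias(obs, rep(0.25, 4), cycles = 1:5), class = "mockval_invalid_input")
})

test_that("larger positional perturbations give larger expected fragmentation bias", {
  set.seed(101)
  small <- replicate(50, {
    bf <- simulate_base_frequencies(5, perturbation_sd = 0.05)
    fragmentation_bias(bf$observed, bf$expected, cycles = 1:5)$bias
  })
  large <- replicate(50, {
    bf <- simulate_base_frequencies(5, perturbation_sd = 0.2)
    fragmentation_bias(bf$observed, bf$expected, cycles = 1:5)$bias
  })
  expect_gt(mean(large), mean(small))
})

test_that("abundance union filter keeps taxa passing in either profile and re-closes", {
  a <- setNames(c(60, 39.94, 0.06), c("x", "y", "z"))
  b <- setNames(c(50, 49.999, 0.001), c("x", "y", "z"))
  out <- abundance_filter_union(a, b)
  expect_true("z" %in% out$taxon)  # kept by the union rule (0.06 in a)
  expect_equal(sum(out$a), 100)
  expect_equal(sum(out$b), 100)
  a2 <- setNames(c(60, 39.999, 0.001), c("x", "y", "z"))
  b2 <- setNames(c(50, 49.999, 0.001), c("x", "y", "z"))
  expect_false("z" %in% abundance_filter_union(a2, b2)$taxon)
  expect_error(
    abundance_filter_union(setNames(c(0.01, 0.01), c("x", "y")),
      setNames(c(0.01, 0.01), c("x", "y"))
    ),
    class = "mockval_empty_result"
  )
})

test_that("assess_accuracy ties the pieces together", {
  truth <- make_ground_truth(D = 8)
  set.seed(111)
  st <- simulate_hierarchy(truth, measurement_model(sigma_within = 0.05), p = 2, n = 3)
  rep_ <- assess_accuracy(st$abundance, truth)
  expect_s3_class(rep_, "accuracy_report")
  expect_gte(rep_$max_afd, rep_$trueness)
  expect_true(all(tidy(rep_)$afd >= 1))
  g <- glance(rep_)
  expect_true(is.logical(g$pass))
  expect_equal(nrow(rep_$per_replicate), 6)
})
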