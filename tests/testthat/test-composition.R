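test_that("closure forces proportions and rejects degenerate input", {
  expect_equal(closure(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_equal(closure(c(0.25, 0.25, 0.5), kappa = 100), c(25, 25, 50))
  expect_equal(closure(closure(c(3, 2, 5))), closure(c(3, 2, 5)))
  expect_error(closure(c(3, 0, 1)), class = "mockval_invalid_input")
  expect_error(closure(c(3, -1, 1)), class = "mockval_invalid_input")
  expect_error(closure(c(5)), class = "mockval_invalid_input")
})

test_that("clr sums to zero, is kappa-invariant, and matches hand values", {
  expect_equal(clr(c(1, 1, 1) / 3), c(0, 0, 0))
  e <- exp(1)
  expect_equal(clr(c(e / (1 + e), 1 / (1 + e))), c(0.5, -0.5))
  set.seed(11)
  for (i in 1:20) {
    x <- rcomp(sample(3:8, 1))
    expect_equal(sum(clr(x)), 0, tolerance = 1e-9)
    expect_equal(clr(x), clr(100 * x))
  }
})

test_that("geometric center is idempotent and is the clr arithmetic mean", {
  x <- c(0.2, 0.3, 0.5)
  expect_equal(geometric_center(rbind(x, x, x)), x, ignore_attr = TRUE)
  expect_equal(
    geometric_center(rbind(c(0.4, 0.6), c(0.6, 0.4))),
    c(0.5, 0.5),
    ignore_attr = TRUE
  )
  set.seed(21)
  m <- rcomp_set(12, 5)
  expect_equal(clr(geometric_center(m)), colMeans(clr(m)), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("variation matrix has the defining entries and invariances", {
  X <- rbind(c(0.4, 0.6), c(0.6, 0.4))
  vm <- variation_matrix(X)
  expect_equal(vm[1, 2], var(c(log(0.4 / 0.6), log(0.6 / 0.4))))
  expect_equal(diag(vm), c(0, 0), ignore_attr = TRUE)
  expect_equal(vm, t(vm))
  set.seed(31)
  m <- rcomp_set(8, 4)
  m_pct <- 100 * m
  expect_equal(variation_matrix(m), variation_matrix(m_pct), tolerance = 1e-9)
  # entries are direct logratio variances
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(variation_matrix(m)[i, j], var(log(m[, i] / m[, j])), tolerance = 1e-12)
    }
  }
  expect_error(variation_matrix(m[1, , drop = FALSE]), class = "mockval_insufficient_replication")
})

test_that("metric variance matches varmat form, totvar identity, and contributions sum", {
  X <- rbind(c(0.4, 0.6), c(0.6, 0.4))
  expect_equal(metric_variance(rbind(X[1, ], X[1, ])), 0)
  expect_equal(metric_variance(X), 0.5 * var(c(log(2 / 3), log(3 / 2))))
  set.seed(41)
  m <- rcomp_set(10, 6)
  expect_equal(metric_variance(m), oracle_mvar_clrsum(m), tolerance = 1e-9)
  ctr <- mvar_contributions(m)
  expect_equal(sum(ctr$contribution), metric_variance(m), tolerance = 1e-12)
})

test_that("Aitchison distance satisfies the metric axioms and both formulas", {
  x <- rcomp(5)
  expect_equal(aitchison_distance(x, x), 0)
  e <- exp(1)
  expect_equal(
    aitchison_distance(c(0.5, 0.5), c(e / (1 + e), 1 / (1 + e))),
    sqrt(0.5)
  )
  set.seed(51)
  for (i in 1:25) {
    D <- sample(3:8, 1)
    a <- rcomp(D); b <- rcomp(D); cc <- rcomp(D)
    expect_equal(aitchison_distance(a, b), oracle_dA_pairwise(a, b), tolerance = 1e-9)
    expect_equal(aitchison_distance(a, b), aitchison_distance(b, a))
    expect_lte(
      aitchison_distance(a, cc),
      aitchison_distance(a, b) + aitchison_distance(b, cc) + 1e-12
    )
    # perturbation invariance
    p <- exp(rnorm(D))
    expect_equal(
      aitchison_distance(closure(p * a), closure(p * b)),
      aitchison_distance(a, b),
      tolerance = 1e-9
    )
    # kappa invariance
    expect_equal(aitchison_distance(100 * a, b), aitchison_distance(a, b), tolerance = 1e-12)
  }
  names(x) <- letters[1:5]
  y <- setNames(rcomp(5), letters[c(1:4, 6)])
  expect_error(aitchison_distance(x, y), class = "mockval_alignment_error")
})

test_that("align_taxa restricts to shared labels with explicit re-closure", {
  x <- setNames(c(0.2, 0.3, 0.5), c("a", "b", "c"))
  y <- setNames(c(0.1, 0.4, 0.5), c("b", "c", "d"))
  al <- align_taxa(x, y)
  expect_equal(names(al$x), c("b", "c"))
  expect_equal(sum(al$x), 1)
  expect_equal(sum(al$y), 1)
  expect_error(align_taxa(x, setNames(0.5, "z")), class = "mockval_alignment_error")
})

test_that("replace_zeros floors zeros, re-closes rows, and leaves clean rows alone", {
  tab <- tibble::tibble(sample_id = c("s1", "s2"), a = c(99.999, 50), b = c(0, 30), c = c(0.001, 20))
  out <- replace_zeros(tab)
  m <- as.matrix(out[-1])
  expect_true(all(m > 0))
  expect_equal(rowSums(m), c(100, 100), ignore_attr = TRUE)
  expect_equal(unlist(out[2, -1]), unlist(tab[2, -1]), tolerance = 1e-12)
  # fraction scale: floor converts to 1e-5
  fr <- matrix(c(0.5, 0.5, 0.6, 0), nrow = 2, byrow = TRUE)
  out2 <- replace_zeros(fr)
  expect_equal(min(out2[2, ]), 0.001 / 100 / (0.6 + 0.001 / 100), tolerance = 1e-9)
  expect_error(replace_zeros(rbind(c(0, 0), c(1, 1))), class = "mockval_invalid_input")
  expect_error(replace_zeros(matrix(c(-1, 2, 1, 1), 2)), class = "mockval_invalid_input")
})

test_that("compositional PCA round-trips training scores and centers the truth", {
  set.seed(61)
  m <- rcomp_set(10, 6)
  rownames(m) <- paste0("s", 1:10)
  fit <- compositional_pca(m)
  expect_equal(sum(fit$var_explained), 1, tolerance = 1e-9)
  proj <- predict(fit, m)
  expect_equal(
    as.matrix(proj[-1]), as.matrix(fit$scores[-1]),
    ignore_attr = TRUE, tolerance = 1e-9
  )
  ctr <- geometric_center(m)
  names(ctr) <- colnames(m)
  sc <- predict(fit, matrix(ctr, nrow = 1, dimnames = list("c", names(ctr))))
  expect_equal(unname(unlist(sc[-1])), rep(0, 6), tolerance = 1e-9)
  # identical samples give zero scores
  flat <- compositional_pca(rbind(m[1, ], m[1, ], m[1, ]))
  expect_equal(max(abs(as.matrix(flat$scores[-1]))), 0, tolerance = 1e-9)
  expect_error(compositional_pca(m[1, , drop = FALSE]), class = "mockval_insufficient_replication")
})

test_that("scale detection distinguishes percent from fraction and rejects neither", {
  expect_equal(detect_scale(rcomp_set(3, 4, kappa = 100)), 100)
  expect_equal(detect_scale(rcomp_set(3, 4, kappa = 1)), 1)
  expect_error(detect_scale(matrix(c(5, 6, 7, 8), 2)), class = "mockval_invalid_input")
})
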