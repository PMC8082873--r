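# Shared fixture generators and independent brute-force oracles. Oracles
# are written from the defining formulas, not via the package's own code
# paths.

# one random composition (strictly positive, closed to kappa)
rcomp <- function(D, kappa = 1) {
  closure(exp(rnorm(D, 0, 1)), kappa = kappa)
}

# n random compositions over D taxa as a matrix
rcomp_set <- function(n, D, kappa = 1) {
  m <- t(replicate(n, rcomp(D, kappa)))
  colnames(m) <- paste0("t", seq_len(D))
  m
}

# Aitchison distance via the pairwise-logratio formula with the 1/(2D)
# factor (independent of the clr-Euclidean route used by the package)
oracle_dA_pairwise <- function(x, y) {
  D <- length(x)
  s <- 0
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      s <- s + (log(x[i] / x[j]) - log(y[i] / y[j]))^2
    }
  }
  sqrt(s / (2 * D))
}

# metric variance as the sum of clr-coordinate variances (totvar identity)
oracle_mvar_clrsum <- function(m) {
  lm_ <- log(m)
  z <- lm_ - rowMeans(lm_)
  sum(apply(z, 2, var))
}

# numeric matrix from selected rows of a wide abundance tibble
as_matrix_rows <- function(tab, idx) {
  as.matrix(tab[idx, -1, drop = FALSE])
}

# total sum of squares about the grand compositional center, computed
# sample by sample from squared Aitchison distances
oracle_total_ss <- function(m) {
  ctr <- exp(colMeans(log(m)))
  ctr <- ctr / sum(ctr)
  sum(apply(m, 1, function(r) oracle_dA_pairwise(r / sum(r), ctr)^2))
}
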