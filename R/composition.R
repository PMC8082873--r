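# Aitchison-geometry primitives. A composition is a named (or unnamed)
# numeric vector of strictly positive relative abundances summing to a
# closure constant kappa (1 for fractions, 100 for percent). Sets of
# compositions are handled as numeric matrices (samples in rows) or as
# wide data frames whose first column is `sample_id`.

#' Close a vector of abundances to a constant sum
#'
#' Rescales a vector of non-negative abundances so its elements sum to the
#' closure constant `kappa` (1 for fractions, 100 for percent). Closure is
#' the basic operation of compositional data analysis: only the relative
#' information in the vector is meaningful, and closure fixes the
#' representation.
#'
#' @param x Numeric vector of abundances, length >= 2, all > 0.
#' @param kappa Closure constant; the output sums to this value. Default 1.
#' @return Numeric vector proportional to `x`, summing to `kappa`.
#' @examples
#' closure(c(1, 1, 2))
#' closure(c(0.25, 0.25, 0.5), kappa = 100)
#' @export
closure <- function(x, kappa = 1) {
  if (!is.numeric(x) || length(x) < 2) {
    stop_invalid("`x` must be a numeric vector with at least 2 elements.")
  }
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) {
    stop_invalid("`kappa` must be a single positive number.")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_invalid("`x` must be finite and non-missing.")
  }
  if (any(x < 0)) {
    stop_invalid("`x` contains negative abundances.")
  }
  if (any(x == 0)) {
    stop_invalid(
      "`x` contains zero abundances; replace them first (see `replace_zeros()`)."
    )
  }
  kappa * x / sum(x)
}

#' Centred log-ratio (clr) transform
#'
#' Maps a composition to real space by taking the log of each part relative
#' to the geometric mean of all parts. The clr vector sums to zero and is
#' invariant to the closure constant, so compositions on the percent and
#' fraction scales transform identically.
#'
#' @param x Strictly positive numeric vector, or a matrix / wide abundance
#'   data frame of such rows.
#' @return A numeric vector (or matrix) of the same shape with zero row sums.
#' @examples
#' clr(c(1, 1, 1))
#' clr(c(0.4, 0.6))
#' @export
clr <- function(x) {
  if (is.data.frame(x) || is.matrix(x)) {
    m <- as_abundance_matrix(x)
    if (any(m <= 0)) stop_invalid("clr requires strictly positive abundances.")
    lm_ <- log(m)
    sweep(lm_, 1, rowMeans(lm_))
  } else {
    if (!is.numeric(x) || length(x) < 2) {
      stop_invalid("`x` must be numeric with at least 2 parts.")
    }
    if (any(x <= 0)) stop_invalid("clr requires strictly positive abundances.")
    lx <- log(x)
    lx - mean(lx)
  }
}

#' Compositional mean (closed geometric mean) of a set of compositions
#'
#' The centre of a compositional data set: the per-taxon geometric mean
#' across samples, re-closed to `kappa`. Equivalent to the inverse clr of
#' the arithmetic mean of the clr-transformed samples.
#'
#' @param data Matrix or wide data frame (first column `sample_id`) of
#'   strictly positive abundances, samples in rows.
#' @param kappa Closure constant of the returned composition. Default 1.
#' @return Named numeric vector: one entry per taxon, summing to `kappa`.
#' @examples
#' geometric_center(rbind(c(0.4, 0.6), c(0.6, 0.4)))
#' @export
geometric_center <- function(data, kappa = 1) {
  m <- as_abundance_matrix(data)
  if (any(m <= 0)) stop_invalid("geometric_center requires strictly positive abundances.")
  closure(exp(colMeans(log(m))), kappa = kappa)
}

#' Variation matrix of a compositional data set
#'
#' The D x D matrix whose (i, j) entry is the sample variance, across
#' samples, of the log-ratio log(x_i / x_j). The diagonal is zero and the
#' matrix is symmetric; it is invariant to per-sample closure.
#'
#' @inheritParams geometric_center
#' @return D x D symmetric numeric matrix with zero diagonal, dimnames set
#'   to the taxon labels.
#' @export
variation_matrix <- function(data) {
  m <- as_abundance_matrix(data)
  if (nrow(m) < 2) {
    stop_replication("variation_matrix needs at least 2 compositions.")
  }
  if (any(m <= 0)) stop_invalid("variation_matrix requires strictly positive abundances.")
  cl <- cov(log(m))  # var(log xi - log xj) = Cii + Cjj - 2 Cij
  v <- diag(cl)
  vm <- outer(v, rep(1, length(v))) + outer(rep(1, length(v)), v) - 2 * cl
  vm[abs(vm) < .Machine$double.eps * 100] <- pmax(
    vm[abs(vm) < .Machine$double.eps * 100], 0
  )
  diag(vm) <- 0
  dimnames(vm) <- list(colnames(m), colnames(m))
  vm
}

#' Metric (total) variance of a compositional data set
#'
#' Total compositional dispersion: 1/(2D) times the sum of all entries of
#' the variation matrix, equal to the sum over taxa of the variances of the
#' clr coordinates.
#'
#' @inheritParams geometric_center
#' @return A single non-negative number.
#' @seealso [mvar_contributions()] for the per-pair breakdown.
#' @export
metric_variance <- function(data) {
  vm <- variation_matrix(data)
  sum(vm) / (2 * ncol(vm))
}

#' Per-pair contributions to the metric variance
#'
#' Each unordered taxon pair (i, j) contributes its log-ratio variance
#' divided by D to the metric variance; the contributions sum to
#' [metric_variance()]. Useful for attributing dispersion to taxon pairs,
#' e.g. pairs with large GC-content differences.
#'
#' @inheritParams geometric_center
#' @return A tibble with columns `taxon_i`, `taxon_j`, `logratio_variance`
#'   and `contribution`, one row per unordered pair.
#' @export
mvar_contributions <- function(data) {
  vm <- variation_matrix(data)
  d <- ncol(vm)
  idx <- which(upper.tri(vm), arr.ind = TRUE)
  tibble::tibble(
    taxon_i = colnames(vm)[idx[, 1]],
    taxon_j = colnames(vm)[idx[, 2]],
    logratio_variance = vm[idx],
    contribution = vm[idx] / d
  )
}

#' Aitchison distance between two compositions
#'
#' The Euclidean distance between the clr transforms of two compositions;
#' equivalently the square root of 1/(2D) times the sum of squared
#' differences of all pairwise log-ratios. It is a true metric on the
#' simplex, invariant to closure and to perturbation.
#'
#' @param x,y Strictly positive numeric vectors over the same taxa, in the
#'   same order. If both are named the names must match.
#' @return A single non-negative number.
#' @examples
#' aitchison_distance(c(0.4, 0.6), c(0.4, 0.6))
#' aitchison_distance(c(0.5, 0.5), c(0.25, 0.75))
#' @export
aitchison_distance <- function(x, y) {
  check_aligned(x, y)
  sqrt(sum((clr(x) - clr(y))^2))
}

check_aligned <- function(x, y) {
  if (length(x) != length(y)) {
    stop_alignment("Compositions have different numbers of parts.")
  }
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y))) {
    stop_alignment(
      "Taxon labels differ or are ordered differently; align explicitly (see `align_taxa()`)."
    )
  }
  invisible(TRUE)
}

#' Align two named abundance vectors on their shared taxa
#'
#' Restricts both vectors to the intersection of their taxon labels (in the
#' order of `x`) and re-closes each to `kappa`. Alignment is always explicit:
#' distance and fold-difference functions refuse mismatched labels rather
#' than aligning silently.
#'
#' @param x,y Named numeric vectors of abundances.
#' @param kappa Closure constant applied to both outputs. Default 1.
#' @return A list with elements `x` and `y`, aligned and re-closed.
#' @export
align_taxa <- function(x, y, kappa = 1) {
  if (is.null(names(x)) || is.null(names(y))) {
    stop_alignment("Both vectors must be named to align them.")
  }
  shared <- intersect(names(x), names(y))
  if (length(shared) < 2) {
    stop_alignment("Fewer than 2 shared taxa; cannot align.")
  }
  list(x = closure(x[shared], kappa), y = closure(y[shared], kappa))
}

# Coerce a matrix or wide data frame into a numeric matrix of abundances
# (samples in rows). A leading non-numeric column is treated as sample_id
# and becomes rownames.
as_abundance_matrix <- function(data) {
  if (is.matrix(data)) {
    if (!is.numeric(data)) stop_invalid("Abundance matrix must be numeric.")
    return(data)
  }
  if (is.data.frame(data)) {
    df <- data
    rn <- NULL
    if (ncol(df) >= 1 && !is.numeric(df[[1]])) {
      rn <- as.character(df[[1]])
      df <- df[-1]
    }
    if (!all(vapply(df, is.numeric, logical(1)))) {
      stop_invalid("All abundance columns must be numeric.")
    }
    m <- as.matrix(df)
    if (!is.null(rn)) rownames(m) <- rn
    return(m)
  }
  if (is.numeric(data)) return(matrix(data, nrow = 1, dimnames = list(NULL, names(data))))
  stop_invalid("`data` must be a matrix, data frame, or numeric vector.")
}
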