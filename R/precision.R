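# Precision metrics (qmCV) and the distance-based one-way random-effects
# ANOVA used for intermediate precision and interlaboratory
# reproducibility. Sums of squares are squared Aitchison distances to
# group and grand compositional means; because the clr transform maps the
# compositional mean to the arithmetic clr mean, the usual Euclidean ANOVA
# identities hold exactly.

#' Quadratic mean of taxon-wise coefficients of variation (qmCV)
#'
#' Precision of replicated compositional measurements summarised as the
#' root-mean-square of the per-taxon coefficients of variation of relative
#' abundance, reported in percent. For sufficiently small dispersion, qmCV
#' is proportional to the square root of the metric variance with constant
#' `1/sqrt(D)` (see [qmcv_from_mvar()]); both routes are reported when the
#' data permit.
#'
#' @param data Wide abundance table or matrix of replicated measurements
#'   (at least 2 rows). Zeros are allowed for the direct CV route; the
#'   metric-variance route requires zero-free data and is `NA` otherwise.
#' @return An object of class `precision_report` with `qmcv_direct` and
#'   `qmcv_from_mvar` (percent), the per-taxon CVs, the metric variance and
#'   the replicate count.
#' @examples
#' qmcv_direct(rbind(c(0.4, 0.6), c(0.6, 0.4)))
#' @export
qmcv_direct <- function(data) {
  m <- as_abundance_matrix(data)
  if (nrow(m) < 2) stop_replication("qmCV needs at least 2 replicates.")
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  qm <- 100 * sqrt(mean(cv^2, na.rm = TRUE))
  mv <- if (all(m > 0)) metric_variance(m) else NA_real_
  structure(
    list(
      qmcv_direct = qm,
      qmcv_from_mvar = if (is.na(mv)) NA_real_ else qmcv_from_mvar(mv, ncol(m)),
      per_taxon_cv = tibble::tibble(
        taxon = colnames(m) %||% paste0("taxon_", seq_len(ncol(m))),
        mean = unname(mu),
        sd = unname(s),
        cv = unname(cv)
      ),
      mvar = mv,
      n = nrow(m)
    ),
    class = "precision_report"
  )
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf(
    "Precision over %d replicates: qmCV = %.3f%% (direct), %.3f%% (from metric variance)\n",
    x$n, x$qmcv_direct, x$qmcv_from_mvar
  ))
  invisible(x)
}

#' @exportS3Method
tidy.precision_report <- function(x, ...) x$per_taxon_cv

#' @exportS3Method
glance.precision_report <- function(x, ...) {
  tibble::tibble(
    qmcv_direct = x$qmcv_direct,
    qmcv_from_mvar = x$qmcv_from_mvar,
    mvar = x$mvar,
    n = x$n
  )
}

#' Convert a metric variance to an approximate qmCV
#'
#' For small dispersion the qmCV (percent) is approximately
#' `100 * sqrt(mvar / D)`, where D is the number of taxa in the analysed
#' table. This is the conversion used to express distance-based ANOVA
#' variance components as qmCVs.
#'
#' @param mvar Metric variance (>= 0).
#' @param D Number of taxa (>= 2).
#' @return qmCV in percent.
#' @examples
#' qmcv_from_mvar(0.0016, 16)  # 1%
#' @export
qmcv_from_mvar <- function(mvar, D) {
  if (mvar < 0) stop_invalid("`mvar` must be non-negative.")
  if (D < 2) stop_invalid("`D` must be at least 2.")
  100 * sqrt(mvar / D)
}

#' Distance-based one-way random-effects ANOVA of compositions
#'
#' Decomposes the dispersion of replicated compositional measurements into
#' between-group and within-group components, using squared Aitchison
#' distances to group and grand compositional means:
#' `TSS_b = n * sum_i d_A^2(cen(X_i), cen(X))` and
#' `TSS_w = sum_ij d_A^2(x_ij, cen(X_i))`. Mean squares follow standard
#' one-way random-effects ANOVA: the within component is `MS_w` and the
#' between component `(MS_b - MS_w) / n`, truncated at zero (flagged) when
#' the raw estimate is negative. Components are metric variances and are
#' also converted to approximate qmCVs via [qmcv_from_mvar()]. One-sided
#' 95% upper confidence bounds are attached via
#' [upper_confidence_bound()].
#'
#' @param data Wide abundance table (first column `sample_id`) or matrix of
#'   strictly positive abundances.
#' @param metadata Data frame with `sample_id` and the grouping column, or
#'   `NULL` if `group` is a vector.
#' @param group Name of the grouping column in `metadata`, or a vector of
#'   group labels, one per sample.
#' @param unbalanced How to handle unequal group sizes: `"error"` (default;
#'   the supported designs are balanced) or `"harmonic"` (substitute the
#'   harmonic mean of group sizes for n).
#' @param conf_level One-sided confidence level for the upper bounds.
#'   Default 0.95.
#' @return An object of class `variance_decomposition`.
#' @export
decompose_variance <- function(data, metadata = NULL, group = "group",
                               unbalanced = c("error", "harmonic"),
                               conf_level = 0.95) {
  unbalanced <- match.arg(unbalanced)
  m <- as_abundance_matrix(data)
  if (any(m <= 0)) stop_invalid("Distance-based ANOVA requires zero-free data; see `replace_zeros()`.")
  g <- resolve_groups(data, metadata, group, nrow(m))
  p <- length(unique(g))
  if (p < 2) stop_invalid("At least 2 groups are required.")
  sizes <- table(g)
  if (any(sizes < 2)) stop_replication("Every group needs at least 2 replicates.")
  balanced <- length(unique(sizes)) == 1
  if (!balanced && unbalanced == "error") {
    stop_invalid("Unbalanced design; set unbalanced = \"harmonic\" to proceed.")
  }
  n_eff <- if (balanced) unname(sizes[1]) else 1 / mean(1 / as.numeric(sizes))

  z <- clr(m)                       # Aitchison geometry == Euclidean on clr
  grand <- colMeans(z)              # clr of the closed geometric mean of all samples
  groups <- split(seq_len(nrow(m)), g)
  tss_b <- 0
  tss_w <- 0
  for (idx in groups) {
    zc <- colMeans(z[idx, , drop = FALSE])
    tss_b <- tss_b + length(idx) * sum((zc - grand)^2)
    tss_w <- tss_w + sum(sweep(z[idx, , drop = FALSE], 2, zc)^2)
  }
  df_b <- p - 1
  df_w <- nrow(m) - p
  ms_b <- tss_b / df_b
  ms_w <- tss_w / df_w
  raw_between <- (ms_b - ms_w) / n_eff
  truncated <- raw_between < 0
  var_between <- max(0, raw_between)
  var_within <- ms_w
  var_total <- var_within + var_between
  D <- ncol(m)

  out <- structure(
    list(
      p = p, n = n_eff, D = D, balanced = balanced,
      tss_between = tss_b, tss_within = tss_w,
      df_between = df_b, df_within = df_w,
      ms_between = ms_b, ms_within = ms_w,
      var_within = var_within, var_between = var_between,
      var_between_raw = raw_between, var_total = var_total,
      truncated = truncated,
      qmcv_within = qmcv_from_mvar(var_within, D),
      qmcv_between = qmcv_from_mvar(var_between, D),
      qmcv_total = qmcv_from_mvar(var_total, D),
      conf_level = conf_level
    ),
    class = "variance_decomposition"
  )
  cb <- upper_confidence_bound(out, level = conf_level)
  out$upper_cb_within <- cb$qmcv_upper[cb$component == "within"]
  out$upper_cb_total <- cb$qmcv_upper[cb$component == "total"]
  out
}

resolve_groups <- function(data, metadata, group, n_samples) {
  if (is.null(metadata)) {
    if (length(group) == n_samples) return(as.character(group))
    stop_invalid("Without `metadata`, `group` must be a vector with one label per sample.")
  }
  if (!is.data.frame(metadata) || !"sample_id" %in% names(metadata)) {
    stop_invalid("`metadata` must be a data frame with a `sample_id` column.")
  }
  if (!group %in% names(metadata)) {
    stop_invalid(paste0("Column `", group, "` not found in metadata."))
  }
  ids <- if (is.data.frame(data) && !is.numeric(data[[1]])) {
    as.character(data[[1]])
  } else {
    rownames(as_abundance_matrix(data))
  }
  if (is.null(ids)) stop_invalid("Samples must carry ids to join metadata.")
  pos <- match(ids, metadata$sample_id)
  if (anyNA(pos)) stop_alignment("Some samples are missing from the metadata.")
  as.character(metadata[[group]][pos])
}

#' One-sided upper confidence bounds for ANOVA variance components
#'
#' The within-group component gets an exact chi-square bound on its
#' `p(n-1)` degrees of freedom; the total component
#' `(MS_b + (n-1) MS_w) / n` gets a chi-square bound on
#' Satterthwaite-approximated degrees of freedom. Bounds are reported both
#' as metric variances and as qmCVs (percent). With `level = 0.5` and
#' large degrees of freedom the bound approaches the point estimate.
#'
#' @param decomp A [decompose_variance()] result.
#' @param level One-sided confidence level, default 0.95.
#' @return A tibble with one row per component (`within`, `total`):
#'   estimate, upper bound, degrees of freedom, and the same on the qmCV
#'   scale.
#' @export
upper_confidence_bound <- function(decomp, level = 0.95) {
  stopifnot(inherits(decomp, "variance_decomposition"))
  if (decomp$df_within <= 0 || decomp$df_between <= 0) {
    stop_invalid("Non-positive degrees of freedom.")
  }
  alpha <- 1 - level
  ub_within <- decomp$df_within * decomp$ms_within / qchisq(alpha, decomp$df_within)
  # total = (MS_b + (n-1) MS_w) / n; Satterthwaite df for the combination
  n <- decomp$n
  c1 <- 1 / n
  c2 <- (n - 1) / n
  est_total <- c1 * decomp$ms_between + c2 * decomp$ms_within
  if (est_total > 0) {
    df_total <- est_total^2 /
      ((c1 * decomp$ms_between)^2 / decomp$df_between +
        (c2 * decomp$ms_within)^2 / decomp$df_within)
    ub_total <- df_total * est_total / qchisq(alpha, df_total)
  } else {
    # degenerate data with no dispersion at all: bound collapses to zero
    df_total <- NA_real_
    ub_total <- 0
  }
  tibble::tibble(
    component = c("within", "total"),
    estimate = c(decomp$ms_within, est_total),
    df = c(decomp$df_within, df_total),
    upper = c(ub_within, ub_total),
    qmcv_estimate = qmcv_from_mvar_vec(c(decomp$ms_within, est_total), decomp$D),
    qmcv_upper = qmcv_from_mvar_vec(c(ub_within, ub_total), decomp$D)
  )
}

qmcv_from_mvar_vec <- function(v, D) vapply(v, qmcv_from_mvar, numeric(1), D = D)

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(
    "Distance-based one-way random-effects ANOVA (p = %d groups, n = %s replicates, D = %d taxa)\n",
    x$p, format(x$n, digits = 4), x$D
  ))
  cat(sprintf("  TSS between = %.5f (df %d), TSS within = %.5f (df %d)\n",
    x$tss_between, x$df_between, x$tss_within, x$df_within))
  cat(sprintf(
    "  components: within %.6f, between %.6f%s, total %.6f\n",
    x$var_within, x$var_between, ifelse(x$truncated, " (truncated at 0)", ""),
    x$var_total
  ))
  cat(sprintf(
    "  qmCV: within %.3f%% (95%% UCB %.3f%%), between %.3f%%, total %.3f%% (95%% UCB %.3f%%)\n",
    x$qmcv_within, x$upper_cb_within, x$qmcv_between, x$qmcv_total, x$upper_cb_total
  ))
  invisible(x)
}

#' @exportS3Method
tidy.variance_decomposition <- function(x, ...) {
  tibble::tibble(
    component = c("within", "between", "total"),
    variance = c(x$var_within, x$var_between, x$var_total),
    qmcv = c(x$qmcv_within, x$qmcv_between, x$qmcv_total),
    qmcv_upper_95 = c(x$upper_cb_within, NA_real_, x$upper_cb_total),
    truncated = c(FALSE, x$truncated, FALSE)
  )
}

#' @exportS3Method
glance.variance_decomposition <- function(x, ...) {
  tibble::tibble(
    p = x$p, n = x$n, D = x$D,
    tss_between = x$tss_between, tss_within = x$tss_within,
    ms_between = x$ms_between, ms_within = x$ms_within,
    var_within = x$var_within, var_between = x$var_between,
    var_total = x$var_total, truncated = x$truncated,
    qmcv_within = x$qmcv_within, qmcv_between = x$qmcv_between,
    qmcv_total = x$qmcv_total
  )
}

#' All within-stratum pairwise Aitchison distances
#'
#' Enumerates the Aitchison distances between every pair of samples that
#' share a stratum (e.g. a laboratory or an operator-lot combination), the
#' raw material behind violin plots of replicate agreement.
#'
#' @inheritParams decompose_variance
#' @param stratifier Name of the stratifying column in `metadata`, or a
#'   vector of stratum labels.
#' @return A tibble with columns `stratum`, `sample_1`, `sample_2`,
#'   `distance`. Strata with a single sample are skipped with a warning.
#' @export
pairwise_distance_summary <- function(data, metadata = NULL, stratifier = "group") {
  m <- as_abundance_matrix(data)
  if (any(m <= 0)) stop_invalid("Pairwise Aitchison distances require zero-free data.")
  g <- resolve_groups(data, metadata, stratifier, nrow(m))
  ids <- rownames(m) %||% paste0("sample_", seq_len(nrow(m)))
  z <- clr(m)
  res <- purrr::map(split(seq_len(nrow(m)), g), function(idx) {
    if (length(idx) < 2) return(NULL)
    pr <- combn(idx, 2)
    tibble::tibble(
      sample_1 = ids[pr[1, ]],
      sample_2 = ids[pr[2, ]],
      distance = apply(pr, 2, function(ij) sqrt(sum((z[ij[1], ] - z[ij[2], ])^2)))
    )
  })
  singletons <- names(res)[vapply(res, is.null, logical(1))]
  if (length(singletons) > 0) {
    warning("Skipping singleton strata: ", paste(singletons, collapse = ", "))
  }
  dplyr::bind_rows(res, .id = "stratum")
}

#' Violin plot of within-stratum pairwise Aitchison distances
#'
#' @param data A tibble as produced by [pairwise_distance_summary()].
#' @return A ggplot object.
#' @export
plot_distance_distributions <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(.data$stratum, .data$distance)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "Pairwise Aitchison distance") +
    ggplot2::theme_minimal()
}
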