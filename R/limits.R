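# Limits of detection and quantification. The LOD comes from a binomial
# regression of species-wise probabilities of detection (POD) on log mean
# relative abundance with a complementary log-log link; the LOQ from a
# negative-exponential fit of species-wise CVs to mean abundance with the
# mean CV of the most abundant species imposed as a lower plateau.

#' Per-taxon detection and variability summaries over replicate sets
#'
#' For each taxon within each replicate set: the mean relative abundance
#' (zeros included), the number of replicates in which the taxon was
#' observed (abundance strictly positive), the replicate count, and the
#' coefficient of variation across replicates. CVs are not capped; a taxon
#' undetected in some replicates has an inflated CV, which is exactly the
#' signal the LOQ regression uses.
#'
#' @param data Wide abundance table (first column `sample_id`) or matrix;
#'   zeros allowed.
#' @param metadata Optional data frame with `sample_id` and the replicate
#'   set column; `NULL` treats all samples as one replicate set.
#' @param replicate_set Name of the replicate-set column in `metadata`, or
#'   a vector of set labels per sample. Ignored when `metadata` is `NULL`
#'   and left at its default.
#' @return A tibble with columns `replicate_set`, `taxon`,
#'   `mean_abundance`, `detected`, `total`, `pod`, `cv` (NA when the mean
#'   is zero).
#' @export
summarize_detection <- function(data, metadata = NULL, replicate_set = NULL) {
  m <- as_abundance_matrix(data)
  if (any(m < 0)) stop_invalid("Abundances must be non-negative.")
  g <- if (is.null(metadata) && is.null(replicate_set)) {
    rep("all", nrow(m))
  } else {
    resolve_groups(data, metadata, replicate_set %||% "replicate_set", nrow(m))
  }
  sets <- split(seq_len(nrow(m)), g)
  if (any(lengths(sets) < 2)) stop_replication("Each replicate set needs at least 2 members.")
  taxa <- colnames(m) %||% paste0("taxon_", seq_len(ncol(m)))
  purrr::map_dfr(names(sets), function(s) {
    sub <- m[sets[[s]], , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, sd)
    tibble::tibble(
      replicate_set = s,
      taxon = taxa,
      mean_abundance = unname(mu),
      detected = unname(colSums(sub > 0)),
      total = nrow(sub),
      pod = unname(colSums(sub > 0)) / nrow(sub),
      cv = unname(ifelse(mu > 0, sdv / mu, NA_real_))
    )
  })
}

cloglog <- function(p) log(-log(1 - p))

#' Fit the limit of detection (LOD) from probabilities of detection
#'
#' Binomial regression of per-taxon detection outcomes on the log of the
#' mean relative abundance, with a complementary log-log link:
#' `cloglog(POD) = b0 + b1 * log(mean_abundance)`. The LOD is the abundance
#' at which the fitted POD reaches `pod_threshold` (0.95 by default):
#' `LOD = exp((cloglog(pod_threshold) - b0) / b1)`. The fit requires both
#' detected and undetected outcomes and a positive slope (detection must
#' improve with abundance).
#'
#' @param summaries A tibble from [summarize_detection()] (columns
#'   `mean_abundance`, `detected`, `total`); rows with zero mean abundance
#'   are dropped.
#' @param pod_threshold POD defining the LOD. Default 0.95.
#' @param weighted If `TRUE` (default) each taxon enters with binomial
#'   weight equal to its replicate count; if `FALSE` all taxa are weighted
#'   equally (quasibinomial fit on the observed proportions).
#' @return An object of class `lod_fit` with elements `lod`,
#'   `coefficients`, `pod_threshold`, `converged` and the underlying model.
#' @export
fit_lod <- function(summaries, pod_threshold = 0.95, weighted = TRUE) {
  need <- c("mean_abundance", "detected", "total")
  if (!all(need %in% names(summaries))) {
    stop_invalid("`summaries` must have columns mean_abundance, detected, total.")
  }
  d <- summaries[summaries$mean_abundance > 0, ]
  if (nrow(d) < 3) stop_invalid("Too few taxa with positive mean abundance.")
  if (all(d$detected == d$total) || all(d$detected == 0)) {
    abort(
      "POD shows no variation (all detected or none); the LOD is not estimable from these data.",
      class = "mockval_non_estimable"
    )
  }
  lm_ab <- log(d$mean_abundance)
  pod <- d$detected / d$total
  # taxa far above the LOD fit at POD numerically 1; that glm warning is
  # expected here, not a defect of the data
  fit <- withCallingHandlers(
    if (weighted) {
      glm(cbind(d$detected, d$total - d$detected) ~ lm_ab,
        family = binomial(link = "cloglog")
      )
    } else {
      glm(pod ~ lm_ab, family = quasibinomial(link = "cloglog"))
    },
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  b <- coef(fit)
  if (!is.finite(b[2]) || b[2] <= 0) {
    abort(
      "Fitted POD is not increasing in abundance; the LOD is not interpretable.",
      class = "mockval_monotonicity_error"
    )
  }
  lod <- exp((cloglog(pod_threshold) - b[1]) / b[2])
  structure(
    list(
      lod = unname(lod),
      coefficients = c(intercept = unname(b[1]), slope = unname(b[2])),
      pod_threshold = pod_threshold,
      weighted = weighted,
      converged = fit$converged %||% TRUE,
      n_taxa = nrow(d),
      model = fit,
      data = d
    ),
    class = "lod_fit"
  )
}

#' @export
print.lod_fit <- function(x, ...) {
  cat(sprintf(
    "LOD fit (cloglog binomial, %s): LOD = %.3g at POD %.2f; slope %.3f, intercept %.3f\n",
    ifelse(x$weighted, "weighted by replicate counts", "unweighted"),
    x$lod, x$pod_threshold, x$coefficients["slope"], x$coefficients["intercept"]
  ))
  invisible(x)
}

#' @exportS3Method
tidy.lod_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(x$coefficients)
  )
}

#' @exportS3Method
glance.lod_fit <- function(x, ...) {
  tibble::tibble(
    lod = x$lod, pod_threshold = x$pod_threshold,
    n_taxa = x$n_taxa, converged = x$converged
  )
}

#' Fit the limit of quantification (LOQ) from CV-vs-abundance data
#'
#' Fits the species-wise coefficients of variation to mean relative
#' abundance with the negative-exponential curve
#' `CV(m) = c0 + a * m^(-b)` (`a, b > 0`), where the lower plateau `c0` is
#' fixed at the mean CV of the top `top_fraction` most abundant taxa. The
#' LOQ is the abundance at which the fitted CV falls to `cv_threshold`:
#' `LOQ = (a / (cv_threshold - c0))^(1/b)`, requiring `c0 < cv_threshold`.
#'
#' Nonlinear least squares starts from `b = 0.5` with `a` set from the
#' median scaled excess CV above the plateau; ties in abundance when
#' selecting plateau taxa are broken by taxon label order.
#'
#' @param summaries A tibble with columns `mean_abundance` and `cv` (and
#'   optionally `taxon`), e.g. from [summarize_detection()].
#' @param cv_threshold CV defining the LOQ, as a fraction. Default 0.40.
#' @param top_fraction Fraction of most-abundant taxa whose mean CV fixes
#'   the plateau. Default 0.10 (at least one taxon).
#' @return An object of class `loq_fit` with `loq`, `plateau`,
#'   `coefficients` (a, b), thresholds and the underlying `nls` fit.
#' @export
fit_loq <- function(summaries, cv_threshold = 0.40, top_fraction = 0.10) {
  if (!all(c("mean_abundance", "cv") %in% names(summaries))) {
    stop_invalid("`summaries` must have columns mean_abundance and cv.")
  }
  d <- summaries[is.finite(summaries$cv) & summaries$mean_abundance > 0, ]
  if (nrow(d) < 10) stop_invalid("LOQ fitting needs at least 10 taxa with computable CVs.")
  tx <- if ("taxon" %in% names(d)) d$taxon else as.character(seq_len(nrow(d)))
  ord <- order(-d$mean_abundance, tx)
  k <- max(1L, ceiling(top_fraction * nrow(d)))
  c0 <- mean(d$cv[ord[seq_len(k)]])
  if (c0 >= cv_threshold) {
    abort(
      sprintf(
        "Plateau CV (%.3f) is at or above the threshold (%.3f); the LOQ is undefined.",
        c0, cv_threshold
      ),
      class = "mockval_loq_undefined"
    )
  }
  excess <- d$cv - c0
  pos <- excess > 0
  a0 <- if (any(pos)) median(excess[pos] * d$mean_abundance[pos]^0.5) else 0.1
  a0 <- max(a0, 1e-8)
  fit <- tryCatch(
    nls(cv ~ c0 + a * mean_abundance^(-b),
      data = d, start = list(a = a0, b = 0.5),
      algorithm = "port", lower = c(a = 1e-12, b = 1e-6),
      control = list(warnOnly = FALSE)
    ),
    error = function(e) {
      abort(
        paste0("LOQ curve fit did not converge: ", conditionMessage(e)),
        class = "mockval_fit_error"
      )
    }
  )
  ab <- coef(fit)
  loq <- (ab[["a"]] / (cv_threshold - c0))^(1 / ab[["b"]])
  structure(
    list(
      loq = loq,
      plateau = c0,
      coefficients = c(a = ab[["a"]], b = ab[["b"]]),
      cv_threshold = cv_threshold,
      top_fraction = top_fraction,
      n_taxa = nrow(d),
      converged = TRUE,
      model = fit,
      data = d
    ),
    class = "loq_fit"
  )
}

#' @export
print.loq_fit <- function(x, ...) {
  cat(sprintf(
    "LOQ fit (CV = c0 + a*m^-b): LOQ = %.3g at CV %.2f; plateau %.3f, a = %.4g, b = %.3f\n",
    x$loq, x$cv_threshold, x$plateau, x$coefficients["a"], x$coefficients["b"]
  ))
  invisible(x)
}

#' @exportS3Method
tidy.loq_fit <- function(x, ...) {
  tibble::tibble(
    term = c("plateau", "a", "b"),
    estimate = c(x$plateau, unname(x$coefficients))
  )
}

#' @exportS3Method
glance.loq_fit <- function(x, ...) {
  tibble::tibble(
    loq = x$loq, plateau = x$plateau, cv_threshold = x$cv_threshold,
    n_taxa = x$n_taxa, converged = x$converged
  )
}

#' Fit both detection limits from one detection summary
#'
#' Convenience wrapper running [fit_lod()] and [fit_loq()] on the same
#' [summarize_detection()] output.
#'
#' @inheritParams fit_lod
#' @inheritParams fit_loq
#' @return A list of class `detection_limits` with elements `lod` and
#'   `loq`.
#' @export
detection_limits <- function(summaries, pod_threshold = 0.95, cv_threshold = 0.40,
                             top_fraction = 0.10, weighted = TRUE) {
  structure(
    list(
      lod = fit_lod(summaries, pod_threshold = pod_threshold, weighted = weighted),
      loq = fit_loq(summaries, cv_threshold = cv_threshold, top_fraction = top_fraction)
    ),
    class = "detection_limits"
  )
}

#' @export
print.detection_limits <- function(x, ...) {
  print(x$lod)
  print(x$loq)
  invisible(x)
}

#' @exportS3Method
glance.detection_limits <- function(x, ...) {
  tibble::tibble(
    lod = x$lod$lod, pod_threshold = x$lod$pod_threshold,
    loq = x$loq$loq, cv_threshold = x$loq$cv_threshold,
    loq_plateau = x$loq$plateau
  )
}

#' Fitted-curve plots for detection-limit fits
#'
#' @param object A `lod_fit` or `loq_fit`.
#' @param ... Unused.
#' @return A ggplot object showing the per-taxon points, the fitted curve
#'   and the threshold/limit lines.
#' @exportS3Method
autoplot.lod_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    mean_abundance = exp(seq(log(min(d$mean_abundance)), log(max(d$mean_abundance)),
      length.out = 200
    ))
  )
  b <- object$coefficients
  grid$pod <- 1 - exp(-exp(b["intercept"] + b["slope"] * log(grid$mean_abundance)))
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_abundance, .data$detected / .data$total)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$pod), colour = "red") +
    ggplot2::geom_hline(yintercept = object$pod_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$lod, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean relative abundance", y = "Probability of detection") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lod_fit
#' @exportS3Method
autoplot.loq_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    mean_abundance = exp(seq(log(min(d$mean_abundance)), log(max(d$mean_abundance)),
      length.out = 200
    ))
  )
  ab <- object$coefficients
  grid$cv <- object$plateau + ab["a"] * grid$mean_abundance^(-ab["b"])
  ggplot2::ggplot(d, ggplot2::aes(.data$mean_abundance, .data$cv)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$cv), colour = "red") +
    ggplot2::geom_hline(yintercept = object$cv_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$loq, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Mean relative abundance", y = "Coefficient of variation") +
    ggplot2::theme_minimal()
}
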