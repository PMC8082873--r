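# Closeness-of-agreement metrics against mock-community ground truth, the
# best-practice threshold check, and the two bias summaries (genomic GC
# content, fragmentation).

#' Geometric mean of taxon-wise absolute fold-differences (gmAFD)
#'
#' Agreement between two compositions summarised as the geometric mean of
#' the per-taxon absolute fold-differences `exp(|log(x_i / y_i)|)`; 1.0
#' means perfect agreement and e.g. 1.15 means measured abundances differ
#' from expectation by 15% on average (in the multiplicative sense). The
#' metric is symmetric in its arguments and invariant to the closure
#' constant of either composition.
#'
#' @param x,y Strictly positive abundance vectors over the same taxa, in
#'   the same order (names checked when present).
#' @return A single number >= 1.
#' @seealso [afd_profile()] for the per-taxon fold-differences and their
#'   maximum, [trueness()] / [accuracy_each()] for replicate sets.
#' @examples
#' gmafd(c(0.5, 0.5), c(0.25, 0.75))  # sqrt(3)
#' @export
gmafd <- function(x, y) {
  exp(mean(abs(log_ratio_parts(x, y))))
}

#' Per-taxon absolute fold-differences between two compositions
#'
#' @inheritParams gmafd
#' @return A tibble with columns `taxon`, `afd` (each >= 1), plus the
#'   summary columns repeated: `gmafd` and `max_afd`.
#' @export
afd_profile <- function(x, y) {
  lr <- abs(log_ratio_parts(x, y))
  taxa <- names(lr) %||% paste0("taxon_", seq_along(lr))
  tibble::tibble(
    taxon = taxa,
    afd = exp(lr),
    gmafd = exp(mean(lr)),
    max_afd = exp(max(lr))
  )
}

#' Maximum taxon-wise absolute fold-difference
#'
#' @inheritParams gmafd
#' @return A single number >= 1.
#' @export
max_afd <- function(x, y) {
  exp(max(abs(log_ratio_parts(x, y))))
}

log_ratio_parts <- function(x, y) {
  check_aligned(x, y)
  if (any(x <= 0) || any(y <= 0)) {
    stop_invalid("Fold-differences require zero-free compositions; see `replace_zeros()`.")
  }
  log(closure(x) / closure(y))
}

#' Trueness: agreement of the compositional mean with the ground truth
#'
#' Trueness is the gmAFD between the compositional mean (closed geometric
#' mean) of replicated measurements and the expected composition; accuracy
#' is the same quantity for an individual measurement (see
#' [accuracy_each()]).
#'
#' @param data Wide abundance table or matrix of replicated measurements,
#'   strictly positive, samples in rows.
#' @param expected Named ground-truth composition over the same taxa, or a
#'   ground-truth tibble with columns `taxon` and `expected_pct` (as read
#'   by [read_ground_truth()] or built by [make_ground_truth()]).
#' @return A single number >= 1.
#' @export
trueness <- function(data, expected) {
  expected <- as_expected_composition(expected)
  m <- as_abundance_matrix(data)
  ctr <- geometric_center(m)
  if (!is.null(colnames(m))) ctr <- setNames(ctr, colnames(m))
  gmafd(ctr, expected)
}

#' Accuracy of each individual measurement against the ground truth
#'
#' @inheritParams trueness
#' @return A tibble with columns `sample_id`, `accuracy` (gmAFD of that
#'   measurement to the ground truth) and `aitchison_distance`.
#' @export
accuracy_each <- function(data, expected) {
  expected <- as_expected_composition(expected)
  m <- as_abundance_matrix(data)
  ids <- rownames(m) %||% paste0("sample_", seq_len(nrow(m)))
  tibble::tibble(
    sample_id = ids,
    accuracy = apply(m, 1, function(r) gmafd(setNames(r, colnames(m)), expected)),
    aitchison_distance = apply(
      m, 1, function(r) aitchison_distance(setNames(r, colnames(m)), expected)
    )
  )
}

as_expected_composition <- function(expected) {
  if (is.data.frame(expected)) {
    if (!all(c("taxon", "expected_pct") %in% names(expected))) {
      stop_invalid("Ground-truth table must have columns `taxon` and `expected_pct`.")
    }
    return(setNames(expected$expected_pct, expected$taxon))
  }
  if (!is.numeric(expected)) stop_invalid("`expected` must be numeric or a ground-truth table.")
  expected
}

#' Best-practice accuracy thresholds for mock-community validation
#'
#' Bundled target values for achievable trueness/accuracy: gmAFD at most
#' 1.15 and maximum AFD at most 1.5 for a genomic-DNA mock community
#' (library-construction validation), and 1.55 / 3.1 for a whole-cell mock
#' community (DNA-extraction validation, where ground-truth assignment
#' itself carries more bias). Custom bounds can be supplied instead.
#'
#' @param material `"dna_mock"`, `"cell_mock"`, or `"custom"`.
#' @param gmafd_max,maxafd_max Numeric bounds, required when `material =
#'   "custom"`; ignored otherwise.
#' @param precision_targets Optional named list of qmCV bounds (percent) per
#'   precision level, e.g. `list(repeatability = 2)`. Not set by default.
#' @return A list of class `threshold_config`.
#' @examples
#' threshold_config("dna_mock")
#' threshold_config("custom", gmafd_max = 1.2, maxafd_max = 2)
#' @export
threshold_config <- function(material = c("dna_mock", "cell_mock", "custom"),
                             gmafd_max = NULL, maxafd_max = NULL,
                             precision_targets = NULL) {
  material <- match.arg(material)
  defaults <- list(
    dna_mock = c(gmafd_max = 1.15, maxafd_max = 1.5),
    cell_mock = c(gmafd_max = 1.55, maxafd_max = 3.1)
  )
  if (material == "custom") {
    if (is.null(gmafd_max) || is.null(maxafd_max)) {
      abort(
        "Custom thresholds require numeric `gmafd_max` and `maxafd_max`.",
        class = "mockval_configuration_error"
      )
    }
  } else {
    gmafd_max <- defaults[[material]][["gmafd_max"]]
    maxafd_max <- defaults[[material]][["maxafd_max"]]
  }
  if (gmafd_max <= 1 || maxafd_max <= 1 || gmafd_max > maxafd_max) {
    abort(
      "Thresholds must satisfy 1 < gmafd_max <= maxafd_max.",
      class = "mockval_configuration_error"
    )
  }
  structure(
    list(
      material = material,
      gmafd_max = gmafd_max,
      maxafd_max = maxafd_max,
      precision_targets = precision_targets
    ),
    class = "threshold_config"
  )
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(
    sprintf(
      "Accuracy thresholds (%s): gmAFD <= %.2f, max AFD <= %.2f\n",
      x$material, x$gmafd_max, x$maxafd_max
    )
  )
  invisible(x)
}

#' Evaluate accuracy metrics against best-practice thresholds
#'
#' Pass/fail evaluation of a gmAFD and maximum-AFD pair against a
#' [threshold_config()]. A value exactly at the bound passes (the bounds
#' are stated as achievable targets).
#'
#' @param gmafd Observed gmAFD (>= 1).
#' @param max_afd Observed maximum AFD (>= 1).
#' @param config A [threshold_config()].
#' @return A tibble with the values, bounds and logical `pass_gmafd`,
#'   `pass_maxafd`, `pass` columns.
#' @examples
#' evaluate_thresholds(1.06, 1.3, threshold_config("dna_mock"))
#' @export
evaluate_thresholds <- function(gmafd, max_afd, config = threshold_config("dna_mock")) {
  stopifnot(inherits(config, "threshold_config"))
  tibble::tibble(
    material = config$material,
    gmafd = gmafd,
    max_afd = max_afd,
    gmafd_max = config$gmafd_max,
    maxafd_max = config$maxafd_max,
    pass_gmafd = gmafd <= config$gmafd_max,
    pass_maxafd = max_afd <= config$maxafd_max,
    pass = gmafd <= config$gmafd_max & max_afd <= config$maxafd_max
  )
}

#' Full accuracy report for replicated measurements against ground truth
#'
#' Computes trueness (gmAFD of the compositional mean to the ground truth),
#' the maximum taxon-wise AFD and Aitchison distance of the mean, per-taxon
#' fold-differences, per-replicate accuracies, and the threshold evaluation.
#'
#' @inheritParams trueness
#' @param config A [threshold_config()]; default DNA-mock bounds.
#' @return An object of class `accuracy_report`; see [tidy()] for the
#'   per-taxon table and [glance()] for the one-row summary.
#' @export
assess_accuracy <- function(data, expected, config = threshold_config("dna_mock")) {
  expected_vec <- as_expected_composition(expected)
  m <- as_abundance_matrix(data)
  ctr <- setNames(geometric_center(m), colnames(m))
  per_taxon <- afd_profile(ctr, expected_vec)
  ev <- evaluate_thresholds(per_taxon$gmafd[1], per_taxon$max_afd[1], config)
  structure(
    list(
      trueness = per_taxon$gmafd[1],
      max_afd = per_taxon$max_afd[1],
      aitchison_distance = aitchison_distance(ctr, expected_vec),
      per_taxon = per_taxon[c("taxon", "afd")],
      per_replicate = accuracy_each(m, expected_vec),
      thresholds = ev,
      config = config,
      n = nrow(m)
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "Accuracy vs ground truth (n = %d replicates):\n  trueness (gmAFD) = %.4f  max AFD = %.4f  d_A = %.4f\n",
    x$n, x$trueness, x$max_afd, x$aitchison_distance
  ))
  cat(sprintf(
    "  thresholds (%s): gmAFD %s, max AFD %s\n",
    x$config$material,
    ifelse(x$thresholds$pass_gmafd, "PASS", "FAIL"),
    ifelse(x$thresholds$pass_maxafd, "PASS", "FAIL")
  ))
  invisible(x)
}

#' @exportS3Method
tidy.accuracy_report <- function(x, ...) x$per_taxon

#' @exportS3Method
glance.accuracy_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      trueness = x$trueness,
      aitchison_distance = x$aitchison_distance,
      n = x$n
    ),
    x$thresholds[c("max_afd", "pass_gmafd", "pass_maxafd", "pass")]
  )
}

#' Summarise GC-content quantification bias as a regression slope
#'
#' For every unordered pair of taxa, the log2 abundance ratio is regressed
#' (without intercept) on the pairwise difference in genomic GC content.
#' For an even community the slope summarises how strongly measurement
#' distorts abundances along the GC axis: negative slopes mean lower-GC
#' genomes are overrepresented. The slope has units log2-fold per
#' percentage point of GC; `fold_per_10pct = 2^(10 * slope)` restates it as
#' the abundance fold-ratio expected for a 10% GC difference.
#'
#' Ordered pairs are redundant by antisymmetry, so only pairs i < j enter
#' the fit; the estimate is identical either way.
#'
#' @param abundance Strictly positive (mean) abundance vector, one entry
#'   per taxon, at least 3 taxa.
#' @param gc_percent Genomic GC content (%) per taxon, same order.
#' @return An object of class `gc_bias` with `slope`, `fold_per_10pct`,
#'   `n_pairs`, and the per-pair data.
#' @examples
#' gc <- c(40, 50, 60)
#' x <- 2^(-0.02 * gc); x <- x / sum(x)
#' gc_bias_slope(x, gc)$slope
#' @export
gc_bias_slope <- function(abundance, gc_percent) {
  if (length(abundance) < 3) stop_invalid("GC-bias regression needs at least 3 taxa.")
  if (length(gc_percent) != length(abundance)) {
    stop_alignment("`gc_percent` must match `abundance` in length.")
  }
  if (any(abundance <= 0)) stop_invalid("Abundances must be strictly positive.")
  pairs <- combn(length(abundance), 2)
  r <- log2(abundance[pairs[1, ]] / abundance[pairs[2, ]])
  dgc <- gc_percent[pairs[1, ]] - gc_percent[pairs[2, ]]
  if (all(dgc == 0)) {
    abort("All pairwise GC differences are zero; slope is not identifiable.",
      class = "mockval_degenerate_design"
    )
  }
  slope <- sum(r * dgc) / sum(dgc^2)
  taxa <- names(abundance) %||% paste0("taxon_", seq_along(abundance))
  structure(
    list(
      slope = slope,
      fold_per_10pct = 2^(10 * slope),
      n_pairs = ncol(pairs),
      pairs = tibble::tibble(
        taxon_i = taxa[pairs[1, ]],
        taxon_j = taxa[pairs[2, ]],
        log2_ratio = unname(r),
        delta_gc = unname(dgc)
      )
    ),
    class = "gc_bias"
  )
}

#' @export
print.gc_bias <- function(x, ...) {
  cat(sprintf(
    "GC bias: slope = %.5f log2-fold per %%GC (%.3f-fold per 10%% GC difference), %d pairs\n",
    x$slope, x$fold_per_10pct, x$n_pairs
  ))
  invisible(x)
}

#' @exportS3Method
tidy.gc_bias <- function(x, ...) x$pairs

#' @exportS3Method
glance.gc_bias <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    fold_per_10pct = x$fold_per_10pct,
    n_pairs = x$n_pairs
  )
}

#' Pairwise log-ratio vs GC-difference plot for a GC-bias fit
#'
#' @param object A `gc_bias` object.
#' @param ... Unused.
#' @return A ggplot object with the per-pair points and the intercept-free
#'   fitted line.
#' @exportS3Method
autoplot.gc_bias <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$delta_gc, .data$log2_ratio)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = 0, slope = object$slope, colour = "red") +
    ggplot2::labs(
      x = "Difference in genomic GC content (%)",
      y = "log2 abundance ratio"
    ) +
    ggplot2::theme_minimal()
}

#' Fragmentation bias from positional base frequencies
#'
#' Non-random DNA fragmentation shows up as a deviation of observed read
#' base frequencies at early sequencing cycles from the frequencies
#' expected from the reference genomes. The statistic is the Aitchison
#' distance between the observed and expected (A, C, G, T) composition at
#' each read position, averaged over the requested cycles (the first 15 of
#' the forward read by default).
#'
#' @param observed Base-frequency table: columns `position`, `A`, `C`, `G`,
#'   `T`, rows summing to 1 (see [read_base_frequencies()]).
#' @param expected Either a single 4-part composition (named or in A, C, G,
#'   T order) applied at every position, or a base-frequency table like
#'   `observed`.
#' @param cycles Integer vector of read positions to average over. Default
#'   `1:15`.
#' @param floor Replacement for zero base frequencies before the clr-based
#'   distance. Default `1e-6`.
#' @return An object of class `frag_bias` with the mean distance and the
#'   per-position distances.
#' @export
fragmentation_bias <- function(observed, expected, cycles = 1:15, floor = 1e-6) {
  obs <- check_base_freqs(observed)
  if (!all(cycles %in% obs$position)) {
    missing_cycles <- setdiff(cycles, obs$position)
    stop_invalid(paste0(
      "Observed base frequencies missing requested cycles: ",
      paste(missing_cycles, collapse = ", ")
    ))
  }
  exp_at <- function(pos) {
    if (is.data.frame(expected)) {
      e <- check_base_freqs(expected)
      if (!pos %in% e$position) stop_invalid(paste0("Expected frequencies missing cycle ", pos))
      unlist(e[e$position == pos, c("A", "C", "G", "T")])
    } else {
      if (length(expected) != 4) stop_invalid("`expected` must be a 4-part composition.")
      setNames(as.numeric(expected), c("A", "C", "G", "T"))
    }
  }
  per_pos <- purrr::map_dbl(cycles, function(pos) {
    o <- unlist(obs[obs$position == pos, c("A", "C", "G", "T")])
    e <- exp_at(pos)
    o[o == 0] <- floor
    e[e == 0] <- floor
    aitchison_distance(closure(o), closure(e))
  })
  structure(
    list(
      bias = mean(per_pos),
      per_position = tibble::tibble(position = cycles, distance = per_pos),
      cycles = cycles
    ),
    class = "frag_bias"
  )
}

check_base_freqs <- function(x) {
  if (!is.data.frame(x) || !all(c("position", "A", "C", "G", "T") %in% names(x))) {
    stop_invalid("Base-frequency table needs columns position, A, C, G, T.")
  }
  s <- rowSums(x[, c("A", "C", "G", "T")])
  if (any(abs(s - 1) > 1e-6)) {
    stop_invalid("Base-frequency rows must sum to 1 (within 1e-6).")
  }
  if (is.unsorted(x$position, strictly = TRUE)) {
    stop_invalid("Positions must be strictly increasing.")
  }
  x
}

#' @export
print.frag_bias <- function(x, ...) {
  cat(sprintf(
    "Fragmentation bias: mean Aitchison distance %.5f over cycles %d-%d\n",
    x$bias, min(x$cycles), max(x$cycles)
  ))
  invisible(x)
}

#' @exportS3Method
tidy.frag_bias <- function(x, ...) x$per_position

#' @exportS3Method
glance.frag_bias <- function(x, ...) {
  tibble::tibble(bias = x$bias, n_cycles = length(x$cycles))
}
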