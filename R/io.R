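# TSV readers/writers for the package's external interfaces, and the
# end-to-end validation orchestrator with its JSON report.

read_tsv_strict <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a wide abundance table from TSV
#'
#' Expects a tab-delimited UTF-8 file whose first column is `sample_id`
#' and whose remaining columns are taxon labels holding relative
#' abundances (percent or fraction scale). Duplicate sample ids,
#' non-numeric cells, and negative or non-finite abundances are rejected
#' with informative errors.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `sample_id` plus one numeric column per taxon.
#' @export
read_abundance <- function(path) {
  x <- read_tsv_strict(path)
  if (names(x)[1] != "sample_id") {
    abort("First column of an abundance table must be `sample_id`.",
      class = "mockval_parse_error"
    )
  }
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample_id: ", paste(unique(dup), collapse = ", ")),
      class = "mockval_parse_error"
    )
  }
  vals <- x[-1]
  bad <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric abundance column(s): ", paste(bad, collapse = ", ")),
      class = "mockval_parse_error"
    )
  }
  m <- as.matrix(vals)
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0)) {
    bad_rows <- which(apply(m, 1, function(r) anyNA(r) || any(!is.finite(r)) || any(r < 0)))
    abort(
      paste0(
        "Abundances must be finite and non-negative; offending row(s): ",
        paste(x$sample_id[bad_rows], collapse = ", ")
      ),
      class = "mockval_parse_error"
    )
  }
  x
}

#' Read a sample-metadata table from TSV
#'
#' @param path Path to a TSV with a `sample_id` column plus factor columns
#'   (e.g. `laboratory`, `operator`, `lot`, `protocol`, `replicate`,
#'   `material`).
#' @return A tibble.
#' @export
read_metadata <- function(path) {
  x <- read_tsv_strict(path)
  if (!"sample_id" %in% names(x)) {
    abort("Metadata must contain a `sample_id` column.", class = "mockval_parse_error")
  }
  x
}

#' Read a ground-truth profile from TSV
#'
#' @param path Path to a TSV with columns `taxon`, `expected_pct`,
#'   `gc_percent`, `gram_type`, `genome_size_bp`.
#' @return A tibble with those columns.
#' @export
read_ground_truth <- function(path) {
  x <- read_tsv_strict(path)
  need <- c("taxon", "expected_pct", "gc_percent", "gram_type", "genome_size_bp")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("Ground-truth table missing column(s): ", paste(miss, collapse = ", ")),
      class = "mockval_parse_error"
    )
  }
  if (any(x$expected_pct <= 0)) {
    abort("Expected abundances must be strictly positive.", class = "mockval_parse_error")
  }
  if (any(x$gc_percent <= 0 | x$gc_percent >= 100)) {
    abort("GC content must lie strictly between 0 and 100%.", class = "mockval_parse_error")
  }
  x
}

#' Read a positional base-frequency table from TSV
#'
#' @param path Path to a TSV with columns `position`, `A`, `C`, `G`, `T`
#'   (fractions summing to 1 per row, positions strictly increasing).
#' @return A tibble.
#' @export
read_base_frequencies <- function(path) {
  x <- read_tsv_strict(path)
  check_base_freqs(x)
}

#' Write a wide abundance table (or any tibble) to TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_abundance <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' Write the files of a simulated study to a directory
#'
#' Writes `abundance.tsv`, `metadata.tsv`, `ground_truth.tsv` and
#' `parameters.json` for a [simulate_hierarchy()] result, so a simulated
#' study round-trips through the same readers as real data.
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(study$abundance, file.path(dir, "abundance.tsv"))
  readr::write_tsv(study$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(study$truth, file.path(dir, "ground_truth.tsv"))
  jsonlite::write_json(
    unclass(study$model),
    file.path(dir, "parameters.json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(dir)
}

#' Run the full mock-community validation workflow
#'
#' Orchestrates the validation of a set of replicated measurements against
#' a ground truth: zero replacement, trueness/accuracy and threshold
#' evaluation, precision (qmCV), and optionally the distance-based ANOVA,
#' detection limits, and GC bias. Deterministic for fixed inputs.
#'
#' @param abundance Wide abundance tibble (or path to a TSV).
#' @param truth Ground-truth tibble (or path to a TSV).
#' @param metadata Optional metadata tibble (or path); required for the
#'   ANOVA and replicate-set grouping.
#' @param config A [threshold_config()].
#' @param group Optional metadata column for the distance-based ANOVA;
#'   `NULL` skips it.
#' @param limits If `TRUE`, fit LOD/LOQ from the detection summaries
#'   (treating all samples as one replicate set unless `group` is given).
#' @param zero_floor_pct Floor for [replace_zeros()], percent scale.
#' @return A list of class `validation_report`.
#' @export
run_validation <- function(abundance, truth, metadata = NULL,
                           config = threshold_config("dna_mock"),
                           group = NULL, limits = FALSE,
                           zero_floor_pct = 0.001) {
  if (is.character(abundance)) abundance <- read_abundance(abundance)
  if (is.character(truth)) truth <- read_ground_truth(truth)
  if (is.character(metadata)) metadata <- read_metadata(metadata)

  m <- as_abundance_matrix(abundance)
  if (!setequal(colnames(m), truth$taxon)) {
    stop_alignment("Abundance table and ground truth cover different taxa.")
  }
  m <- m[, truth$taxon, drop = FALSE]
  kappa <- detect_scale(m)
  if (any(m == 0)) m <- replace_zeros(m, floor_pct = zero_floor_pct, kappa = kappa)
  frac <- m / kappa

  acc <- assess_accuracy(frac, setNames(truth$expected_pct, truth$taxon), config)
  prec <- if (nrow(frac) >= 2) qmcv_direct(frac) else NULL
  anova <- if (!is.null(group)) decompose_variance(abundance_with_ids(abundance, frac), metadata, group) else NULL
  gc <- gc_bias_slope(
    setNames(geometric_center(frac), colnames(frac)),
    truth$gc_percent
  )
  lim <- if (limits) {
    sm <- summarize_detection(
      abundance_with_ids(abundance, frac),
      metadata = if (is.null(group)) NULL else metadata,
      replicate_set = group
    )
    tryCatch(detection_limits(sm), error = function(e) e)
  } else {
    NULL
  }

  structure(
    list(
      material = config$material,
      accuracy = acc,
      precision = prec,
      anova = anova,
      gc_bias = gc,
      limits = lim,
      n_samples = nrow(frac),
      n_taxa = ncol(frac),
      version = as.character(utils::packageVersion("mockval"))
    ),
    class = "validation_report"
  )
}

# keep sample ids attached when handing a fraction matrix to grouped ops
abundance_with_ids <- function(template, frac) {
  if (is.data.frame(template) && !is.numeric(template[[1]])) {
    dplyr::bind_cols(template[1], tibble::as_tibble(frac))
  } else {
    frac
  }
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Mock-community validation (%s material): %d samples x %d taxa\n",
    x$material, x$n_samples, x$n_taxa
  ))
  print(x$accuracy)
  if (!is.null(x$precision)) print(x$precision)
  if (!is.null(x$anova)) print(x$anova)
  print(x$gc_bias)
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' Writes every numeric result of [run_validation()] to a machine-readable
#' JSON file; the mapping is lossless for all scalar fields and per-taxon
#' tables.
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  out <- list(
    material = report$material,
    version = report$version,
    n_samples = report$n_samples,
    n_taxa = report$n_taxa,
    accuracy = c(
      as.list(glance(report$accuracy)),
      list(per_taxon_afd = report$accuracy$per_taxon)
    ),
    precision = if (!is.null(report$precision)) as.list(glance(report$precision)),
    anova = if (!is.null(report$anova)) as.list(glance(report$anova)),
    gc_bias = as.list(glance(report$gc_bias)),
    limits = if (!is.null(report$limits) && inherits(report$limits, "detection_limits")) {
      as.list(glance(report$limits))
    }
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows")
  invisible(path)
}
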