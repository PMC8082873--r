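# Table-level operations on wide abundance tibbles: first column
# `sample_id`, remaining columns one per taxon, values relative abundances
# on the percent (rows sum to ~100) or fraction (rows sum to ~1) scale.

#' Detect whether an abundance table is on the percent or fraction scale
#'
#' Row sums near 100 indicate percent, near 1 indicate fraction. Tables
#' whose row sums fall outside both bands are rejected rather than guessed.
#'
#' @param data Wide abundance table (matrix or data frame with leading
#'   `sample_id` column).
#' @return The closure constant: `100` or `1`.
#' @export
detect_scale <- function(data) {
  m <- as_abundance_matrix(data)
  s <- rowSums(m)
  if (all(s > 50 & s < 200)) return(100)
  if (all(s > 0.5 & s < 2)) return(1)
  stop_invalid(
    "Cannot tell percent from fraction scale: row sums are neither all near 100 nor all near 1."
  )
}

#' Replace zero abundances by a small floor and re-close rows
#'
#' Compositional analysis requires strictly positive parts, so observed
#' zeros (taxa below the detection limit at the sequenced depth) are set to
#' a small floor -- 0.001% by default -- and each row is then re-closed to
#' its original constant sum. Non-zero values change only through the
#' re-closure.
#'
#' @param data Wide abundance table (first column `sample_id`) or numeric
#'   matrix; percent or fraction scale, autodetected.
#' @param floor_pct Replacement value on the percent scale. Default `0.001`
#'   (i.e. 0.001%); converted automatically if the table is on the fraction
#'   scale.
#' @param kappa Closure constant of the table; `NULL` (default) autodetects
#'   via [detect_scale()].
#' @return A table of the same shape and class with no zeros, rows summing
#'   to `kappa`.
#' @examples
#' tab <- tibble::tibble(sample_id = "s1", a = 99.999, b = 0, c = 0.001)
#' replace_zeros(tab)
#' @export
replace_zeros <- function(data, floor_pct = 0.001, kappa = NULL) {
  m <- as_abundance_matrix(data)
  if (anyNA(m) || any(!is.finite(m))) stop_invalid("Abundances must be finite and non-missing.")
  if (any(m < 0)) stop_invalid("Abundances must be non-negative.")
  if (any(rowSums(m) == 0)) stop_invalid("A row of all zeros cannot be re-closed.")
  if (is.null(kappa)) kappa <- detect_scale(m)
  floor_val <- floor_pct * kappa / 100
  m[m == 0] <- floor_val
  m <- kappa * m / rowSums(m)
  rebuild_table(data, m)
}

#' Keep taxa above a minimum mean abundance in either of two profiles
#'
#' For cross-protocol comparisons, taxa are retained when their mean
#' abundance reaches `min_pct` in profile `a` *or* profile `b` (union rule);
#' both profiles are then re-closed over the retained taxa.
#'
#' @param a,b Named numeric vectors of (mean) relative abundances on the
#'   percent scale, over the same taxa.
#' @param min_pct Minimum mean abundance (percent) to retain a taxon in the
#'   union rule. Default `0.05`.
#' @return A tibble with columns `taxon`, `a`, `b`: retained taxa, each
#'   profile re-closed to 100.
#' @export
abundance_filter_union <- function(a, b, min_pct = 0.05) {
  if (is.null(names(a)) || is.null(names(b))) {
    stop_alignment("`a` and `b` must be named by taxon.")
  }
  if (!identical(names(a), names(b))) stop_alignment("`a` and `b` must share taxon labels and order.")
  keep <- a >= min_pct | b >= min_pct
  if (sum(keep) < 2) {
    abort("Fewer than 2 taxa pass the abundance filter.", class = "mockval_empty_result")
  }
  tibble::tibble(
    taxon = names(a)[keep],
    a = closure(unname(a[keep]), kappa = 100),
    b = closure(unname(b[keep]), kappa = 100)
  )
}

# Put a transformed abundance matrix back into the container the caller
# supplied (tibble with sample_id, data.frame, or matrix).
rebuild_table <- function(template, m) {
  if (is.data.frame(template)) {
    out <- template
    if (!is.numeric(template[[1]])) {
      out[, -1] <- m
    } else {
      out[, ] <- m
    }
    return(tibble::as_tibble(out))
  }
  m
}
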