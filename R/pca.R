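#' Compositional principal component analysis
#'
#' PCA of the column-centred clr-transformed abundance table (no scaling),
#' the standard ordination for compositional microbiome data. New
#' compositions -- e.g. a mock community's ground truth -- can be projected
#' onto the fitted ordination with [predict()].
#'
#' Component signs are fixed so that the largest-magnitude loading of each
#' component is positive, making results deterministic across platforms.
#'
#' @param data Wide abundance table (first column `sample_id`) or numeric
#'   matrix of strictly positive abundances, samples in rows.
#' @return An object of class `comp_pca` with elements `scores` (tibble),
#'   `loadings` (tibble), `var_explained` (numeric, sums to 1), plus the
#'   fitted centring vector and rotation used for projection.
#' @examples
#' set.seed(1)
#' m <- matrix(rexp(40) + 0.1, nrow = 8)
#' fit <- compositional_pca(m / rowSums(m))
#' glance(fit)
#' @export
compositional_pca <- function(data) {
  m <- as_abundance_matrix(data)
  if (nrow(m) < 2) stop_replication("compositional_pca needs at least 2 samples.")
  if (any(m <= 0)) stop_invalid("compositional_pca requires zero-free data.")
  if (is.null(colnames(m))) colnames(m) <- paste0("taxon_", seq_len(ncol(m)))
  z <- clr(m)
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  # deterministic sign: largest |loading| positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  ids <- rownames(m) %||% paste0("sample_", seq_len(nrow(m)))
  scores <- tibble::as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = ids), scores)
  loadings <- tibble::as_tibble(pc$rotation)
  loadings <- dplyr::bind_cols(tibble::tibble(taxon = colnames(m)), loadings)
  structure(
    list(
      scores = scores,
      loadings = loadings,
      var_explained = ve,
      center = pc$center,
      rotation = pc$rotation,
      taxa = colnames(m)
    ),
    class = "comp_pca"
  )
}

#' Project new compositions onto a fitted compositional PCA
#'
#' @param object A `comp_pca` fit.
#' @param newdata A strictly positive composition (named numeric vector over
#'   the fitted taxa) or a matrix / wide table of such rows.
#' @param ... Unused.
#' @return A tibble of scores, one row per projected composition.
#' @export
predict.comp_pca <- function(object, newdata, ...) {
  m <- as_abundance_matrix(newdata)
  if (ncol(m) != length(object$taxa)) {
    stop_alignment("New composition does not match the fitted taxa.")
  }
  if (!is.null(colnames(m)) && !identical(colnames(m), object$taxa)) {
    stop_alignment("Taxon labels of `newdata` differ from the fitted taxa.")
  }
  z <- clr(m)
  sc <- sweep(z, 2, object$center) %*% object$rotation
  out <- tibble::as_tibble(sc)
  ids <- rownames(m) %||% paste0("new_", seq_len(nrow(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = ids), out)
}

#' @export
print.comp_pca <- function(x, ...) {
  cat("Compositional PCA:", length(x$taxa), "taxa,", nrow(x$scores), "samples\n")
  cat(
    "Variance explained (first components):",
    paste0(sprintf("%.1f%%", 100 * head(x$var_explained, 3)), collapse = ", "), "\n"
  )
  invisible(x)
}

#' @exportS3Method
tidy.comp_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$var_explained)),
    var_explained = x$var_explained,
    cum_var_explained = cumsum(x$var_explained)
  )
}

#' @exportS3Method
glance.comp_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_taxa = length(x$taxa),
    pc1_var_explained = x$var_explained[1],
    pc2_var_explained = ifelse(length(x$var_explained) > 1, x$var_explained[2], NA_real_)
  )
}

#' Ordination plot for a compositional PCA
#'
#' @param object A `comp_pca` fit.
#' @param truth Optional named composition (e.g. the ground truth) projected
#'   onto the ordination and drawn as a labelled point.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.comp_pca <- function(object, truth = NULL, ...) {
  ve <- object$var_explained
  p <- ggplot2::ggplot(object$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tr <- predict(object, matrix(truth, nrow = 1, dimnames = list("truth", names(truth))))
    p <- p + ggplot2::annotate(
      "text",
      x = tr$PC1, y = tr$PC2, label = "T", colour = "red", fontface = "bold", size = 5
    )
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
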