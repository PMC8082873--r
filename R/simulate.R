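# Synthetic mock-community studies. The generator emulates the statistical
# structure the estimators assume: a near-even multi-strain ground truth
# spanning a wide genomic GC range, a log-linear GC-bias distortion, a
# log-scale under-recovery of Gram-positive taxa (lysis bias), nested
# group random effects, multiplicative log-normal taxon noise, and
# optional multinomial count sampling at a chosen read depth. All bias and
# noise terms act additively on the log scale before closure, matching the
# log-linear GC-bias summary and the multiplicative fold-difference
# metrics applied downstream.

#' Construct a mock-community ground-truth profile
#'
#' Builds a ground truth for a defined community of `D` strains: expected
#' relative abundances (even by default, emulating an equimolar design),
#' genomic GC contents evenly spaced across `gc_range`, alternating Gram
#' types, and genome sizes evenly spaced between 2 and 6 Mbp.
#'
#' @param D Number of strains. Default 20.
#' @param gc_range Range (%) spanned by the genomic GC contents. Default
#'   `c(31.5, 62.3)`.
#' @param even If `TRUE` (default) every strain has expected abundance
#'   `100/D` percent; if `FALSE` expected abundances are drawn log-normally
#'   (clr sd 1) and closed.
#' @param seed RNG seed (used only when `even = FALSE`).
#' @return A tibble with columns `taxon`, `expected_pct`, `gc_percent`,
#'   `gram_type`, `genome_size_bp`.
#' @examples
#' make_ground_truth(D = 4)
#' @export
make_ground_truth <- function(D = 20, gc_range = c(31.5, 62.3), even = TRUE,
                              seed = NULL) {
  if (D < 2) stop_invalid("A ground truth needs at least 2 taxa.")
  expected <- if (even) {
    rep(100 / D, D)
  } else {
    with_seed_or_not(seed, closure(exp(rnorm(D, 0, 1)), kappa = 100))
  }
  tibble::tibble(
    taxon = sprintf("taxon_%02d", seq_len(D)),
    expected_pct = expected,
    gc_percent = seq(gc_range[1], gc_range[2], length.out = D),
    gram_type = rep(c("positive", "negative"), length.out = D),
    genome_size_bp = as.integer(round(seq(2e6, 6e6, length.out = D)))
  )
}

#' Specify a measurement model for simulated mock-community measurements
#'
#' Collects the distortion and noise parameters applied, on the log scale,
#' to the expected abundances before closure:
#' `log a_i = log e_i + log(2) * gc_slope * (GC_i - mean GC) - penalty_i +
#' group_effect_i + N(0, sigma_within)`, followed by closure and, when
#' `depth` is set, multinomial count sampling.
#'
#' @param gc_slope GC bias in log2-fold per percentage point of GC
#'   difference (negative favours low-GC taxa). Default 0.
#' @param sigma_within clr-scale standard deviation of per-measurement
#'   taxon noise. Default 0.
#' @param sigma_between clr-scale standard deviation of per-group random
#'   effects (see [simulate_hierarchy()]). Default 0.
#' @param gram_positive_penalty Log-scale under-recovery applied to
#'   Gram-positive taxa (emulating incomplete lysis). Default 0.
#' @param depth Optional multinomial read depth; `NULL` returns exact
#'   fractions.
#' @return A list of class `measurement_model`.
#' @export
measurement_model <- function(gc_slope = 0, sigma_within = 0, sigma_between = 0,
                              gram_positive_penalty = 0, depth = NULL) {
  if (sigma_within < 0 || sigma_between < 0) stop_invalid("Noise sds must be non-negative.")
  if (!is.null(depth) && depth <= 0) stop_invalid("`depth` must be positive when set.")
  structure(
    list(
      gc_slope = gc_slope, sigma_within = sigma_within,
      sigma_between = sigma_between,
      gram_positive_penalty = gram_positive_penalty, depth = depth
    ),
    class = "measurement_model"
  )
}

#' Simulate one measured composition from a ground truth
#'
#' Applies the [measurement_model()] distortions to the expected
#' composition and returns the measured relative abundances as a named
#' fraction-scale vector (zeros possible only with finite `depth`). With
#' all parameters zero and no depth the truth is returned exactly.
#'
#' @param truth A ground-truth tibble from [make_ground_truth()] (or with
#'   the same columns).
#' @param model A [measurement_model()].
#' @param group_effect Optional per-taxon log-scale effect vector (drawn by
#'   [simulate_hierarchy()] and shared within a group).
#' @param seed Optional RNG seed for this draw.
#' @return Named numeric vector summing to 1.
#' @export
simulate_measurement <- function(truth, model = measurement_model(),
                                 group_effect = NULL, seed = NULL) {
  stopifnot(inherits(model, "measurement_model"))
  D <- nrow(truth)
  if (is.null(group_effect)) group_effect <- rep(0, D)
  if (length(group_effect) != D) stop_alignment("`group_effect` must have one entry per taxon.")
  with_seed_or_not(seed, {
    log_a <- log(truth$expected_pct / 100) +
      log(2) * model$gc_slope * (truth$gc_percent - mean(truth$gc_percent)) -
      ifelse(truth$gram_type == "positive", model$gram_positive_penalty, 0) +
      group_effect +
      rnorm(D, 0, model$sigma_within)
    p <- closure(exp(log_a))
    if (!is.null(model$depth)) {
      counts <- as.vector(rmultinom(1, size = model$depth, prob = p))
      p <- counts / sum(counts)
    }
    setNames(p, truth$taxon)
  })
}

#' Simulate a balanced hierarchical (interlaboratory-style) study
#'
#' Draws `p` groups (laboratories, or operator-lot combinations) each with
#' a shared per-taxon random effect `N(0, sigma_between)`, and `n`
#' replicate measurements per group with independent within-measurement
#' noise, mirroring the one-way random-effects model the distance-based
#' ANOVA assumes.
#'
#' @inheritParams simulate_measurement
#' @param p Number of groups (>= 2).
#' @param n Replicates per group (>= 2).
#' @param seed RNG seed; the whole study is a pure function of
#'   (parameters, seed).
#' @return A list of class `simulated_study` with elements `abundance`
#'   (wide tibble, fraction scale), `metadata` (tibble with `sample_id`,
#'   `group`, `replicate`), `truth`, and `model`.
#' @export
simulate_hierarchy <- function(truth, model = measurement_model(), p = 2, n = 2,
                               seed = NULL) {
  if (p < 2 || n < 2) stop_invalid("Need p >= 2 groups and n >= 2 replicates per group.")
  with_seed_or_not(seed, {
    rows <- list()
    meta <- list()
    k <- 0
    for (i in seq_len(p)) {
      eff <- rnorm(nrow(truth), 0, model$sigma_between)
      for (j in seq_len(n)) {
        k <- k + 1
        rows[[k]] <- simulate_measurement(truth, model, group_effect = eff)
        meta[[k]] <- tibble::tibble(
          sample_id = sprintf("g%02d_r%02d", i, j),
          group = sprintf("group_%02d", i),
          replicate = j
        )
      }
    }
    ab <- tibble::as_tibble(do.call(rbind, rows))
    metadata <- dplyr::bind_rows(meta)
    abundance <- dplyr::bind_cols(metadata["sample_id"], ab)
    structure(
      list(abundance = abundance, metadata = metadata, truth = truth, model = model),
      class = "simulated_study"
    )
  })
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "Simulated study: %d samples x %d taxa (%d groups)\n",
    nrow(x$abundance), nrow(x$truth), length(unique(x$metadata$group))
  ))
  invisible(x)
}

#' Simulate observed and expected positional base-frequency profiles
#'
#' Produces a fixture pair for [fragmentation_bias()]: the expected profile
#' is uniform (A, C, G, T each 0.25) at every position, and the observed
#' profile perturbs each position's clr coordinates with independent
#' `N(0, perturbation_sd)` noise before re-closure.
#'
#' @param n_positions Number of read positions. Default 15.
#' @param perturbation_sd clr-scale sd of the positional perturbation; 0
#'   reproduces the expected profile exactly.
#' @param seed RNG seed.
#' @return A list with tibbles `observed` and `expected` (columns
#'   `position`, `A`, `C`, `G`, `T`).
#' @export
simulate_base_frequencies <- function(n_positions = 15, perturbation_sd = 0,
                                      seed = NULL) {
  if (n_positions < 1) stop_invalid("`n_positions` must be at least 1.")
  with_seed_or_not(seed, {
    expected <- tibble::tibble(
      position = seq_len(n_positions),
      A = 0.25, C = 0.25, G = 0.25, T = 0.25
    )
    obs <- t(vapply(seq_len(n_positions), function(i) {
      closure(exp(log(rep(0.25, 4)) + rnorm(4, 0, perturbation_sd)))
    }, numeric(4)))
    observed <- tibble::tibble(
      position = seq_len(n_positions),
      A = obs[, 1], C = obs[, 2], G = obs[, 3], T = obs[, 4]
    )
    list(observed = observed, expected = expected)
  })
}

#' Genome copies in a given mass of genomic DNA
#'
#' Converts a DNA mass to genome copy numbers using a molecular weight of
#' 660 g per mole per base pair, the conversion used when assigning
#' ground-truth abundances from measured DNA content.
#'
#' @param mass_g DNA mass in grams (> 0).
#' @param genome_size_bp Genome size in base pairs (> 0).
#' @return Number of genome copies.
#' @examples
#' genome_copies_from_mass(1e-9, 5e6)  # ~1.8e5 copies in 1 ng of a 5 Mbp genome
#' @export
genome_copies_from_mass <- function(mass_g, genome_size_bp) {
  if (any(mass_g <= 0) || any(genome_size_bp <= 0)) {
    stop_invalid("Mass and genome size must be positive.")
  }
  avogadro <- 6.02214076e23
  mass_g / (genome_size_bp * 660) * avogadro
}
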