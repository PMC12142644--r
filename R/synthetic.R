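#' Configuration for the synthetic longitudinal cohort generator
#'
#' The generator emulates the structure of a large imaging cohort in which
#' only a small fraction of patients return for follow-up imaging: correlated
#' baseline features from a low-rank latent factor model, labels that mix
#' binary disease/demographic flags with a continuous covariate, a
#' label-dependent progression (a global near-identity gain plus decay
#' concentrated on a designated feature block for flagged patients),
#' observation noise on the follow-up, and rare within-vector missingness.
#'
#' Default effect sizes are chosen once so the progression signal dominates
#' observation noise and is identifiable at a few thousand patients — an
#' accelerated-progression design: a 40% global shrink per follow-up
#' interval, a decay of 0.3 raw units on a 6-feature block for patients
#' carrying the disease flag (prevalence 0.25), and follow-up observation
#' noise of 0.05 raw units per feature (baseline features have raw scale
#' ~1).
#'
#' @param d feature count (default 24).
#' @param n_patients cohort size.
#' @param paired_fraction fraction of patients retaining a follow-up
#'   (default 0.12; the count is `ceiling(paired_fraction * n_patients)`).
#' @param n_labels number of labels (default 3: binary disease flag, binary
#'   demographic flag, continuous covariate).
#' @param latent_rank rank of the latent factor model for baselines
#'   (default 4).
#' @param progression_gain `d x d` matrix applied to the raw baseline to form
#'   the follow-up mean; default `0.6 * I`.
#' @param label_effects `n_labels x d` matrix of additive raw-scale label
#'   effects on the follow-up mean; default: the disease flag (label 1)
#'   contributes `decay` on features `block`; other labels contribute 0.
#' @param decay raw-scale additive change for flagged patients on the block
#'   (default -0.3).
#' @param block integer feature indices of the disease-sensitive block
#'   (default `1:6`, the case-study volume block).
#' @param prevalence disease-flag prevalence (default 0.25).
#' @param noise_scale follow-up observation-noise standard deviation, raw
#'   scale (default 0.05).
#' @param baseline_noise independent baseline noise on top of the latent
#'   factors (default 0.5).
#' @param missing_rate per-entry masking probability, in `[0, 0.05]`
#'   (default 0).
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(d = 24L, n_patients = 1000L,
                             paired_fraction = 0.12, n_labels = 3L,
                             latent_rank = 4L, progression_gain = NULL,
                             label_effects = NULL, decay = -0.3,
                             block = 1:6, prevalence = 0.25,
                             noise_scale = 0.05, baseline_noise = 0.5,
                             missing_rate = 0, seed = 1L) {
  if (latent_rank > d) rlang::abort("`latent_rank` must not exceed `d`.")
  if (!(paired_fraction > 0 && paired_fraction <= 1)) {
    rlang::abort("`paired_fraction` must be in (0, 1].")
  }
  if (missing_rate < 0 || missing_rate > 0.05) {
    rlang::abort("`missing_rate` must be in [0, 0.05].")
  }
  if (any(block > d)) rlang::abort("`block` indices exceed `d`.")
  if (is.null(progression_gain)) progression_gain <- diag(0.6, d)
  if (!all(dim(progression_gain) == c(d, d))) {
    rlang::abort("`progression_gain` must be d x d.")
  }
  if (is.null(label_effects)) {
    label_effects <- matrix(0, n_labels, d)
    label_effects[1, block] <- decay
  }
  if (!all(dim(label_effects) == c(n_labels, d))) {
    rlang::abort("`label_effects` must be n_labels x d.")
  }
  structure(list(d = as.integer(d), n_patients = as.integer(n_patients),
                 paired_fraction = paired_fraction,
                 n_labels = as.integer(n_labels),
                 latent_rank = as.integer(latent_rank),
                 progression_gain = progression_gain,
                 label_effects = label_effects, block = as.integer(block),
                 prevalence = prevalence, noise_scale = noise_scale,
                 baseline_noise = baseline_noise,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Draws latent factors `z ~ N(0, I)` of rank `latent_rank`, forms raw
#' baselines `z %*% loading + baseline_noise * N(0, I)`, labels (binary
#' disease flag at the configured prevalence, a balanced binary flag, a
#' standard-normal covariate), noiseless follow-up means
#' `baseline %*% t(progression_gain) + labels %*% label_effects`, and
#' observed follow-ups (mean plus `noise_scale` Gaussian noise). A
#' `ceiling(paired_fraction * n)` subset drawn at random keeps its follow-up;
#' the rest have it dropped. Optional entry-level masking at `missing_rate`
#' is applied to the retained feature vectors. Everything is min-max
#' normalized to `[-1, 1]`; the noiseless follow-up means are returned on
#' the same normalized scale for ALL patients, including unpaired ones.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort`: `cohort` (normalized; contains
#'   `NA` entries if `missing_rate > 0`), `ground_truth` (matrix `n x d`,
#'   normalized-scale noiseless follow-up means), and `config`.
#' @export
generate_cohort <- function(config) {
  cf <- config
  withr::with_seed(cf$seed, {
    n <- cf$n_patients; d <- cf$d
    loading <- matrix(stats::rnorm(cf$latent_rank * d, sd = 1 / sqrt(cf$latent_rank)),
                      cf$latent_rank, d)
    z <- matrix(stats::rnorm(n * cf$latent_rank), n, cf$latent_rank)
    i1_raw <- z %*% loading +
      cf$baseline_noise * matrix(stats::rnorm(n * d), n, d)

    labels <- matrix(0, n, cf$n_labels)
    labels[, 1] <- as.numeric(stats::runif(n) < cf$prevalence)
    if (cf$n_labels >= 2) labels[, 2] <- as.numeric(stats::runif(n) < 0.5)
    if (cf$n_labels >= 3) {
      labels[, 3:cf$n_labels] <- stats::rnorm(n * (cf$n_labels - 2))
    }
    colnames(labels) <- c("disease", "flag2", if (cf$n_labels >= 3)
      paste0("cov", seq_len(cf$n_labels - 2)))[seq_len(cf$n_labels)]

    mean_raw <- i1_raw %*% t(cf$progression_gain) + labels %*% cf$label_effects
    i2_raw <- mean_raw + cf$noise_scale * matrix(stats::rnorm(n * d), n, d)

    n_paired <- ceiling(cf$paired_fraction * n)
    paired <- sort(sample.int(n, n_paired))
    i2_obs <- matrix(NA_real_, n, d)
    i2_obs[paired, ] <- i2_raw[paired, , drop = FALSE]

    if (cf$missing_rate > 0) {
      m1 <- matrix(stats::runif(n * d) < cf$missing_rate, n, d)
      i1_raw[m1] <- NA_real_
      m2 <- matrix(stats::runif(n * d) < cf$missing_rate, n, d)
      i2_obs[m2 & !is.na(i2_obs)] <- NA_real_
    }

    co <- cohort(i1_raw, labels, i2 = i2_obs,
                 i2_present = seq_len(n) %in% paired,
                 feature_names = paste0("f", seq_len(d)))
    co <- normalize_cohort(co)

    # Ground truth mapped with the same per-feature ranges (no clipping: a
    # noiseless mean can sit slightly outside the observed range).
    rg <- co$feature_ranges
    span <- ifelse(rg$max - rg$min > 0, rg$max - rg$min, 1)
    gt <- sweep(sweep(mean_raw, 2, rg$min, "-"), 2, span, "/") * 2 - 1
    gt[, rg$max - rg$min == 0] <- 0
    colnames(gt) <- co$feature_names

    structure(list(cohort = co, ground_truth = gt, config = cf),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n=%d, d=%d, paired=%d, seed=%d\n",
              n_records(x$cohort), n_features(x$cohort),
              sum(x$cohort$i2_present), x$config$seed))
  invisible(x)
}

#' Error of imputations against the noiseless ground truth
#'
#' Per-patient Euclidean distance and Pearson correlation between imputed
#' follow-ups and the noiseless ground-truth follow-up means, averaged over
#' patients — the oracle score only a simulator can provide.
#'
#' @param imputed matrix `n x d` of imputed (normalized) follow-ups.
#' @param ground_truth matrix `n x d` of noiseless means (same scale).
#' @return one-row tibble: `mean_euclidean_to_truth`, `mean_pearson_to_truth`.
#' @export
oracle_error <- function(imputed, ground_truth) {
  if (!all(dim(imputed) == dim(ground_truth))) {
    rlang::abort("Shape mismatch between imputations and ground truth.")
  }
  eu <- mean(sqrt(rowSums((imputed - ground_truth)^2)))
  pe <- mean(vapply(seq_len(nrow(imputed)), function(i) {
    a <- imputed[i, ]; b <- ground_truth[i, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1)), na.rm = TRUE)
  tibble::tibble(mean_euclidean_to_truth = eu, mean_pearson_to_truth = pe)
}
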