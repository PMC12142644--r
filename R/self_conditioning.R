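#' Lightly perturb a baseline vector by a few forward-noise steps
#'
#' Applies the closed-form forward noising at step `k`:
#' `sqrt(alpha_bar_k) * i1 + sqrt(1 - alpha_bar_k) * eps` with fresh Gaussian
#' `eps`. With the default schedule and `k = 5` the signal retention
#' `alpha_bar_5` is about 0.99, so the perturbation is a light augmentation
#' rather than a destruction of the vector.
#'
#' @param i1 baseline feature vector, or matrix with one row per record.
#' @param schedule a [noise_schedule()].
#' @param k number of diffusion steps of noise to apply (default 5; must be
#'   in `1..T` — `k = 0` is rejected so a perturbed sample is always
#'   genuinely perturbed).
#' @param eps optional fixed noise for deterministic checks.
#' @return perturbed vector/matrix, same shape as `i1`.
#' @export
perturb_self <- function(i1, schedule, k = 5L, eps = NULL) {
  if (k < 1 || k > schedule$n_steps) {
    rlang::abort(sprintf("`k` must be in 1..%d.", schedule$n_steps))
  }
  forward_noise(i1, as.integer(k), schedule, eps = eps)$x_t
}

#' Build one epoch's training samples (paired + self-conditioned)
#'
#' Every record contributes one sample. A record with an observed follow-up
#' yields the genuine pair: target `i2`, conditioning `i1`. A record without
#' follow-up is self-conditioned: its target is its own baseline `i1` and its
#' conditioning is, with equal probability (`delta ~ Bernoulli(0.5)`), either
#' `i1` itself or a lightly noised copy from [perturb_self()]. The Bernoulli
#' draw and the perturbation noise are redrawn on every call, so each epoch
#' sees a fresh augmentation of the unpaired pool.
#'
#' @param x a normalized `cohort`.
#' @param schedule a [noise_schedule()].
#' @param k perturbation steps for the noised self-conditioning arm
#'   (default 5).
#' @param paired_only if `TRUE`, drop the self-conditioned samples and keep
#'   only records with observed follow-up (the "without self-conditioning"
#'   ablation).
#' @return list of class `training_samples` with matrices `target`,
#'   `cond_features`, `labels` (one row per sample) and logical vectors
#'   `is_self_conditioned`, `was_perturbed`.
#' @export
build_training_samples <- function(x, schedule, k = 5L, paired_only = FALSE) {
  paired <- x$i2_present
  if (paired_only) {
    idx <- which(paired)
    return(structure(list(
      target = x$i2[idx, , drop = FALSE],
      cond_features = x$i1[idx, , drop = FALSE],
      labels = x$labels[idx, , drop = FALSE],
      is_self_conditioned = rep(FALSE, length(idx)),
      was_perturbed = rep(FALSE, length(idx))
    ), class = "training_samples"))
  }

  n <- n_records(x)
  target <- x$i1
  target[paired, ] <- x$i2[paired, , drop = FALSE]
  cond <- x$i1
  delta <- rep(FALSE, n)
  unpaired <- which(!paired)
  if (length(unpaired)) {
    delta[unpaired] <- stats::runif(length(unpaired)) < 0.5
    flip <- which(delta)
    if (length(flip)) {
      cond[flip, ] <- perturb_self(x$i1[flip, , drop = FALSE], schedule, k)
    }
  }
  structure(list(
    target = target, cond_features = cond, labels = x$labels,
    is_self_conditioned = !paired, was_perturbed = delta
  ), class = "training_samples")
}
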