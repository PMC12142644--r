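#' Generate a follow-up feature vector for one patient
#'
#' Full reverse-diffusion sampling conditioned on the patient's baseline
#' features and labels, using the trained denoiser. Deterministic given
#' `(fit, i1, l, seed)`; output is clamped to the data range `[-1, 1]`.
#'
#' @param fit a `diffusion_fit` (or a bare `denoiser_state` with its config
#'   attribute, plus `schedule`).
#' @param i1 normalized baseline vector (length `d`), or a matrix of them.
#' @param l label vector (length `n_labels`), or a matrix of them.
#' @param seed integer seed.
#' @param schedule optional override of the fit's noise schedule.
#' @return generated follow-up vector (or matrix), entries in `[-1, 1]`.
#' @export
generate_followup <- function(fit, i1, l, seed, schedule = NULL) {
  if (inherits(fit, "diffusion_fit")) {
    state <- fit$state; config <- fit$net_config
    schedule <- schedule %||% fit$schedule
  } else {
    state <- fit; config <- attr(state, "config")
    if (is.null(schedule)) rlang::abort("Supply `schedule` for a bare state.")
  }
  d_in <- if (is.matrix(i1)) ncol(i1) else length(i1)
  l_in <- if (is.matrix(l)) ncol(l) else length(l)
  if (d_in != config$d || l_in != config$n_labels) {
    rlang::abort("Conditioning shapes do not match the trained network.")
  }
  diffusion_sample(as_denoiser(state, config, schedule$n_steps),
                   i1, l, schedule, seed = seed, clamp = TRUE)
}

# Stable 31-bit hash of (seed, id) so per-record generation seeds do not
# depend on record order.
record_seed <- function(seed, id) {
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(as.character(id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Enrich a cohort by imputing missing follow-ups
#'
#' Records that already carry a follow-up are returned untouched (bitwise);
#' every record without one receives a generated follow-up, flagged
#' `i2_synthetic`. Per-record seeds are derived by a stable hash of
#' `(seed, patient_id)`, so enrichment is independent of record order and
#' reproducible from the master seed.
#'
#' Labels condition the generation exactly as during training; use this on
#' training-side cohorts only (held-out evaluation records should keep real
#' follow-ups — [downstream_auroc()] enforces that for its test set).
#'
#' @param fit a `diffusion_fit`.
#' @param x a normalized `cohort`.
#' @param seed master integer seed.
#' @return a `cohort` in which every record has a follow-up.
#' @export
enrich_cohort <- function(fit, x, seed) {
  if (!x$normalized) rlang::abort("Cohort must be normalized for enrichment.")
  todo <- which(!x$i2_present)
  if (!length(todo)) return(x)
  y <- x
  for (i in todo) {
    y$i2[i, ] <- generate_followup(fit, x$i1[i, ], x$labels[i, ],
                                   seed = record_seed(seed, x$patient_id[i]))
  }
  y$i2_present[todo] <- TRUE
  y$i2_synthetic[todo] <- TRUE
  colnames(y$i2) <- x$feature_names
  y
}

#' Generate follow-ups for every record of a cohort
#'
#' Convenience wrapper used by the evaluation harness: one seeded generation
#' per record (present follow-ups are NOT reused — every record gets a fresh
#' generation, e.g. to compare against real follow-ups on a test set).
#'
#' @param object a `diffusion_fit`.
#' @param cohort a normalized `cohort`.
#' @param seed master integer seed (per-record seeds derived as in
#'   [enrich_cohort()]).
#' @param ... unused.
#' @return matrix `n_records x d` of generated follow-ups.
#' @export
predict.diffusion_fit <- function(object, cohort, seed = 1L, ...) {
  gen <- matrix(NA_real_, n_records(cohort), n_features(cohort),
                dimnames = list(NULL, cohort$feature_names))
  for (i in seq_len(n_records(cohort))) {
    gen[i, ] <- generate_followup(object, cohort$i1[i, ], cohort$labels[i, ],
                                  seed = record_seed(seed, cohort$patient_id[i]))
  }
  gen
}
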