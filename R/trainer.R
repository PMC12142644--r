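#' Gradient-manipulation policy
#'
#' Whole-update thresholding by L2 gradient norm `G`: updates with
#' `G <= delta_max` pass unchanged; updates with
#' `delta_max < G <= delta_err` are rescaled to norm `delta_max` (direction
#' preserved); updates with `G > delta_err` are treated as erroneous and
#' skipped entirely. In `"calibrated"` mode the thresholds are derived from
#' one preliminary pass over the data ([calibrate_policy()]): `delta_max` is
#' the mean per-batch norm and `delta_err` is `err_multiplier` times the
#' largest. The fixed defaults are `delta_max = 0.3`, `delta_err = 0.75`.
#'
#' @param mode `"fixed"` or `"calibrated"`.
#' @param delta_max clip threshold (maximum allowed update norm).
#' @param delta_err skip threshold; must exceed `delta_max`.
#' @param err_multiplier multiplier on the maximum observed norm in
#'   calibrated mode (default 3).
#' @return object of class `gradient_policy`.
#' @export
gradient_policy <- function(mode = c("fixed", "calibrated"),
                            delta_max = 0.3, delta_err = 0.75,
                            err_multiplier = 3) {
  mode <- match.arg(mode)
  if (!(delta_max > 0 && delta_err > delta_max)) {
    rlang::abort("Need 0 < delta_max < delta_err.")
  }
  structure(list(mode = mode, delta_max = delta_max, delta_err = delta_err,
                 err_multiplier = err_multiplier),
            class = "gradient_policy")
}

#' L2 norm of a full gradient
#'
#' Square root of the sum of squared components over every parameter array —
#' the magnitude of the intended update, direction left untouched.
#'
#' @param grads named list of numeric arrays (as produced by backprop), or a
#'   single numeric vector.
#' @return nonnegative scalar.
#' @export
grad_norm <- function(grads) {
  if (!is.list(grads)) grads <- list(grads)
  ss <- 0
  for (g in grads) {
    if (any(!is.finite(g))) rlang::abort("Non-finite gradient component.")
    ss <- ss + sum(g * g)
  }
  sqrt(ss)
}

#' Clip or skip a gradient update by its norm
#'
#' Implements the three-branch rule of [gradient_policy()]. Scaling applies
#' the same factor `delta_max / G` to every component, so the update
#' direction is exactly preserved; a skipped update is returned as all-zero
#' arrays.
#'
#' @param grads named list of numeric arrays (or a single vector).
#' @param policy a [gradient_policy()].
#' @return list with `grads` (same structure as the input) and `action`
#'   (`"pass"`, `"clip"`, or `"skip"`).
#' @export
clip_or_skip_gradient <- function(grads, policy) {
  vec_in <- !is.list(grads)
  gl <- if (vec_in) list(g = grads) else grads
  G <- grad_norm(gl)
  if (G <= policy$delta_max) {
    action <- "pass"
  } else if (G <= policy$delta_err) {
    gl <- lapply(gl, function(g) g * (policy$delta_max / G))
    action <- "clip"
  } else {
    gl <- lapply(gl, function(g) g * 0)
    action <- "skip"
  }
  list(grads = if (vec_in) gl$g else gl, action = action)
}

#' Calibrate gradient thresholds from one preliminary pass
#'
#' Runs a single epoch of forward/backward passes over the training samples
#' WITHOUT applying any parameter updates, collecting the per-batch L2
#' gradient norms, and returns the policy with `delta_max` set to their mean
#' and `delta_err` to `err_multiplier` times their maximum.
#'
#' @param state a `denoiser_state` (typically freshly initialized).
#' @param samples a `training_samples` object from [build_training_samples()].
#' @param schedule a [noise_schedule()].
#' @param policy a [gradient_policy()] with `mode = "calibrated"`.
#' @param config the matching [denoiser_config()].
#' @param batch_size batch size used for the pass (default 128).
#' @param seed seed for the step/noise draws of the pass.
#' @return the calibrated `gradient_policy` (mode kept as `"calibrated"`),
#'   with the observed norms attached as attribute `"norms"`.
#' @export
calibrate_policy <- function(state, samples, schedule, policy, config,
                             batch_size = 128L, seed = 1L) {
  n <- nrow(samples$target)
  if (n < 1) rlang::abort("No training samples to calibrate on.")
  norms <- withr::with_seed(seed, {
    batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
    vapply(batches, function(idx) {
      gb <- batch_gradients(state, config, schedule, samples, idx)
      grad_norm(gb$grads)
    }, numeric(1))
  })
  out <- gradient_policy("calibrated", delta_max = mean(norms),
                         delta_err = policy$err_multiplier * max(norms),
                         err_multiplier = policy$err_multiplier)
  attr(out, "norms") <- unname(norms)
  out
}

# Forward/backward on one batch: draw a uniform step per sample, noise the
# target, predict the noise from (x_t, t, cond, labels), return MSE loss and
# gradients. Uses the ambient RNG stream.
batch_gradients <- function(state, config, schedule, samples, idx) {
  Xt <- samples$target[idx, , drop = FALSE]
  IS <- samples$cond_features[idx, , drop = FALSE]
  L <- samples$labels[idx, , drop = FALSE]
  tvec <- sample.int(schedule$n_steps, length(idx), replace = TRUE)
  ns <- forward_noise(Xt, tvec, schedule)
  fw <- denoiser_forward(state, config, ns$x_t, tvec, IS, L, schedule$n_steps,
                         cache = TRUE)
  resid <- fw$out - ns$eps
  loss <- mean(resid^2)
  dOut <- 2 * resid / length(resid)
  grads <- denoiser_backward(state, config, fw$cache, dOut)
  list(loss = loss, grads = grads)
}

adam_init <- function(state) {
  list(m = lapply(state, function(p) p * 0),
       v = lapply(state, function(p) p * 0), t = 0L)
}

adam_step <- function(state, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1 ^ opt$t
  b2t <- 1 - beta2 ^ opt$t
  for (nm in names(state)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    state[[nm]] <- state[[nm]] -
      lr * (opt$m[[nm]] / b1t) / (sqrt(opt$v[[nm]] / b2t) + eps)
  }
  list(state = state, opt = opt)
}

#' Training configuration
#'
#' @param epochs maximum training epochs (default 1000).
#' @param patience epochs without validation improvement before stopping
#'   (default 50).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 128).
#' @param seed integer seed governing initialization, epoch shuffles, step
#'   and noise draws, and validation generation.
#' @param self_conditioning include the unpaired pool via self-conditioned
#'   samples (default `TRUE`; `FALSE` gives the paired-only ablation).
#' @param gradient_manipulation apply [clip_or_skip_gradient()] to every
#'   update (default `TRUE`; `FALSE` gives the plain-optimizer ablation).
#' @param k_perturb perturbation steps for self-conditioning (default 5).
#' @param val_subsample maximum longitudinal validation records scored per
#'   epoch (default 400).
#' @param verbose print a line per epoch (default `FALSE`).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, patience = 50L, learning_rate = 0.001,
                         batch_size = 128L, seed = 1L,
                         self_conditioning = TRUE, gradient_manipulation = TRUE,
                         k_perturb = 5L, val_subsample = 400L, verbose = FALSE) {
  if (patience > epochs) rlang::abort("`patience` cannot exceed `epochs`.")
  if (learning_rate <= 0) rlang::abort("`learning_rate` must be positive.")
  structure(list(epochs = as.integer(epochs), patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 self_conditioning = isTRUE(self_conditioning),
                 gradient_manipulation = isTRUE(gradient_manipulation),
                 k_perturb = as.integer(k_perturb),
                 val_subsample = as.integer(val_subsample),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Fit the conditional diffusion model
#'
#' Gradient-manipulated minibatch training with early stopping and
#' validation-based model selection. Each epoch rebuilds the training set
#' (fresh self-conditioning draws), then for every batch draws one uniform
#' step per sample, noises the target, predicts the noise given the
#' conditioning, backpropagates the mean-squared denoising loss, passes the
#' update through [clip_or_skip_gradient()], and takes an Adam step. After
#' each epoch the model generates one seeded follow-up per longitudinal
#' validation record and is scored by the mean per-patient Euclidean distance
#' to the true follow-up; the best-scoring weights are kept, and training
#' stops after `patience` epochs without improvement.
#'
#' @param splits a `cohort_splits` (train and validation used; cohorts must
#'   be normalized). Validation must contain at least one record with real
#'   follow-up.
#' @param net_config a [denoiser_config()] matching the cohort dimensions.
#' @param config a [train_config()].
#' @param policy a [gradient_policy()]; `"calibrated"` mode runs
#'   [calibrate_policy()] on the first epoch's samples before training.
#' @param schedule a [noise_schedule()] (default: the standard 100-step
#'   schedule).
#' @return object of class `diffusion_fit`: list with the selected `state`,
#'   `history` (per-epoch tibble), `best_epoch`, `best_score`, the configs,
#'   the resolved `policy`, and the `schedule`.
#' @export
fit_diffusion <- function(splits, net_config, config = train_config(),
                          policy = gradient_policy(),
                          schedule = noise_schedule()) {
  train <- splits$train
  val <- splits$validation
  if (!train$normalized || !val$normalized) {
    rlang::abort("Training and validation cohorts must be normalized.")
  }
  val_long <- which(val$i2_present)
  if (!length(val_long)) {
    rlang::abort("Validation must contain at least one record with real follow-up.")
  }

  withr::local_seed(config$seed)
  state <- init_denoiser(net_config, seed = config$seed)
  opt <- adam_init(state)

  if (length(val_long) > config$val_subsample) {
    val_long <- sample(val_long, config$val_subsample)
  }
  val_is <- val$i1[val_long, , drop = FALSE]
  val_l <- val$labels[val_long, , drop = FALSE]
  val_i2 <- val$i2[val_long, , drop = FALSE]
  gen_seed <- (config$seed + 1L) %% 2147483647L

  if (policy$mode == "calibrated") {
    cal_samples <- build_training_samples(train, schedule, config$k_perturb,
                                          paired_only = !config$self_conditioning)
    policy <- calibrate_policy(state, cal_samples, schedule, policy, net_config,
                               config$batch_size,
                               seed = (config$seed + 2L) %% 2147483647L)
  }

  hist <- vector("list", config$epochs)
  best_score <- Inf; best_state <- state; best_epoch <- 0L; stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    samples <- build_training_samples(train, schedule, config$k_perturb,
                                      paired_only = !config$self_conditioning)
    n <- nrow(samples$target)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    losses <- numeric(length(batches))
    norms <- numeric(length(batches))
    n_clip <- 0L; n_skip <- 0L
    for (b in seq_along(batches)) {
      gb <- batch_gradients(state, net_config, schedule, samples, batches[[b]])
      losses[b] <- gb$loss
      norms[b] <- grad_norm(gb$grads)
      g <- gb$grads
      if (config$gradient_manipulation) {
        cs <- clip_or_skip_gradient(g, policy)
        if (cs$action == "skip") { n_skip <- n_skip + 1L; next }
        if (cs$action == "clip") n_clip <- n_clip + 1L
        g <- cs$grads
      }
      st <- adam_step(state, g, opt, config$learning_rate)
      state <- st$state; opt <- st$opt
    }

    gen <- diffusion_sample(as_denoiser(state, net_config, schedule$n_steps),
                            val_is, val_l, schedule, seed = gen_seed)
    score <- mean(sqrt(rowSums((gen - val_i2)^2)))

    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(losses), val_score = score,
      n_clipped = n_clip, n_skipped = n_skip,
      mean_grad_norm = mean(norms), max_grad_norm = max(norms),
      n_samples = n, n_self = sum(samples$is_self_conditioned),
      n_perturbed = sum(samples$was_perturbed)
    )
    if (config$verbose) {
      message(sprintf("epoch %d: loss %.5f val %.4f (clip %d skip %d)",
                      epoch, mean(losses), score, n_clip, n_skip))
    }

    if (score < best_score) {
      best_score <- score; best_state <- state; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  structure(list(state = best_state, history = dplyr::bind_rows(hist),
                 best_epoch = best_epoch, best_score = best_score,
                 net_config = net_config, train_config = config,
                 policy = policy, schedule = schedule),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> d=%d, %d params; %d epochs run, best epoch %d (val %.4f)\n",
    x$net_config$d, n_params(x$state), nrow(x$history), x$best_epoch,
    x$best_score))
  invisible(x)
}
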