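#' Discrete linear noise schedule
#'
#' Defines the forward noising process over `T` discrete steps: `beta_t` is
#' linearly spaced between `beta_start` and `beta_end` (both endpoints
#' included), `alpha_t = 1 - beta_t`, and `alpha_bar_t` is the cumulative
#' product of the first `t` alphas — the signal-retention factor after `t`
#' steps. Step indexing is 1-based, `t` in `1..T`.
#'
#' @param n_steps number of diffusion steps `T` (default 100).
#' @param beta_start,beta_end endpoints of the linear beta spacing
#'   (defaults 0.0015 and 0.02).
#' @return An object of class `noise_schedule`: list with `n_steps`, `beta`,
#'   `alpha`, `alpha_bar`, `beta_start`, `beta_end`.
#' @examples
#' sch <- noise_schedule()
#' sch$beta[1]        # 0.0015
#' sch$alpha_bar[100] # ~0.34
#' @export
noise_schedule <- function(n_steps = 100L, beta_start = 0.0015, beta_end = 0.02) {
  if (!(beta_start > 0 && beta_start < beta_end && beta_end < 1)) {
    rlang::abort("Need 0 < beta_start < beta_end < 1.")
  }
  if (n_steps < 2) rlang::abort("Need at least 2 diffusion steps.")
  beta <- seq(beta_start, beta_end, length.out = n_steps)
  alpha <- 1 - beta
  structure(
    list(n_steps = as.integer(n_steps), beta = beta, alpha = alpha,
         alpha_bar = cumprod(alpha),
         beta_start = beta_start, beta_end = beta_end),
    class = "noise_schedule"
  )
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> T=%d, beta in [%g, %g], alpha_bar_T=%.4f\n",
              x$n_steps, x$beta_start, x$beta_end, x$alpha_bar[x$n_steps]))
  invisible(x)
}

#' Serialize / restore a noise schedule (JSON)
#'
#' Only the three defining parameters are stored; the arrays are rebuilt on
#' load, so checkpoints stay exactly reproducible.
#' @param x a `noise_schedule`.
#' @param path JSON file path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `noise_schedule`.
#' @export
write_schedule <- function(x, path) {
  jsonlite::write_json(
    list(n_steps = x$n_steps, beta_start = x$beta_start, beta_end = x$beta_end),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  noise_schedule(p$n_steps, p$beta_start, p$beta_end)
}

check_step <- function(t, schedule) {
  if (any(t < 1L) || any(t > schedule$n_steps)) {
    rlang::abort(sprintf("Step index out of range 1..%d.", schedule$n_steps))
  }
  as.integer(t)
}

#' Forward noising of clean vectors
#'
#' Draws `eps ~ N(0, I)` and returns
#' `x_t = sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps`, the
#' closed-form marginal of the iterative noising process after `t` steps.
#'
#' @param x0 numeric vector, or matrix with one row per sample.
#' @param t step index in `1..T`; scalar, or one per row of a matrix `x0`.
#' @param schedule a `noise_schedule`.
#' @param eps optional noise to use instead of a fresh Gaussian draw (same
#'   shape as `x0`); used for deterministic checks.
#' @return list of class `noised_sample`: `x_t`, `t`, `eps`.
#' @export
forward_noise <- function(x0, t, schedule, eps = NULL) {
  t <- check_step(t, schedule)
  x0m <- if (is.matrix(x0)) x0 else matrix(x0, nrow = 1)
  if (length(t) == 1L) t <- rep(t, nrow(x0m))
  if (length(t) != nrow(x0m)) rlang::abort("`t` must be scalar or one per row.")
  if (is.null(eps)) {
    eps <- matrix(stats::rnorm(length(x0m)), nrow(x0m), ncol(x0m))
  } else {
    eps <- if (is.matrix(eps)) eps else matrix(eps, nrow = 1)
    stopifnot(all(dim(eps) == dim(x0m)))
  }
  ab <- schedule$alpha_bar[t]
  x_t <- sqrt(ab) * x0m + sqrt(1 - ab) * eps
  if (!is.matrix(x0)) { x_t <- drop(x_t); eps <- drop(eps) }
  structure(list(x_t = x_t, t = t, eps = eps), class = "noised_sample")
}

#' Denoising training loss
#'
#' Mean squared difference between the true noise drawn by [forward_noise()]
#' and the noise predicted by the denoiser, averaged over all coordinates.
#'
#' @param eps_true,eps_pred numeric vectors or matrices of equal shape.
#' @return nonnegative scalar.
#' @export
denoising_loss <- function(eps_true, eps_pred) {
  if (length(eps_true) != length(eps_pred)) {
    rlang::abort("Noise vectors have mismatched lengths.")
  }
  mean((eps_true - eps_pred)^2)
}

#' One ancestral reverse-diffusion step
#'
#' Standard DDPM update: the posterior mean
#' `(x_t - beta_t / sqrt(1 - alpha_bar_t) * eps_pred) / sqrt(alpha_t)`,
#' plus injected noise `sqrt(beta_t) * z` with `z ~ N(0, I)` for `t > 1`.
#' No noise is injected at the final step `t = 1` (the reverse-process
#' variance is `beta_t`, the simpler standard choice).
#'
#' @param x_t current state (vector, or matrix with one row per sample).
#' @param t step index in `1..T` (scalar; the whole batch shares a step
#'   during sampling).
#' @param eps_pred predicted noise, same shape as `x_t`.
#' @param schedule a `noise_schedule`.
#' @param z optional injected standard-normal noise (for deterministic
#'   checks); ignored at `t = 1`.
#' @return the state at step `t - 1`, same shape as `x_t`.
#' @export
reverse_step <- function(x_t, t, eps_pred, schedule, z = NULL) {
  t <- check_step(t, schedule)
  stopifnot(length(t) == 1L)
  mean_t <- (x_t - schedule$beta[t] / sqrt(1 - schedule$alpha_bar[t]) * eps_pred) /
    sqrt(schedule$alpha[t])
  if (t == 1L) return(mean_t)
  if (is.null(z)) {
    z <- if (is.matrix(x_t)) matrix(stats::rnorm(length(x_t)), nrow(x_t), ncol(x_t))
         else stats::rnorm(length(x_t))
  }
  mean_t + sqrt(schedule$beta[t]) * z
}

#' Draw conditional samples by full reverse diffusion
#'
#' Starts from pure Gaussian noise and runs the ancestral reverse chain for
#' `t = T..1`, feeding the conditioning (baseline features and labels) to the
#' denoiser at every step. The result is a pure function of the denoiser
#' weights, the conditioning, and `seed`.
#'
#' With `clamp = TRUE` (the default), each step applies static thresholding:
#' the implied clean vector `x0_hat = (x_t - sqrt(1 - alpha_bar_t) *
#' eps_hat) / sqrt(alpha_bar_t)` is clipped to the data range `[-1, 1]`
#' before forming the posterior mean (algebraically identical to
#' [reverse_step()] whenever `x0_hat` is already in range). This keeps the
#' chain anchored to the domain the data live on and markedly reduces drift
#' accumulated from imperfect noise predictions; the final output is clipped
#' as well. With `clamp = FALSE` the plain unclipped update is used.
#'
#' @param denoiser function `(x_t, t, i_s, l) -> eps_hat` operating on
#'   matrices with one row per sample (see [predict_noise()]).
#' @param i_s conditioning feature matrix (`n x d`) or single vector.
#' @param l conditioning label matrix (`n x n_l`) or single vector.
#' @param schedule a `noise_schedule`.
#' @param seed integer seed governing the initial noise and every injected
#'   noise; the caller's RNG state is left untouched.
#' @param clamp apply per-step static thresholding and clip the final output
#'   to `[-1, 1]` (default `TRUE`). The noisy intermediate states themselves
#'   are never clipped.
#' @return matrix `n x d` of sampled vectors (or a vector if `i_s` was one).
#' @export
diffusion_sample <- function(denoiser, i_s, l, schedule, seed, clamp = TRUE) {
  vec_in <- !is.matrix(i_s)
  i_s <- if (vec_in) matrix(i_s, nrow = 1) else i_s
  if (!is.matrix(l)) {
    l <- matrix(l, nrow = nrow(i_s), ncol = length(l), byrow = TRUE)
  }
  if (nrow(l) != nrow(i_s)) rlang::abort("Conditioning row counts differ.")
  n <- nrow(i_s); d <- ncol(i_s)
  x <- withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    for (t in rev(seq_len(schedule$n_steps))) {
      eps_hat <- denoiser(x, t, i_s, l)
      if (!is.matrix(eps_hat) || !all(dim(eps_hat) == c(n, d))) {
        rlang::abort("Denoiser output shape mismatch.")
      }
      if (clamp) {
        ab <- schedule$alpha_bar[t]
        ab_prev <- if (t > 1) schedule$alpha_bar[t - 1] else 1
        x0_hat <- pmin(pmax((x - sqrt(1 - ab) * eps_hat) / sqrt(ab), -1), 1)
        mean_t <- (sqrt(ab_prev) * schedule$beta[t] * x0_hat +
                     sqrt(schedule$alpha[t]) * (1 - ab_prev) * x) / (1 - ab)
        x <- if (t > 1) {
          mean_t + sqrt(schedule$beta[t]) * matrix(stats::rnorm(n * d), n, d)
        } else mean_t
      } else {
        x <- reverse_step(x, t, eps_hat, schedule)
      }
    }
    x
  })
  if (clamp) x <- pmin(pmax(x, -1), 1)
  if (vec_in) drop(x) else x
}
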