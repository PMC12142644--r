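#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the training history of a fitted diffusion model
#'
#' One row per completed epoch: mean training loss, validation selection
#' score (mean per-patient Euclidean distance of seeded generations to the
#' true follow-ups), clip/skip counts, and gradient-norm summaries.
#'
#' @param x a `diffusion_fit`.
#' @param ... unused.
#' @return a tibble with one row per epoch.
#' @export
tidy.diffusion_fit <- function(x, ...) x$history

#' One-row summary of a fitted diffusion model
#'
#' @param x a `diffusion_fit`.
#' @param ... unused.
#' @return tibble: parameter count, epochs run, best epoch and score, total
#'   clipped and skipped updates, and the resolved gradient thresholds.
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    n_params = n_params(x$state),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_score = x$best_score,
    total_clipped = sum(x$history$n_clipped),
    total_skipped = sum(x$history$n_skipped),
    delta_max = x$policy$delta_max,
    delta_err = x$policy$delta_err,
    self_conditioning = x$train_config$self_conditioning,
    gradient_manipulation = x$train_config$gradient_manipulation)
}

#' Plot the training history of a fitted diffusion model
#'
#' Training loss and validation selection score per epoch, with the selected
#' epoch marked.
#'
#' @param object a `diffusion_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.diffusion_fit <- function(object, ...) {
  h <- object$history |>
    dplyr::select("epoch", "train_loss", "val_score") |>
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "value") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
                                         train_loss = "training loss",
                                         val_score = "validation distance"))
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Diffusion training history",
                  subtitle = sprintf("selected epoch %d", object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap comparison of real vs generated feature correlation matrices
#'
#' @param real,generated matrices `n x d` of follow-up vectors.
#' @return a ggplot object with one tile panel per source.
#' @export
plot_correlation_matrices <- function(real, generated) {
  melt <- function(m, nm) {
    C <- stats::cor(m)
    tibble::tibble(row = rep(seq_len(nrow(C)), ncol(C)),
                   col = rep(seq_len(ncol(C)), each = nrow(C)),
                   r = as.vector(C), source = nm)
  }
  df <- dplyr::bind_rows(melt(real, "real"), melt(generated, "generated"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~source) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Covariate correlation structure") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL

#' Save / load a fitted model checkpoint (JSON, text-only)
#'
#' Bundles the denoiser weights, network configuration, schedule parameters
#' and training configuration into one JSON file, so a fit can be restored
#' without binary serialization.
#'
#' @param fit a `diffusion_fit`.
#' @param path JSON file path.
#' @return `write_checkpoint()` returns `path` invisibly; `read_checkpoint()`
#'   returns a `diffusion_fit` (history reduced to what was saved).
#' @export
write_checkpoint <- function(fit, path) {
  ck <- list(
    net_config = unclass(fit$net_config),
    schedule = list(n_steps = fit$schedule$n_steps,
                    beta_start = fit$schedule$beta_start,
                    beta_end = fit$schedule$beta_end),
    train_config = unclass(fit$train_config),
    policy = unclass(fit$policy),
    best_epoch = fit$best_epoch, best_score = fit$best_score,
    state = lapply(fit$state, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = NULL, data = as.vector(p))
    }),
    history = as.list(fit$history))
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(denoiser_config,
                 ck$net_config[c("d", "n_labels", "down_sizes", "n_residual",
                                 "up_sizes", "embed_dim")])
  state <- lapply(ck$state, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  class(state) <- "denoiser_state"
  attr(state, "config") <- cfg
  tc <- ck$train_config
  structure(list(
    state = state,
    history = tibble::as_tibble(ck$history),
    best_epoch = ck$best_epoch, best_score = ck$best_score,
    net_config = cfg,
    train_config = train_config(tc$epochs, tc$patience, tc$learning_rate,
                                tc$batch_size, tc$seed, tc$self_conditioning,
                                tc$gradient_manipulation, tc$k_perturb,
                                tc$val_subsample),
    policy = gradient_policy(ck$policy$mode, ck$policy$delta_max,
                             ck$policy$delta_err, ck$policy$err_multiplier),
    schedule = noise_schedule(ck$schedule$n_steps, ck$schedule$beta_start,
                              ck$schedule$beta_end)),
    class = "diffusion_fit")
}
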