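test_that("gradient norm is the L2 norm over all parameter arrays", {
  expect_equal(grad_norm(c(3, 4)), 5)
  expect_equal(grad_norm(list(a = matrix(0, 2, 2), b = numeric(3))), 0)
  expect_equal(grad_norm(list(g = -2.5)), 2.5)
  expect_equal(grad_norm(list(a = matrix(c(1, 2), 1), b = c(2, 4))), 5)
  expect_error(grad_norm(list(a = c(1, NaN))), "finite")
})

test_that("clip-or-skip implements the three branches exactly", {
  pol <- gradient_policy("fixed", 0.3, 0.75)

  r1 <- clip_or_skip_gradient(c(0.1, 0.2), pol)   # G ~ 0.224 <= 0.3
  expect_equal(r1$action, "pass")
  expect_identical(r1$grads, c(0.1, 0.2))

  r2 <- clip_or_skip_gradient(c(0.3, 0.4), pol)   # G = 0.5, rescale to 0.3
  expect_equal(r2$action, "clip")
  expect_equal(r2$grads, c(0.18, 0.24))
  expect_equal(grad_norm(r2$grads), 0.3)

  r3 <- clip_or_skip_gradient(c(0.6, 0.8), pol)   # G = 1 > 0.75, skip
  expect_equal(r3$action, "skip")
  expect_identical(r3$grads, c(0, 0))

  expect_error(gradient_policy(delta_max = 0.8, delta_err = 0.75), "delta")
})

test_that("clipping preserves direction and caps norms (property)", {
  withr::with_seed(14, {
    for (rep in 1:500) {
      g <- list(a = matrix(rnorm(6, sd = runif(1, 0.01, 2)), 2, 3),
                b = rnorm(4, sd = runif(1, 0.01, 2)))
      dm <- runif(1, 0.05, 1)
      pol <- gradient_policy("fixed", dm, dm * runif(1, 1.5, 4))
      out <- clip_or_skip_gradient(g, pol)$grads
      Gout <- grad_norm(out)
      expect_true(Gout <= pol$delta_max + 1e-12 || Gout == 0)
      if (grad_norm(g) > pol$delta_max && grad_norm(g) <= pol$delta_err) {
        vin <- c(as.vector(g$a), g$b); vout <- c(as.vector(out$a), out$b)
        cosine <- sum(vin * vout) / sqrt(sum(vin^2) * sum(vout^2))
        expect_gt(cosine, 1 - 1e-9)
      }
    }
  })
})

test_that("threshold calibration takes mean and multiplier-times-max of a dry pass", {
  sch <- noise_schedule()
  co <- normalize_cohort(toy_cohort(n = 30, d = 8, n_paired = 10, seed = 3))
  cfg <- toy_net()
  st <- init_denoiser(cfg, seed = 1)
  s <- withr::with_seed(1, build_training_samples(co, sch))
  pol <- calibrate_policy(st, s, sch, gradient_policy("calibrated"), cfg,
                          batch_size = 8L, seed = 11)
  norms <- attr(pol, "norms")
  expect_length(norms, 4)          # 30 samples in batches of 8
  expect_equal(pol$delta_max, mean(norms))
  expect_equal(pol$delta_err, 3 * max(norms))
  expect_lt(pol$delta_max, pol$delta_err)
  # the dry pass must not touch the weights (pure readout)
  expect_identical(st, init_denoiser(cfg, seed = 1))
})

make_splits <- function(n = 60, d = 8, n_paired = 24, seed = 5) {
  co <- normalize_cohort(toy_cohort(n = n, d = d, n_paired = n_paired,
                                    seed = seed))
  split_cohort(co, test_frac = 0.2, val_frac = 0.2, seed = seed)
}

test_that("an all-skip policy leaves the parameters at initialization", {
  sp <- make_splits()
  cfg <- toy_net()
  tc <- train_config(epochs = 3, patience = 3, seed = 9, batch_size = 16)
  fit <- fit_diffusion(sp, cfg, tc, gradient_policy("fixed", 1e-13, 1e-12))
  expect_identical(fit$state, init_denoiser(cfg, seed = 9))
  expect_equal(sum(fit$history$n_skipped),
               sum(fit$history$n_skipped + fit$history$n_clipped))
  expect_true(all(fit$history$n_skipped > 0))
})

test_that("early stopping halts after `patience` stale epochs", {
  sp <- make_splits()
  cfg <- toy_net()
  # all updates skipped -> validation score frozen after epoch 1
  fit <- fit_diffusion(sp, cfg,
                       train_config(epochs = 50, patience = 4, seed = 2,
                                    batch_size = 16),
                       gradient_policy("fixed", 1e-13, 1e-12))
  expect_equal(nrow(fit$history), 1 + 4)
  expect_equal(fit$best_epoch, 1)
})

test_that("a short seeded run reduces the training loss", {
  sp <- make_splits(n = 120, d = 8, n_paired = 60, seed = 8)
  cfg <- toy_net()
  fit <- fit_diffusion(sp, cfg,
                       train_config(epochs = 40, patience = 40, seed = 3,
                                    batch_size = 32),
                       gradient_policy("fixed", 0.3, 0.75))
  h <- fit$history
  expect_lt(median(h$train_loss[31:40]), median(h$train_loss[1:10]))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})

test_that("ablation flags change exactly the expected training components", {
  sp <- make_splits(n = 50, d = 8, n_paired = 20, seed = 4)
  cfg <- toy_net()
  base_tc <- function(...) train_config(epochs = 2, patience = 2, seed = 6,
                                        batch_size = 16, ...)
  full <- fit_diffusion(sp, cfg, base_tc())
  no_self <- fit_diffusion(sp, cfg, base_tc(self_conditioning = FALSE))
  no_grad <- fit_diffusion(sp, cfg, base_tc(gradient_manipulation = FALSE))

  # without self-conditioning only paired records are trained on
  n_paired_train <- sum(sp$train$i2_present)
  expect_true(all(no_self$history$n_samples == n_paired_train))
  expect_true(all(no_self$history$n_self == 0))
  expect_true(all(full$history$n_samples == n_records(sp$train)))
  expect_true(all(full$history$n_self ==
                    n_records(sp$train) - n_paired_train))
  # without gradient manipulation no update is ever clipped or skipped
  expect_true(all(no_grad$history$n_clipped == 0))
  expect_true(all(no_grad$history$n_skipped == 0))
})

test_that("training is reproducible from its seed", {
  sp <- make_splits(n = 40, d = 8, n_paired = 16, seed = 12)
  cfg <- toy_net()
  tc <- train_config(epochs = 2, patience = 2, seed = 21, batch_size = 16)
  f1 <- fit_diffusion(sp, cfg, tc)
  f2 <- fit_diffusion(sp, cfg, tc)
  expect_identical(f1$state, f2$state)
  expect_identical(f1$history, f2$history)
})

test_that("checkpoints round-trip weights and configuration through JSON", {
  sp <- make_splits(n = 30, d = 8, n_paired = 12, seed = 13)
  cfg <- toy_net()
  fit <- fit_diffusion(sp, cfg, train_config(epochs = 1, patience = 1,
                                             seed = 5, batch_size = 16))
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit, path)
  back <- read_checkpoint(path)
  expect_equal(back$state, fit$state, ignore_attr = TRUE, tolerance = 1e-12)
  i1 <- sp$test$i1[1, ]; l <- sp$test$labels[1, ]
  expect_equal(generate_followup(back, i1, l, seed = 3),
               generate_followup(fit, i1, l, seed = 3), tolerance = 1e-9)
})
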