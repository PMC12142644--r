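# Small in-code fixtures shared across test files.

# A tiny raw-scale cohort: n records, d features, first `n_paired` records
# carry a follow-up. Values are reproducible given `seed`.
toy_cohort <- function(n = 10, d = 4, n_paired = 4, n_labels = 2, seed = 1) {
  withr::with_seed(seed, {
    i1 <- matrix(rnorm(n * d, mean = 20, sd = 5), n, d)
    i2 <- matrix(NA_real_, n, d)
    if (n_paired > 0) {
      i2[seq_len(n_paired), ] <- i1[seq_len(n_paired), ] + rnorm(n_paired * d)
    }
    labels <- matrix(rbinom(n * n_labels, 1, 0.5), n, n_labels)
    cohort(i1, labels, i2 = i2,
           i2_present = seq_len(n) <= n_paired,
           feature_names = paste0("f", seq_len(d)),
           label_names = paste0("l", seq_len(n_labels)))
  })
}

# A small denoiser configuration that keeps forward/backward passes fast.
toy_net <- function(d = 8, n_labels = 2) {
  denoiser_config(d, n_labels, down_sizes = c(16L, 12L, 8L), embed_dim = 8L)
}

# CSV text for a 3-record cohort with 2 features, 1 label, one record
# lacking follow-up.
toy_csv <- function(path) {
  writeLines(c(
    "patient_id,f1,f2,f1_fu,f2_fu,age",
    "A,1.0,2.0,1.5,2.5,60",
    "B,3.0,4.0,,,70",
    "C,5.0,6.0,5.5,6.5,80"), path)
  path
}

toy_schema <- list(id = "patient_id", features = c("f1", "f2"), labels = "age")

# A cohort with a binary task label that (optionally) drives a large
# follow-up shift, for downstream-classifier checks.
make_task_cohort <- function(n, d = 6, informative = TRUE, seed = 1) {
  withr::with_seed(seed, {
    i1 <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, 0.4)
    i2 <- i1
    if (informative) i2[, 1:3] <- i2[, 1:3] - 2 * y  # large follow-up shift
    i2 <- i2 + 0.1 * matrix(rnorm(n * d), n, d)
    labels <- cbind(task = y, other = rbinom(n, 1, 0.5))
    co <- cohort(i1, labels, i2 = i2, label_names = c("task", "other"))
    co$normalized <- TRUE
    co
  })
}
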