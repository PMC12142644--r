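#' Per-patient similarity between real and generated feature vectors
#'
#' For each patient, computes the Pearson correlation across the `d`
#' coordinates of the real and generated vectors, their Euclidean distance,
#' and the cosine distance (1 - cosine similarity), then averages each over
#' patients. Degenerate patients (zero-variance vector for Pearson,
#' zero-norm vector for cosine) are excluded from the affected mean and
#' counted in the exclusion tallies rather than silently scored.
#'
#' @param real,generated numeric matrices `n x d`, one row per patient.
#' @return one-row tibble: `mean_pearson`, `mean_euclidean`,
#'   `mean_cosine_distance`, `n`, `n_excluded_pearson`, `n_excluded_cosine`.
#' @export
paired_similarity <- function(real, generated) {
  stopifnot(is.matrix(real), is.matrix(generated),
            all(dim(real) == dim(generated)), ncol(real) >= 2, nrow(real) >= 1)
  n <- nrow(real)
  pear <- numeric(n); cosd <- numeric(n)
  ok_p <- logical(n); ok_c <- logical(n)
  for (i in seq_len(n)) {
    a <- real[i, ]; b <- generated[i, ]
    if (stats::sd(a) > 0 && stats::sd(b) > 0) {
      pear[i] <- stats::cor(a, b); ok_p[i] <- TRUE
    }
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na > 0 && nb > 0) {
      cosd[i] <- 1 - sum(a * b) / (na * nb); ok_c[i] <- TRUE
    }
  }
  eucl <- sqrt(rowSums((real - generated)^2))
  tibble::tibble(
    mean_pearson = if (any(ok_p)) mean(pear[ok_p]) else NA_real_,
    mean_euclidean = mean(eucl),
    mean_cosine_distance = if (any(ok_c)) mean(cosd[ok_c]) else NA_real_,
    n = n, n_excluded_pearson = sum(!ok_p), n_excluded_cosine = sum(!ok_c))
}

# Symmetric PSD square root via eigendecomposition, clipping tiny negative
# eigenvalues from floating error.
sqrtm_sym <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two feature-vector samples
#'
#' The 2-Wasserstein distance between Gaussians fitted to the two samples:
#' `||mu_a - mu_b||^2 + tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, with the matrix
#' square root computed as `S_a^{1/2} (S_a^{1/2} S_b S_a^{1/2})^{1/2}
#' S_a^{-1/2}` via symmetric eigendecompositions — the usual
#' Frechet-inception-distance recipe with feature vectors in place of network
#' embeddings. A small diagonal jitter (`1e-6`) regularizes rank-deficient
#' covariances (e.g. when `n <= d`).
#'
#' @param set_a,set_b numeric matrices `n x d` and `m x d` (`n, m >= 2`).
#' @return nonnegative scalar.
#' @export
frechet_distance <- function(set_a, set_b) {
  stopifnot(is.matrix(set_a), is.matrix(set_b), ncol(set_a) == ncol(set_b))
  if (nrow(set_a) < 2 || nrow(set_b) < 2) {
    rlang::abort("Need at least 2 vectors per set to fit a covariance.")
  }
  mu_a <- colMeans(set_a); mu_b <- colMeans(set_b)
  jit <- 1e-6 * diag(ncol(set_a))
  S_a <- stats::cov(set_a) + jit
  S_b <- stats::cov(set_b) + jit
  Ra <- sqrtm_sym(S_a)
  inner <- sqrtm_sym(Ra %*% S_b %*% Ra)
  covmean_trace <- sum(diag(inner))
  val <- sum((mu_a - mu_b)^2) + sum(diag(S_a)) + sum(diag(S_b)) -
    2 * covmean_trace
  max(val, 0)
}

#' Correlation between per-feature mean profiles
#'
#' Pearson correlation between the two length-`d` vectors of per-feature
#' means — a check that generated data reproduce the marginal scale of each
#' feature.
#'
#' @param set_a,set_b numeric matrices with the same number of columns
#'   (`d >= 3`).
#' @return scalar in `[-1, 1]` (`NA` if either mean profile is constant).
#' @export
mean_correlation <- function(set_a, set_b) {
  stopifnot(ncol(set_a) == ncol(set_b), ncol(set_a) >= 3)
  ma <- colMeans(set_a); mb <- colMeans(set_b)
  if (stats::sd(ma) == 0 || stats::sd(mb) == 0) return(NA_real_)
  stats::cor(ma, mb)
}

#' Covariate-correlation similarity between two feature samples
#'
#' Mean absolute elementwise difference between the two `d x d` Pearson
#' correlation matrices, over off-diagonal entries only. 0 means identical
#' correlation structure. Constant features (undefined correlations) are
#' dropped from both matrices and reported via the `n_dropped` attribute.
#'
#' @param set_a,set_b numeric matrices `n x d` (`n >= 3`).
#' @return nonnegative scalar.
#' @export
covariate_similarity <- function(set_a, set_b) {
  stopifnot(ncol(set_a) == ncol(set_b), nrow(set_a) >= 3, nrow(set_b) >= 3)
  keep <- apply(set_a, 2, stats::sd) > 0 & apply(set_b, 2, stats::sd) > 0
  if (sum(keep) < 2) rlang::abort("Fewer than 2 non-constant shared features.")
  Ca <- stats::cor(set_a[, keep, drop = FALSE])
  Cb <- stats::cor(set_b[, keep, drop = FALSE])
  off <- row(Ca) != col(Ca)
  out <- mean(abs(Ca - Cb)[off])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Correlation matrices behind the covariate similarity
#' @param x a `cohort` with follow-ups present.
#' @return `d x d` Pearson correlation matrix of the follow-up features.
#' @export
followup_correlation <- function(x) {
  stats::cor(x$i2[x$i2_present, , drop = FALSE])
}

#' Rank-based AUROC
#' @param scores numeric classifier scores.
#' @param labels binary 0/1 labels (both classes present).
#' @return area under the ROC curve in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) rlang::abort("AUROC undefined: single-class labels.")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---- small MLP binary classifier (Adam, early stopping) -------------------

mlp_init <- function(sizes, seed) {
  withr::with_seed(seed, {
    p <- list()
    for (k in seq_len(length(sizes) - 1)) {
      p[[paste0("W", k)]] <- rand_mat(sizes[k], sizes[k + 1])
      p[[paste0("b", k)]] <- numeric(sizes[k + 1])
    }
    p
  })
}

mlp_logits <- function(p, X) {
  L <- length(p) / 2
  H <- X
  for (k in seq_len(L - 1)) {
    H <- pmax(add_bias(H %*% p[[paste0("W", k)]], p[[paste0("b", k)]]), 0)
  }
  drop(add_bias(H %*% p[[paste0("W", L)]], p[[paste0("b", L)]]))
}

mlp_grad <- function(p, X, y) {
  L <- length(p) / 2
  hs <- list(X)
  for (k in seq_len(L - 1)) {
    hs[[k + 1]] <- pmax(add_bias(hs[[k]] %*% p[[paste0("W", k)]],
                                 p[[paste0("b", k)]]), 0)
  }
  z <- drop(add_bias(hs[[L]] %*% p[[paste0("W", L)]], p[[paste0("b", L)]]))
  prob <- stats::plogis(z)
  loss <- mean(-y * log(pmax(prob, 1e-12)) - (1 - y) * log(pmax(1 - prob, 1e-12)))
  dz <- matrix((prob - y) / length(y), ncol = 1)
  g <- list()
  dH <- dz
  for (k in rev(seq_len(L))) {
    g[[paste0("W", k)]] <- t(hs[[k]]) %*% dH
    g[[paste0("b", k)]] <- colSums(dH)
    if (k > 1) {
      dH <- (dH %*% t(p[[paste0("W", k)]])) * (hs[[k]] > 0)
    }
  }
  list(loss = loss, grads = g)
}

train_mlp <- function(X, y, hidden = 256L, lr = 0.001, batch_size = 128L,
                      patience = 5L, max_epochs = 100L, seed = 1L) {
  withr::with_seed(seed, {
    n <- nrow(X)
    val_idx <- sample.int(n, max(1L, ceiling(0.1 * n)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    p <- mlp_init(c(ncol(X), hidden, hidden, 1L), seed = sample.int(2^31 - 1, 1))
    opt <- adam_init(p)
    best <- Inf; best_p <- p; stall <- 0L
    for (ep in seq_len(max_epochs)) {
      ord <- sample(tr_idx)
      for (idx in split(ord, ceiling(seq_along(ord) / batch_size))) {
        gb <- mlp_grad(p, X[idx, , drop = FALSE], y[idx])
        st <- adam_step(p, gb$grads, opt, lr)
        p <- st$state; opt <- st$opt
      }
      zv <- mlp_logits(p, X[val_idx, , drop = FALSE])
      pv <- stats::plogis(zv)
      vloss <- mean(-y[val_idx] * log(pmax(pv, 1e-12)) -
                      (1 - y[val_idx]) * log(pmax(1 - pv, 1e-12)))
      if (vloss < best) { best <- vloss; best_p <- p; stall <- 0L }
      else { stall <- stall + 1L; if (stall >= patience) break }
    }
    best_p
  })
}

#' Downstream classification utility of a (possibly enriched) cohort
#'
#' Trains a three-layer neural network (two hidden layers of width `hidden`,
#' ReLU, Adam at learning rate 0.001, batch size 128, early stopping with
#' patience 5 on an internal 10% validation split) to predict a binary task
#' label, and reports the rank-based AUROC on the test cohort. The feature
#' vector is `[i1; i2; labels minus the task label]`; with
#' `features = "baseline_only"` it is `[i1; labels minus the task label]`
#' (the "all first" naive mode — every record is used regardless of
#' follow-up). In the default mode only records with a follow-up enter
#' training, so passing an unenriched cohort gives the "limited paired"
#' naive mode and passing an enriched cohort gives the imputation mode.
#'
#' @param train a `cohort` used for training (enriched, paired-only, or any).
#' @param test a `cohort` whose records all carry REAL follow-ups.
#' @param task_label name of a binary label column.
#' @param seed integer seed.
#' @param features `"followup"` (default) or `"baseline_only"`.
#' @param hidden hidden width (default 256).
#' @param max_epochs training-epoch cap (default 100).
#' @return scalar AUROC in `[0, 1]`.
#' @export
downstream_auroc <- function(train, test, task_label, seed = 1L,
                             features = c("followup", "baseline_only"),
                             hidden = 256L, max_epochs = 100L) {
  features <- match.arg(features)
  j <- match(task_label, train$label_names)
  if (is.na(j)) rlang::abort(sprintf("Unknown task label '%s'.", task_label))
  if (features == "followup" && any(test$i2_synthetic)) {
    rlang::abort("Test cohort contains synthetic follow-ups; evaluation requires real ones.")
  }

  build <- function(co, need_i2) {
    keep <- if (need_i2) co$i2_present else rep(TRUE, n_records(co))
    X <- if (need_i2) {
      cbind(co$i1[keep, , drop = FALSE], co$i2[keep, , drop = FALSE],
            co$labels[keep, -j, drop = FALSE])
    } else {
      cbind(co$i1[keep, , drop = FALSE], co$labels[keep, -j, drop = FALSE])
    }
    list(X = X, y = co$labels[keep, j])
  }
  need_i2 <- features == "followup"
  tr <- build(train, need_i2)
  te <- build(test, need_i2)
  if (length(unique(tr$y)) < 2 || length(unique(te$y)) < 2) {
    rlang::abort("Task label must have both classes in train and test.")
  }
  p <- train_mlp(tr$X, tr$y, hidden = hidden, seed = seed,
                 max_epochs = max_epochs)
  auroc(mlp_logits(p, te$X), te$y)
}

#' Subgroup volume-change contrast (case study statistic)
#'
#' Denormalizes baseline, real follow-up, and generated follow-up features
#' back to their raw scale, averages a named feature subset (e.g. the six
#' substantia-nigra-pars-compacta volume measurements) into a single volume
#' per patient, and contrasts the mean volume change (follow-up minus
#' baseline) between patients with and without a binary group label — once
#' for real and once for generated follow-ups. Only records with a real
#' follow-up enter.
#'
#' @param x a normalized `cohort` carrying `feature_ranges`, with real
#'   follow-ups for the records of interest.
#' @param generated matrix `n_records(x) x d` of generated (normalized)
#'   follow-ups, e.g. from [predict.diffusion_fit()].
#' @param feature_subset character vector of feature names to average.
#' @param group_label name of a binary label column.
#' @return tibble with columns `source` (`"real"`/`"generated"`),
#'   `mean_change_group`, `mean_change_rest`, `ratio` (group over rest) and
#'   `n_group`, `n_rest`.
#' @export
subgroup_volume_change <- function(x, generated, feature_subset, group_label) {
  if (!x$normalized || is.null(x$feature_ranges)) {
    rlang::abort("Cohort must be normalized and carry feature_ranges.")
  }
  if (!length(feature_subset)) rlang::abort("`feature_subset` is empty.")
  fidx <- match(feature_subset, x$feature_names)
  if (anyNA(fidx)) rlang::abort("Unknown features in `feature_subset`.")
  gidx <- match(group_label, x$label_names)
  if (is.na(gidx)) rlang::abort(sprintf("Unknown label '%s'.", group_label))

  keep <- x$i2_present & !x$i2_synthetic
  if (!any(keep)) rlang::abort("No records with real follow-up.")
  grp <- x$labels[keep, gidx] > 0.5
  if (!any(grp) || all(grp)) rlang::abort("Empty subgroup for the contrast.")

  raw_i1 <- denormalize_matrix(x$i1[keep, , drop = FALSE], x$feature_ranges)
  raw_i2 <- denormalize_matrix(x$i2[keep, , drop = FALSE], x$feature_ranges)
  raw_gen <- denormalize_matrix(generated[keep, , drop = FALSE], x$feature_ranges)

  vol <- function(m) rowMeans(m[, fidx, drop = FALSE])
  base <- vol(raw_i1)
  one <- function(fu, nm) {
    ch <- vol(fu) - base
    tibble::tibble(source = nm,
                   mean_change_group = mean(ch[grp]),
                   mean_change_rest = mean(ch[!grp]),
                   ratio = mean(ch[grp]) / mean(ch[!grp]),
                   n_group = sum(grp), n_rest = sum(!grp))
  }
  dplyr::bind_rows(one(raw_i2, "real"), one(raw_gen, "generated"))
}

#' Full metrics report for a fitted model on a test cohort
#'
#' Generates one follow-up per test record and assembles the headline
#' metrics: per-patient similarity (Pearson, Euclidean, cosine distance),
#' Frechet distance and mean-profile correlation between the generated and
#' real follow-up sets, and covariate-correlation similarity.
#'
#' @param fit a `diffusion_fit`.
#' @param test a normalized `cohort` whose records carry real follow-ups.
#' @param seed integer seed for generation.
#' @return one-row tibble (a metrics report).
#' @export
evaluate_followups <- function(fit, test, seed = 1L) {
  keep <- test$i2_present & !test$i2_synthetic
  if (!any(keep)) rlang::abort("Test cohort has no records with real follow-up.")
  co <- test[which(keep)]
  gen <- predict(fit, co, seed = seed)
  real <- co$i2
  sim <- paired_similarity(real, gen)
  dplyr::bind_cols(sim, tibble::tibble(
    frechet = frechet_distance(real, gen),
    mean_profile_correlation = mean_correlation(real, gen),
    covariate_similarity = as.numeric(covariate_similarity(real, gen))))
}
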