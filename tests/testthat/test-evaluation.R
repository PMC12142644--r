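test_that("paired similarity identities and degenerate handling", {
  withr::with_seed(1, {
    real <- matrix(rnorm(50), 10, 5)
    self <- paired_similarity(real, real)
    expect_equal(self$mean_pearson, 1)
    expect_equal(self$mean_euclidean, 0)
    expect_equal(self$mean_cosine_distance, 0)

    anti <- paired_similarity(real, -real)
    expect_equal(anti$mean_pearson, -1)
    expect_equal(anti$mean_cosine_distance, 2)

    # degenerate rows are excluded and tallied, not silently scored
    gen <- real; gen[1, ] <- 0
    res <- paired_similarity(real, gen)
    expect_equal(res$n_excluded_pearson, 1)
    expect_equal(res$n_excluded_cosine, 1)
    expect_equal(res$mean_pearson, 1)
  })
})

test_that("paired similarity is order-invariant and near zero on independent sets", {
  withr::with_seed(2, {
    a <- matrix(rnorm(200 * 40), 200, 40)
    b <- matrix(rnorm(200 * 40), 200, 40)
    r1 <- paired_similarity(a, b)
    perm <- sample(200)
    r2 <- paired_similarity(a[perm, ], b[perm, ])
    expect_equal(r1, r2)
  })
  withr::with_seed(3, {
    a <- matrix(rnorm(1000 * 769), 1000, 769)
    b <- matrix(rnorm(1000 * 769), 1000, 769)
    expect_lt(abs(paired_similarity(a, b)$mean_pearson), 0.01)
  })
})

test_that("Frechet distance: identity, closed form, Monte-Carlo, symmetry", {
  withr::with_seed(4, {
    a <- matrix(rnorm(100 * 5), 100, 5)
    expect_lt(frechet_distance(a, a), 1e-6)

    # equal covariances: distance reduces to ||mu_a - mu_b||^2 exactly
    shift <- a; shift[, 1] <- shift[, 1] + 3; shift[, 2] <- shift[, 2] + 4
    expect_equal(frechet_distance(a, shift), 25, tolerance = 1e-6)

    # sampled version of N(0, I2) vs N((3,4), I2)
    x <- matrix(rnorm(10000 * 2), 10000, 2)
    y <- matrix(rnorm(10000 * 2), 10000, 2)
    y[, 1] <- y[, 1] + 3; y[, 2] <- y[, 2] + 4
    fd <- frechet_distance(x, y)
    expect_lt(abs(fd - 25) / 25, 0.05)

    # symmetry and nonnegativity on random Gaussians
    for (i in 1:5) {
      p <- matrix(rnorm(300 * 4), 300, 4) %*% matrix(rnorm(16), 4, 4)
      q <- matrix(rnorm(300 * 4), 300, 4)
      expect_gte(frechet_distance(p, q), 0)
      expect_equal(frechet_distance(p, q), frechet_distance(q, p),
                   tolerance = 1e-6)
    }
    expect_error(frechet_distance(a[1, , drop = FALSE], a), "at least 2")
  })
})

test_that("mean-profile correlation identities and null", {
  withr::with_seed(5, {
    a <- matrix(rnorm(100 * 20, mean = rep(1:20, each = 100)), 100, 20)
    expect_equal(mean_correlation(a, a), 1)
    # shifting by twice the mean profile negates it: correlation -1
    expect_equal(mean_correlation(a, sweep(a, 2, 2 * colMeans(a))), -1)
    # exchangeable features -> near-zero correlation of mean profiles
    b <- matrix(rnorm(2000 * 50), 2000, 50)
    cmat <- matrix(rnorm(2000 * 50), 2000, 50)
    expect_lt(abs(mean_correlation(b, cmat)), 0.5)
  })
})

test_that("covariate-correlation similarity behaves like a distance", {
  a <- matrix(rnorm(600), 200, 3)
  expect_equal(as.numeric(covariate_similarity(a, a)), 0)

  # exactly uncorrelated columns vs perfectly correlated columns -> 1
  ortho <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  v <- c(1, 2, 3, 4.5)
  perfect <- cbind(v, 2 * v, v + 0)
  expect_equal(as.numeric(covariate_similarity(ortho, perfect)), 1)

  # two large samples from one correlated Gaussian are close
  withr::with_seed(6, {
    mix <- matrix(rnorm(100), 10, 10)
    s1 <- matrix(rnorm(5000 * 10), 5000, 10) %*% mix
    s2 <- matrix(rnorm(5000 * 10), 5000, 10) %*% mix
    expect_lt(as.numeric(covariate_similarity(s1, s2)), 0.03)
  })
})

test_that("rank AUROC: perfect, null, chance, and error cases", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auroc(c(1, 1, 1, 1), c(1, 0, 1, 0)), 0.5)  # ties -> chance
  expect_error(auroc(runif(5), rep(1, 5)), "single-class")
  # monotone rescaling leaves the rank statistic unchanged
  withr::with_seed(7, {
    sc <- rnorm(200); y <- rbinom(200, 1, stats::plogis(sc))
    expect_equal(auroc(sc, y), auroc(exp(3 * sc), y))
  })
})

test_that("downstream classifier separates a separable task and not a null task", {
  tr <- make_task_cohort(600, seed = 11)
  te <- make_task_cohort(400, seed = 12)
  auc <- downstream_auroc(tr, te, "task", seed = 1, hidden = 32L,
                          max_epochs = 40L)
  expect_gte(auc, 0.95)

  tr0 <- make_task_cohort(1000, informative = FALSE, seed = 13)
  te0 <- make_task_cohort(1000, informative = FALSE, seed = 14)
  auc0 <- downstream_auroc(tr0, te0, "task", seed = 1, hidden = 16L,
                           max_epochs = 10L)
  expect_gt(auc0, 0.4)
  expect_lt(auc0, 0.6)

  one_class <- make_task_cohort(100, seed = 15)
  one_class$labels[, "task"] <- 1
  expect_error(downstream_auroc(tr, one_class, "task", seed = 1, hidden = 8L),
               "both classes")
})

test_that("baseline-only mode uses every record without follow-up features", {
  tr <- make_task_cohort(300, seed = 16)
  tr$i2_present[1:200] <- FALSE
  tr$i2[1:200, ] <- NA_real_
  te <- make_task_cohort(200, seed = 17)
  # runs even though most records lack follow-up
  auc <- downstream_auroc(tr, te, "task", seed = 1,
                          features = "baseline_only", hidden = 16L,
                          max_epochs = 20L)
  expect_true(auc >= 0 && auc <= 1)
  # synthetic follow-ups in the test set are rejected
  te_bad <- te
  te_bad$i2_synthetic[1] <- TRUE
  expect_error(downstream_auroc(tr, te_bad, "task", seed = 1), "synthetic")
})

test_that("subgroup volume change recovers hand-set raw-scale changes", {
  # two patients, three features; subset = f1, f2; patient A in the group.
  # raw volumes: A 10 -> 8, B 10 -> 9 on the subset average.
  rg <- tibble::tibble(feature = c("f1", "f2", "f3"), min = c(0, 0, 0),
                       max = c(20, 20, 20))
  norm <- function(x) 2 * x / 20 - 1
  i1 <- rbind(A = norm(c(10, 10, 5)), B = norm(c(10, 10, 5)))
  i2 <- rbind(A = norm(c(7, 9, 5)), B = norm(c(9, 9, 5)))
  labels <- matrix(c(1, 0), 2, 1, dimnames = list(NULL, "disease"))
  co <- cohort(i1, labels, i2 = i2, feature_names = c("f1", "f2", "f3"),
               label_names = "disease", feature_ranges = rg,
               normalized = TRUE)
  res <- subgroup_volume_change(co, i1, c("f1", "f2"), "disease")
  real <- res[res$source == "real", ]
  expect_equal(real$mean_change_group, -2)
  expect_equal(real$mean_change_rest, -1)
  expect_equal(real$ratio, 2)
  # generated follow-ups equal to baseline give zero change
  gen <- res[res$source == "generated", ]
  expect_equal(gen$mean_change_group, 0)
  expect_equal(gen$mean_change_rest, 0)
  expect_error(subgroup_volume_change(co, i1, character(), "disease"), "empty")
  expect_error(subgroup_volume_change(co, i1, "f1", "nope"), "label")
})
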