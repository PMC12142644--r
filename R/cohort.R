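#' @importFrom rlang abort warn `%||%`
#' @importFrom tibble tibble as_tibble
NULL

#' Construct a longitudinal imaging cohort
#'
#' A cohort bundles, for `n` patients, a baseline feature vector `i1` (length
#' `d`, anatomical measurements), an optional follow-up vector `i2`, and a
#' label vector (demographics, disease flags, mortality). Features are stored
#' as numeric matrices; a follow-up is either present for a record or absent
#' for the whole record. Entry-level `NA`s inside a present vector mark rare
#' within-vector missingness, to be filled by [impute_missing_features()].
#'
#' @param i1 numeric matrix, `n x d`, baseline features (raw or normalized).
#' @param labels numeric matrix, `n x n_l`, per-patient labels.
#' @param i2 numeric matrix `n x d` of follow-up features, or `NULL`. Rows for
#'   patients without follow-up must be all-`NA` and flagged absent via
#'   `i2_present`.
#' @param patient_id character vector of unique ids; defaults to `"P1".."Pn"`.
#' @param i2_present logical vector, whether each record has a follow-up.
#'   Defaults to rows of `i2` containing any observed value.
#' @param i2_synthetic logical vector, whether a present follow-up was imputed
#'   by the generative model rather than observed.
#' @param feature_names,label_names column names; defaulted from the matrices.
#' @param feature_ranges tibble with columns `feature`, `min`, `max` holding
#'   the raw-scale per-feature ranges used by [normalize_cohort()], or `NULL`.
#' @param normalized logical, whether feature values are on the `[-1, 1]` scale.
#'
#' @return An object of class `cohort`.
#' @seealso [read_cohort()], [normalize_cohort()], [split_cohort()]
#' @export
cohort <- function(i1, labels, i2 = NULL, patient_id = NULL,
                   i2_present = NULL, i2_synthetic = NULL,
                   feature_names = NULL, label_names = NULL,
                   feature_ranges = NULL, normalized = FALSE) {
  i1 <- as.matrix(i1)
  storage.mode(i1) <- "double"
  n <- nrow(i1)
  d <- ncol(i1)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  if (nrow(labels) != n) abort("`labels` must have one row per record.")

  patient_id <- as.character(patient_id %||% paste0("P", seq_len(n)))
  if (length(patient_id) != n) abort("`patient_id` has wrong length.")
  if (anyDuplicated(patient_id)) {
    abort(paste0("Duplicated patient_id: ",
                 paste(unique(patient_id[duplicated(patient_id)]), collapse = ", ")))
  }

  if (is.null(i2)) {
    i2 <- matrix(NA_real_, n, d)
  } else {
    i2 <- as.matrix(i2)
    storage.mode(i2) <- "double"
    if (!all(dim(i2) == c(n, d))) abort("`i2` must match the dimensions of `i1`.")
  }
  i2_present <- i2_present %||% (rowSums(!is.na(i2)) > 0)
  if (length(i2_present) != n) abort("`i2_present` has wrong length.")
  i2_synthetic <- i2_synthetic %||% rep(FALSE, n)
  if (length(i2_synthetic) != n) abort("`i2_synthetic` has wrong length.")
  if (any(i2_synthetic & !i2_present)) {
    abort("A record cannot have a synthetic follow-up flag without a follow-up.")
  }
  if (any(i2_present & rowSums(!is.na(i2)) == 0)) {
    abort("A record flagged as having follow-up has an all-NA follow-up row.")
  }
  i2[!i2_present, ] <- NA_real_

  feature_names <- feature_names %||% colnames(i1) %||% paste0("f", seq_len(d))
  label_names <- label_names %||% colnames(labels) %||%
    (if (ncol(labels)) paste0("l", seq_len(ncol(labels))) else character())
  colnames(i1) <- feature_names
  colnames(i2) <- feature_names
  colnames(labels) <- label_names

  if (!is.null(feature_ranges)) {
    feature_ranges <- as_tibble(feature_ranges)
    stopifnot(all(c("feature", "min", "max") %in% names(feature_ranges)))
    if (nrow(feature_ranges) != d) abort("`feature_ranges` must have one row per feature.")
    if (any(feature_ranges$min > feature_ranges$max)) abort("feature range with min > max.")
  }

  structure(
    list(i1 = i1, i2 = i2, labels = labels, patient_id = patient_id,
         i2_present = as.logical(i2_present),
         i2_synthetic = as.logical(i2_synthetic),
         feature_names = feature_names, label_names = label_names,
         feature_ranges = feature_ranges, normalized = isTRUE(normalized)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d records x %d features (%d labels)\n", n_records(x),
    n_features(x), length(x$label_names)))
  cat(sprintf("  follow-up present: %d (%d synthetic)\n",
              sum(x$i2_present), sum(x$i2_synthetic)))
  cat(sprintf("  scale: %s\n", if (x$normalized) "normalized [-1,1]" else "raw"))
  invisible(x)
}

#' Number of records / features in a cohort
#' @param x a `cohort`.
#' @return integer count.
#' @export
n_records <- function(x) nrow(x$i1)

#' @rdname n_records
#' @export
n_features <- function(x) ncol(x$i1)

#' Subset a cohort by record index
#' @param x a `cohort`.
#' @param i integer or logical index over records.
#' @param ... unused.
#' @return a `cohort` with the selected records, carrying the same
#'   feature ranges and normalization state.
#' @export
`[.cohort` <- function(x, i, ...) {
  cohort(x$i1[i, , drop = FALSE], x$labels[i, , drop = FALSE],
         i2 = x$i2[i, , drop = FALSE], patient_id = x$patient_id[i],
         i2_present = x$i2_present[i], i2_synthetic = x$i2_synthetic[i],
         feature_names = x$feature_names, label_names = x$label_names,
         feature_ranges = x$feature_ranges, normalized = x$normalized)
}

#' Tidy one-row-per-patient view of a cohort
#'
#' Baseline features keep their names; follow-up columns carry `suffix`;
#' labels keep their names; bookkeeping columns `patient_id`, `i2_present`
#' and `i2_synthetic` are included.
#'
#' @param x a `cohort`.
#' @param suffix follow-up column suffix (default `"_fu"`).
#' @param ... unused.
#' @return a tibble with `n_records(x)` rows.
#' @export
as_tibble.cohort <- function(x, ..., suffix = "_fu") {
  i2 <- x$i2
  colnames(i2) <- paste0(x$feature_names, suffix)
  out <- dplyr::bind_cols(
    tibble(patient_id = x$patient_id),
    as_tibble(x$i1), as_tibble(i2), as_tibble(x$labels),
    tibble(i2_present = x$i2_present, i2_synthetic = x$i2_synthetic)
  )
  out
}

#' Read a cohort from a delimited text file
#'
#' Expects a comma-separated UTF-8 file with a header row and one row per
#' patient. Baseline feature columns are named in `schema$features`; the
#' matching follow-up columns share the base name plus `schema$suffix` and may
#' be absent per row (empty cells) for patients without follow-up imaging.
#' Empty cells inside an otherwise observed vector are kept as `NA` for
#' [impute_missing_features()].
#'
#' @param path CSV file path.
#' @param schema list with elements `id` (id column name), `features`
#'   (character vector of baseline feature columns), `labels` (character
#'   vector of label columns), and optionally `suffix` (default `"_fu"`) and
#'   `synthetic_col` (logical provenance column written by [write_cohort()]).
#' @param ranges_path optional JSON sidecar (written by [write_cohort()])
#'   holding raw-scale feature ranges; restored onto the cohort when present.
#' @return a `cohort` on the raw scale (unless the sidecar marks it normalized).
#' @export
read_cohort <- function(path, schema, ranges_path = NULL) {
  suffix <- schema$suffix %||% "_fu"
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(sprintf("Malformed row %d in %s: %s", prob$row[1], path, prob$expected[1]))
  }
  need <- c(schema$id, schema$features, schema$labels)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  ids <- df[[schema$id]]
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicated patient_id: ", ids[duplicated(ids)][1]))
  }

  parse_block <- function(cols, what) {
    m <- matrix(NA_real_, nrow(df), length(cols), dimnames = list(NULL, cols))
    for (j in seq_along(cols)) {
      raw <- df[[cols[j]]]
      filled <- !is.na(raw) & raw != ""
      val <- suppressWarnings(as.numeric(raw[filled]))
      bad <- which(is.na(val))
      if (length(bad)) {
        abort(sprintf("Non-numeric %s cell at row %d, column '%s': '%s'",
                      what, which(filled)[bad[1]], cols[j], raw[filled][bad[1]]))
      }
      m[filled, j] <- val
    }
    m
  }

  i1 <- parse_block(schema$features, "feature")
  lab <- parse_block(schema$labels, "label")
  fu_cols <- paste0(schema$features, suffix)
  i2 <- if (all(fu_cols %in% names(df))) {
    m <- parse_block(fu_cols, "follow-up feature")
    colnames(m) <- schema$features
    m
  } else NULL

  synth <- if (!is.null(schema$synthetic_col) && schema$synthetic_col %in% names(df)) {
    as.logical(df[[schema$synthetic_col]])
  } else NULL

  ranges <- NULL; normalized <- FALSE
  if (!is.null(ranges_path) && file.exists(ranges_path)) {
    side <- jsonlite::read_json(ranges_path, simplifyVector = TRUE)
    ranges <- tibble(feature = side$feature_ranges$feature,
                     min = side$feature_ranges$min, max = side$feature_ranges$max)
    normalized <- isTRUE(side$normalized)
  }

  cohort(i1, lab, i2 = i2, patient_id = ids, i2_synthetic = synth,
         feature_names = schema$features, label_names = schema$labels,
         feature_ranges = ranges, normalized = normalized)
}

#' Write a cohort to CSV (plus a JSON sidecar with feature ranges)
#'
#' @param x a `cohort`.
#' @param path output CSV path.
#' @param ranges_path output JSON sidecar path; default `paste0(path, ".meta.json")`.
#'   Stores feature ranges, the normalization flag, and the schema, so that
#'   [read_cohort()] recovers an equivalent object and denormalization stays exact.
#' @param suffix follow-up column suffix.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, ranges_path = paste0(path, ".meta.json"),
                         suffix = "_fu") {
  df <- as_tibble(x, suffix = suffix)
  readr::write_csv(df, path, na = "", progress = FALSE)
  meta <- list(
    normalized = x$normalized,
    schema = list(id = "patient_id", features = x$feature_names,
                  labels = x$label_names, suffix = suffix,
                  synthetic_col = "i2_synthetic"),
    feature_ranges = if (is.null(x$feature_ranges)) NULL else
      as.list(x$feature_ranges)
  )
  jsonlite::write_json(meta, ranges_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Min-max normalize cohort features to [-1, 1]
#'
#' Each feature `x` maps to `2 * (x - min) / (max - min) - 1`. When `ranges`
#' is not supplied, per-feature min/max are computed over all observed
#' baseline and follow-up values in this cohort. Values outside supplied
#' ranges are clipped to `[-1, 1]`. A constant feature (`min == max`) maps to
#' 0 and is restored to its constant by [denormalize_cohort()].
#'
#' @param x a raw-scale `cohort`.
#' @param ranges optional tibble (`feature`, `min`, `max`) of raw-scale ranges,
#'   e.g. taken from a training cohort so that held-out data share its scale.
#' @return a normalized `cohort` carrying `feature_ranges` for inversion.
#' @export
normalize_cohort <- function(x, ranges = NULL) {
  if (x$normalized) abort("Cohort is already normalized.")
  if (is.null(ranges)) {
    lo <- pmin(suppressWarnings(apply(x$i1, 2, min, na.rm = TRUE)),
               suppressWarnings(apply(x$i2, 2, min, na.rm = TRUE)), na.rm = TRUE)
    hi <- pmax(suppressWarnings(apply(x$i1, 2, max, na.rm = TRUE)),
               suppressWarnings(apply(x$i2, 2, max, na.rm = TRUE)), na.rm = TRUE)
    ranges <- tibble(feature = x$feature_names, min = unname(lo),
                     max = unname(hi))
  } else {
    ranges <- as_tibble(ranges)
    ranges <- ranges[match(x$feature_names, ranges$feature), ]
    if (anyNA(ranges$min)) abort("`ranges` does not cover every feature.")
  }
  span <- ranges$max - ranges$min
  scale_mat <- function(m) {
    out <- sweep(sweep(m, 2, ranges$min, "-"), 2, ifelse(span > 0, span, 1), "/") * 2 - 1
    out[, span == 0] <- 0
    pmin(pmax(out, -1), 1) * NA ^ is.na(m)
  }
  y <- x
  y$i1 <- scale_mat(x$i1); colnames(y$i1) <- x$feature_names
  y$i2 <- scale_mat(x$i2); colnames(y$i2) <- x$feature_names
  y$i2[!y$i2_present, ] <- NA_real_
  y$feature_ranges <- ranges
  y$normalized <- TRUE
  y
}

#' Invert min-max normalization using the stored feature ranges
#'
#' Exact inverse of [normalize_cohort()] up to floating tolerance; lossy only
#' for values clipped at normalize time. Constant features are restored to
#' their constant.
#'
#' @param x a normalized `cohort` carrying `feature_ranges`.
#' @return a raw-scale `cohort`.
#' @export
denormalize_cohort <- function(x) {
  if (!x$normalized) abort("Cohort is not normalized.")
  if (is.null(x$feature_ranges)) abort("Cohort carries no feature_ranges to invert.")
  y <- x
  y$i1 <- denormalize_matrix(x$i1, x$feature_ranges)
  y$i2 <- denormalize_matrix(x$i2, x$feature_ranges)
  y$normalized <- FALSE
  y
}

#' Map a matrix of normalized features back to the raw scale
#' @param m numeric matrix with one column per feature, values in `[-1, 1]`.
#' @param ranges tibble (`feature`, `min`, `max`).
#' @return matrix on the raw scale.
#' @export
denormalize_matrix <- function(m, ranges) {
  span <- ranges$max - ranges$min
  out <- sweep(sweep((m + 1) / 2, 2, span, "*"), 2, ranges$min, "+")
  if (any(span == 0)) out[, span == 0] <- rep(ranges$min[span == 0],
                                              each = nrow(out))
  out[is.na(m)] <- NA_real_
  colnames(out) <- ranges$feature
  out
}

#' Fill rare within-vector missingness by chained regression
#'
#' Round-robin multivariate imputation: missing entries are initialized to
#' per-feature means, then each incomplete feature is regressed (ordinary
#' least squares) on all other features over the currently filled matrix and
#' its missing entries refilled, repeating until the largest change is below
#' `tol` or `max_rounds` is reached. Baseline and observed follow-up vectors
#' are stacked so both contribute to (and are filled by) the same model.
#' Observed entries are never altered.
#'
#' @param x a `cohort` (raw or normalized scale).
#' @param max_rounds maximum sweeps over the features (default 10).
#' @param tol convergence tolerance on the max absolute change (default 1e-3).
#' @param seed integer; kept for interface stability — the round-robin sweep
#'   itself is deterministic (features are visited in column order).
#' @return a `cohort` with no missing feature entries.
#' @export
impute_missing_features <- function(x, max_rounds = 10, tol = 1e-3, seed = 1L) {
  n1 <- anyNA(x$i1)
  n2 <- anyNA(x$i2[x$i2_present, , drop = FALSE])
  if (!n1 && !n2) return(x)

  stack <- rbind(x$i1, x$i2[x$i2_present, , drop = FALSE])
  miss <- is.na(stack)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    abort(paste0("Feature entirely missing: ",
                 paste(x$feature_names[all_missing], collapse = ", ")))
  }
  mu <- colMeans(stack, na.rm = TRUE)
  for (j in which(colSums(miss) > 0)) stack[miss[, j], j] <- mu[j]

  d <- ncol(stack)
  incomplete <- which(colSums(miss) > 0)
  for (round in seq_len(max_rounds)) {
    delta <- 0
    for (j in incomplete) {
      obs <- !miss[, j]
      X <- cbind(1, stack[, -j, drop = FALSE])
      fit <- stats::lm.fit(X[obs, , drop = FALSE], stack[obs, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- X[miss[, j], , drop = FALSE] %*% beta
      delta <- max(delta, max(abs(pred - stack[miss[, j], j])))
      stack[miss[, j], j] <- pred
    }
    if (delta < tol) break
  }

  y <- x
  y$i1 <- stack[seq_len(n_records(x)), , drop = FALSE]
  if (any(x$i2_present)) {
    y$i2[x$i2_present, ] <- stack[-seq_len(n_records(x)), , drop = FALSE]
  }
  colnames(y$i1) <- colnames(y$i2) <- x$feature_names
  y
}

#' Split a cohort into train / validation / test sets
#'
#' Held-out sets are drawn from the longitudinal stratum: the test set takes
#' `ceiling(test_frac * n_longitudinal)` records with real follow-up, drawn
#' uniformly at random. All remaining records (the rest of the longitudinal
#' stratum plus every record without follow-up) form the combined training
#' pool, from which the validation set takes `ceiling(val_frac * stratum
#' size)` records per stratum (longitudinal / non-longitudinal). Cell sizes
#' are deterministic given the counts; membership is random given `seed`.
#'
#' @param x a `cohort`.
#' @param test_frac fraction of longitudinal records held out for testing
#'   (default 0.2).
#' @param val_frac fraction of the combined training pool split off for
#'   validation, per stratum (default 0.1).
#' @param seed integer RNG seed.
#' @return a list of class `cohort_splits` with elements `train`,
#'   `validation`, `test`, each a `cohort`.
#' @export
split_cohort <- function(x, test_frac = 0.2, val_frac = 0.1, seed = 1L) {
  long_idx <- which(x$i2_present & !x$i2_synthetic)
  nonlong_idx <- setdiff(seq_len(n_records(x)), long_idx)
  n_long <- length(long_idx)
  if (n_long < 2) abort("Need at least 2 records with real follow-up to split.")

  draw <- function(x, n) x[sample.int(length(x), n)]  # safe for length-1 x
  withr::with_seed(seed, {
    n_test <- ceiling(test_frac * n_long)
    test_idx <- draw(long_idx, n_test)
    pool_long <- setdiff(long_idx, test_idx)
    n_val_long <- ceiling(val_frac * length(pool_long))
    n_val_nonlong <- ceiling(val_frac * length(nonlong_idx))
    val_idx <- c(if (n_val_long) draw(pool_long, n_val_long),
                 if (n_val_nonlong) draw(nonlong_idx, n_val_nonlong))
    train_idx <- setdiff(c(pool_long, nonlong_idx), val_idx)
  })

  structure(list(train = x[train_idx], validation = x[val_idx], test = x[test_idx]),
            class = "cohort_splits")
}

#' @export
print.cohort_splits <- function(x, ...) {
  tab <- split_sizes(x)
  cat("<cohort_splits>\n")
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Tabulate split sizes by stratum
#' @param x a `cohort_splits`.
#' @return tibble with columns `split`, `longitudinal`, `non_longitudinal`.
#' @export
split_sizes <- function(x) {
  one <- function(co, nm) tibble(
    split = nm,
    longitudinal = sum(co$i2_present),
    non_longitudinal = sum(!co$i2_present)
  )
  dplyr::bind_rows(one(x$train, "train"), one(x$validation, "validation"),
                   one(x$test, "test"))
}
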