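# Group classification from behavioral feature vectors: cross-validated
# multinomial logistic regression, permutation-based chance levels, and 2-D
# embedding for visualization.

# Stratified fold assignment: within each class, flies are shuffled and
# dealt round-robin into k folds.
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    i <- i[sample.int(length(i))]
    fold[i] <- rep_len(sample.int(k), length(i))
  }
  fold
}

#' Cross-validated multinomial logistic classification
#'
#' Fits a multinomial logistic regression with a light ridge penalty (weight
#' decay) under repeated stratified k-fold cross-validation and reports the
#' mean held-out accuracy. Features are z-scored per column using statistics
#' fit on the training folds only (default on). Deterministic under `seed`.
#'
#' @param features Numeric matrix, one row per fly (e.g. from
#'   [cohort_features()]). Non-finite entries are replaced by 0.
#' @param labels Group label per row (defaults to the matrix's `"labels"`
#'   attribute).
#' @param k Folds (default 5); reduced with a warning if a class has fewer
#'   members than folds.
#' @param repeats CV repetitions (default 10); accuracy is the mean.
#' @param decay Ridge (weight-decay) penalty for numerical stability with
#'   42-140 features and tens of flies (default 0.05).
#' @param standardize z-score features on training folds (default TRUE).
#' @param seed Integer seed.
#' @return List of class `"classification_result"`: `accuracy`,
#'   `per_class_accuracy`, `n_classes`, `cv_scheme`, `seed`.
#' @export
classify <- function(features, labels = attr(features, "labels"), k = 5L,
                     repeats = 10L, decay = 0.05, standardize = TRUE,
                     seed = NULL) {
  features <- as.matrix(features)
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  counts <- table(labels)
  if (any(counts < 2L)) stop("every class needs at least 2 flies")
  if (min(counts) < k) {
    k <- max(2L, as.integer(min(counts)))
    warning("smallest class has fewer members than folds; using k = ", k)
  }
  features[!is.finite(features)] <- 0
  cls <- sort(unique(labels))
  y <- factor(labels, levels = cls)

  run_cv <- function() {
    acc_mat <- matrix(NA, length(y), repeats)
    for (rep_i in seq_len(repeats)) {
      fold <- .stratified_folds(labels, k)
      rep_correct <- logical(length(y))
      for (f in seq_len(k)) {
        tr <- fold != f; te <- !tr
        xtr <- features[tr, , drop = FALSE]
        xte <- features[te, , drop = FALSE]
        if (standardize) {
          mu <- colMeans(xtr)
          sg <- apply(xtr, 2L, stats::sd)
          sg[sg == 0 | !is.finite(sg)] <- 1
          xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
          xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
        }
        dtr <- data.frame(y = y[tr], xtr, check.names = FALSE)
        fit <- nnet::multinom(y ~ ., data = dtr, decay = decay, trace = FALSE,
                              maxit = 200, MaxNWts = 10000)
        pred <- predict(fit, newdata = data.frame(xte, check.names = FALSE))
        rep_correct[te] <- as.character(pred) == as.character(y[te])
      }
      acc_mat[, rep_i] <- rep_correct
    }
    acc_mat
  }
  acc_mat <- with_seed(seed, run_cv())
  per_fly <- rowMeans(acc_mat)
  per_class <- vapply(cls, function(cl) mean(per_fly[labels == cl]), numeric(1))
  structure(
    list(accuracy = mean(per_fly),
         per_class_accuracy = setNames(per_class, cls),
         n_classes = length(cls),
         cv_scheme = sprintf("stratified %d-fold x %d repeats, ridge decay %g",
                             k, repeats, decay),
         seed = seed),
    class = "classification_result"
  )
}

#' Permutation-estimated chance level of classification
#'
#' Repeats [classify()] with group labels randomly permuted and reports the
#' mean cross-validated accuracy over permutations together with its
#' 2.5-97.5 percentile band. For balanced cohorts this converges to
#' `1 / n_classes` (20% for five classes, 25% for four).
#'
#' @inheritParams classify
#' @param n_permutations Number of label permutations (default 100; fewer
#'   than 10 triggers a warning).
#' @param repeats CV repetitions per permutation (default 1).
#' @return List of class `"chance_level"`: `chance` (mean accuracy),
#'   `band` (2.5/97.5 percentiles), `accuracies` (per permutation).
#' @export
chance_level <- function(features, labels = attr(features, "labels"),
                         n_permutations = 100L, k = 5L, repeats = 1L,
                         decay = 0.05, standardize = TRUE, seed = NULL) {
  if (n_permutations < 10L)
    warning("fewer than 10 permutations gives an unstable chance estimate")
  labels <- as.character(labels)
  seeds <- derive_seeds(seed %||% 0L, 2L * n_permutations)
  acc <- vapply(seq_len(n_permutations), function(i) {
    perm <- with_seed(seeds[i], sample(labels))
    suppressWarnings(
      classify(features, perm, k = k, repeats = repeats, decay = decay,
               standardize = standardize, seed = seeds[n_permutations + i])$accuracy
    )
  }, numeric(1))
  structure(
    list(chance = mean(acc),
         band = quantile(acc, c(0.025, 0.975), names = FALSE),
         accuracies = acc, n_permutations = n_permutations, seed = seed),
    class = "chance_level"
  )
}

#' 2-D embedding of behavioral feature vectors
#'
#' Projects per-fly feature vectors to two dimensions for visualization.
#' Glue around standard embeddings -- no novel computation: `"pca"`
#' (default; deterministic principal components of the z-scored features) or
#' `"sammon"` (MASS non-linear distance-preserving mapping).
#'
#' @param features Numeric matrix, one row per fly.
#' @param method `"pca"` or `"sammon"`.
#' @param seed Integer seed (used to break ties in degenerate distance
#'   configurations for `"sammon"`).
#' @return An n x 2 matrix of coordinates (rownames preserved).
#' @export
embed_2d <- function(features, method = c("pca", "sammon"), seed = NULL) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("need at least 3 flies to embed")
  features[!is.finite(features)] <- 0
  keep <- apply(features, 2L, function(col) stats::sd(col) > 0)
  x <- scale(features[, keep, drop = FALSE])
  coords <- with_seed(seed, {
    if (method == "pca") {
      pc <- prcomp(x, center = FALSE, scale. = FALSE)
      sc <- pc$x
      if (ncol(sc) < 2L) sc <- cbind(sc, 0)
      sc[, 1:2, drop = FALSE]
    } else {
      d <- dist(x)
      d[d == 0] <- 1e-8 * max(d)          # sammon requires nonzero distances
      MASS::sammon(d, k = 2L, trace = FALSE)$points
    }
  })
  colnames(coords) <- c("dim1", "dim2")
  rownames(coords) <- rownames(features)
  coords
}
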