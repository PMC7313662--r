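# Rejection-ABC model choice between the Kingman and MMC models, operating
# on standardized summary-statistic vectors.

#' Greedy correlation pruning of summary statistics
#'
#' Iterates columns in their given order and drops any column whose absolute
#' Pearson correlation with an already-kept column exceeds `threshold`. The
#' column order is therefore part of the procedure; the panel uses the fixed
#' order of [summary_stat_names()], which makes the result deterministic.
#'
#' @param stats Numeric matrix or data frame of statistics (rows =
#'   replicates). Rows containing `NA` are ignored when computing
#'   correlations.
#' @param threshold Absolute correlation above which a column is dropped.
#' @return Integer vector of kept column indices (named when input has
#'   column names).
#' @export
#' @examples
#' x <- cbind(a = 1:10, b = (1:10) * 2, c = rnorm(10))
#' prune_correlated(x)   # b is a copy of a and is dropped
prune_correlated <- function(stats, threshold = 0.8) {
  x <- as.matrix(stats)
  ok <- stats::complete.cases(x)
  if (sum(ok) < 2) abort("need at least two complete rows to prune")
  x <- x[ok, , drop = FALSE]
  constant <- apply(x, 2, function(col) sd(col) == 0 || !is.finite(sd(col)))
  kept <- integer(0)
  for (j in seq_len(ncol(x))) {
    if (constant[j]) next
    if (length(kept) == 0) {
      kept <- j
      next
    }
    r <- abs(cor(x[, j], x[, kept, drop = FALSE]))
    if (all(r <= threshold)) kept <- c(kept, j)
  }
  if (length(kept) == 0) abort("all columns degenerate or correlated away")
  if (!is.null(colnames(x))) kept <- setNames(kept, colnames(x)[kept])
  kept
}

#' Centre and scale statistics
#'
#' Training data are standardized to zero mean and unit standard deviation
#' per column; targets must reuse the training parameters so that distances
#' are measured in the same units.
#'
#' @param stats Numeric matrix (rows = replicates or targets).
#' @param center,scale Per-column parameters; when `NULL` they are computed
#'   from `stats` (column means and standard deviations).
#' @return Standardized matrix with `center` and `scale` attributes.
#' @export
standardize_stats <- function(stats, center = NULL, scale = NULL) {
  x <- as.matrix(stats)
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2, sd)
  if (any(!is.finite(scale)) || any(scale == 0))
    abort("zero-variance column: prune before standardizing")
  out <- sweep(sweep(x, 2, center), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

# Replace NA statistics (degenerate windows, e.g. S = 0 after a strong
# sweepstakes episode) by the most extreme value observed for that statistic
# in the training set: the observed value farthest from the column mean.
# Zero-variation windows are an MMC hallmark, so they must stay classifiable.
sentinel_values <- function(stats_mat) {
  vapply(seq_len(ncol(stats_mat)), function(j) {
    x <- stats_mat[, j]
    x <- x[is.finite(x)]
    x[which.max(abs(x - mean(x)))]
  }, numeric(1))
}

fill_sentinels <- function(x, sentinels) {
  for (j in seq_len(ncol(x))) {
    bad <- !is.finite(x[, j])
    if (any(bad)) x[bad, j] <- sentinels[j]
  }
  x
}

#' Build an ABC training set from simulated summary statistics
#'
#' Takes the labelled replicate table of [simulate_training_set()] and
#' prepares it for rejection: correlation pruning at `cor_threshold`
#' (computed on non-degenerate rows), sentinel replacement of degenerate
#' values, and centring/scaling on the pooled training statistics.
#'
#' @param replicates Tibble with a `model` column (`"kingman"`/`"mmc"`), the
#'   eleven statistic columns, and optionally `psi`.
#' @param cor_threshold Absolute-correlation pruning threshold.
#' @return An object of class `abc_training`: standardized kept-column
#'   matrix, labels, psi draws, kept columns, centring parameters and
#'   sentinel values.
#' @export
abc_training <- function(replicates, cor_threshold = 0.8) {
  nm <- summary_stat_names()
  if (!all(nm %in% names(replicates)))
    abort("`replicates` must contain the eleven summary statistic columns")
  if (!all(replicates$model %in% c("kingman", "mmc")))
    abort("`model` must be 'kingman' or 'mmc'")
  raw <- as.matrix(replicates[, nm])
  kept <- prune_correlated(raw, cor_threshold)
  sent <- sentinel_values(raw[, kept, drop = FALSE])
  filled <- fill_sentinels(raw[, kept, drop = FALSE], sent)
  std <- standardize_stats(filled)
  structure(
    list(stats = std, labels = replicates$model,
         psi = replicates$psi %||% rep(NA_real_, nrow(raw)),
         kept_columns = kept,
         center = attr(std, "center"), scale = attr(std, "scale"),
         sentinels = sent, cor_threshold = cor_threshold),
    class = "abc_training")
}

#' @export
print.abc_training <- function(x, ...) {
  cat(sprintf("<abc_training> %d replicates (%d kingman / %d mmc), %d of 11 statistics kept\n",
              length(x$labels), sum(x$labels == "kingman"),
              sum(x$labels == "mmc"), length(x$kept_columns)))
  cat("  kept:", paste(names(x$kept_columns), collapse = ", "), "\n")
  invisible(x)
}

# Standardize target rows (tibble of window stats or plain matrix) with the
# training parameters, applying kept columns and sentinel replacement.
standardize_targets <- function(targets, training) {
  nm <- names(training$kept_columns)
  x <- as.matrix(as.data.frame(targets)[, nm, drop = FALSE])
  x <- fill_sentinels(x, training$sentinels)
  standardize_stats(x, training$center, training$scale)
}

#' Rejection-ABC model choice for one target vector
#'
#' Computes Euclidean distances from the standardized target to every
#' training row, accepts the `round(tolerance * R)` nearest (rows tied with
#' the boundary distance are all included), and estimates the posterior
#' probability of each model as its share of accepted rows.
#'
#' @param target One window's statistics: a one-row tibble from
#'   [window_stats()] or a named numeric vector.
#' @param training An [abc_training()].
#' @param tolerance Acceptance fraction (default 0.10).
#' @return An object of class `abc_posterior` with `p_kingman`, `p_mmc`,
#'   `n_accepted`, `tolerance`.
#' @export
rejection_model_choice <- function(target, training, tolerance = 0.1) {
  if (is.numeric(target) && is.null(dim(target)))
    target <- tibble::as_tibble(as.list(target))
  z <- standardize_targets(target, training)[1, ]
  p <- posterior_mmc(matrix(z, nrow = 1), training$stats, training$labels,
                     tolerance)
  structure(list(p_kingman = 1 - p$p_mmc, p_mmc = p$p_mmc,
                 n_accepted = p$n_accepted, tolerance = tolerance),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> P(kingman) = %.4f, P(mmc) = %.4f (%d accepted, tolerance %g)\n",
              x$p_kingman, x$p_mmc, x$n_accepted, x$tolerance))
  invisible(x)
}

#' @export
#' @method tidy abc_posterior
tidy.abc_posterior <- function(x, ...) {
  tibble::tibble(model = c("kingman", "mmc"),
                 posterior = c(x$p_kingman, x$p_mmc))
}

# vectorised rejection kernel: standardized target rows x training matrix
posterior_mmc <- function(targets_std, train_std, labels, tolerance) {
  R <- nrow(train_std)
  k <- round(tolerance * R)
  k <- max(k, 1L)
  is_mmc <- labels == "mmc"
  p <- numeric(nrow(targets_std))
  n_acc <- integer(nrow(targets_std))
  tt <- t(train_std)
  for (i in seq_len(nrow(targets_std))) {
    d2 <- colSums((tt - targets_std[i, ])^2)
    cut <- sort(d2, partial = k)[k]
    acc <- d2 <= cut          # boundary ties all included
    p[i] <- mean(is_mmc[acc])
    n_acc[i] <- sum(acc)
  }
  list(p_mmc = p, n_accepted = n_acc)
}

#' Leave-one-out cross-validation of the model choice
#'
#' Holds out one training replicate at a time (uniformly subsampled to
#' `n_folds` for tractability), classifies it by rejection against the
#' remaining rows, and reports the confusion matrix and per-model
#' misclassification rates. A posterior tie counts as misclassified.
#'
#' @param training An [abc_training()].
#' @param tolerance Acceptance fraction used for each held-out
#'   classification.
#' @param n_folds Number of held-out replicates.
#' @param seed Integer seed for the fold subsample.
#' @return An object of class `abc_cv` with `confusion` (tibble),
#'   `misclassification` (named numeric, per model) and `n_folds`.
#' @export
loo_cv <- function(training, tolerance = 0.1, n_folds = 1000, seed = 1) {
  R <- length(training$labels)
  stopifnot(n_folds <= R)
  folds <- with_seed(seed, sample.int(R, n_folds))
  is_mmc <- training$labels == "mmc"
  tt <- t(training$stats)
  k <- max(round(tolerance * (R - 1)), 1L)
  pred <- character(n_folds)
  for (i in seq_along(folds)) {
    f <- folds[i]
    d2 <- colSums((tt - training$stats[f, ])^2)
    d2[f] <- Inf
    cut <- sort(d2, partial = k)[k]
    acc <- d2 <= cut
    pm <- mean(is_mmc[acc])
    pred[i] <- if (pm > 0.5) "mmc" else if (pm < 0.5) "kingman" else "tie"
  }
  truth <- training$labels[folds]
  confusion <- tibble::tibble(truth = truth, predicted = pred) |>
    dplyr::count(.data$truth, .data$predicted)
  mis <- vapply(c("kingman", "mmc"), function(mod) {
    idx <- truth == mod
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] != mod)   # ties count as misclassified
  }, numeric(1))
  structure(list(confusion = confusion, misclassification = mis,
                 n_folds = n_folds, tolerance = tolerance),
            class = "abc_cv")
}

#' @export
print.abc_cv <- function(x, ...) {
  cat(sprintf("<abc_cv> %d folds, tolerance %g\n", x$n_folds, x$tolerance))
  cat(sprintf("  misclassification: kingman %.3f, mmc %.3f\n",
              x$misclassification["kingman"], x$misclassification["mmc"]))
  invisible(x)
}

#' @export
#' @method tidy abc_cv
tidy.abc_cv <- function(x, ...) x$confusion

#' @export
#' @method glance abc_cv
glance.abc_cv <- function(x, ...) {
  tibble::tibble(n_folds = x$n_folds, tolerance = x$tolerance,
                 mis_kingman = unname(x$misclassification["kingman"]),
                 mis_mmc = unname(x$misclassification["mmc"]))
}

#' Neutral credible threshold for sweep-like calls
#'
#' The empirical 99% point (nearest-rank definition: the value at rank
#' `ceiling(level * n)` of the sorted sample) of the MMC posterior
#' probability over windows of neutral replicates simulated under the same
#' demography. Windows whose posterior exceeds this threshold are called
#' sweep-like.
#'
#' @param neutral_pmmc Numeric vector of neutral-window MMC posterior
#'   probabilities (at least 100).
#' @param level Credible level (default 0.99).
#' @return The threshold (single numeric).
#' @export
neutral_threshold <- function(neutral_pmmc, level = 0.99) {
  if (length(neutral_pmmc) < 100)
    abort("need at least 100 neutral window probabilities")
  stopifnot(level > 0, level <= 1)
  sort(neutral_pmmc)[ceiling(level * length(neutral_pmmc))]
}
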