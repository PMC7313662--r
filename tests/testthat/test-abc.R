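test_that("correlation pruning applies the greedy rule in column order", {
  set.seed(501)
  a <- rnorm(50)
  # exact duplicate: the later copy is dropped
  x <- cbind(s1 = a, s2 = a, s3 = rnorm(50))
  expect_identical(names(prune_correlated(x)), c("s1", "s3"))
  # mutually weakly correlated columns are all kept
  y <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(length(prune_correlated(y)), 3)
})

test_that("pruning drops columns only through correlation with kept columns", {
  # target correlations: r(1,2) = .9 (2 pruned by 1), r(1,3) = .55 (3 kept),
  # r(2,3) = .85 (> threshold, but 2 is already dropped so it cannot veto 3)
  set.seed(502)
  R <- matrix(c(1, .9, .55, .9, 1, .85, .55, .85, 1), 3)
  x <- matrix(rnorm(3 * 4000), ncol = 3) %*% chol(R)
  colnames(x) <- c("v1", "v2", "v3")
  stopifnot(abs(cor(x)[1, 2]) > 0.8, abs(cor(x)[2, 3]) > 0.8,
            abs(cor(x)[1, 3]) < 0.8)
  kept <- prune_correlated(x, threshold = 0.8)
  expect_equal(unname(kept), c(1L, 3L))
  # brute-force application of the stated greedy rule agrees
  brute <- integer(0)
  for (j in 1:3) {
    if (length(brute) == 0 ||
        all(abs(cor(x[, j], x[, brute, drop = FALSE])) <= 0.8))
      brute <- c(brute, j)
  }
  expect_equal(unname(kept), brute)
  # and when both later columns exceed the threshold against column 1,
  # everything collapses onto column 1
  y <- cbind(a = x[, 1], b = x[, 1] + rnorm(4000, 0, 0.1),
             c = x[, 1] + rnorm(4000, 0, 0.1))
  expect_equal(unname(prune_correlated(y, 0.8)), 1L)
})

test_that("standardization has the documented fixed points", {
  set.seed(503)
  x <- matrix(rnorm(200, 5, 3), 50, 4)
  z <- standardize_stats(x)
  expect_equal(unname(colMeans(z)), rep(0, 4))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4))
  # reusing the stored parameters reproduces the matrix
  z2 <- standardize_stats(x, attr(z, "center"), attr(z, "scale"))
  expect_equal(unclass(z2), unclass(z), ignore_attr = TRUE)
  # a target at the training mean maps to zero
  z3 <- standardize_stats(matrix(colMeans(x), 1), attr(z, "center"),
                          attr(z, "scale"))
  expect_equal(unname(z3[1, ]), rep(0, 4))
  expect_error(standardize_stats(cbind(x, 0 * x[, 1])), "zero-variance")
})

# small synthetic training set with controllable separation
fake_training <- function(n = 100, sep = 3, seed = 1) {
  set.seed(seed)
  k <- as.data.frame(matrix(rnorm(n * 11), n, 11))
  m <- as.data.frame(matrix(rnorm(n * 11, mean = sep), n, 11))
  names(k) <- names(m) <- summary_stat_names()
  tib <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(k), model = "kingman", psi = NA_real_),
    dplyr::mutate(tibble::as_tibble(m), model = "mmc",
                  psi = runif(n, 0.004, 0.08)))
  abc_training(tib, cor_threshold = 0.99)
}

test_that("rejection posterior follows the accepted-label fractions", {
  tr <- fake_training(n = 50, sep = 4)
  # a target sitting on a kingman row with tolerance accepting ~1 neighbour
  target <- setNames(as.list(tr$stats[1, ] * tr$scale + tr$center),
                     names(tr$kept_columns))
  post <- rejection_model_choice(tibble::as_tibble(target), tr,
                                 tolerance = 1 / 100)
  expect_equal(post$p_kingman, 1)
  expect_equal(post$p_kingman + post$p_mmc, 1)
  # all-MMC training forces p_mmc = 1 whatever the target
  all_mmc <- fake_training(n = 30, sep = 0)
  all_mmc$labels <- rep("mmc", length(all_mmc$labels))
  post2 <- rejection_model_choice(tibble::as_tibble(target), all_mmc, 0.2)
  expect_equal(post2$p_mmc, 1)
})

test_that("a hand-computed four-row rejection at 50% tolerance", {
  # 2 kingman rows and 2 mmc rows, target nearest to one row of each model
  stats <- rbind(c(0, 0), c(10, 10), c(1, 0), c(9, 10))
  tr <- list(stats = scale(stats), labels = c("kingman", "mmc", "mmc", "kingman"),
             psi = rep(NA_real_, 4),
             kept_columns = setNames(1:2, c("S", "pi")),
             center = attr(scale(stats), "scaled:center"),
             scale = attr(scale(stats), "scaled:scale"),
             sentinels = c(0, 0), cor_threshold = 0.8)
  class(tr) <- "abc_training"
  target <- tibble::tibble(S = 0.4, pi = 0.1)
  # exhaustive distances: rows 1 (kingman) and 3 (mmc) are the two nearest
  post <- rejection_model_choice(target, tr, tolerance = 0.5)
  expect_equal(post$n_accepted, 2)
  expect_equal(post$p_mmc, 0.5)
})

test_that("rejection is invariant to permuting training rows", {
  tr <- fake_training(n = 60, sep = 1)
  target <- tibble::as_tibble(setNames(as.list(rnorm(11)), summary_stat_names()))
  post1 <- rejection_model_choice(target, tr, 0.1)
  perm <- sample(nrow(tr$stats))
  tr2 <- tr
  tr2$stats <- tr$stats[perm, ]
  tr2$labels <- tr$labels[perm]
  post2 <- rejection_model_choice(target, tr2, 0.1)
  expect_equal(post1$p_mmc, post2$p_mmc)
})

test_that("degenerate windows are imputed with the most extreme training value", {
  tr <- fake_training(n = 40, sep = 2)
  target <- tibble::as_tibble(setNames(as.list(rep(NA_real_, 11)),
                                       summary_stat_names()))
  z <- mmcscan:::standardize_targets(target, tr)
  # imputed values are the training extremes, so they standardize finitely
  expect_true(all(is.finite(z)))
})

test_that("cross-validation separates separated clusters and not shuffled labels", {
  tr <- fake_training(n = 80, sep = 6)
  cv <- loo_cv(tr, tolerance = 0.1, n_folds = 80, seed = 3)
  expect_equal(unname(cv$misclassification), c(0, 0))
  expect_equal(sum(cv$confusion$n), 80)
  # labels independent of the statistics: misclassification near 0.5
  tr2 <- fake_training(n = 300, sep = 0, seed = 9)
  cv2 <- loo_cv(tr2, tolerance = 0.1, n_folds = 600, seed = 4)
  expect_gt(mean(cv2$misclassification), 0.4)
  expect_lt(mean(cv2$misclassification), 0.6)
  g <- glance(cv2)
  expect_equal(g$n_folds, 600)
})

test_that("neutral threshold uses the nearest-rank percentile", {
  vals <- seq(0, 0.99, by = 0.01)
  # rank ceiling(0.99 * 100) = 99 of the sorted sample -> 0.98
  expect_equal(neutral_threshold(vals, 0.99), 0.98)
  expect_equal(neutral_threshold(rep(0.25, 150), 0.99), 0.25)
  # non-decreasing in the level
  set.seed(7)
  x <- runif(500)
  lv <- c(0.5, 0.9, 0.95, 0.99, 1)
  th <- vapply(lv, function(l) neutral_threshold(x, l), numeric(1))
  expect_true(all(diff(th) >= 0))
  expect_error(neutral_threshold(runif(50)), "at least 100")
})

test_that("posteriors are probabilities and sum to one across random targets", {
  tr <- fake_training(n = 60, sep = 1.5)
  set.seed(8)
  for (i in 1:20) {
    target <- tibble::as_tibble(setNames(as.list(rnorm(11, 1)),
                                         summary_stat_names()))
    post <- rejection_model_choice(target, tr, 0.1)
    expect_gte(post$p_mmc, 0)
    expect_lte(post$p_mmc, 1)
    expect_equal(post$p_kingman + post$p_mmc, 1)
  }
})
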