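# single deterministic tree on the full index set (no bootstrap)
grow1 <- function(X, y, cat = rep(FALSE, ncol(X)), min_leaf = 1,
                  surrogate = TRUE, curvature = TRUE) {
  clockbias:::.cb_grow_tree(X, y, cat, seq_len(nrow(X)),
                            as.integer(min_leaf), surrogate, curvature)
}
predict1 <- function(tree, X) {
  as.numeric(clockbias:::.cb_predict_trees(list(tree), X))
}

test_that("curvature test detects dependence and matches a hand chi-square", {
  set.seed(1)
  y <- sample(seq(1, 18, length.out = 100))
  expect_lt(curvature_test_p(y, y), 1e-10)

  # hand-computed contingency chi-square on a fixed 8-point fixture,
  # using the documented binning (type-7 quartiles, <= edge goes low)
  x <- as.numeric(1:8)
  y8 <- c(5, 3, 8, 1, 9, 2, 7, 4)
  assign_bin <- function(v) {
    e <- quantile(v, c(0.25, 0.5, 0.75), type = 7)
    ifelse(v <= e[1], 0, ifelse(v <= e[2], 1, ifelse(v <= e[3], 2, 3)))
  }
  tab <- table(assign_bin(x), assign_bin(y8))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p_oracle <- stats::pchisq(stat, df, lower.tail = FALSE)
  expect_equal(curvature_test_p(x, y8), p_oracle, tolerance = 1e-12)

  # constant predictor convention
  expect_identical(curvature_test_p(rep(2, 20), rnorm(20)), 1)
  # categorical predictor uses its levels as cells
  xc <- rep(c(0, 1, 2), each = 30)
  yc <- rnorm(90) + 3 * xc
  expect_lt(curvature_test_p(xc, yc, categorical = TRUE), 1e-6)
})

test_that("null curvature p-values are approximately uniform", {
  set.seed(30)
  ps <- replicate(1000, curvature_test_p(rnorm(100), rnorm(100)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("curvature selection finds the associated predictor among noise", {
  set.seed(55)
  hits <- 0L
  for (i in 1:100) {
    n <- 100
    y <- rnorm(n)
    X <- cbind(y + rnorm(n), matrix(rnorm(n * 10), n, 10)) # R^2 = 0.5 signal
    ps <- apply(X, 2, curvature_test_p, y = y)
    if (which.min(ps) == 1L) hits <- hits + 1L
  }
  expect_gte(hits / 100, 0.95)
})

test_that("degenerate and noiseless trees behave as contracts require", {
  # constant response -> single leaf
  X <- matrix(rnorm(20), 20, 1)
  tr <- grow1(X, rep(7, 20))
  expect_identical(tr$feat, -1L)
  expect_equal(predict1(tr, X), rep(7, 20))

  # noiseless step function interpolates exactly at min_leaf 1
  x <- matrix(seq(0, 10, length.out = 40), ncol = 1)
  y <- ifelse(x[, 1] < 5, 0, 10)
  tr <- grow1(x, y)
  expect_equal(predict1(tr, x), y)

  # exhaustive selection: zero training MSE when features separate samples
  set.seed(3)
  X2 <- matrix(rnorm(60), 30, 2)
  y2 <- rnorm(30)
  tr2 <- grow1(X2, y2, curvature = FALSE)
  expect_equal(predict1(tr2, X2), y2, tolerance = 1e-12)
})

test_that("an all-constant feature never changes the grown tree", {
  set.seed(9)
  X <- matrix(runif(120, 0, 100), 40, 3)
  y <- 0.1 * X[, 1] + rnorm(40, sd = 0.5)
  t1 <- grow1(X, y)
  t2 <- grow1(cbind(X, 5), y)    # constant appended as last feature
  expect_identical(t1$feat, t2$feat)
  expect_identical(t1$thr, t2$thr)
  expect_identical(t1$pred, t2$pred)
})

test_that("surrogate routing recovers primary routing on correlated
           predictors", {
  set.seed(14)
  n <- 120
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, sd = 0.25)
  y <- ifelse(x1 > 0, 10, 0)
  tr <- grow1(cbind(x1, x2), y, min_leaf = 2)
  # held-out points with the primary predictor masked
  m <- 300
  h1 <- rnorm(m)
  h2 <- h1 + rnorm(m, sd = 0.25)
  full <- predict1(tr, cbind(h1, h2))
  masked <- predict1(tr, cbind(NA_real_, h2))
  expect_gte(mean(full == masked), 0.9)

  # all-missing row still yields a finite prediction (larger-child fallback)
  expect_true(is.finite(predict1(tr, cbind(NA_real_, NA_real_))))
})

test_that("forest fitting is seed-deterministic and a 1-tree forest equals
           its tree", {
  pair <- default_pair(2, n_ref = 50, n_target = 20)
  f1 <- age_forest(pair$ref, n_trees = 20, seed = 5)
  f2 <- age_forest(pair$ref, n_trees = 20, seed = 5)
  expect_identical(predict(f1, pair$target), predict(f2, pair$target))
  f3 <- age_forest(pair$ref, n_trees = 20, seed = 6)
  expect_false(identical(predict(f1, pair$target), predict(f3, pair$target)))

  fo <- age_forest(pair$ref, n_trees = 1, seed = 11, oob = FALSE)
  tp <- clockbias:::.cb_predict_trees(
    fo$trees, clockbias:::forest_features(pair$target, cpg_names(pair$target)))
  expect_identical(predict(fo, pair$target), rowMeans(tp))
})

test_that("forest predictions stay within the training-age hull", {
  pair <- default_pair(6, n_ref = 80, n_target = 40)
  f <- age_forest(pair$ref, cpgs = clock_names(pair$panel), n_trees = 30,
                  seed = 2, oob = FALSE)
  rng <- range(pair$ref$age)
  set.seed(10)
  # random inputs, including values far outside the training distribution
  Xr <- cbind(sample(0:1, 200, TRUE),
              matrix(runif(200 * 11, 0, 100), 200, 11))
  pr <- predict(f, Xr)
  expect_true(all(pr >= rng[1] & pr <= rng[2]))
  pr2 <- predict(f, pair$target)
  expect_true(all(pr2 >= rng[1] & pr2 <= rng[2]))
})

test_that("forest approximates a noiseless monotone function", {
  set.seed(19)
  x <- matrix(runif(200, 0, 9), ncol = 1)
  y <- 2 * x[, 1]
  f <- age_forest(x, age = y, n_trees = 100, seed = 4, oob = FALSE)
  xt <- matrix(runif(200, 0.5, 8.5), ncol = 1)
  mae <- mean(abs(predict(f, xt) - 2 * xt[, 1]))
  expect_lt(mae, 0.5)
})

test_that("oob accounting, summary and residuals are consistent", {
  pair <- default_pair(13, n_ref = 60, n_target = 20)
  f <- age_forest(pair$ref, n_trees = 50, seed = 8)
  expect_identical(dim(f$inbag), c(60L, 50L))
  expect_equal(unname(colSums(f$inbag)), rep(60, 50))
  r <- residuals(f)
  expect_length(r, 60)
  s <- summary(f)
  expect_equal(s$oob_mae, mean(abs(r[!is.na(r)])))
})
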