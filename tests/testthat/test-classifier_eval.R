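test_that("the Gaussian kernel evaluates, bounds and symmetrises correctly", {
  expect_equal(gaussian_kernel(c(0, 0), c(0, 2), 1), exp(-2))
  withr::with_seed(1, {
    x <- rnorm(5); z <- rnorm(5)
  })
  expect_equal(gaussian_kernel(x, x, 2), 1)
  expect_equal(gaussian_kernel(x, z, 1.3), gaussian_kernel(z, x, 1.3))
  expect_true(gaussian_kernel(x, z, 0.5) > 0 && gaussian_kernel(x, z, 0.5) <= 1)
  expect_error(gaussian_kernel(x, z, 0), "positive")
  expect_error(gaussian_kernel(x, z[1:3], 1), "equal length")
})

test_that("a separable pair and the XOR toy are fitted exactly", {
  pair <- tibble::tibble(f = c(0, 1), label = c(0L, 1L))
  mod <- train_svm(pair, C = 10, sigma = 1)
  pr <- predict(mod, pair)
  expect_identical(pr$.pred, c(-1L, 1L))

  xor <- tibble::tibble(a = c(0, 1, 0, 1), b = c(0, 1, 1, 0),
                        label = c(1L, 1L, 0L, 0L))
  mx <- train_svm(xor, C = 100, sigma = 0.5)
  px <- predict(mx, xor)
  expect_identical(px$.pred, c(1L, 1L, -1L, -1L))  # RBF separates XOR
})

test_that("every fit satisfies the dual KKT constraints", {
  withr::with_seed(2, {
    for (i in 1:5) {
      n <- 40
      X <- matrix(rnorm(n * 3), n, 3)
      y <- as.integer(X[, 1] + rnorm(n, sd = 0.5) > 0)
      d <- feature_tibble(X, y)
      C <- sample(c(0.5, 1, 10), 1)
      mod <- train_svm(d, C = C)
      expect_lt(abs(sum(mod$sv_coefs)), 1e-6)          # sum alpha_i y_i = 0
      expect_true(all(mod$alphas >= -1e-9 & mod$alphas <= C + 1e-9))
    }
  })
  expect_error(train_svm(tibble::tibble(a = 1:4, label = 1L)), "single class")
})

test_that("decision scores equal the explicit kernel-expansion oracle", {
  withr::with_seed(3, {
    X <- matrix(rnorm(60), 20, 3)
    y <- as.integer(X[, 1] > 0)
    Q <- matrix(rnorm(15), 5, 3)
  })
  mod <- train_svm(feature_tibble(X, y), C = 2, sigma = 1.5)
  pr <- predict(mod, Q)
  # brute-force sum over support vectors, scalar kernel calls
  oracle <- sapply(seq_len(nrow(Q)), function(r) {
    sum(sapply(seq_along(mod$sv_coefs), function(i) {
      mod$sv_coefs[i] * gaussian_kernel(mod$support_vectors[i, ], Q[r, ], mod$sigma)
    })) + mod$bias
  })
  expect_equal(pr$.score, oracle, tolerance = 1e-10)
  # duplicated query rows get duplicated scores
  pr2 <- predict(mod, Q[c(1, 1), ])
  expect_equal(pr2$.score[1], pr2$.score[2])
  expect_error(predict(mod, Q[, 1:2]), "dimension mismatch")
})

test_that("libsvm's own decision values agree with our re-evaluation", {
  withr::with_seed(4, {
    X <- matrix(rnorm(100), 25, 4)
    y <- as.integer(X[, 2] - X[, 3] > 0)
  })
  d <- feature_tibble(X, y)
  mod <- train_svm(d, C = 3, sigma = 2)
  ref <- e1071::svm(x = X, y = factor(ifelse(y == 1, 1, -1), levels = c(-1, 1)),
                    scale = FALSE, kernel = "radial", gamma = 1 / (2 * 2^2),
                    cost = 3)
  dv <- attr(stats::predict(ref, X, decision.values = TRUE), "decision.values")
  sign_fix <- if (grepl("^-1", colnames(dv)[1])) -1 else 1
  expect_equal(predict(mod, d)$.score, sign_fix * as.numeric(dv),
               tolerance = 1e-8)
})

test_that("sensitivity, specificity and the tie rule behave as defined", {
  rep <- evaluate(c(1, 1, 0, 0), c(2, 1, -1, -2))
  expect_equal(rep$sen, 1)
  expect_equal(rep$spe, 1)
  expect_equal(rep$auc, 1)
  all_tied <- evaluate(c(1, 1, 0, 0), rep(0.3, 4))
  expect_equal(all_tied$auc, 0.5)
  expect_error(evaluate(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("pairwise AUC equals the rank-based Mann-Whitney oracle", {
  withr::with_seed(5, {
    for (i in 1:20) {
      y <- c(rep(1, 50), rep(0, 50))
      scores <- round(rnorm(100), 1)  # rounding forces ties
      a <- evaluate(y, scores)$auc
      # independent oracle: average-rank Mann-Whitney statistic
      r <- rank(scores)
      u <- sum(r[y == 1]) - 50 * 51 / 2
      expect_equal(a, u / (50 * 50), tolerance = 1e-12)
      # complement law under the tie rule
      expect_equal(evaluate(y, -scores)$auc, 1 - a, tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly increasing score transforms", {
  withr::with_seed(6, {
    y <- rbinom(80, 1, 0.4)
    y[1:2] <- c(0, 1)
    s <- rnorm(80)
  })
  a <- evaluate(y, s)$auc
  expect_equal(evaluate(y, exp(s))$auc, a)
  expect_equal(evaluate(y, 3 * s + 10)$auc, a)
})

test_that("roc points span (0,0) to (1,1) and match AUC direction", {
  withr::with_seed(7, {
    y <- c(rep(1, 30), rep(0, 30))
    s <- rnorm(60, mean = ifelse(y == 1, 1, 0))
  })
  roc <- roc_points(y, s)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(roc$fpr[nrow(roc)], 1)
  expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))
})

test_that("stratified cross-validation recovers a separable geometry", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(40, 5), 20, 2), matrix(rnorm(40, -5), 20, 2))
    y <- c(rep(1L, 20), rep(0L, 20))
  })
  d <- feature_tibble(X, y)
  cv <- cross_validate(d, strategy = "none", n_folds = 4, seed = 1)
  expect_equal(cv$summary$auc, 1)
  expect_equal(cv$summary$sen, mean(cv$folds$sen))  # aggregate = fold mean
  expect_equal(nrow(tidy(cv)), 4)
})

test_that("label shuffling drives cross-validated AUC to chance", {
  withr::with_seed(9, {
    X <- matrix(rnorm(200 * 4), 200, 4)
    y <- sample(rep(0:1, each = 100))
  })
  cv <- cross_validate(feature_tibble(X, y), strategy = "none",
                       n_folds = 5, seed = 2)
  expect_lt(abs(cv$summary$auc - 0.5), 0.1)
})

test_that("the held-out fold cannot leak into the fitted model", {
  withr::with_seed(10, {
    X <- matrix(rnorm(120), 40, 3)
    y <- as.integer(X[, 1] > 0)
  })
  d <- feature_tibble(X, y)
  folds <- balansite:::stratified_folds(d$label, 4, seed = 3)
  tr <- d[folds != 1, ]
  te <- d[folds == 1, ]
  fit1 <- fit_evaluate(tr, te, strategy = "none", seed = 5)
  te_bad <- te
  te_bad$label <- 1L - te_bad$label
  fit2 <- fit_evaluate(tr, te_bad, strategy = "none", seed = 5)
  expect_identical(fit1$model$sv_coefs, fit2$model$sv_coefs)
  expect_identical(fit1$model$bias, fit2$model$bias)
})

test_that("unsatisfiable fold counts raise an actionable error", {
  d <- feature_tibble(matrix(rnorm(30), 15, 2), c(rep(0L, 13), 1L, 1L))
  expect_error(cross_validate(d, n_folds = 10), "fewer folds")
})
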