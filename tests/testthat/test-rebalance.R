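test_that("optimal scale reproduces the closed form and its bounds", {
  expect_identical(optimal_scale(3, 1000), 55L)    # sqrt(3000) = 54.77
  expect_identical(optimal_scale(10, 1000), 100L)  # exact square root
  expect_identical(optimal_scale(4, 4), 4L)        # m = M forces s = m
  expect_error(optimal_scale(0, 10), "positive")
  expect_error(optimal_scale(10, 3), "must not exceed")
})

test_that("optimal scale matches the brute-force ratio-sum minimiser", {
  brute <- function(m, M) {
    s <- m:M
    s[which.min(s / m + M / s)]
  }
  withr::with_seed(3, {
    for (i in 1:200) {
      m <- sample(1:2000, 1)
      M <- sample(m:10000, 1)
      s_hat <- optimal_scale(m, M)
      s_star <- brute(m, M)
      # rounding may land on either neighbour of the real-valued optimum
      expect_lte(abs(s_hat - s_star), 1)
    }
  })
})

test_that("optimal scale is monotone in each argument", {
  M <- 5000
  s_m <- sapply(1:100, function(m) optimal_scale(m, M))
  expect_true(all(diff(s_m) >= 0))
  s_M <- sapply(200:400, function(M) optimal_scale(150, M))
  expect_true(all(diff(s_M) >= 0))
})

test_that("attention rows are stochastic and identical rows share weight", {
  X <- matrix(rep(c(1, 2, 3), 4), nrow = 4, byrow = TRUE)
  A <- attention_scores(X)
  expect_equal(unname(A), matrix(1 / 4, 4, 4))
  withr::with_seed(5, {
    Y <- matrix(rnorm(60), 10, 6)
  })
  A2 <- attention_scores(Y)
  expect_true(all(A2 >= 0 & A2 <= 1))
  expect_equal(rowSums(A2), rep(1, 10), tolerance = 1e-9)
})

test_that("attention diagonal matches a hand cosine + softmax computation", {
  X <- rbind(c(1, 0), c(0, 1), c(1, 0))  # e1, e2, e1
  A <- attention_scores(X)
  # oracle: cosine rows then softmax, written out independently
  cosine <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1))
  oracle <- t(apply(cosine, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(unname(A), oracle, tolerance = 1e-12)
  expect_equal(diag(A), diag(oracle), tolerance = 1e-12)
})

test_that("attention errors on zero rows and mismatched dimensions", {
  expect_error(attention_scores(rbind(c(0, 0), c(1, 1))), "index 1")
  expect_error(attention_scores(matrix(1, 2, 3), matrix(1, 2, 4)),
               "dimension mismatch")
})

test_that("two-stage undersampling keeps everything when s = M", {
  withr::with_seed(8, {
    neg <- matrix(runif(40), 10, 4)
    pos <- matrix(runif(8), 2, 4)
  })
  plan <- attention_undersample(neg, pos, s = 10)
  expect_identical(plan$final_keep, 1:10)
  expect_identical(plan$n_synthesize, 8L)
})

test_that("stage 2 drops the positive-like negative on the toy geometry", {
  # three near-duplicate negatives plus one isolated negative collinear
  # with the lone positive
  neg <- rbind(c(1, 0), c(0.99, 0.1), c(1, 0.05), c(0, 1))
  pos <- rbind(c(0, 1))
  plan <- attention_undersample(neg, pos, s = 2)

  # oracle: both attention stages computed by hand from first principles
  unit <- function(M) M / sqrt(rowSums(M^2))
  softmax_rows <- function(S) t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  a1 <- diag(softmax_rows(unit(neg) %*% t(unit(neg))))
  keep1 <- sort(order(a1)[1:3])
  Xc <- rbind(neg[keep1, ], pos)
  a2 <- diag(softmax_rows(unit(Xc) %*% t(unit(Xc))))[1:3]
  keep2 <- sort(keep1[order(-a2)[1:2]])

  expect_identical(plan$stage1_keep, keep1)
  expect_identical(plan$final_keep, keep2)
  expect_false(4 %in% plan$final_keep)  # the positive-like negative goes
})

test_that("undersampling plans honour their contracts", {
  withr::with_seed(21, {
    neg <- matrix(runif(200), 20, 10)
    pos <- matrix(runif(50), 5, 10)
  })
  for (s in c(3, 8, 15)) {
    plan <- attention_undersample(neg, pos, s = s)
    expect_length(plan$final_keep, s)
    expect_true(all(plan$final_keep %in% plan$stage1_keep))
    expect_length(plan$stage1_keep, ceiling((s + 20) / 2))
  }
  expect_error(attention_undersample(neg, pos, s = 21), "cannot exceed")
})

test_that("attention undersampling is deterministic and permutation-equivariant", {
  withr::with_seed(22, {
    neg <- matrix(runif(120), 12, 10)
    pos <- matrix(runif(30), 3, 10)
  })
  p1 <- attention_undersample(neg, pos, s = 5)
  p2 <- attention_undersample(neg, pos, s = 5)
  expect_identical(p1$final_keep, p2$final_keep)
  perm <- withr::with_seed(23, sample(12))
  p3 <- attention_undersample(neg[perm, ], pos, s = 5)
  expect_setequal(perm[p3$final_keep], p1$final_keep)
})

test_that("random undersampling is seeded and uniform", {
  neg <- matrix(0.5, 10, 2)
  expect_identical(random_undersample(neg, 10, seed = 4), 1:10)
  expect_identical(random_undersample(neg, 5, seed = 4),
                   random_undersample(neg, 5, seed = 4))
  counts <- integer(10)
  for (seed in 1:1000) {
    counts[random_undersample(neg, 5, seed = seed)] <-
      counts[random_undersample(neg, 5, seed = seed)] + 1L
  }
  # each index is a Binomial(1000, 0.5) draw
  expect_true(all(abs(counts / 1000 - 0.5) < 0.05))
})

test_that("SMOTE interpolates inside the minority bounding box", {
  withr::with_seed(31, {
    pos <- tibble::as_tibble(matrix(runif(60), 12, 5),
                             .name_repair = ~sprintf("f%d", 1:5))
  })
  synth <- smote_oversample(pos, 50, k_neighbors = 3, seed = 1)
  expect_equal(nrow(synth), 50)
  lo <- sapply(pos, min); hi <- sapply(pos, max)
  for (j in 1:5) {
    expect_true(all(synth[[j]] >= lo[j] - 1e-12 & synth[[j]] <= hi[j] + 1e-12))
  }
  expect_equal(nrow(smote_oversample(pos, 0, 3, seed = 1)), 0)
  ident <- pos[rep(1, 6), ]
  s2 <- smote_oversample(ident, 10, k_neighbors = 2, seed = 1)
  expect_true(all(apply(s2, 1, function(r) all(r == unlist(pos[1, ])))))
  expect_error(smote_oversample(pos[1:3, ], 5, k_neighbors = 3), "too few")
})

test_that("rebalance plans survive a JSON round trip with 0-based indices", {
  withr::with_seed(41, {
    neg <- matrix(runif(80), 8, 10)
    pos <- matrix(runif(20), 2, 10)
  })
  plan <- attention_undersample(neg, pos, s = 4)
  path <- tempfile(fileext = ".json")
  write_plan(plan, path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(raw$final_keep, plan$final_keep - 1L)  # 0-based on disk
  back <- read_plan(path)
  expect_identical(back$final_keep, plan$final_keep)
  expect_identical(back$s, plan$s)
})
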