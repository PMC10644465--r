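test_that("windows are cut around sites and padded at termini", {
  paths <- write_tiny_fasta(
    list(prot1 = "MKAV"),
    data.frame(record_id = "prot1", position = 2, residue = "K", label = 1)
  )
  w <- read_sites(paths$fasta, paths$sites, window_len = 5)
  expect_equal(w$window, "XMKAV")
  expect_equal(substr(w$window, 3, 3), "K")
  expect_equal(w$label, 1L)
})

test_that("a generated protein yields one centred 21-mer per site", {
  prot <- withr::with_seed(7, random_window(60))
  kpos <- which(strsplit(prot, "")[[1]] == "K")[1:3]
  kpos <- kpos[!is.na(kpos)]
  skip_if(length(kpos) < 1)  # K occurs in a random 60-mer almost surely
  paths <- write_tiny_fasta(
    list(p = prot),
    data.frame(record_id = "p", position = kpos, residue = "K",
               label = rep(1, length(kpos)))
  )
  w <- read_sites(paths$fasta, paths$sites, window_len = 21)
  expect_equal(nrow(w), length(kpos))
  expect_true(all(nchar(w$window) == 21))
  expect_true(all(substr(w$window, 11, 11) == "K"))
  # oracle: direct string slicing with explicit padding
  for (i in seq_along(kpos)) {
    padded <- paste0(strrep("X", 10), prot, strrep("X", 10))
    expect_equal(w$window[i], substr(padded, kpos[i], kpos[i] + 20))
  }
})

test_that("site-table errors name the offending record, residue, parity", {
  paths <- write_tiny_fasta(
    list(prot1 = "MKAV"),
    data.frame(record_id = "prot1", position = 3, residue = "K", label = 0)
  )
  expect_error(read_sites(paths$fasta, paths$sites, 5), "mismatch.*position 3")
  paths2 <- write_tiny_fasta(
    list(prot1 = "MKAV"),
    data.frame(record_id = "ghost", position = 2, residue = "K", label = 0)
  )
  expect_error(read_sites(paths2$fasta, paths2$sites, 5), "ghost")
  expect_error(read_sites(paths$fasta, paths$sites, window_len = 4), "odd")
})

test_that("DR counting matches the hand examples", {
  v <- dr_features("AAA", d_max = 1)
  expect_equal(v$A, 3L)
  expect_equal(sum(as.matrix(v)), 3L + 2L)  # only T_A and T_AA nonzero
  expect_equal(v$AA_1, 2L)

  v2 <- dr_features("ACA", d_max = 2)
  expect_equal(v2$A, 2L)
  expect_equal(v2$C, 1L)
  expect_equal(v2$AC_1, 1L)
  expect_equal(v2$CA_1, 1L)
  expect_equal(v2$AA_2, 1L)
  expect_equal(sum(as.matrix(v2)), 3L + 2L + 1L)
})

test_that("DR dimension and block-sum laws hold on random 21-mers", {
  withr::with_seed(11, {
    wins <- replicate(100, random_window(21))
  })
  d_max <- 3
  F <- dr_features(wins, d_max = d_max)
  expect_equal(ncol(F), 20 + 400 * d_max)
  X <- as.matrix(F)
  expect_true(all(X >= 0) && all(X == round(X)))
  expect_true(all(rowSums(X[, 1:20]) == 21))
  for (k in 1:d_max) {
    blk <- X[, 20 + 400 * (k - 1) + 1:400]
    expect_true(all(rowSums(blk) == 21 - k))
  }
})

test_that("DR features agree with an independent brute-force enumerator", {
  withr::with_seed(12, {
    wins <- replicate(60, random_window(sample(9:25, 1) * 2 + 1))
  })
  for (w in wins) {
    expect_equal(as.numeric(as.matrix(dr_features(w, d_max = 3))),
                 brute_dr(w, 3))
  }
  # padded windows: 'X' contributes to no counter
  wx <- "XXAKCXA"
  expect_equal(as.numeric(as.matrix(dr_features(wx, d_max = 2))),
               brute_dr(wx, 2))
})

test_that("reversing a non-palindromic window moves pair counts only", {
  w <- "ACDEFGHIKL"
  rw <- paste(rev(strsplit(w, "")[[1]]), collapse = "")
  f <- as.matrix(dr_features(w, d_max = 2))
  fr <- as.matrix(dr_features(rw, d_max = 2))
  expect_equal(f[, 1:20], fr[, 1:20])       # composition unchanged
  expect_false(all(f == fr))                # some pair block differs
})

test_that("DR rejects out-of-range d_max and foreign characters", {
  expect_error(dr_features("ACA", d_max = 3), "smaller than the window length")
  expect_error(dr_features("AB#", d_max = 1), "outside the amino-acid alphabet")
})

test_that("min-max scaling is fitted on train only, without clipping", {
  train <- tibble::tibble(a = c(0, 5, 10), b = c(7, 7, 7), label = c(0L, 1L, 0L))
  test <- tibble::tibble(a = c(20), b = c(9), label = 1L)
  sc <- minmax_scale(train, test)
  expect_equal(sc$train$a, c(0, 0.5, 1))
  expect_equal(sc$train$b, c(0, 0, 0))       # constant column convention
  expect_equal(sc$others[[1]]$a, 2)          # out-of-range, unclipped
  expect_identical(attr(sc$train, "scaling_state"), "minmax")
  expect_error(minmax_scale(sc$train), "already")
  expect_error(minmax_scale(train, tibble::tibble(a = 1, label = 0L)),
               "column count mismatch")
})
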