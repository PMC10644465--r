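# Shared fixtures, built in code at test time.

random_window <- function(len = 21) {
  paste(sample(balansite:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Independent brute-force DR enumerator: loops over every position pair.
brute_dr <- function(window, d_max) {
  aa <- balansite:::AA_ALPHABET
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  L <- length(chars)
  d0 <- sapply(aa, function(a) sum(chars == a))
  blocks <- numeric(0)
  for (k in seq_len(d_max)) {
    blk <- matrix(0, 20, 20, dimnames = list(aa, aa))
    for (p in seq_len(L - k)) {
      i <- chars[p]; j <- chars[p + k]
      if (i %in% aa && j %in% aa) blk[i, j] <- blk[i, j] + 1
    }
    blocks <- c(blocks, as.vector(t(blk)))
  }
  unname(c(d0, blocks))
}

# Tiny FASTA + site table on disk; returns the two paths.
write_tiny_fasta <- function(records, sites) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), fa)
  st <- tempfile(fileext = ".tsv")
  utils::write.table(sites, st, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, sites = st)
}

# 2-D Gaussian minority cloud centred at (0.5, 0.5), clipped to [0, 1].
gaussian_minority <- function(n = 200, mean = 0.5, sd = 0.05, seed = 99) {
  withr::with_seed(seed, {
    X <- matrix(pmin(pmax(stats::rnorm(2 * n, mean, sd), 0), 1), n, 2)
    tibble::tibble(x1 = X[, 1], x2 = X[, 2])
  })
}

fast_gan <- function(epochs = 200, seed = 1) {
  gan_config(hidden_sizes = c(32, 32), epochs = epochs, seed = seed)
}
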