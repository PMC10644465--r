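# Seeded synthetic data generators. These emulate the structure the
# rebalancing method assumes -- a large multi-cluster majority class, a
# scarce minority class, and (in peptide mode) a compositional motif bias --
# not the biology of real carbonylation data.

#' Synthetic imbalanced feature cloud
#'
#' Negatives are drawn from a mixture of `n_neg_clusters` Gaussians whose
#' centres are themselves random; positives come from a single Gaussian
#' offset from the negative centroid by `class_separation` within-class
#' standard deviations along a random direction. All values are squashed
#' into `(0, 1)` with a logistic transform (rather than clipped, which would
#' pile mass on the boundary and distort cosine similarities).
#'
#' @param n_neg,n_pos Class sizes (`n_neg >= n_pos >= 1`).
#' @param d Feature dimension.
#' @param class_separation Distance between class means in units of the
#'   within-class standard deviation; 0 means no signal.
#' @param n_neg_clusters Number of negative-class mixture components
#'   (default 3, so attention undersampling has structure to exploit).
#' @param noise_sd Within-class standard deviation.
#' @param seed Integer seed; output is reproducible.
#' @return A feature tibble with `n_neg + n_pos` rows (negatives first) and
#'   a `label` column.
#' @export
make_feature_dataset <- function(n_neg = 1000, n_pos = 100, d = 10,
                                 class_separation = 2, n_neg_clusters = 3,
                                 noise_sd = 1, seed = 1) {
  n_neg <- check_positive_int(n_neg, "n_neg")
  n_pos <- check_positive_int(n_pos, "n_pos")
  d <- check_positive_int(d, "d")
  n_neg_clusters <- check_positive_int(n_neg_clusters, "n_neg_clusters")
  if (n_pos > n_neg) abort("`n_neg` must be at least `n_pos`")
  if (noise_sd <= 0) abort("`noise_sd` must be positive")

  with_seed(seed, {
    centres <- matrix(stats::rnorm(n_neg_clusters * d, sd = 1.5 * noise_sd),
                      n_neg_clusters, d)
    comp <- sample.int(n_neg_clusters, n_neg, replace = TRUE)
    Xn <- centres[comp, , drop = FALSE] +
      matrix(stats::rnorm(n_neg * d, sd = noise_sd), n_neg, d)
    dir <- stats::rnorm(d)
    dir <- dir / sqrt(sum(dir^2))
    mu_pos <- colMeans(centres) + class_separation * noise_sd * dir
    Xp <- matrix(mu_pos, n_pos, d, byrow = TRUE) +
      matrix(stats::rnorm(n_pos * d, sd = noise_sd), n_pos, d)
    X <- stats::plogis(rbind(Xn, Xp) / (2 * noise_sd))
    feature_tibble(X, c(rep(0L, n_neg), rep(1L, n_pos)),
                   sprintf("f%03d", seq_len(d)))
  })
}

# Signature residues planted at fixed offsets from the centre in positive
# windows; arbitrary synthetic choices, not a real carbonylation motif.
MOTIF_OFFSETS <- c(-5L, -2L, 1L, 3L)
MOTIF_RESIDUES <- c("D", "E", "P", "G")

#' Synthetic peptide windows with a plantable motif bias
#'
#' Generates fixed-length windows centred on `centre_residue`. Background
#' positions are uniform over the 20 standard residues. In positive windows,
#' each of four fixed offsets from the centre receives its signature residue
#' with probability `1/20 + motif_bias` (instead of the background `1/20`);
#' `motif_bias = 0` makes the classes compositionally identical.
#'
#' @inheritParams make_feature_dataset
#' @param window_len Odd window length (default 21).
#' @param centre_residue Centre residue, one of `K`, `R`, `T`, `P`.
#' @param motif_bias Excess signature-residue probability in `[0, 1]`.
#' @return A windows tibble (columns `window`, `label`), negatives first.
#' @export
make_peptide_dataset <- function(n_neg = 1000, n_pos = 100, window_len = 21,
                                 centre_residue = "K", motif_bias = 0.5,
                                 seed = 1) {
  n_neg <- check_positive_int(n_neg, "n_neg")
  n_pos <- check_positive_int(n_pos, "n_pos")
  window_len <- check_window_len(window_len)
  if (!centre_residue %in% CENTRE_RESIDUES) {
    abort("`centre_residue` must be one of K, R, T, P")
  }
  if (motif_bias < 0 || motif_bias > 1) abort("`motif_bias` must be in [0, 1]")
  centre <- (window_len + 1L) %/% 2L
  motif_pos <- centre + MOTIF_OFFSETS
  motif_pos_ok <- motif_pos >= 1L & motif_pos <= window_len

  draw <- function(n, biased) {
    mat <- matrix(sample(AA_ALPHABET, n * window_len, replace = TRUE),
                  n, window_len)
    mat[, centre] <- centre_residue
    if (biased && motif_bias > 0) {
      # Overwrite probability chosen so that the marginal signature
      # frequency is exactly background (1/20) + motif_bias.
      q <- min(motif_bias * 20 / 19, 1)
      for (k in which(motif_pos_ok)) {
        hit <- stats::runif(n) < q
        mat[hit, motif_pos[k]] <- MOTIF_RESIDUES[k]
      }
    }
    apply(mat, 1, paste, collapse = "")
  }

  with_seed(seed, {
    tibble(
      window = c(draw(n_neg, FALSE), draw(n_pos, TRUE)),
      label = c(rep(0L, n_neg), rep(1L, n_pos))
    )
  })
}
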