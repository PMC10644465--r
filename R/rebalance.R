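#' Optimal sampling scale for two-way rebalancing
#'
#' For a training set with `m` minority (positive) and `M` majority
#' (negative) samples, the two-way strategy oversamples the minority and
#' undersamples the majority to a common class size `s`. The scale that
#' minimises the sum of the oversampling ratio `s / m` and the undersampling
#' ratio `M / s` is `s = sqrt(m * M)`; this function returns it rounded to
#' the nearest integer (half away from zero) and clamped into `[m, M]`.
#'
#' @param m Number of minority-class samples (positive integer).
#' @param M Number of majority-class samples; must satisfy `M >= m`.
#' @return The optimal scale `s` as a single integer in `[m, M]`.
#' @examples
#' optimal_scale(3, 1000)   # 55
#' optimal_scale(100, 1000) # 316
#' @export
optimal_scale <- function(m, M) {
  m <- check_positive_int(m, "m")
  M <- check_positive_int(M, "M")
  if (m > M) abort(sprintf("`m` (%d) must not exceed `M` (%d)", m, M))
  s <- as.integer(floor(sqrt(as.numeric(m) * as.numeric(M)) + 0.5))
  min(max(s, m), M)
}

#' Row-normalised attention between samples
#'
#' Computes the cosine similarity between every query row and every key row
#' and normalises each row with a softmax, giving a row-stochastic attention
#' matrix: every entry lies in `[0, 1]` and every row sums to 1. For square
#' (self-attention) inputs the diagonal `A[i, i]` is the sample's normalised
#' self-similarity: low values mark samples that resemble many others
#' (representative), high values mark outliers.
#'
#' @param queries,keys Feature tibbles or numeric matrices with matching
#'   column dimension; a `label` column, if present, is dropped. `keys`
#'   defaults to `queries` (self-attention).
#' @return An `n_queries x n_keys` attention matrix.
#' @export
attention_scores <- function(queries, keys = queries) {
  Q <- as_unit_rows(queries, "queries")
  K <- as_unit_rows(keys, "keys")
  if (ncol(Q) != ncol(K)) {
    abort(sprintf("dimension mismatch: queries have %d features, keys %d",
                  ncol(Q), ncol(K)))
  }
  S <- Q %*% t(K)             # cosine similarities in [-1, 1]
  S <- S - apply(S, 1, max)   # stabilised row softmax
  E <- exp(S)
  E / rowSums(E)
}

as_unit_rows <- function(data, what) {
  X <- if (is.data.frame(data)) feature_parts(data, require_label = FALSE)$X
       else as.matrix(data)
  nrm <- sqrt(rowSums(X^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0) {
    abort(sprintf("zero-norm row in `%s` at index %d: cosine similarity is undefined",
                  what, zero[1]))
  }
  X / nrm
}

#' Two-stage attention-based undersampling of the majority class
#'
#' Selects `s` of the `M` majority (negative) samples in two stages driven by
#' self-attention diagonals. Stage 1 computes self-attention among the
#' negatives and keeps the `ceiling((s + M) / 2)` samples with the smallest
#' diagonal values — the most representative negatives. Stage 2 stacks the
#' kept negatives with all positives, recomputes self-attention on the
#' combined set, and among the negative rows keeps the `s` with the largest
#' diagonal values — those least similar to the rest of the combined set and
#' hence least positive-like. Ties are broken towards the lower original
#' index, so the procedure is deterministic.
#'
#' @param neg Majority-class feature tibble or matrix (`M` rows).
#' @param pos Minority-class feature tibble or matrix with the same feature
#'   columns (`m` rows).
#' @param s Target class size; `s <= M`. Defaults to
#'   `optimal_scale(nrow(pos), nrow(neg))`.
#' @return A `rebalance_plan`: a list with `m`, `M`, `s`, `stage1_keep`,
#'   `final_keep` (1-based row indices into `neg`, in original order), and
#'   `n_synthesize = max(s - m, 0)`.
#' @export
attention_undersample <- function(neg, pos, s = NULL) {
  Xn <- if (is.data.frame(neg)) feature_parts(neg, require_label = FALSE)$X else as.matrix(neg)
  Xp <- if (is.data.frame(pos)) feature_parts(pos, require_label = FALSE)$X else as.matrix(pos)
  if (ncol(Xn) != ncol(Xp)) {
    abort(sprintf("dimension mismatch: negatives have %d features, positives %d",
                  ncol(Xn), ncol(Xp)))
  }
  M <- nrow(Xn)
  m <- nrow(Xp)
  s <- if (is.null(s)) optimal_scale(min(m, M), M) else check_positive_int(s, "s")
  if (s > M) abort(sprintf("`s` (%d) cannot exceed the number of negatives (%d)", s, M))

  # Stage 1: most representative negatives = smallest self-attention diagonal.
  a1 <- diag(attention_scores(Xn))
  n1 <- ceiling((s + M) / 2)
  stage1_keep <- sort(order(a1, seq_along(a1))[seq_len(n1)])

  # Stage 2: among kept negatives + all positives, keep the s negatives
  # least similar to the combined set (largest diagonal).
  Xc <- rbind(Xn[stage1_keep, , drop = FALSE], Xp)
  a2 <- diag(attention_scores(Xc))[seq_len(n1)]
  final_keep <- sort(stage1_keep[order(-a2, seq_along(a2))[seq_len(s)]])

  structure(
    list(m = m, M = M, s = s,
         stage1_keep = stage1_keep,
         final_keep = final_keep,
         n_synthesize = max(s - m, 0L)),
    class = "rebalance_plan"
  )
}

#' @export
print.rebalance_plan <- function(x, ...) {
  cat(sprintf(
    "<rebalance_plan> m = %d positives, M = %d negatives, scale s = %d\n",
    x$m, x$M, x$s))
  cat(sprintf("  stage 1 keeps %d negatives; final keep %d; synthesize %d positives\n",
              length(x$stage1_keep), length(x$final_keep), x$n_synthesize))
  invisible(x)
}

#' @export
tidy.rebalance_plan <- function(x, ...) {
  tibble(index = x$final_keep, stage1 = TRUE, final = TRUE) |>
    dplyr::bind_rows(
      tibble(index = setdiff(x$stage1_keep, x$final_keep),
             stage1 = TRUE, final = FALSE)
    ) |>
    dplyr::arrange(.data$index)
}

#' @export
glance.rebalance_plan <- function(x, ...) {
  tibble(m = x$m, M = x$M, s = x$s,
         n_stage1 = length(x$stage1_keep),
         n_final = length(x$final_keep),
         n_synthesize = x$n_synthesize)
}

#' Serialise a rebalance plan to JSON
#'
#' Kept-negative indices are written 0-based, as documented for the on-disk
#' format; [read_plan()] restores 1-based indices.
#'
#' @param plan A `rebalance_plan`.
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(m = plan$m, M = plan$M, s = plan$s,
         stage1_keep = plan$stage1_keep - 1L,
         final_keep = plan$final_keep - 1L,
         n_synthesize = plan$n_synthesize),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(m = as.integer(p$m), M = as.integer(p$M), s = as.integer(p$s),
         stage1_keep = as.integer(p$stage1_keep) + 1L,
         final_keep = as.integer(p$final_keep) + 1L,
         n_synthesize = as.integer(p$n_synthesize)),
    class = "rebalance_plan"
  )
}

#' Baseline resamplers: random undersampling and SMOTE interpolation
#'
#' `random_undersample()` draws `s` majority rows uniformly without
#' replacement. `smote_oversample()` synthesises `n_new` minority vectors by
#' the standard SMOTE rule: pick a minority sample, pick one of its
#' `k_neighbors` nearest minority neighbours, and interpolate uniformly
#' between them.
#'
#' @param neg Majority-class feature tibble or matrix.
#' @param s Number of rows to keep.
#' @param seed Integer seed; both functions are reproducible.
#' @return `random_undersample()` returns sorted 1-based row indices.
#' @export
random_undersample <- function(neg, s, seed) {
  M <- nrow(neg)
  s <- check_positive_int(s, "s")
  if (s > M) abort(sprintf("`s` (%d) cannot exceed the number of rows (%d)", s, M))
  with_seed(seed, sort(sample.int(M, s)))
}

#' @rdname random_undersample
#' @param pos Minority-class feature tibble (with or without `label`).
#' @param n_new Number of synthetic rows to generate (`>= 0`).
#' @param k_neighbors Neighbourhood size; requires `nrow(pos) > k_neighbors`.
#' @return `smote_oversample()` returns a tibble of `n_new` synthetic rows
#'   (label 1 when the input had labels).
#' @export
smote_oversample <- function(pos, n_new, k_neighbors = 5, seed = 1) {
  p <- feature_parts(pos, require_label = FALSE)
  n_new <- as.integer(n_new)
  if (n_new < 0) abort("`n_new` must be non-negative")
  k_neighbors <- check_positive_int(k_neighbors, "k_neighbors")
  m <- nrow(p$X)
  if (m <= k_neighbors) {
    abort(sprintf("too few minority samples (%d) for k_neighbors = %d; need more than k samples",
                  m, k_neighbors))
  }
  if (n_new == 0) {
    out <- feature_tibble(p$X[0, , drop = FALSE], if (!is.null(p$y)) integer(0),
                          p$feature_names)
    return(out)
  }
  D <- as.matrix(stats::dist(p$X))
  diag(D) <- Inf
  nn <- do.call(rbind, lapply(seq_len(m), function(i) {
    order(D[i, ])[seq_len(k_neighbors)]
  }))
  new <- with_seed(seed, {
    base <- sample.int(m, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    lam <- stats::runif(n_new)
    p$X[base, , drop = FALSE] +
      lam * (p$X[pick, , drop = FALSE] - p$X[base, , drop = FALSE])
  })
  feature_tibble(new, if (!is.null(p$y)) rep(1L, n_new), p$feature_names)
}
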