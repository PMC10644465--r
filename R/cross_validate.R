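REBALANCE_STRATEGIES <- c("none", "random_under", "smote", "attention_gan")

#' Rebalance a training set to the optimal sampling scale
#'
#' Applies one of four strategies to a (scaled) feature tibble and returns a
#' class-balanced training set of `s` positives and `s` negatives (except
#' `"none"`, which returns the data untouched):
#'
#' * `"attention_gan"` — attention-based undersampling of the negatives plus
#'   GAN oversampling of the positives (the two-way strategy);
#' * `"random_under"` — uniform random undersampling plus GAN oversampling
#'   (ablates the attention selection);
#' * `"smote"` — attention-based undersampling plus SMOTE interpolation
#'   (ablates the GAN);
#' * `"none"` — no resampling.
#'
#' Features must already be min-max scaled to `[0, 1]` (see
#' [minmax_scale()]): the GAN's sigmoid output lives there, and the cosine
#' attention is computed on the scaled features.
#'
#' @param data Scaled feature tibble with a binary `label` column.
#' @param strategy One of `"none"`, `"random_under"`, `"smote"`,
#'   `"attention_gan"`.
#' @param s Target class size; default [optimal_scale()] of the class counts.
#' @param gan A [gan_config()] for the GAN-based strategies (its seed is
#'   overridden by `seed`).
#' @param k_neighbors SMOTE neighbourhood size (capped at `m - 1`).
#' @param seed Integer seed controlling every stochastic step.
#' @return A list with `data` (the rebalanced tibble, negatives first) and
#'   `plan` (a `rebalance_plan`, or `NULL` for `"none"`).
#' @export
rebalance <- function(data, strategy = "attention_gan", s = NULL,
                      gan = gan_config(), k_neighbors = 5, seed = 1) {
  strategy <- match.arg(strategy, REBALANCE_STRATEGIES)
  if (strategy == "none") return(list(data = data, plan = NULL))
  p <- feature_parts(data)
  neg <- data[p$y == 0L, , drop = FALSE]
  pos <- data[p$y == 1L, , drop = FALSE]
  m <- nrow(pos); M <- nrow(neg)
  if (m < 1 || M < 1) abort("rebalancing requires both classes")
  s <- if (is.null(s)) optimal_scale(m, M) else check_positive_int(s, "s")

  if (strategy %in% c("attention_gan", "smote")) {
    plan <- attention_undersample(neg, pos, s)
  } else {
    keep <- random_undersample(neg, s, seed = seed)
    plan <- structure(
      list(m = m, M = M, s = s, stage1_keep = keep, final_keep = keep,
           n_synthesize = max(s - m, 0L)),
      class = "rebalance_plan")
  }
  neg_kept <- neg[plan$final_keep, , drop = FALSE]

  n_new <- plan$n_synthesize
  pos_out <- if (strategy == "smote") {
    k <- min(k_neighbors, m - 1L)
    if (n_new > 0 && k < 1) {
      abort("too few minority samples for SMOTE interpolation (need at least 2)")
    }
    bind_rows(pos, smote_oversample(pos, n_new, k_neighbors = k, seed = seed))
  } else {
    cfg <- gan
    cfg$seed <- as.integer(seed)
    gan_oversample(pos, n_new, config = cfg)
  }
  if (nrow(pos_out) > s) pos_out <- pos_out[seq_len(s), , drop = FALSE]
  pos_out$label <- 1L

  out <- bind_rows(neg_kept, pos_out)
  attr(out, "scaling_state") <- attr(data, "scaling_state")
  list(data = out, plan = plan)
}

# Stratified fold assignment: every fold gets an equal share of each class.
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# One rebalance + SVM fit; with n_repeats > 1 the cycle is repeated with
# derived seeds and the model with the best selection score is retained.
# Selection uses cross-validation inside the training set (each repeat's
# pipeline configuration is scored by stratified CV with its own seed, and
# the retained model is that repeat's full-training fit); with a single
# repeat, or when CV is impossible, the training AUC is recorded instead.
fit_best_model <- function(train_scaled, strategy, C, sigma, gan, k_neighbors,
                           seed, n_repeats = 1, s = NULL) {
  y <- feature_parts(train_scaled)$y
  n_sel_folds <- min(3L, sum(y == 1L), sum(y == 0L))
  use_cv <- n_repeats > 1 && n_sel_folds >= 2
  best <- NULL
  for (r in seq_len(n_repeats)) {
    seed_r <- seed + (r - 1L) * 1000L
    rb <- rebalance(train_scaled, strategy, s = s, gan = gan,
                    k_neighbors = k_neighbors, seed = seed_r)
    model <- train_svm(rb$data, C = C, sigma = sigma)
    score <- if (use_cv) {
      inner_cv_auc(train_scaled, strategy, C, sigma, gan, k_neighbors,
                   n_sel_folds, seed_r, s)
    } else {
      tr_pred <- stats::predict(model, train_scaled)
      evaluate(y, tr_pred$.score)$auc
    }
    if (is.null(best) || score > best$train_auc) {
      best <- list(model = model, plan = rb$plan, train_auc = score,
                   balanced = rb$data)
    }
    if (strategy == "none") break  # deterministic; repeats are identical
  }
  best
}

# Mean held-out-fold AUC of one pipeline configuration, estimated entirely
# inside the training split.
inner_cv_auc <- function(train_scaled, strategy, C, sigma, gan, k_neighbors,
                         n_folds, seed, s) {
  folds <- stratified_folds(feature_parts(train_scaled)$y, n_folds, seed)
  aucs <- vapply(seq_len(n_folds), function(f) {
    tr <- train_scaled[folds != f, , drop = FALSE]
    te <- train_scaled[folds == f, , drop = FALSE]
    s_f <- if (is.null(s)) NULL else
      min(as.integer(s), sum(tr$label == 0L))
    rb <- rebalance(tr, strategy, s = s_f, gan = gan,
                    k_neighbors = k_neighbors, seed = seed + f)
    mod <- train_svm(rb$data, C = C, sigma = sigma)
    evaluate(te$label, stats::predict(mod, te)$.score)$auc
  }, numeric(1))
  mean(aucs)
}

#' Stratified cross-validation of the rebalance-and-classify pipeline
#'
#' Splits the data into stratified folds; within each fold the scaling, the
#' rebalancing (attention selection, GAN training, interpolation) and the SVM
#' fit see only the training split, and the held-out split is scored with the
#' fitted decision function. Fold metrics are averaged into the aggregate.
#' With `n_repeats > 1`, each fold repeats the rebalance-and-fit cycle with
#' derived seeds and keeps the model with the best training AUC.
#'
#' @param data Raw (unscaled) feature tibble with a binary `label` column.
#' @param strategy Rebalancing strategy; see [rebalance()].
#' @param C,sigma SVM hyperparameters; see [train_svm()].
#' @param n_folds Number of folds (default 10).
#' @param n_repeats Rebalance-and-fit repetitions per fold (default 1; the
#'   full model-selection protocol uses 200).
#' @param seed Integer seed; the whole procedure is reproducible.
#' @param gan,k_neighbors Passed to [rebalance()].
#' @param s Optional fixed sampling scale overriding [optimal_scale()].
#' @return A `cv_result`: list with `folds` (per-fold tibble of `sen`, `spe`,
#'   `auc`), `summary` (one-row tibble of fold means), `strategy`, and the
#'   call parameters. `glance()` returns the summary, `tidy()` the fold
#'   table.
#' @export
cross_validate <- function(data, strategy = "attention_gan", C = 1,
                           sigma = NULL, n_folds = 10, n_repeats = 1,
                           seed = 1, gan = gan_config(), k_neighbors = 5,
                           s = NULL) {
  strategy <- match.arg(strategy, REBALANCE_STRATEGIES)
  n_folds <- check_positive_int(n_folds, "n_folds")
  p <- feature_parts(data)
  if (min(table(p$y)) < n_folds) {
    abort(sprintf(
      "a class has only %d samples: each of the %d folds would lack it; use fewer folds",
      min(table(p$y)), n_folds))
  }
  folds <- stratified_folds(p$y, n_folds, seed)

  fold_rows <- purrr::map(seq_len(n_folds), function(f) {
    tr <- data[folds != f, , drop = FALSE]
    te <- data[folds == f, , drop = FALSE]
    if (sum(tr$label == 1L) < 1 || sum(tr$label == 0L) < 1) {
      abort("a training split lost a class; use fewer folds")
    }
    sc <- minmax_scale(tr, list(te))
    fit <- fit_best_model(sc$train, strategy, C, sigma, gan, k_neighbors,
                          seed = seed + f * 10000L, n_repeats = n_repeats,
                          s = s)
    pred <- stats::predict(fit$model, sc$others[[1]])
    rep <- evaluate(te$label, pred$.score)
    tibble(fold = f, sen = rep$sen, spe = rep$spe, auc = rep$auc,
           s = if (is.null(fit$plan)) NA_integer_ else fit$plan$s)
  })
  folds_tbl <- bind_rows(fold_rows)

  structure(
    list(folds = folds_tbl,
         summary = tibble(strategy = strategy,
                          sen = mean(folds_tbl$sen),
                          spe = mean(folds_tbl$spe),
                          auc = mean(folds_tbl$auc)),
         strategy = strategy,
         params = list(C = C, sigma = sigma, n_folds = n_folds,
                       n_repeats = n_repeats, seed = seed, s = s)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds: Sen = %.3f  Spe = %.3f  AUC = %.3f\n",
              x$strategy, nrow(x$folds),
              x$summary$sen, x$summary$spe, x$summary$auc))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) x$summary

#' Train on one set, evaluate on another
#'
#' The external-test protocol: min-max scaling is fitted on `train`, the
#' rebalance-and-fit cycle runs `n_repeats` times with derived seeds, the
#' model with the best training AUC is retained and scored on `test`.
#'
#' @inheritParams cross_validate
#' @param train,test Raw feature tibbles with binary `label` columns.
#' @return A list with `report` (an `eval_report` on `test`), `model`,
#'   `plan`, and `train_auc`.
#' @export
fit_evaluate <- function(train, test, strategy = "attention_gan", C = 1,
                         sigma = NULL, n_repeats = 1, seed = 1,
                         gan = gan_config(), k_neighbors = 5, s = NULL) {
  strategy <- match.arg(strategy, REBALANCE_STRATEGIES)
  sc <- minmax_scale(train, list(test))
  fit <- fit_best_model(sc$train, strategy, C, sigma, gan, k_neighbors,
                        seed = seed, n_repeats = n_repeats, s = s)
  pred <- stats::predict(fit$model, sc$others[[1]])
  list(report = evaluate(test$label, pred$.score),
       model = fit$model, plan = fit$plan, train_auc = fit$train_auc)
}
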