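#' Pipeline run configuration
#'
#' Bundles every knob of the features -> rebalance -> train -> evaluate
#' pipeline. Input can be given as FASTA + site table, a windows file, a
#' feature CSV (last column `label`), or an in-memory tibble; exactly one
#' source is used, checked in that order.
#'
#' @param fasta,sites,windows,features Input paths (any may be `NULL`).
#' @param data In-memory windows or feature tibble.
#' @param test_data Optional in-memory test set (same form as `data`).
#' @param test_features,test_windows Optional test-set paths.
#' @param residue Centre residue this model is for (`K`, `R`, `T` or `P`);
#'   metadata carried into reports.
#' @param d_max DR feature distance bound.
#' @param strategy Rebalancing strategy; see [rebalance()].
#' @param C,sigma SVM hyperparameters.
#' @param n_folds,n_repeats Cross-validation folds and rebalance-and-fit
#'   repetitions (the full model-selection protocol uses `n_repeats = 200`).
#' @param s Optional fixed sampling scale.
#' @param gan A [gan_config()].
#' @param k_neighbors SMOTE neighbourhood size.
#' @param seed Integer seed (mandatory for reproducible runs).
#' @param out_dir Optional directory for artifacts (features CSV, plan JSON,
#'   model JSON, report JSON, config JSON).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, sites = NULL, windows = NULL,
                       features = NULL, data = NULL, test_data = NULL,
                       test_features = NULL, test_windows = NULL,
                       residue = "K", d_max = 3, strategy = "attention_gan",
                       C = 1, sigma = NULL, n_folds = 10, n_repeats = 200,
                       s = NULL, gan = gan_config(), k_neighbors = 5,
                       seed = 1, out_dir = NULL) {
  strategy <- match.arg(strategy, REBALANCE_STRATEGIES)
  if (!residue %in% CENTRE_RESIDUES) abort("`residue` must be one of K, R, T, P")
  structure(
    list(fasta = fasta, sites = sites, windows = windows, features = features,
         data = data, test_data = test_data, test_features = test_features,
         test_windows = test_windows, residue = residue,
         d_max = check_positive_int(d_max, "d_max"), strategy = strategy,
         C = C, sigma = sigma, n_folds = check_positive_int(n_folds, "n_folds"),
         n_repeats = check_positive_int(n_repeats, "n_repeats"), s = s,
         gan = gan, k_neighbors = k_neighbors, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

# Resolve any of the input forms to a feature tibble.
load_features <- function(source_paths, data, d_max) {
  if (!is.null(data)) {
    if (is_feature_df(data) && !"window" %in% names(data)) return(data)
    if ("window" %in% names(data)) return(dr_features(data, d_max = d_max))
    abort("in-memory `data` must be a windows or feature tibble with a `label` column")
  }
  if (!is.null(source_paths$fasta) && !is.null(source_paths$sites)) {
    return(dr_features(read_sites(source_paths$fasta, source_paths$sites),
                       d_max = d_max))
  }
  if (!is.null(source_paths$windows)) {
    return(dr_features(read_windows(source_paths$windows), d_max = d_max))
  }
  if (!is.null(source_paths$features)) {
    dat <- utils::read.csv(source_paths$features, check.names = FALSE)
    if (!"label" %in% names(dat)) abort("feature CSV must have a `label` column")
    return(as_tibble(dat))
  }
  abort("no input given: supply `data`, `fasta`+`sites`, `windows`, or `features`")
}

#' Run the full rebalance-and-classify pipeline
#'
#' Extracts DR features if the input is sequence-level, cross-validates the
#' chosen strategy, and (when a test set is supplied) fits the best of
#' `n_repeats` rebalance-and-train cycles on the full training data and
#' scores the test set. With `out_dir` set, the features, rebalance plan,
#' model, report and config (with seed) are persisted as CSV/JSON.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result`: list with `cv` (a `cv_result`), `test`
#'   (an `eval_report` or `NULL`), `plan`, `model`, `config`, and `summary`
#'   (one-row tibble `method, residue, IR, s, sen, spe, auc`, test metrics
#'   when available, CV means otherwise).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  feats <- load_features(config[c("fasta", "sites", "windows", "features")],
                         config$data, config$d_max)
  m <- sum(feats$label == 1L)
  M <- sum(feats$label == 0L)
  if (m < 1 || M < 1) abort("training data must contain both classes")

  n_folds <- min(config$n_folds, m, M)
  cv <- cross_validate(feats, strategy = config$strategy, C = config$C,
                       sigma = config$sigma, n_folds = n_folds,
                       n_repeats = 1, seed = config$seed, gan = config$gan,
                       k_neighbors = config$k_neighbors, s = config$s)

  test_feats <- NULL
  if (!is.null(config$test_data) || !is.null(config$test_features) ||
      !is.null(config$test_windows)) {
    test_feats <- load_features(
      list(fasta = NULL, sites = NULL, windows = config$test_windows,
           features = config$test_features),
      config$test_data, config$d_max)
  }

  test_report <- NULL
  fit <- NULL
  if (!is.null(test_feats)) {
    fit <- fit_evaluate(feats, test_feats, strategy = config$strategy,
                        C = config$C, sigma = config$sigma,
                        n_repeats = config$n_repeats, seed = config$seed,
                        gan = config$gan, k_neighbors = config$k_neighbors,
                        s = config$s)
    test_report <- fit$report
  } else {
    sc <- minmax_scale(feats)
    fit <- list(model = NULL,
                plan = if (config$strategy == "none") NULL else
                  rebalance(sc$train, config$strategy, s = config$s,
                            gan = config$gan,
                            k_neighbors = config$k_neighbors,
                            seed = config$seed)$plan)
  }

  s_used <- if (!is.null(fit$plan)) fit$plan$s else NA_integer_
  summary <- tibble(
    method = config$strategy,
    residue = config$residue,
    IR = round(M / m, 1),
    s = s_used,
    sen = if (!is.null(test_report)) test_report$sen else cv$summary$sen,
    spe = if (!is.null(test_report)) test_report$spe else cv$summary$spe,
    auc = if (!is.null(test_report)) test_report$auc else cv$summary$auc
  )

  result <- structure(
    list(cv = cv, test = test_report, plan = fit$plan, model = fit$model,
         config = config, summary = summary),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) persist_run(result, feats)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) x$summary

persist_run <- function(result, feats) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
  if (!is.null(result$plan)) write_plan(result$plan, file.path(dir, "plan.json"))
  cfg <- result$config
  cfg$data <- cfg$test_data <- cfg$gan <- NULL
  cfg_json <- jsonlite::toJSON(cfg[!vapply(cfg, is.null, TRUE)],
                               auto_unbox = TRUE)
  jsonlite::write_json(
    list(config = jsonlite::fromJSON(cfg_json),
         gan = unclass(result$config$gan),
         config_hash = rlang::hash(cfg_json),
         seed = result$config$seed),
    file.path(dir, "config.json"), auto_unbox = TRUE)
  report <- list(summary = result$summary, cv_folds = result$cv$folds)
  if (!is.null(result$test)) report$test <- glance(result$test)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(result$model)) {
    m <- result$model
    jsonlite::write_json(
      list(support_vectors = m$support_vectors, sv_coefs = m$sv_coefs,
           bias = m$bias, C = m$C, sigma = m$sigma,
           feature_names = m$feature_names),
      file.path(dir, "model.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Benchmark strategies across imbalance ratios
#'
#' For each imbalance ratio, generates a seeded synthetic peptide training
#' set (`n_neg` negatives, `n_neg / IR` positives) plus a balanced held-out
#' test set, and evaluates each strategy with identical folds and seeds.
#'
#' @param irs Imbalance ratios to sweep (default the constructed-dataset
#'   grid 5, 10, 100, 333).
#' @param strategies Strategies to compare; see [rebalance()].
#' @param n_neg Training negatives (default 1000).
#' @param n_test Test-set size per class (default 100).
#' @param motif_bias Planted signal strength; see [make_peptide_dataset()].
#' @param residue Centre residue for the synthetic windows.
#' @inheritParams cross_validate
#' @param d_max DR feature distance bound.
#' @return An `ir_sweep` tibble: one row per (IR, strategy) with columns
#'   `method, residue, IR, s, sen, spe, auc`.
#' @export
run_ir_sweep <- function(irs = c(5, 10, 100, 333),
                         strategies = c("none", "random_under", "smote",
                                        "attention_gan"),
                         n_neg = 1000, n_test = 100, motif_bias = 0.5,
                         residue = "K", d_max = 3, C = 1, sigma = NULL,
                         n_repeats = 1, seed = 1, gan = gan_config()) {
  if (length(strategies) == 0 || length(irs) == 0) {
    return(structure(tibble(method = character(), residue = character(),
                            IR = numeric(), s = integer(), sen = numeric(),
                            spe = numeric(), auc = numeric()),
                     class = c("ir_sweep", "tbl_df", "tbl", "data.frame")))
  }
  strategies <- vapply(strategies, match.arg, "", choices = REBALANCE_STRATEGIES)

  rows <- purrr::map(irs, function(ir) {
    n_pos <- as.integer(round(n_neg / ir))
    if (n_pos < 1) abort(sprintf("IR = %g needs fewer than one positive", ir))
    train <- make_peptide_dataset(n_neg = n_neg, n_pos = n_pos,
                                  centre_residue = residue,
                                  motif_bias = motif_bias, seed = seed)
    test <- make_peptide_dataset(n_neg = n_test, n_pos = n_test,
                                 centre_residue = residue,
                                 motif_bias = motif_bias, seed = seed + 500L)
    ftr <- dr_features(train, d_max = d_max)
    fte <- dr_features(test, d_max = d_max)
    purrr::map(strategies, function(strat) {
      fit <- fit_evaluate(ftr, fte, strategy = strat, C = C, sigma = sigma,
                          n_repeats = n_repeats, seed = seed, gan = gan)
      tibble(method = strat, residue = residue, IR = ir,
             s = if (is.null(fit$plan)) NA_integer_ else fit$plan$s,
             sen = fit$report$sen, spe = fit$report$spe,
             auc = fit$report$auc)
    }) |> bind_rows()
  }) |> bind_rows()
  structure(rows, class = c("ir_sweep", class(rows)))
}

#' Sweep the sampling scale around the optimum
#'
#' Fixes one training/test pair and re-runs the two-way strategy at a grid
#' of sampling scales `s`, tracing how test AUC responds; the closed-form
#' optimum `sqrt(m * M)` should sit near the peak.
#'
#' @param train,test Raw feature tibbles with binary `label` columns.
#' @param s_values Integer vector of scales to try; default an 8-point grid
#'   spanning `[m, M]` geometrically.
#' @inheritParams fit_evaluate
#' @return A `scale_sweep` tibble with columns `s, sen, spe, auc` and
#'   attribute `s_opt = optimal_scale(m, M)`.
#' @export
run_scale_sweep <- function(train, test, s_values = NULL,
                            strategy = "attention_gan", C = 1, sigma = NULL,
                            n_repeats = 1, seed = 1, gan = gan_config()) {
  m <- sum(train$label == 1L)
  M <- sum(train$label == 0L)
  s_opt <- optimal_scale(m, M)
  if (is.null(s_values)) {
    s_values <- unique(round(exp(seq(log(max(m, 2)), log(M), length.out = 8))))
  }
  rows <- purrr::map(s_values, function(sv) {
    fit <- fit_evaluate(train, test, strategy = strategy, C = C,
                        sigma = sigma, n_repeats = n_repeats, seed = seed,
                        gan = gan, s = as.integer(sv))
    tibble(s = as.integer(sv), sen = fit$report$sen, spe = fit$report$spe,
           auc = fit$report$auc)
  }) |> bind_rows()
  structure(rows, s_opt = s_opt, class = c("scale_sweep", class(rows)))
}
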