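#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   facet_wrap labs scale_x_log10 theme_minimal
NULL

#' Plot an imbalance-ratio sweep
#'
#' One panel per metric (AUC, sensitivity, specificity), strategies as
#' coloured lines over the imbalance ratio (log scale).
#'
#' @param object An `ir_sweep` tibble from [run_ir_sweep()].
#' @param ... Unused.
#' @export
autoplot.ir_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("auc", "spe", "sen"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$IR, y = .data$value, colour = .data$method)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    facet_wrap(~metric, ncol = 1) +
    labs(x = "imbalance ratio (M / m)", y = NULL, colour = "strategy") +
    theme_minimal()
}

#' Plot a sampling-scale sweep
#'
#' Test AUC against the sampling scale `s`, with the closed-form optimum
#' `sqrt(m * M)` marked.
#'
#' @param object A `scale_sweep` tibble from [run_scale_sweep()].
#' @param ... Unused.
#' @export
autoplot.scale_sweep <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$s, y = .data$auc)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = attr(object, "s_opt"), linetype = "dashed") +
    labs(x = "sampling scale s", y = "AUC") +
    theme_minimal()
}

#' Plot GAN training losses
#'
#' @param object A `trained_generator` from [train_gan()].
#' @param ... Unused.
#' @export
autoplot.trained_generator <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$loss,
                           colour = .data$network)) +
    geom_line() +
    labs(x = "epoch", y = "loss") +
    theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, c("sen", "spe", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    geom_point(alpha = 0.6) +
    labs(x = NULL, y = NULL,
         title = sprintf("%d-fold cross-validation (%s)",
                         nrow(object$folds), object$strategy)) +
    theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
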