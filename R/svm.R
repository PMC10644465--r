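#' Gaussian (RBF) kernel
#'
#' `K(x, z) = exp(-||x - z||^2 / (2 * sigma^2))`, in `(0, 1]`.
#'
#' @param x,z Numeric vectors of equal length.
#' @param sigma Kernel width, `> 0`.
#' @export
gaussian_kernel <- function(x, z, sigma) {
  if (length(x) != length(z)) abort("`x` and `z` must have equal length")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number")
  }
  exp(-sum((x - z)^2) / (2 * sigma^2))
}

# Full kernel matrix between row sets.
kernel_matrix <- function(X, Z, sigma) {
  sq <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * X %*% t(Z)
  sq[sq < 0] <- 0
  exp(-sq / (2 * sigma^2))
}

# "Scale"-type width heuristic: sigma = sqrt(d * mean column variance / 2),
# i.e. gamma = 1 / (d * mean column variance).
default_sigma <- function(X) {
  v <- mean(apply(X, 2, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  sqrt(ncol(X) * v / 2)
}

#' Train a Gaussian-kernel soft-margin SVM
#'
#' Fits the standard soft-margin dual (box constraint `0 <= alpha_i <= C`,
#' balance constraint `sum(alpha_i y_i) = 0`) with the Gaussian kernel. The
#' quadratic programme is solved by libsvm (via e1071); the fitted multipliers,
#' support vectors and bias are extracted so that the decision function
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` is evaluated by this package's own
#' kernel code in [predict.svm_rbf()].
#'
#' @param train Feature tibble with a binary `label` column (0/1 or -1/+1);
#'   both classes must be present. The positive class (modification sites) is
#'   coded +1.
#' @param C Soft-margin penalty (> 0). Default 1.
#' @param sigma Kernel width; default `sqrt(d * mean column variance / 2)`.
#' @return An object of class `svm_rbf` with `support_vectors`, `alphas`,
#'   `sv_labels`, `bias`, `C`, `sigma`.
#' @export
train_svm <- function(train, C = 1, sigma = NULL) {
  p <- feature_parts(train)
  y <- as_pm1(p$y)
  if (length(unique(y)) < 2) {
    abort("training data contain a single class; both classes are required")
  }
  if (!is.numeric(C) || C <= 0) abort("`C` must be positive")
  sigma <- sigma %||% default_sigma(p$X)
  if (sigma <= 0) abort("`sigma` must be positive")

  fit <- e1071::svm(x = p$X, y = factor(y, levels = c(-1, 1)),
                    scale = FALSE, type = "C-classification",
                    kernel = "radial", gamma = 1 / (2 * sigma^2), cost = C)
  coefs <- as.numeric(fit$coefs)   # alpha_i * y_i, libsvm orientation
  rho <- fit$rho
  # libsvm's decision value is positive for the class it met first; flip so
  # that positive scores mean the +1 class.
  first_level <- fit$levels[fit$labels[1]]
  flip <- if (identical(first_level, "-1")) -1 else 1
  coefs <- flip * coefs
  bias <- -flip * rho

  structure(
    list(support_vectors = unname(as.matrix(fit$SV)),
         alphas = abs(coefs),
         sv_labels = as.integer(sign(coefs)),
         sv_coefs = coefs,
         bias = bias,
         C = C, sigma = sigma,
         feature_names = p$feature_names),
    class = "svm_rbf"
  )
}

#' Decision scores and class labels for a fitted SVM
#'
#' Evaluates `f(x) = sum_i alpha_i y_i K(x_i, x) + b` at every query row;
#' `.pred` is its sign (+1 = predicted modification site).
#'
#' @param object An `svm_rbf` model.
#' @param newdata Feature tibble or matrix with the model's feature
#'   dimension; a `label` column is ignored.
#' @param ... Unused.
#' @return A tibble with columns `.score` and `.pred`.
#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    feature_parts(newdata, require_label = FALSE)$X
  } else {
    as.matrix(newdata)
  }
  if (ncol(X) != ncol(object$support_vectors)) {
    abort(sprintf("dimension mismatch: model expects %d features, got %d",
                  ncol(object$support_vectors), ncol(X)))
  }
  K <- kernel_matrix(X, object$support_vectors, object$sigma)
  score <- as.numeric(K %*% object$sv_coefs + object$bias)
  tibble(.score = score, .pred = ifelse(score >= 0, 1L, -1L))
}

#' @export
print.svm_rbf <- function(x, ...) {
  cat(sprintf("<svm_rbf> %d support vectors, C = %g, sigma = %.4g\n",
              nrow(x$support_vectors), x$C, x$sigma))
  invisible(x)
}

#' @export
tidy.svm_rbf <- function(x, ...) {
  tibble(sv = seq_along(x$alphas), alpha = x$alphas, label = x$sv_labels,
         bound = x$alphas >= x$C - 1e-8)
}

#' @export
glance.svm_rbf <- function(x, ...) {
  tibble(n_sv = length(x$alphas), C = x$C, sigma = x$sigma,
         bias = x$bias, kkt_balance = sum(x$sv_coefs))
}
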