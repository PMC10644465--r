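# A small fully-connected GAN for tabular minority-class oversampling.
# Both networks are multi-layer perceptrons trained with Adam and manual
# backpropagation; the generator maps standard-normal noise to feature
# vectors in [0,1]^d (sigmoid output), the discriminator maps feature
# vectors to a logit.

#' GAN configuration
#'
#' Hyperparameters for the minority-class oversampling GAN. The generator
#' draws `noise_dim`-dimensional standard-normal noise and emits feature
#' vectors through `hidden_sizes` LeakyReLU(0.2) layers and a sigmoid output,
#' so training features must be min-max scaled to `[0, 1]`. The discriminator
#' mirrors the hidden architecture with a sigmoid output. Both networks are
#' updated 1:1 per minibatch with Adam.
#'
#' @param noise_dim Dimension of the Gaussian noise prior.
#' @param hidden_sizes Integer vector of hidden-layer widths, shared by both
#'   networks.
#' @param epochs Training epochs (full passes over the minority set).
#' @param batch_size Minibatch size; reduced to the number of training rows
#'   when larger.
#' @param learning_rate Adam step size.
#' @param instance_noise Initial standard deviation of the Gaussian noise
#'   added to the discriminator's inputs (real and generated alike),
#'   annealed linearly to zero over training. Smooths the discriminator so
#'   it cannot memorise a handful of minority samples. The default `NULL`
#'   calibrates it to the training data (mean per-column standard
#'   deviation); set to 0 to disable.
#' @param init_gain Multiplier on the generator's first-layer weights at
#'   initialisation. Values above 1 give the generator visible output spread
#'   from the first step, instead of a point mass that adversarial training
#'   must inflate. The default `NULL` calibrates the gain so that the
#'   initial output spread matches the per-column spread of the training
#'   data.
#' @param seed Integer seed; training and generation are fully reproducible.
#' @return A `gan_config` list.
#' @export
gan_config <- function(noise_dim = 32, hidden_sizes = c(128, 128),
                       epochs = 200, batch_size = 32,
                       learning_rate = 2e-4, instance_noise = NULL,
                       init_gain = NULL, seed = 1) {
  cfg <- list(
    noise_dim = check_positive_int(noise_dim, "noise_dim"),
    hidden_sizes = vapply(hidden_sizes, check_positive_int, integer(1),
                          name = "hidden_sizes"),
    epochs = check_positive_int(epochs, "epochs"),
    batch_size = check_positive_int(batch_size, "batch_size"),
    learning_rate = learning_rate,
    instance_noise = instance_noise,
    init_gain = init_gain,
    seed = as.integer(seed)
  )
  if (!is.numeric(cfg$learning_rate) || cfg$learning_rate <= 0) {
    abort("`learning_rate` must be positive")
  }
  if (!is.null(cfg$instance_noise) &&
      (!is.numeric(cfg$instance_noise) || cfg$instance_noise < 0)) {
    abort("`instance_noise` must be non-negative (or NULL for automatic)")
  }
  if (!is.null(cfg$init_gain) &&
      (!is.numeric(cfg$init_gain) || cfg$init_gain <= 0)) {
    abort("`init_gain` must be positive (or NULL for automatic)")
  }
  structure(cfg, class = "gan_config")
}

## ---- minimal MLP machinery ------------------------------------------------

lrelu <- function(z) pmax(z, 0) + 0.2 * pmin(z, 0)
lrelu_grad <- function(z) 0.2 + 0.8 * (z > 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(sizes) {
  lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

# Forward pass; hidden layers LeakyReLU, final layer linear (a logit or
# pre-sigmoid output). Caches pre-activations for backprop.
mlp_forward <- function(net, X) {
  L <- length(net)
  Z <- vector("list", L); A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% net[[l]]$W + rep(net[[l]]$b, each = nrow(X))
    A[[l + 1]] <- if (l < L) lrelu(Z[[l]]) else Z[[l]]
  }
  list(out = A[[L + 1]], Z = Z, A = A)
}

# Backprop from dL/d(final pre-activation); returns per-layer grads and
# dL/d(input).
mlp_backward <- function(net, cache, delta_out) {
  L <- length(net)
  grads <- vector("list", L)
  delta <- delta_out
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(cache$A[[l]], delta), b = colSums(delta))
    if (l > 1) {
      delta <- tcrossprod(delta, net[[l]]$W) * lrelu_grad(cache$Z[[l - 1]])
    } else {
      d_input <- tcrossprod(delta, net[[l]]$W)
    }
  }
  list(grads = grads, d_input = d_input)
}

adam_init <- function(net) {
  list(t = 0,
       m = lapply(net, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(net, function(p) list(W = p$W * 0, b = p$b * 0)))
}

adam_step <- function(net, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  # bias-corrected step size folded into one scalar
  alpha <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  for (l in seq_along(net)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      m <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      v <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g * g
      state$m[[l]][[p]] <- m
      state$v[[l]][[p]] <- v
      net[[l]][[p]] <- net[[l]][[p]] - alpha * m / (sqrt(v) + eps)
    }
  }
  list(net = net, state = state)
}

## ---- training -------------------------------------------------------------

#' Train a GAN on minority-class feature vectors
#'
#' Alternates 1:1 minibatch updates of the discriminator (ascending
#' `log D(x) + log(1 - D(G(t)))`) and the generator. The generator uses the
#' non-saturating objective — ascending `log D(G(t))` rather than literally
#' descending `log(1 - D(G(t)))` — the standard stabilisation for small
#' training sets; both objectives share the same fixed point.
#'
#' @param pos Minority-class feature tibble (a `label` column, if present, is
#'   dropped); at least 2 rows, features min-max scaled to `[0, 1]`.
#' @param config A [gan_config()].
#' @return A `trained_generator` with fields `d` (output dimension),
#'   `feature_names`, `config`, `net` (generator weights) and `loss_history`
#'   (tibble of per-epoch mean discriminator and generator losses). Use
#'   [gan_generate()] to sample from it.
#' @export
train_gan <- function(pos, config = gan_config()) {
  stopifnot(inherits(config, "gan_config"))
  p <- feature_parts(pos, require_label = FALSE)
  X <- p$X
  if (nrow(X) < 2) {
    abort("too few samples for the generator to learn (need at least 2 minority rows)")
  }
  d <- ncol(X)
  bs <- min(config$batch_size, nrow(X))
  inst0 <- config$instance_noise %||% mean(apply(X, 2, stats::sd))
  if (!is.finite(inst0)) inst0 <- 0
  g_sizes <- c(config$noise_dim, config$hidden_sizes, d)
  d_sizes <- c(d, config$hidden_sizes, 1)

  with_seed(config$seed, {
    Gnet <- mlp_init(g_sizes)
    # Start the generator at the minority-class column profile with
    # data-scale spread: the output bias is the logit of the training
    # column means (so the first samples already live near the data rather
    # than at sigmoid(0) = 0.5^d), and the noise path is rescaled so the
    # initial output spread matches the per-column spread of the data
    # instead of collapsing to a point mass. Training then shapes the
    # distribution. Both matter for sparse features and very small
    # minority sets.
    mu <- pmin(pmax(colMeans(X), 1e-3), 1 - 1e-3)
    Gnet[[length(Gnet)]]$b <- stats::qlogis(mu)
    if (is.null(config$init_gain)) {
      target_sd <- mean(apply(X, 2, stats::sd))
      probe <- matrix(stats::rnorm(64 * config$noise_dim), 64)
      for (it in 1:2) {   # sigmoid makes spread sublinear in the gain
        out_sd <- mean(apply(sigmoid(mlp_forward(Gnet, probe)$out), 2, stats::sd))
        ratio <- min(max(target_sd / max(out_sd, 1e-8), 0.2), 20)
        Gnet[[1]]$W <- Gnet[[1]]$W * ratio
      }
    } else {
      Gnet[[1]]$W <- Gnet[[1]]$W * config$init_gain
    }
    Dnet <- mlp_init(d_sizes)
    Gopt <- adam_init(Gnet)
    Dopt <- adam_init(Dnet)
    hist_d <- hist_g <- numeric(config$epochs)

    n_steps <- 0
    total_steps <- config$epochs * length(seq(1, nrow(X), by = bs))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(X))
      starts <- seq(1, nrow(X), by = bs)
      ld <- lg <- 0
      for (st in starts) {
        rows <- ord[st:min(st + bs - 1, nrow(X))]
        nb <- length(rows)
        Xr <- X[rows, , drop = FALSE]
        n_steps <- n_steps + 1
        # instance noise, annealed linearly to zero
        sn <- inst0 * max(0, 1 - n_steps / total_steps)

        # --- discriminator step ---
        Zn <- matrix(stats::rnorm(nb * config$noise_dim), nb)
        gfwd <- mlp_forward(Gnet, Zn)
        Xf <- sigmoid(gfwd$out)
        Xd <- rbind(Xr, Xf)
        if (sn > 0) Xd <- Xd + matrix(stats::rnorm(2 * nb * d, sd = sn), 2 * nb)
        tgt <- c(rep(1, nb), rep(0, nb))
        dfwd <- mlp_forward(Dnet, Xd)
        pr <- sigmoid(dfwd$out[, 1])
        ld <- ld - mean(tgt * log(pr + 1e-12) + (1 - tgt) * log(1 - pr + 1e-12))
        delta <- matrix((pr - tgt) / (2 * nb), ncol = 1)
        dbk <- mlp_backward(Dnet, dfwd, delta)
        upd <- adam_step(Dnet, dbk$grads, Dopt, config$learning_rate)
        Dnet <- upd$net; Dopt <- upd$state

        # --- generator step (non-saturating) ---
        Zn <- matrix(stats::rnorm(nb * config$noise_dim), nb)
        gfwd <- mlp_forward(Gnet, Zn)
        Xf <- sigmoid(gfwd$out)
        Xg <- if (sn > 0) Xf + matrix(stats::rnorm(nb * d, sd = sn), nb) else Xf
        dfwd <- mlp_forward(Dnet, Xg)
        pr <- sigmoid(dfwd$out[, 1])
        lg <- lg - mean(log(pr + 1e-12))
        delta <- matrix((pr - 1) / nb, ncol = 1)
        dXf <- mlp_backward(Dnet, dfwd, delta)$d_input
        deltaG <- dXf * Xf * (1 - Xf)   # through the sigmoid output
        gbk <- mlp_backward(Gnet, gfwd, deltaG)
        upd <- adam_step(Gnet, gbk$grads, Gopt, config$learning_rate)
        Gnet <- upd$net; Gopt <- upd$state
      }
      hist_d[epoch] <- ld / length(starts)
      hist_g[epoch] <- lg / length(starts)
    }

    structure(
      list(d = d, feature_names = p$feature_names, config = config, net = Gnet,
           loss_history = tibble(epoch = seq_len(config$epochs),
                                 loss_d = hist_d, loss_g = hist_g)),
      class = "trained_generator"
    )
  })
}

#' Sample synthetic minority vectors from a trained generator
#'
#' @param gen A `trained_generator` from [train_gan()].
#' @param n Number of rows to generate (`>= 0`).
#' @param seed Integer seed for the noise draw; defaults to a fixed offset of
#'   the training seed so repeated calls are reproducible.
#' @return An `n x d` feature tibble with values in `(0, 1)`.
#' @export
gan_generate <- function(gen, n, seed = NULL) {
  stopifnot(inherits(gen, "trained_generator"))
  n <- as.integer(n)
  if (n < 0) abort("`n` must be non-negative")
  if (n == 0) {
    return(feature_tibble(matrix(numeric(0), 0, gen$d),
                          feature_names = gen$feature_names))
  }
  seed <- seed %||% (gen$config$seed + 1e6L)
  Z <- with_seed(seed, matrix(stats::rnorm(n * gen$config$noise_dim), n))
  X <- sigmoid(mlp_forward(gen$net, Z)$out)
  feature_tibble(X, feature_names = gen$feature_names)
}

#' @export
print.trained_generator <- function(x, ...) {
  cat(sprintf("<trained_generator> %d-dim output, noise %d, %d epochs\n",
              x$d, x$config$noise_dim, x$config$epochs))
  cat(sprintf("  final losses: D = %.3f, G = %.3f\n",
              utils::tail(x$loss_history$loss_d, 1),
              utils::tail(x$loss_history$loss_g, 1)))
  invisible(x)
}

#' @export
tidy.trained_generator <- function(x, ...) {
  tidyr::pivot_longer(x$loss_history, c("loss_d", "loss_g"),
                      names_to = "network", values_to = "loss") |>
    dplyr::mutate(network = ifelse(.data$network == "loss_d",
                                   "discriminator", "generator"))
}

#' Oversample the minority class with a GAN
#'
#' Trains the GAN on `pos` and returns `pos` stacked with `n_new` generated
#' rows, all labelled positive.
#'
#' @inheritParams train_gan
#' @param n_new Number of synthetic rows to append (`>= 0`).
#' @return A feature tibble with `nrow(pos) + n_new` rows. The fitted
#'   generator is attached as `attr(-, "generator")`.
#' @export
gan_oversample <- function(pos, n_new, config = gan_config()) {
  n_new <- as.integer(n_new)
  if (n_new < 0) abort("`n_new` must be non-negative")
  p <- feature_parts(pos, require_label = FALSE)
  real <- feature_tibble(p$X, rep(1L, nrow(p$X)), p$feature_names)
  if (n_new == 0) return(real)
  gen <- train_gan(pos, config)
  synth <- gan_generate(gen, n_new)
  synth$label <- 1L
  out <- bind_rows(real, synth)
  attr(out, "generator") <- gen
  out
}
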