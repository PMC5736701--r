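#' Specify a deep autoencoder for reconstruction-error anomaly scoring
#'
#' Default geometry mirrors a feature-space anomaly detector for 512-d
#' penultimate-layer activations: two fully-connected encoding layers (128,
#' 32 units) followed by two decoding layers (128 and `input_dim` units).
#' Hidden layers use rectifier activations; the output layer is linear since
#' features are unbounded reals.
#'
#' @param input_dim Feature dimensionality (default 512).
#' @param encoder_widths Encoding layer widths (default `c(128, 32)`).
#' @param decoder_widths Decoding layer widths before the final linear
#'   reconstruction layer (default `c(128)`); the output layer of width
#'   `input_dim` is appended automatically.
#' @param epochs,batch_size,learning_rate,momentum Training settings for
#'   seeded mini-batch SGD with momentum on mean squared reconstruction
#'   error; `epochs = 0` leaves the initialised model untouched.
#' @param seed Integer seed.
#' @return A `dae_spec` object.
#' @export
dae_spec <- function(input_dim = 512, encoder_widths = c(128, 32),
                     decoder_widths = c(128), epochs = 30, batch_size = 32,
                     learning_rate = 0.01, momentum = 0.9, seed = 1) {
  stopifnot(input_dim >= 1, all(encoder_widths >= 1),
            all(decoder_widths >= 1), epochs >= 0, batch_size >= 1,
            learning_rate > 0, momentum >= 0, momentum < 1)
  structure(list(input_dim = as.integer(input_dim),
                 widths = as.integer(c(input_dim, encoder_widths,
                                       decoder_widths, input_dim)),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 momentum = momentum,
                 seed = as.integer(seed)),
            class = "dae_spec")
}

dae_forward <- function(model, x, keep = FALSE) {
  L <- length(model$W)
  a <- x
  acts <- if (keep) vector("list", L + 1L) else NULL
  if (keep) acts[[1L]] <- a
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z   # linear output layer
    if (keep) acts[[l + 1L]] <- a
  }
  if (keep) acts else a
}

#' Train a deep autoencoder on feature vectors
#'
#' Minimises the mean squared reconstruction error by seeded mini-batch SGD
#' with momentum; the per-epoch average loss is recorded in `$training_log`.
#'
#' @param features `N x d` real matrix (`N >= 2`, `d = spec$input_dim`).
#' @param spec A [dae_spec()].
#' @return A `dae_fit` model.
#' @export
train_dae <- function(features, spec) {
  stopifnot(inherits(spec, "dae_spec"))
  x <- as.matrix(features)
  if (nrow(x) < 2) stop("need at least two feature vectors", call. = FALSE)
  if (ncol(x) != spec$input_dim)
    stop("features have ", ncol(x), " columns but the spec expects ",
         spec$input_dim, call. = FALSE)
  widths <- spec$widths
  L <- length(widths) - 1L
  model <- with_seed(derive_seed(spec$seed, "dae_init"), {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      lim <- sqrt(6 / widths[l])
      W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1L], -lim, lim),
                       widths[l], widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    list(W = W, b = b, spec = spec, training_log = numeric(0))
  })
  if (spec$epochs == 0L) {
    class(model) <- "dae_fit"
    return(model)
  }
  n <- nrow(x)
  mu <- spec$momentum
  vW <- lapply(model$W, function(w) w * 0)
  vb <- lapply(model$b, function(bb) bb * 0)
  log_loss <- numeric(spec$epochs)
  with_seed(derive_seed(spec$seed, "dae_sgd"), {
    for (epoch in seq_len(spec$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = spec$batch_size)
      ep <- 0
      for (s in starts) {
        idx <- perm[s:min(s + spec$batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        acts <- dae_forward(model, xb, keep = TRUE)
        xhat <- acts[[L + 1L]]
        resid <- xhat - xb
        nb <- nrow(xb)
        ep <- ep + mean(resid^2)
        delta <- 2 * resid / (nb * ncol(xb))
        for (l in rev(seq_len(L))) {
          gW <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) {
            da <- tcrossprod(delta, model$W[[l]])
            delta <- da * (acts[[l]] > 0)
          }
          vW[[l]] <- mu * vW[[l]] - spec$learning_rate * gW
          vb[[l]] <- mu * vb[[l]] - spec$learning_rate * gb
          model$W[[l]] <- model$W[[l]] + vW[[l]]
          model$b[[l]] <- model$b[[l]] + vb[[l]]
        }
      }
      log_loss[epoch] <- ep / length(starts)
    }
  })
  model$training_log <- log_loss
  class(model) <- "dae_fit"
  model
}

#' Reconstruction-error anomaly scores
#'
#' Per-sample mean squared error between a feature vector and its autoencoder
#' reconstruction; higher scores indicate samples farther from the training
#' distribution.
#'
#' @param model A `dae_fit`.
#' @param features `N x d` matrix with `d` matching the model.
#' @return Non-negative numeric vector of length `N`.
#' @export
anomaly_score <- function(model, features) {
  x <- as.matrix(features)
  if (ncol(x) != model$spec$input_dim)
    stop("features have ", ncol(x), " columns but the model expects ",
         model$spec$input_dim, call. = FALSE)
  xhat <- dae_forward(model, x)
  rowMeans((xhat - x)^2)
}

#' Penultimate-layer features of a dropout network
#'
#' Deterministic-mode activations of the last hidden layer, the
#' representation used as input to reconstruction-error anomaly scoring.
#'
#' @param net A `fitted_net`.
#' @param x Feature matrix.
#' @return `N x last_hidden_width` matrix.
#' @export
penultimate_features <- function(net, x) {
  forward(net, x, mode = "deterministic", type = "hidden")
}
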