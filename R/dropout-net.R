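#' Specify a feed-forward softmax classifier with Bernoulli dropout
#'
#' @param input_dim Input feature dimensionality.
#' @param hidden Integer vector of hidden-layer widths.
#' @param n_classes Number of softmax output classes (>= 2).
#' @param dropout_prob Per-hidden-layer drop probability in `[0, 1)`;
#'   recycled to one value per hidden layer.
#' @param activation Hidden nonlinearity: `"relu"` (default) or
#'   `"identity"`.
#' @return A `net_spec` object.
#' @examples
#' net_spec(2, hidden = c(100, 100, 100), dropout_prob = 0.5)
#' @export
net_spec <- function(input_dim, hidden = c(100, 100, 100), n_classes = 2,
                     dropout_prob = 0.5, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  stopifnot(input_dim >= 1, n_classes >= 2, all(hidden >= 1))
  dropout_prob <- rep_len(dropout_prob, length(hidden))
  if (any(dropout_prob < 0) || any(dropout_prob >= 1))
    stop("`dropout_prob` must lie in [0, 1)", call. = FALSE)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 n_classes = as.integer(n_classes),
                 dropout_prob = dropout_prob,
                 activation = activation),
            class = "net_spec")
}

#' Training configuration for dropout networks
#'
#' Mini-batch SGD with Nesterov momentum minimising (optionally
#' class-reweighted) cross-entropy plus an L2 penalty `l2_lambda * sum(theta^2)`
#' over all weights and biases. `learning_rate` may be a vector, indexed by
#' epoch (last value reused past its end), to express piecewise-constant
#' schedules.
#'
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param learning_rate Positive step size(s).
#' @param momentum Nesterov momentum coefficient in `[0, 1)`.
#' @param l2_lambda Non-negative L2 coefficient.
#' @param class_weighting If `TRUE`, reweight the cross-entropy by inverse
#'   relative class frequency within each mini-batch (see
#'   [weighted_cross_entropy()]).
#' @param seed Integer seed covering initialisation, shuffling and dropout
#'   masks.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 100, batch_size = 32, learning_rate = 0.01,
                         momentum = 0.9, l2_lambda = 0.001,
                         class_weighting = TRUE, seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, all(learning_rate >= 0),
            momentum >= 0, momentum < 1, l2_lambda >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 momentum = momentum,
                 l2_lambda = l2_lambda,
                 class_weighting = isTRUE(class_weighting),
                 seed = as.integer(seed)),
            class = "train_config")
}

# He-style scaled-uniform fan-in initialisation; biases start at zero.
init_net <- function(spec, seed) {
  widths <- c(spec$input_dim, spec$hidden, spec$n_classes)
  with_seed(seed, {
    W <- vector("list", length(widths) - 1L)
    b <- vector("list", length(widths) - 1L)
    for (l in seq_along(W)) {
      lim <- sqrt(6 / widths[l])
      W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1L], -lim, lim),
                       widths[l], widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    structure(list(spec = spec, W = W, b = b, training_log = numeric(0)),
              class = "fitted_net")
  })
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else z
}

# One forward pass; masks is NULL (deterministic) or a list of per-layer
# multiplier matrices/vectors already scaled by 1/(1 - p_drop) (inverted
# dropout), so the deterministic pass needs no weight rescaling.
forward_pass <- function(net, x, masks = NULL, keep_hidden = FALSE) {
  spec <- net$spec
  a <- x
  H <- length(spec$hidden)
  last_hidden <- NULL
  for (l in seq_len(H)) {
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
    a <- act_fun(z, spec$activation)
    if (!is.null(masks)) {
      m <- masks[[l]]
      a <- if (is.matrix(m)) a * m else sweep(a, 2, m, "*")
    }
    if (l == H) last_hidden <- a
  }
  logits <- sweep(a %*% net$W[[H + 1L]], 2, net$b[[H + 1L]], "+")
  if (keep_hidden) list(logits = logits, hidden = last_hidden) else logits
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Draw one shared-across-samples inverted-dropout mask per hidden layer.
draw_masks <- function(spec) {
  lapply(seq_along(spec$hidden), function(l) {
    p <- spec$dropout_prob[l]
    if (p == 0) rep(1, spec$hidden[l])
    else (stats::runif(spec$hidden[l]) >= p) / (1 - p)
  })
}

#' Forward pass through a dropout network
#'
#' In `"deterministic"` mode dropout is off and the output is the
#' conventional softmax probability (inverted-dropout convention: no weight
#' rescaling is needed). In `"sampled"` mode a Bernoulli mask is applied to
#' every hidden layer — either an explicit `mask` (list of per-layer 0/1
#' vectors) or one drawn from `seed` — with kept activations scaled by
#' `1/(1 - p_drop)`.
#'
#' @param net A `fitted_net`.
#' @param x Feature vector or `N x d` matrix.
#' @param mode `"deterministic"` or `"sampled"`.
#' @param mask Optional list of 0/1 vectors, one per hidden layer.
#' @param seed Optional integer seed used to draw the mask when `mask` is
#'   `NULL` in sampled mode.
#' @param type `"prob"` for softmax probabilities (default), `"logit"` for
#'   pre-softmax scores, `"hidden"` for last-hidden-layer activations
#'   (penultimate features).
#' @return An `N x n_classes` matrix (or `N x last_hidden_width` for
#'   `type = "hidden"`).
#' @export
forward <- function(net, x, mode = c("deterministic", "sampled"), mask = NULL,
                    seed = NULL, type = c("prob", "logit", "hidden")) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  spec <- net$spec
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != spec$input_dim)
    stop("input has ", ncol(x), " columns but the network expects ",
         spec$input_dim, call. = FALSE)
  masks <- NULL
  if (mode == "sampled") {
    if (!is.null(mask)) {
      stopifnot(length(mask) == length(spec$hidden))
      masks <- lapply(seq_along(mask), function(l)
        mask[[l]] / (1 - spec$dropout_prob[l]))
    } else if (!is.null(seed)) {
      masks <- with_seed(seed, draw_masks(spec))
    } else {
      masks <- draw_masks(spec)
    }
  }
  out <- forward_pass(net, x, masks, keep_hidden = (type == "hidden"))
  if (type == "hidden") return(out$hidden)
  if (type == "logit") return(out)
  softmax_rows(out)
}

#' Class-frequency-reweighted cross-entropy
#'
#' The mini-batch loss `-(1/(K*n)) * sum_i log(p_i(y_i)) / freq(y_i)` where
#' `freq(k)` is class `k`'s relative frequency within the batch. Equivalent to
#' macro-averaging the per-class mean cross-entropies, it attributes more
#' weight to the minority class; with equal class counts it reduces exactly to
#' the unweighted mean cross-entropy. Probabilities are clamped at 1e-12
#' before the log.
#'
#' @param probs `n x K` matrix of predicted class probabilities.
#' @param labels Integer class indices in `0..K-1`.
#' @param n_classes Number of classes `K`.
#' @return Non-negative scalar loss (natural log).
#' @export
weighted_cross_entropy <- function(probs, labels, n_classes) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  stopifnot(length(labels) == n, ncol(probs) == n_classes)
  freq <- tabulate(labels + 1L, nbins = n_classes) / n
  p_true <- pmax(probs[cbind(seq_len(n), labels + 1L)], 1e-12)
  -sum(log(p_true) / freq[labels + 1L]) / (n_classes * n)
}

# Per-sample loss weights: class-reweighted or uniform 1/n.
batch_weights <- function(labels, n_classes, class_weighting) {
  n <- length(labels)
  if (class_weighting) {
    freq <- tabulate(labels + 1L, nbins = n_classes) / n
    1 / (n_classes * n * freq[labels + 1L])
  } else rep(1 / n, n)
}

#' Train a dropout network by SGD with Nesterov momentum
#'
#' Minimises the (optionally class-reweighted) cross-entropy plus
#' `l2_lambda * sum(theta^2)` over all weights and biases, with independent
#' per-sample Bernoulli dropout masks on every hidden layer during training
#' (inverted dropout). Fully deterministic given `cfg$seed`.
#'
#' @param spec A `net_spec`.
#' @param x `N x d` feature matrix.
#' @param y Integer class labels in `0..n_classes-1`; at least two classes
#'   must be present.
#' @param cfg A `train_config`.
#' @return A `fitted_net` with per-epoch average training loss in
#'   `$training_log`.
#' @examples
#' toy <- make_toy2d(200, seed = 1)
#' sp <- net_spec(2, hidden = 16, dropout_prob = 0.2)
#' fit <- train_net(sp, toy$points, toy$labels,
#'                  train_config(epochs = 5, seed = 1))
#' @export
train_net <- function(spec, x, y, cfg) {
  stopifnot(inherits(spec, "net_spec"), inherits(cfg, "train_config"))
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training data must contain at least two classes", call. = FALSE)
  if (any(y < 0) || any(y >= spec$n_classes))
    stop("labels must lie in 0..n_classes-1", call. = FALSE)
  n <- nrow(x)
  K <- spec$n_classes
  H <- length(spec$hidden)
  net <- init_net(spec, derive_seed(cfg$seed, "init"))
  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(b) b * 0)
  mu <- cfg$momentum
  log_loss <- numeric(cfg$epochs)
  with_seed(derive_seed(cfg$seed, "sgd"), {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate[min(epoch, length(cfg$learning_rate))]
      perm <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- perm[s:min(s + cfg$batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        nb <- length(idx)
        # forward with cached activations and per-sample masks
        A <- vector("list", H + 1L)   # layer inputs
        M <- vector("list", H)        # dropout multiplier matrices
        a <- xb
        for (l in seq_len(H)) {
          A[[l]] <- a
          z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
          a <- act_fun(z, spec$activation)
          p <- spec$dropout_prob[l]
          m <- if (p == 0) NULL else
            matrix((stats::runif(nb * spec$hidden[l]) >= p) / (1 - p),
                   nb, spec$hidden[l])
          if (!is.null(m)) a <- a * m
          M[l] <- list(m)   # keep NULL placeholders for p = 0 layers
        }
        A[[H + 1L]] <- a
        logits <- sweep(a %*% net$W[[H + 1L]], 2, net$b[[H + 1L]], "+")
        P <- softmax_rows(logits)
        w_i <- batch_weights(yb, K, cfg$class_weighting)
        p_true <- pmax(P[cbind(seq_len(nb), yb + 1L)], 1e-12)
        l2 <- cfg$l2_lambda *
          (sum(vapply(net$W, function(w) sum(w^2), 0)) +
           sum(vapply(net$b, function(b) sum(b^2), 0)))
        ep_loss <- ep_loss + (-sum(w_i * log(p_true)) + l2)
        # backward
        dlog <- P
        dlog[cbind(seq_len(nb), yb + 1L)] <-
          dlog[cbind(seq_len(nb), yb + 1L)] - 1
        dlog <- dlog * w_i
        delta <- dlog
        for (l in rev(seq_len(H + 1L))) {
          gW <- crossprod(A[[l]], delta) + 2 * cfg$l2_lambda * net$W[[l]]
          gb <- colSums(delta) + 2 * cfg$l2_lambda * net$b[[l]]
          if (l > 1L) {
            da <- tcrossprod(delta, net$W[[l]])
            if (!is.null(M[[l - 1L]])) da <- da * M[[l - 1L]]
            if (spec$activation == "relu") {
              zpos <- A[[l]]   # post-activation (masked); relu grad via sign
              da <- da * (zpos > 0)
            }
            delta <- da
          }
          vW[[l]] <- mu * vW[[l]] - lr * gW
          vb[[l]] <- mu * vb[[l]] - lr * gb
          net$W[[l]] <- net$W[[l]] + mu * vW[[l]] - lr * gW
          net$b[[l]] <- net$b[[l]] + mu * vb[[l]] - lr * gb
        }
      }
      log_loss[epoch] <- ep_loss / length(starts)
    }
  })
  net$training_log <- log_loss
  net
}

#' @export
print.fitted_net <- function(x, ...) {
  s <- x$spec
  cat("Dropout softmax network:", s$input_dim, "->",
      paste(s$hidden, collapse = "-"), "->", s$n_classes,
      sprintf("(p_drop = %s, %s)\n",
              paste(unique(s$dropout_prob), collapse = "/"), s$activation))
  if (length(x$training_log))
    cat("Trained", length(x$training_log), "epochs; final loss",
        format(utils::tail(x$training_log, 1), digits = 4), "\n")
  invisible(x)
}
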