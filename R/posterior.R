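#' Monte Carlo dropout sampling of the approximate predictive posterior
#'
#' Keeps the dropout mechanism switched on at test time and performs `T`
#' stochastic forward passes; each pass draws one Bernoulli mask per hidden
#' layer (shared across all inputs, i.e. one sampled sub-network per pass) and
#' records every input's diseased-class probability. For `n_classes > 2` the
#' diseased probability is the summed softmax mass of all classes at or above
#' `onset`.
#'
#' @param net A `fitted_net`.
#' @param x Feature matrix (or single vector).
#' @param T Number of Monte Carlo samples (default 100).
#' @param seed Integer seed; the sample matrix is reproducible.
#' @param onset Disease onset level for diseased-mass aggregation.
#' @return A `posterior_samples` object: list with `samples` (`T x N`
#'   matrix of probabilities), `T` and `sample_ids`.
#' @export
mc_predict <- function(net, x, T = 100, seed = 1, onset = 1) {
  stopifnot(T >= 1)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  K <- net$spec$n_classes
  cols <- if (K == 2L) 2L else seq.int(onset + 1L, K)
  S <- matrix(NA_real_, T, nrow(x))
  with_seed(seed, {
    for (t in seq_len(T)) {
      masks <- draw_masks(net$spec)
      p <- softmax_rows(forward_pass(net, x, masks))
      S[t, ] <- rowSums(p[, cols, drop = FALSE])
    }
  })
  structure(list(samples = S, T = as.integer(T),
                 sample_ids = rownames(x) %||% seq_len(nrow(x))),
            class = "posterior_samples")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

samples_matrix <- function(s) {
  if (inherits(s, "posterior_samples")) s$samples else as.matrix(s)
}

#' Exact dropout-mask enumeration oracle
#'
#' Enumerates all `2^D` Bernoulli dropout masks of a small network (`D` =
#' total hidden units, at most 20), weights each sampled forward pass by its
#' mask probability under the product-Bernoulli measure, and returns the exact
#' first two moments of the induced diseased-probability distribution — the
#' estimands that Monte Carlo dropout approximates.
#'
#' @inheritParams mc_predict
#' @return List with numeric vectors `mean` and `sd` (population sd), one
#'   entry per input row.
#' @export
enumerate_posterior <- function(net, x, onset = 1) {
  spec <- net$spec
  D <- sum(spec$hidden)
  if (D > 20)
    stop("refusing to enumerate 2^", D, " masks (limit D <= 20)",
         call. = FALSE)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  K <- spec$n_classes
  cols <- if (K == 2L) 2L else seq.int(onset + 1L, K)
  keep <- rep(1 - spec$dropout_prob, times = spec$hidden)
  layer_of <- rep(seq_along(spec$hidden), times = spec$hidden)
  m1 <- numeric(nrow(x))
  m2 <- numeric(nrow(x))
  wsum <- 0
  for (code in 0:(2^D - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(D)]
    w <- prod(ifelse(bits == 1L, keep, 1 - keep))
    if (w == 0) next
    mask <- split(as.numeric(bits), layer_of)
    masks <- lapply(seq_along(spec$hidden), function(l)
      mask[[l]] / (1 - spec$dropout_prob[l]))
    p <- softmax_rows(forward_pass(net, x, masks))
    d <- rowSums(p[, cols, drop = FALSE])
    m1 <- m1 + w * d
    m2 <- m2 + w * d^2
    wsum <- wsum + w
  }
  list(mean = m1 / wsum, sd = sqrt(pmax(0, m2 / wsum - (m1 / wsum)^2)))
}

#' Predictive mean over Monte Carlo dropout samples
#'
#' @param s A `posterior_samples` object or `T x N` matrix.
#' @return Per-sample arithmetic mean of the `T` sampled diseased
#'   probabilities — the quantity used for the final prediction.
#' @export
predictive_mean <- function(s) {
  colMeans(samples_matrix(s))
}

#' Predictive standard deviation over Monte Carlo dropout samples
#'
#' Bessel-corrected sample standard deviation of the `T` sampled diseased
#' probabilities, the per-sample proxy for model uncertainty.
#'
#' @param s A `posterior_samples` object or `T x N` matrix (`T >= 2`).
#' @return Per-sample non-negative standard deviation.
#' @export
predictive_std <- function(s) {
  m <- samples_matrix(s)
  Tn <- nrow(m)
  if (Tn < 2) stop("predictive_std requires T >= 2 samples", call. = FALSE)
  mu <- colMeans(m)
  sqrt(pmax(0, (colSums(m^2) - Tn * mu^2) / (Tn - 1)))
}

#' Binary entropy in bits
#'
#' `H(p) = -(p log2 p + (1-p) log2 (1-p))` with `0 log 0 := 0`; maximal (1
#' bit) at `p = 0.5`, symmetric in `p <-> 1-p`.
#'
#' @param p Probability vector in `[0, 1]`.
#' @return Entropies in `[0, 1]` bits.
#' @export
binary_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  q <- 1 - p
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log2(p[ok]) + q[ok] * log2(q[ok]))
  h
}

#' Per-sample uncertainty summary of a dropout network
#'
#' Bundles, for every input: the MC-dropout predictive mean `mu_pred`,
#' predictive standard deviation `sigma_pred`, the binary entropy of
#' `mu_pred` (bits), and the conventional deterministic softmax output
#' `p_standard` (dropout off).
#'
#' @inheritParams mc_predict
#' @param sample_ids Optional identifiers (default: row numbers).
#' @return An `uncertainty_summary` data frame with columns `sample_id`,
#'   `mu_pred`, `sigma_pred`, `entropy`, `p_standard`.
#' @export
uncertainty_summary <- function(net, x, T = 100, seed = 1, onset = 1,
                                sample_ids = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  ps <- mc_predict(net, x, T = T, seed = seed, onset = onset)
  K <- net$spec$n_classes
  cols <- if (K == 2L) 2L else seq.int(onset + 1L, K)
  det <- softmax_rows(forward_pass(net, x, NULL))
  mu <- predictive_mean(ps)
  out <- data.frame(
    sample_id = if (is.null(sample_ids)) seq_len(nrow(x)) else sample_ids,
    mu_pred = mu,
    sigma_pred = if (ps$T >= 2) predictive_std(ps) else rep(0, nrow(x)),
    entropy = binary_entropy(pmin(1, pmax(0, mu))),
    p_standard = rowSums(det[, cols, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("uncertainty_summary", "data.frame")
  out
}
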