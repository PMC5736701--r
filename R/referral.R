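#' Partition samples by tolerated uncertainty
#'
#' Samples with uncertainty at or below the tolerated threshold `tau` are
#' retained for automatic decision; the rest are referred for further
#' inspection. The partition is exhaustive and disjoint.
#'
#' @param uncertainties Per-sample non-negative uncertainty values.
#' @param tau Tolerated uncertainty threshold (>= 0).
#' @return List with integer index vectors `retained` (`u <= tau`) and
#'   `referred` (`u > tau`).
#' @export
split_by_tolerated_uncertainty <- function(uncertainties, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
    stop("`tau` must be a non-negative real", call. = FALSE)
  keep <- uncertainties <= tau
  list(retained = which(keep), referred = which(!keep))
}

#' Classification accuracy of thresholded probabilities
#'
#' Predicts diseased when the probability is at or above `threshold` (an
#' exact tie counts as diseased — conservative for screening) and reports the
#' agreement rate with the labels.
#'
#' @param labels Binary 0/1 labels.
#' @param mu Predicted diseased probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(labels, mu, threshold = 0.5) {
  if (length(labels) == 0L || length(mu) == 0L)
    stop("`labels` and `mu` must be non-empty", call. = FALSE)
  stopifnot(length(labels) == length(mu))
  mean((mu >= threshold) == (labels == 1))
}

#' ROC curve and rank-based AUC
#'
#' AUC is the probability that a randomly drawn diseased score exceeds a
#' randomly drawn healthy score, with ties credited 1/2 (equivalent to
#' trapezoidal integration of the ROC curve). ROC points are reported at
#' every distinct threshold.
#'
#' @param labels Binary 0/1 labels; both classes must be present.
#' @param scores Real-valued scores, larger = more diseased.
#' @return List with `auc` and `points` (data frame `threshold`, `fpr`,
#'   `tpr`, ordered from the all-negative to the all-positive corner).
#' @export
roc_and_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  is_last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- cumsum(l == 1)[is_last]
  fp <- cumsum(l == 0)[is_last]
  points <- data.frame(threshold = c(Inf, s[is_last]),
                       fpr = c(0, fp / n0),
                       tpr = c(0, tp / n1))
  list(auc = auc, points = points)
}

#' Sensitivity and specificity at a decision threshold
#'
#' @inheritParams roc_and_auc
#' @param threshold Scores at or above it are called diseased.
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(labels, scores, threshold) {
  stopifnot(length(labels) == length(scores))
  if (!any(labels == 1) || !any(labels == 0))
    stop("sensitivity/specificity undefined: both classes must be present",
         call. = FALSE)
  pred <- scores >= threshold
  c(sensitivity = sum(pred & labels == 1) / sum(labels == 1),
    specificity = sum(!pred & labels == 0) / sum(labels == 0))
}

#' Percentile-bootstrap confidence interval
#'
#' Resamples rows (or elements) of `values` with replacement `B` times,
#' applies `statistic`, and returns the central `level` percentile interval.
#' Resamples where the statistic is undefined (`NA`) are dropped.
#'
#' @param values Numeric vector, or data frame / matrix resampled by row.
#' @param statistic Function of a resample returning a scalar (default
#'   [mean()]).
#' @param B Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(values, statistic = mean, B = 10000, level = 0.95,
                         seed = 1) {
  n <- NROW(values)
  if (n == 0L) stop("`values` must be non-empty", call. = FALSE)
  stopifnot(B >= 1, level > 0, level < 1)
  tab <- is.data.frame(values) || is.matrix(values)
  stats_b <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      s <- tryCatch(
        if (tab) statistic(values[idx, , drop = FALSE])
        else statistic(values[idx]),
        error = function(e) NA_real_)
      as.double(s)
    }, 0)
  })
  a <- (1 - level) / 2
  q <- stats::quantile(stats_b, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  c(low = q[1], high = q[2])
}

metric_value <- function(metric, labels, preds, threshold = 0.5) {
  if (metric == "accuracy") accuracy(labels, preds, threshold)
  else if (length(unique(labels)) < 2) NA_real_
  else roc_and_auc(labels, preds)$auc
}

#' Uncertainty-informed referral curve
#'
#' Sorts predictions by uncertainty (stable descending sort, ties broken by
#' sample index), refers the `ceiling((1 - f) * N)` most-uncertain samples at
#' each retained fraction `f`, and evaluates the metric on the retained rest,
#' with a percentile-bootstrap confidence interval per grid point. AUC on a
#' single-class retained set is recorded as missing.
#'
#' @param summary An [uncertainty_summary()] data frame (or any data frame
#'   with the chosen uncertainty field and `mu_pred`).
#' @param labels Binary 0/1 labels aligned with `summary` rows.
#' @param uncertainty_field `"sigma_pred"`, `"entropy"` (of `mu_pred`) or
#'   `"entropy_of_p_standard"` (standard-dropout baseline).
#' @param metric `"accuracy"` or `"auc"`.
#' @param fractions Retained-fraction grid in `(0, 1]`.
#' @param bootstrap_B Bootstrap resamples per grid point.
#' @param level Confidence level for the intervals.
#' @param threshold Probability threshold used by the accuracy metric.
#' @param seed Integer seed (per-point streams derived from it).
#' @return A `referral_curve` data frame: `fraction`, `n_retained`, `value`,
#'   `ci_low`, `ci_high`; attributes `metric` and `uncertainty_field`.
#' @export
referral_curve <- function(summary, labels,
                           uncertainty_field = c("sigma_pred", "entropy",
                                                 "entropy_of_p_standard"),
                           metric = c("accuracy", "auc"),
                           fractions = seq(1, 0.5, by = -0.05),
                           bootstrap_B = 10000, level = 0.95,
                           threshold = 0.5, seed = 1) {
  uncertainty_field <- match.arg(uncertainty_field)
  metric <- match.arg(metric)
  stopifnot(all(fractions > 0), all(fractions <= 1),
            nrow(summary) == length(labels))
  u <- switch(uncertainty_field,
              sigma_pred = summary$sigma_pred,
              entropy = summary$entropy,
              entropy_of_p_standard = binary_entropy(summary$p_standard))
  mu <- summary$mu_pred
  N <- length(u)
  ord <- order(-u)   # stable radix sort: ties keep ascending index order
  res <- lapply(fractions, function(f) {
    k <- ceiling((1 - f) * N)
    retained <- if (k == 0L) seq_len(N) else sort(ord[-seq_len(k)])
    lab_r <- labels[retained]
    mu_r <- mu[retained]
    val <- metric_value(metric, lab_r, mu_r, threshold)
    if (is.na(val)) {
      ci <- c(NA_real_, NA_real_)
    } else if (metric == "accuracy") {
      correct <- as.numeric((mu_r >= threshold) == (lab_r == 1))
      ci <- bootstrap_ci(correct, mean, B = bootstrap_B, level = level,
                         seed = derive_seed(seed, sprintf("frac%g", f)))
    } else {
      df <- data.frame(l = lab_r, s = mu_r)
      ci <- bootstrap_ci(df, function(d) metric_value("auc", d$l, d$s),
                         B = bootstrap_B, level = level,
                         seed = derive_seed(seed, sprintf("frac%g", f)))
    }
    data.frame(fraction = f, n_retained = length(retained), value = val,
               ci_low = ci[1], ci_high = ci[2])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  attr(out, "uncertainty_field") <- uncertainty_field
  class(out) <- c("referral_curve", "data.frame")
  out
}

#' Random-referral baseline
#'
#' Refers the same number of samples as the informed curve but uniformly at
#' random, averaging the metric over `n_draws` retained subsets of size
#' `ceiling(f * N)` per fraction; at `f = 1` the full-data metric is returned
#' with a zero-width interval.
#'
#' @param labels Binary 0/1 labels.
#' @param predictions Diseased probabilities (accuracy) or scores (AUC).
#' @param metric `"accuracy"` or `"auc"`.
#' @param fractions Retained-fraction grid in `(0, 1]`.
#' @param n_draws Random subsets per fraction (default 100).
#' @param threshold Probability threshold for accuracy.
#' @param seed Integer seed.
#' @return Data frame `fraction`, `value` (mean over draws), `ci_low`,
#'   `ci_high` (2.5/97.5 percentiles over draws).
#' @export
random_referral_baseline <- function(labels, predictions,
                                     metric = c("accuracy", "auc"),
                                     fractions = seq(1, 0.5, by = -0.05),
                                     n_draws = 100, threshold = 0.5,
                                     seed = 1) {
  metric <- match.arg(metric)
  stopifnot(n_draws >= 1, length(labels) == length(predictions))
  N <- length(labels)
  res <- with_seed(seed, lapply(fractions, function(f) {
    m <- ceiling(f * N)
    if (m >= N) {
      v <- metric_value(metric, labels, predictions, threshold)
      return(data.frame(fraction = f, value = v, ci_low = v, ci_high = v))
    }
    vals <- vapply(seq_len(n_draws), function(d) {
      keep <- sample.int(N, m)
      metric_value(metric, labels[keep], predictions[keep], threshold)
    }, 0)
    q <- stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    data.frame(fraction = f, value = mean(vals, na.rm = TRUE),
               ci_low = q[1], ci_high = q[2])
  }))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Disease-level composition of referred samples
#'
#' For each tolerated uncertainty `tau`, the distribution of ordinal disease
#' levels among the referred samples (`u > tau`). At `tau = 0` (all samples
#' referred when every uncertainty is positive) the composition equals the
#' dataset's empirical level prior exactly.
#'
#' @param levels Integer grades 0..4 of all samples.
#' @param uncertainties Aligned per-sample uncertainties.
#' @param tau_grid Tolerated-uncertainty grid; default 50 evenly spaced
#'   values over `[0, max(u)]`.
#' @return A `level_composition` data frame: `tau`, `n_referred`,
#'   `level0..level4` (each row of proportions sums to 1; `NA` when the
#'   referred set is empty).
#' @export
level_composition <- function(levels, uncertainties, tau_grid = NULL) {
  if (any(levels < 0) || any(levels > 4) || any(levels != as.integer(levels)))
    stop("`levels` must be integer grades in 0..4", call. = FALSE)
  stopifnot(length(levels) == length(uncertainties))
  if (is.null(tau_grid))
    tau_grid <- seq(0, max(uncertainties), length.out = 50)
  rows <- lapply(tau_grid, function(tau) {
    ref <- uncertainties > tau
    if (!any(ref)) {
      props <- rep(NA_real_, 5)
    } else {
      props <- tabulate(levels[ref] + 1L, nbins = 5L) / sum(ref)
    }
    c(tau = tau, n_referred = sum(ref), stats::setNames(props, paste0("level", 0:4)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("level_composition", "data.frame")
  out
}

#' Contra-lateral ambiguity in referred vs retained samples
#'
#' An image is ambiguous iff its binarised label disagrees with its
#' contra-lateral (same-patient, other-eye) image's binarised label — the
#' patient's disease state is then undefined at the chosen onset. For each
#' tolerated uncertainty `tau` the ambiguous fraction is reported separately
#' within the referred (`u > tau`) and retained (`u <= tau`) buckets.
#'
#' @param cohort A `graded_cohort` data frame (paired eyes required).
#' @param onset Disease onset level (1 or 2) for binarisation.
#' @param uncertainties Per-image uncertainties aligned with `cohort` rows.
#' @param tau_grid Tolerated-uncertainty grid; default 50 evenly spaced
#'   values over `[0, max(u)]`.
#' @return An `ambiguity_report` data frame: `tau`,
#'   `referred_ambiguous_fraction`, `retained_ambiguous_fraction` (`NA` for
#'   an empty bucket).
#' @export
ambiguity_report <- function(cohort, onset, uncertainties, tau_grid = NULL) {
  stopifnot(nrow(cohort) == length(uncertainties))
  amb <- ambiguous_flags(cohort, onset)
  if (is.null(tau_grid))
    tau_grid <- seq(0, max(uncertainties), length.out = 50)
  rows <- lapply(tau_grid, function(tau) {
    ref <- uncertainties > tau
    c(tau = tau,
      referred_ambiguous_fraction =
        if (any(ref)) mean(amb[ref]) else NA_real_,
      retained_ambiguous_fraction =
        if (any(!ref)) mean(amb[!ref]) else NA_real_)
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("ambiguity_report", "data.frame")
  out
}

# Per-image logical flag: binarised label disagrees with the contra-lateral
# eye's. Requires exactly two records (left + right) per patient.
ambiguous_flags <- function(cohort, onset) {
  cnt <- table(cohort$patient_id)
  if (any(cnt != 2))
    stop("every patient must contribute exactly two records (paired eyes)",
         call. = FALSE)
  b <- binarize(cohort$level, onset)
  other <- stats::ave(b, cohort$patient_id, FUN = function(v) rev(v))
  b != other
}

#' Gaussian kernel density summary with Scott bandwidth
#'
#' Evaluates a 1-D Gaussian kernel density estimate with Scott's bandwidth
#' `n^(-1/5) * sd(values)` on an even grid covering the data range plus three
#' bandwidths on each side.
#'
#' @param values Numeric sample (`n >= 2`, non-zero spread).
#' @param n_grid Number of grid points (default 512).
#' @return Data frame `x`, `density`; attribute `bandwidth`.
#' @export
density_summary <- function(values, n_grid = 512) {
  n <- length(values)
  if (n < 2) stop("need at least two values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("zero variance: density bandwidth undefined", call. = FALSE)
  bw <- s * n^(-1 / 5)
  grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw,
              length.out = n_grid)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g - values, sd = bw)), 0)
  out <- data.frame(x = grid, density = dens)
  attr(out, "bandwidth") <- bw
  out
}
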