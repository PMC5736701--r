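test_that("tolerated-uncertainty split partitions samples at the threshold", {
  sp <- split_by_tolerated_uncertainty(c(0.1, 0.3), 0.2)
  expect_identical(sp$retained, 1L)
  expect_identical(sp$referred, 2L)
  u <- c(0.2, 0.05, 0.4)
  expect_identical(split_by_tolerated_uncertainty(u, 0.4)$retained, 1:3)
  expect_identical(split_by_tolerated_uncertainty(u, 0)$referred, 1:3)
  expect_error(split_by_tolerated_uncertainty(u, -0.1), "non-negative")
})

test_that("accuracy thresholds at 0.5 with diseased tie-break", {
  expect_equal(accuracy(c(1, 0), c(0.68, 0.36)), 1)
  mu <- c(0.9, 0.2, 0.7, 0.4)
  lab <- c(1, 0, 0, 1)
  expect_equal(accuracy(lab, mu) + accuracy(lab, 1 - mu), 1)
  expect_equal(accuracy(1, 0.5), 1)   # exact threshold counts as diseased
  expect_equal(accuracy(0, 0.5), 0)
  expect_error(accuracy(numeric(0), numeric(0)), "non-empty")
})

test_that("rank-based AUC matches the all-pairs oracle and pROC", {
  expect_equal(roc_and_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_and_auc(c(0, 1, 0, 1), rep(0.3, 4))$auc, 0.5)
  set.seed(5)
  lab <- rbinom(20, 1, 0.4)
  lab[1:2] <- c(0, 1)
  sc <- round(rnorm(20), 1)      # ties likely
  pairs <- expand.grid(i = which(lab == 1), j = which(lab == 0))
  oracle <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                        ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
  expect_equal(roc_and_auc(lab, sc)$auc, oracle)
  skip_if_not_installed("pROC")
  expect_equal(roc_and_auc(lab, sc)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))))
  expect_error(roc_and_auc(c(1, 1), c(0.1, 0.2)), "both classes")
})

test_that("sensitivity/specificity agree with contingency arithmetic and ROC", {
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0)
  sc <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1, 0.15, 0.05)  # TP=3 FN=1 TN=4 FP=0
  ss <- sensitivity_specificity(lab, sc, 0.5)
  expect_equal(unname(ss), c(0.75, 1))
  expect_equal(unname(sensitivity_specificity(lab, sc, 0)[1]), 1)
  roc <- roc_and_auc(lab, sc)
  pt <- roc$points[roc$points$threshold == 0.7, ]
  expect_equal(pt$tpr, unname(ss[1]))
  expect_equal(pt$fpr, 1 - unname(ss[2]))
})

test_that("percentile bootstrap is seeded and degenerate on constants", {
  ci <- bootstrap_ci(rep(0.7, 50), B = 100, seed = 1)
  expect_equal(unname(ci), c(0.7, 0.7))
  set.seed(3)
  v <- rnorm(30)
  expect_identical(bootstrap_ci(v, mean, B = 500, seed = 9),
                   bootstrap_ci(v, mean, B = 500, seed = 9))
  expect_error(bootstrap_ci(numeric(0)), "non-empty")
})

test_that("the referral curve removes the most-uncertain samples first", {
  # 10 samples, 8 correct; the two errors carry the two largest uncertainties
  lab <- c(rep(1, 5), rep(0, 5))
  mu <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1, 0.2, 0.3, 0.9, 0.4)  # errors at rows 5 and 9
  u <- c(0.1, 0.1, 0.1, 0.1, 0.9, 0.1, 0.1, 0.1, 0.8, 0.1)
  summ <- data.frame(mu_pred = mu, sigma_pred = u,
                     entropy = binary_entropy(mu), p_standard = mu)
  crv <- referral_curve(summ, lab, "sigma_pred", "accuracy",
                        fractions = c(1, 0.8), bootstrap_B = 50, seed = 1)
  expect_equal(crv$value, c(0.8, 1.0))
  expect_true(all(crv$ci_low <= crv$value & crv$value <= crv$ci_high))
})

test_that("uninformative uncertainties leave the curve flat", {
  set.seed(11)
  lab <- rbinom(60, 1, 0.5)
  mu <- runif(60)
  full <- accuracy(lab, mu)
  summ <- data.frame(mu_pred = mu, sigma_pred = rep(0.3, 60),
                     entropy = rep(0.3, 60), p_standard = mu)
  crv <- referral_curve(summ, lab, "sigma_pred", "accuracy",
                        fractions = c(1, 0.9, 0.7), bootstrap_B = 50, seed = 2)
  # ties broken by index: retained sets are deterministic head-subsets
  manual <- vapply(c(1, 0.9, 0.7), function(f) {
    keep <- seq_len(60 - ceiling((1 - f) * 60)) + ceiling((1 - f) * 60)
    accuracy(lab[keep], mu[keep])
  }, 0)
  expect_equal(crv$value, manual)
})

test_that("curve values equal brute-force recomputation on the retained subset", {
  fx <- cohort_fixture(1)
  fr <- c(1, 0.85, 0.6)
  for (metric in c("accuracy", "auc")) {
    crv <- referral_curve(fx$summary, fx$test_labels, "sigma_pred", metric,
                          fractions = fr, bootstrap_B = 20, seed = 3)
    u <- fx$summary$sigma_pred
    rk <- rank(-u, ties.method = "first")   # independent referral ordering
    for (i in seq_along(fr)) {
      k <- ceiling((1 - fr[i]) * length(u))
      keep <- which(rk > k)
      want <- if (metric == "accuracy")
        accuracy(fx$test_labels[keep], fx$summary$mu_pred[keep])
      else roc_and_auc(fx$test_labels[keep], fx$summary$mu_pred[keep])$auc
      expect_equal(crv$value[i], want)
      expect_equal(crv$n_retained[i], length(keep))
    }
  }
})

test_that("random referral is unbiased and exact at full retention", {
  set.seed(7)
  lab <- rbinom(300, 1, 0.4)
  mu <- plogis(1.5 * (2 * lab - 1) + rnorm(300))  # imperfect classifier
  full <- accuracy(lab, mu)
  expect_lt(full, 1)
  base <- random_referral_baseline(lab, mu, "accuracy",
                                   fractions = c(1, 0.8, 0.6),
                                   n_draws = 400, seed = 5)
  expect_equal(base$value[1], full)
  expect_equal(base$ci_low[1], base$ci_high[1])
  # exchangeability: mean over draws stays within 2 subset standard errors
  for (i in 2:3) {
    m <- ceiling(base$fraction[i] * 300)
    expect_lt(abs(base$value[i] - full), 2 * sqrt(full * (1 - full) / m))
  }
  expect_identical(base, random_referral_baseline(lab, mu, "accuracy",
                                                  fractions = c(1, 0.8, 0.6),
                                                  n_draws = 400, seed = 5))
})

test_that("level composition recovers the prior at tau = 0 and normalizes", {
  lv <- c(0, 0, 0, 1, 2, 2, 3, 4)
  u <- c(0.5, 0.4, 0.3, 0.2, 0.6, 0.7, 0.1, 0.2)
  comp <- level_composition(lv, u, tau_grid = c(0, 0.45, 1))
  expect_equal(as.numeric(comp[1, paste0("level", 0:4)]),
               as.numeric(prop.table(table(factor(lv, 0:4)))))
  expect_equal(sum(comp[2, paste0("level", 0:4)]), 1)
  expect_true(all(is.na(comp[3, paste0("level", 0:4)])))  # empty referral
  # constructed: only level-1 samples above tau
  comp2 <- level_composition(c(1, 1, 0, 2), c(0.9, 0.8, 0.1, 0.1),
                             tau_grid = 0.5)
  expect_equal(comp2$level1, 1)
  expect_error(level_composition(c(0, 7), c(0.1, 0.2)), "0..4")
})

test_that("ambiguity report separates referred and retained buckets", {
  coh <- data.frame(
    patient_id = rep(c("a", "b"), each = 2),
    eye = rep(c("left", "right"), 2),
    level = c(0, 1, 2, 2),                 # patient a ambiguous at onset 1
    f0 = rnorm(4)
  )
  u <- c(0.9, 0.8, 0.1, 0.2)               # ambiguous pair most uncertain
  rep1 <- ambiguity_report(coh, 1, u, tau_grid = 0.5)
  expect_equal(rep1$referred_ambiguous_fraction, 1)
  expect_equal(rep1$retained_ambiguous_fraction, 0)
  bad <- coh[-1, ]
  expect_error(ambiguity_report(bad, 1, u[-1]), "exactly two")
})

test_that("ambiguity fractions match a brute-force recount on a simulated cohort", {
  coh <- make_graded_cohort(400, eye_correlation = 0.9, seed = 15)
  set.seed(16)
  u <- runif(nrow(coh))
  tau <- 0.7
  rep1 <- ambiguity_report(coh, 1, u, tau_grid = tau)
  b <- binarize(coh$level, 1)
  amb <- logical(nrow(coh))
  for (i in seq_len(nrow(coh))) {
    j <- which(coh$patient_id == coh$patient_id[i] & coh$eye != coh$eye[i])
    amb[i] <- b[i] != b[j]
  }
  expect_equal(rep1$referred_ambiguous_fraction, mean(amb[u > tau]))
  expect_equal(rep1$retained_ambiguous_fraction, mean(amb[u <= tau]))
  # perfectly correlated eyes: no ambiguity anywhere
  coh1 <- make_graded_cohort(200, eye_correlation = 1, seed = 18)
  rep2 <- ambiguity_report(coh1, 1, runif(nrow(coh1)), tau_grid = c(0.2, 0.8))
  expect_equal(rep2$referred_ambiguous_fraction, c(0, 0))
  expect_equal(rep2$retained_ambiguous_fraction, c(0, 0))
})

test_that("Scott-bandwidth density is normalized, symmetric and matches stats::density", {
  set.seed(20)
  half <- rnorm(100)
  v <- c(half, -half)            # exactly symmetric about 0
  d <- density_summary(v, n_grid = 401)
  expect_equal(d$density, rev(d$density), tolerance = 1e-9)
  integral <- sum(diff(d$x) * (d$density[-1] + d$density[-nrow(d)]) / 2)
  expect_gte(integral, 0.99)
  expect_lte(integral, 1.01)
  # Scott bandwidth on a sample scaled to unit sd
  w <- as.numeric(scale(rnorm(100)))
  dw <- density_summary(w)
  expect_equal(attr(dw, "bandwidth"), 100^(-0.2), tolerance = 1e-9)
  ref <- density(v, bw = attr(d, "bandwidth"), kernel = "gaussian",
                 from = min(d$x), to = max(d$x), n = 401)
  expect_equal(d$density, ref$y, tolerance = 1e-3)
  expect_error(density_summary(rep(1, 10)), "variance")
})
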