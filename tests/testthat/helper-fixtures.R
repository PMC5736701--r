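# Expensive fixtures (trained networks, MC grids) built once per test run.
.fix_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix_cache[[name]])) assign(name, builder(), envir = .fix_cache)
  get(name, envir = .fix_cache)
}

# Two-moons problem with the 3x100 / p_drop = 0.5 network.
toy_fixture <- function() fixture("toy", function() {
  toy <- make_toy2d(1000, noise_sd = 0.15, seed = 7)
  tr <- toy$split == "train"
  net <- train_net(net_spec(2, c(100, 100, 100), dropout_prob = 0.5),
                   toy$points[tr, ], toy$labels[tr],
                   train_config(epochs = 150, learning_rate = 0.05,
                                seed = 11))
  summ <- uncertainty_summary(net, toy$points[!tr, ], T = 100, seed = 3)
  list(toy = toy, net = net, is_train = tr, summary = summ,
       test_points = toy$points[!tr, ], test_labels = toy$labels[!tr])
})

# 100x100 input-grid posterior summary for the toy network.
toy_grid_fixture <- function() fixture("toy_grid", function() {
  fx <- toy_fixture()
  r1 <- range(fx$toy$points[, 1])
  r2 <- range(fx$toy$points[, 2])
  gx <- seq(r1[1] - 0.5, r1[2] + 0.5, length.out = 100)
  gy <- seq(r2[1] - 0.5, r2[2] + 0.5, length.out = 100)
  grid <- as.matrix(expand.grid(x1 = gx, x2 = gy))
  gs <- uncertainty_summary(fx$net, grid, T = 100, seed = 5)
  list(grid = grid, gx = gx, gy = gy, summary = gs)
})

# Default graded cohort with a trained dropout classifier for a given onset.
cohort_fixture <- function(onset = 1) {
  fixture(paste0("cohort_onset", onset), function() {
    coh <- make_graded_cohort(2000, seed = derive_seed(1, "cohort"))
    pats <- unique(coh$patient_id)
    set.seed(derive_seed(1, "split"))
    train_pat <- sample(pats, floor(0.6 * length(pats)))
    is_train <- coh$patient_id %in% train_pat
    feats <- as.matrix(coh[, c("f0", "f1")])
    y <- binarize(coh$level, onset)
    net <- train_net(net_spec(2, c(32, 32), dropout_prob = 0.3),
                     feats[is_train, ], y[is_train],
                     train_config(epochs = 40, learning_rate = 0.05,
                                  seed = derive_seed(1, "train")))
    test <- coh[!is_train, , drop = FALSE]
    summ <- uncertainty_summary(net, feats[!is_train, ], T = 100,
                                seed = derive_seed(1, "mc"))
    list(cohort = coh, net = net, test = test, summary = summ,
         test_labels = y[!is_train], test_levels = test$level,
         test_features = feats[!is_train, ])
  })
}

# Tiny enumerable network (2 -> 4 -> 4 -> 2, D = 8 droppable units) with
# amplified random weights so the mask-induced posterior has visible spread.
tiny_net_fixture <- function() fixture("tiny_net", function() {
  spec <- net_spec(2, c(4, 4), n_classes = 2, dropout_prob = 0.5)
  net <- mcrefer:::init_net(spec, seed = 5)
  net$W <- lapply(net$W, function(w) w * 2.5)
  set.seed(13)
  xs <- matrix(rnorm(40), 20, 2)
  exact <- enumerate_posterior(net, xs)
  list(net = net, inputs = xs, exact = exact)
})

# Two well-separated Gaussian blobs for optimisation sanity checks.
blobs_fixture <- function() fixture("blobs", function() {
  set.seed(21)
  n <- 400
  x <- rbind(matrix(rnorm(n, mean = -2, sd = 0.7), n / 2, 2),
             matrix(rnorm(n, mean = 2, sd = 0.7), n / 2, 2))
  y <- rep(c(0L, 1L), each = n / 2)
  test <- sample.int(n, 100)
  list(x = x[-test, ], y = y[-test], x_test = x[test, ], y_test = y[test])
})
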