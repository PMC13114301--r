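make_xy <- function(n, p_signal, p_noise, beta = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * (p_signal + p_noise)), n)
  colnames(X) <- c(sprintf("sig%d", seq_len(p_signal)),
                   sprintf("noise%02d", seq_len(p_noise)))
  lp <- X[, seq_len(p_signal), drop = FALSE] %*% rep(beta, p_signal)
  y <- rbinom(n, 1, plogis(lp))
  X <- apply(X, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  list(X = X, y = y)
}

test_that("shuffle-split AUC separates the separable and nulls the noise", {
  # a perfectly separating feature
  set.seed(1)
  y <- rep(0:1, each = 100)
  X <- cbind(sep = y + runif(200, 0, 0.2), junk = runif(200))
  r <- shuffle_split_auc(X, y, scheme = split_scheme(20, seed = 2))
  expect_equal(r$mean_auc, 1, tolerance = 1e-6)
  expect_true(all(r$per_split_auc >= 0 & r$per_split_auc <= 1))
  # pure noise: mean AUC near one half
  set.seed(3)
  Xn <- matrix(runif(300 * 5), 300)
  yn <- rbinom(300, 1, 0.5)
  rn <- shuffle_split_auc(Xn, yn, scheme = split_scheme(200, seed = 4))
  expect_lt(abs(rn$mean_auc - 0.5), 0.05)
})

test_that("mean shuffle-split AUC equals a hand-computed per-split average", {
  set.seed(5)
  dat <- make_xy(40, 1, 3, seed = 5)
  scheme <- split_scheme(2, seed = 9)
  splits <- brachytox:::make_splits(dat$y, scheme)
  r <- shuffle_split_auc(dat$X, dat$y, scheme = scheme, splits = splits)
  # oracle: refit each split independently and average pROC AUCs
  skip_if_not_installed("pROC")
  oracle <- vapply(splits, function(te) {
    yf <- factor(dat$y, levels = 0:1)
    fit <- e1071::svm(dat$X[-te, ], yf[-te], kernel = "radial",
                      cost = 1, gamma = 1 / ncol(dat$X), scale = FALSE)
    dv <- attr(predict(fit, dat$X[te, ], decision.values = TRUE),
               "decision.values")
    s <- if (startsWith(colnames(dv)[1], "1")) dv[, 1] else -dv[, 1]
    as.numeric(pROC::auc(pROC::roc(dat$y[te], s, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  expect_equal(r$mean_auc, mean(oracle), tolerance = 1e-9)
})

test_that("rank AUC matches the Mann-Whitney statistic from pROC", {
  skip_if_not_installed("pROC")
  set.seed(6)
  for (i in 1:5) {
    s <- rnorm(40); y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(brachytox:::rank_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<",
                                                levels = c(0, 1)))),
                 tolerance = 1e-12)
  }
})

test_that("SBS terminates at the one-in-ten level and is reproducible", {
  for (n in c(20, 50)) {
    dat <- make_xy(n, 1, floor(n / 10) + 4, seed = n)
    fit <- sbs_select(dat$X, dat$y, scheme = split_scheme(3, seed = 1))
    expect_length(fit$selected, floor(n / 10))
    expect_equal(nrow(fit$trace), ncol(dat$X) - floor(n / 10))
  }
  dat <- make_xy(30, 1, 6, seed = 77)
  f1 <- sbs_select(dat$X, dat$y, scheme = split_scheme(4, seed = 3))
  f2 <- sbs_select(dat$X, dat$y, scheme = split_scheme(4, seed = 3))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$selected, f2$selected)
  expect_equal(f1$mean_auc, f2$mean_auc)
  expect_error(sbs_select(dat$X[, 1:2], dat$y, scheme = split_scheme(2),
                          stop_level = 3),
               "must exceed")
})

test_that("SBS retains planted predictors over noise", {
  dat <- make_xy(200, 3, 12, beta = 2.5, seed = 42)
  fit <- sbs_select(dat$X, dat$y, scheme = split_scheme(15, seed = 2),
                    stop_level = 3)
  expect_setequal(fit$selected, c("sig1", "sig2", "sig3"))
  expect_true(all(fit$trace$mean_auc >= 0 & fit$trace$mean_auc <= 1))
  # mean ROC is a curve from (0,0)-ish to (1,1), non-decreasing
  expect_true(all(diff(fit$roc$tpr) >= -1e-12))
  expect_equal(fit$roc$tpr[nrow(fit$roc)], 1)

  # importance by removal: dropping a planted feature hurts most
  imp <- importance_by_removal(fit, dat$X, dat$y,
                               scheme = split_scheme(15, seed = 4))
  expect_equal(nrow(imp), 3L)
  expect_true(all(imp$mean_auc_without <= fit$mean_auc + 0.05))
})

test_that("removal importance ranks a planted feature above noise", {
  dat <- make_xy(150, 1, 4, beta = 3, seed = 9)
  scheme <- split_scheme(10, seed = 5)
  fit <- sbs_select(dat$X, dat$y, scheme = scheme, stop_level = 3)
  if ("sig1" %in% fit$selected && length(fit$selected) > 1) {
    imp <- importance_by_removal(fit, dat$X, dat$y, scheme = scheme)
    expect_equal(imp$feature[1], "sig1")  # lowest AUC-without = most important
  }
  single <- structure(list(selected = "sig1", feature_names = "sig1",
                           final_scheme = scheme),
                      class = "sbs_svm")
  expect_equal(nrow(importance_by_removal(single, dat$X, dat$y)), 1L)
})

test_that("PSO search respects the hyperparameter box and helps when tuning matters", {
  dat <- make_xy(80, 2, 2, seed = 12)
  hp <- pso_tune(dat$X, dat$y, scheme = split_scheme(5, seed = 3),
                 n_particles = 5, n_iter = 3)
  expect_gte(hp[["C"]], 0)
  expect_lte(hp[["C"]], 100)
  expect_gte(hp[["gamma"]], 1e-5)
  expect_lte(hp[["gamma"]], 100)

  # on RBF-separable rings, tuned parameters beat a mismatched default
  set.seed(13)
  n <- 120
  r <- c(runif(n / 2, 0, 0.6), runif(n / 2, 1.4, 2))
  a <- runif(n, 0, 2 * pi)
  Xr <- cbind(x = r * cos(a) / 4 + 0.5, y = r * sin(a) / 4 + 0.5)
  yr <- rep(0:1, each = n / 2)
  sch <- split_scheme(10, seed = 6)
  base_auc <- shuffle_split_auc(Xr, yr, hyper = c(C = 1, gamma = 1e-4),
                                scheme = sch)$mean_auc
  hp2 <- pso_tune(Xr, yr, scheme = sch, n_particles = 6, n_iter = 4)
  tuned_auc <- shuffle_split_auc(Xr, yr, hyper = hp2, scheme = sch)$mean_auc
  expect_gte(tuned_auc, base_auc)
})

test_that("prediction methods work on new data", {
  dat <- make_xy(60, 1, 4, seed = 21)
  fit <- sbs_select(dat$X, dat$y, scheme = split_scheme(3, seed = 1),
                    stop_level = 2)
  sc <- predict(fit, dat$X)
  expect_length(sc, 60)
  cls <- predict(fit, dat$X, type = "class")
  expect_true(all(cls %in% 0:1))
  expect_output(print(fit), "retained")
})
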