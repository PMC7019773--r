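test_that("backward selection keeps informative features and rejects degenerate input", {
  d <- planted_features(600, p = 300, informative = 12, shift = 1,
                        windows_per_video = 10, seed = 5)
  cfg <- cima_cfg(drop_frac = 0.3, min_features = 8, inner_folds = 3, seed = 1)
  sel <- fit_pls_backward(d$features$features, d$y, cfg,
                          groups = d$features$meta$video_id)
  expect_gte(sum(d$informative %in% sel$selected), 9)
  expect_gt(sel$inner_auc, 0.9)
  # trace is monotone in set size and records every iterate
  expect_true(all(diff(sel$trace$n_features) < 0))

  expect_error(fit_pls_backward(d$features$features, rep(1, 600), cfg), "single-class")
  Xz <- d$features$features
  Xz[, 50] <- 3
  expect_warning(
    sel2 <- fit_pls_backward(Xz, d$y, cfg, groups = d$features$meta$video_id),
    "zero-variance")
  expect_false(50 %in% sel2$selected)
})

test_that("selection is deterministic and unaffected by raw feature scaling", {
  d <- planted_features(400, p = 120, informative = 8, shift = 1,
                        windows_per_video = 10, seed = 6)
  cfg <- cima_cfg(drop_frac = 0.3, min_features = 8, inner_folds = 3, seed = 9)
  s1 <- fit_pls_backward(d$features$features, d$y, cfg)
  s2 <- fit_pls_backward(d$features$features, d$y, cfg)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$trace, s2$trace)
  # standardization absorbs any raw rescaling of a feature column
  Xs <- d$features$features
  Xs[, 3] <- Xs[, 3] * 10
  s3 <- fit_pls_backward(Xs, d$y, cfg)
  expect_identical(s3$selected, s1$selected)
  expect_equal(s3$trace$inner_auc, s1$trace$inner_auc, tolerance = 1e-12)
})

test_that("composite scores are five orthogonal zero-mean latent variables", {
  d <- planted_features(400, p = 120, informative = 8, shift = 1.2, seed = 7)
  X <- d$features$features
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  pls <- cima:::pls1_fit(Xs, d$y - mean(d$y), 5L)
  sc <- composite_scores(Xs, pls)
  expect_equal(ncol(sc), 5L)
  expect_true(all(abs(colMeans(sc)) < 1e-8))
  G <- crossprod(sc)
  off <- G[upper.tri(G)]
  expect_true(all(abs(off) / sqrt(diag(G)[1] * diag(G)[5]) < 1e-6))
  expect_error(composite_scores(Xs[, 1:10], pls), "match")
})

test_that("pls predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  d <- planted_features(150, p = 40, informative = 5, shift = 1, seed = 8)
  X <- d$features$features
  mu <- colMeans(X); sigma <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  yc <- d$y - mean(d$y)
  fit <- cima:::pls1_fit(Xs, yc, 5L)
  pred_ours <- as.vector(Xs %*% fit$coef)
  ref <- mixOmics::pls(Xs, yc, ncomp = 5, scale = FALSE, mode = "regression")
  pred_ref <- predict(ref, Xs)$predict[, 1, 5]
  expect_equal(pred_ours, unname(pred_ref), tolerance = 1e-6)
})

test_that("pure-noise features give a chance-level inner AUC", {
  d <- planted_features(5000, p = 990, informative = 0, shift = 0,
                        windows_per_video = 1, seed = 10)
  cfg <- cima_cfg(drop_frac = 0.5, min_features = 20, inner_folds = 3, seed = 2)
  sel <- fit_pls_backward(d$features$features, d$y, cfg)
  expect_gte(sel$inner_auc, 0.45)
  expect_lte(sel$inner_auc, 0.55)
})

test_that("the discriminant separates, respects symmetry and matches a density oracle", {
  set.seed(42)
  sc0 <- matrix(rnorm(200 * 1, -3, 0.1), ncol = 1)
  sc1 <- matrix(rnorm(200 * 1, 3, 0.1), ncol = 1)
  scores <- rbind(sc0, sc1)
  y <- rep(c(0, 1), each = 200)
  lda <- fit_lda(scores, y, priors = "equal")
  pr <- cima:::lda_predict(lda, scores)
  expect_equal(as.integer(pr$posterior >= 0.5), y)
  # symmetric classes: boundary at 0
  b0 <- cima:::lda_predict(lda, matrix(1e-9, 1, 1))$posterior
  expect_gt(b0, 0.5 - 1e-3)
  # posterior normalization and brute-force Gaussian density oracle
  set.seed(43)
  test_pts <- matrix(rnorm(50, 0, 3), ncol = 1)
  pr_t <- cima:::lda_predict(lda, test_pts)
  dens <- function(x, m, S, p) p * exp(-0.5 * (x - m)^2 / S) / sqrt(2 * pi * S)
  for (i in 1:50) {
    d0 <- dens(test_pts[i], lda$means[1, ], lda$cov[1, 1], lda$priors[1])
    d1 <- dens(test_pts[i], lda$means[2, ], lda$cov[1, 1], lda$priors[2])
    expect_equal(unname(pr_t$posterior[i]), unname(d1 / (d0 + d1)),
                 tolerance = 1e-10)
  }
  expect_error(fit_lda(scores[c(1:3, 201:203), , drop = FALSE], y[c(1:3, 201:203)]),
               "per class")
})

test_that("posteriors agree with the reference lda implementation", {
  skip_if_not_installed("MASS")
  set.seed(11)
  sc <- matrix(rnorm(600 * 3), ncol = 3)
  y <- rbinom(600, 1, 0.5)
  sc[y == 1, 1] <- sc[y == 1, 1] + 1.5
  lda <- fit_lda(sc, y, priors = "equal")
  pr <- cima:::lda_predict(lda, sc)
  ref <- MASS::lda(sc, grouping = y, prior = c(0.5, 0.5))
  pref <- predict(ref, sc)$posterior[, "1"]
  expect_equal(pr$posterior, unname(pref), tolerance = 1e-6)
})

test_that("frozen models classify deterministically and check their manifest", {
  d <- planted_features(300, p = 990, informative = 15, shift = 1.2, seed = 12)
  model <- suppressWarnings(train_cima(d$features, d$labels, fast_cfg()))
  w1 <- classify_windows(d$features, model)
  w2 <- classify_windows(d$features, model)
  expect_identical(w1, w2)
  expect_true(all(abs((w1$posterior + (1 - w1$posterior)) - 1) < 1e-12))
  # manifest mismatch is caught and named
  bad <- d$features
  colnames(bad$features)[7] <- "g0007"
  expect_error(classify_windows(bad, model), "g0007")
})

test_that("held-out windows with a strong planted effect are ranked almost perfectly", {
  d <- planted_features(1200, p = 990, informative = 20, shift = 1.5, seed = 13)
  tr_vids <- sprintf("V%03d", 1:80)
  tr_rows <- d$features$meta$video_id %in% tr_vids
  train <- list(features = d$features$features[tr_rows, ],
                meta = d$features$meta[tr_rows, ])
  test <- list(features = d$features$features[!tr_rows, ],
               meta = d$features$meta[!tr_rows, ])
  model <- suppressWarnings(
    train_cima(train, d$labels[d$labels$video_id %in% tr_vids, ], fast_cfg()))
  w <- classify_windows(test, model)
  y_te <- d$y[!tr_rows]
  expect_gte(cima:::auc_rank(w$posterior, y_te), 0.9)
})
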