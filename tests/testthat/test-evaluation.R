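mk_windows <- function(labels, scores = NULL, video_id = "V1") {
  data.frame(video_id = video_id, window_index = seq_along(labels),
             label = labels,
             posterior = ifelse(labels == 1, 0.9, 0.1),
             lda_score = scores %||% ifelse(labels == 1, 2, -2))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("video aggregation computes proportions, ties classify positive", {
  expect_error(aggregate_videos(data.frame(video_id = character(0),
                                           label = integer(0),
                                           lda_score = numeric(0))), "empty")
  a1 <- aggregate_video(mk_windows(rep(1L, 60)))
  expect_equal(a1$proportion, 1)
  expect_equal(a1$decision, 1L)
  a2 <- aggregate_video(mk_windows(rep(c(1L, 0L), 30)))
  expect_equal(a2$proportion, 0.5)
  expect_equal(a2$decision, 1L) # >= rule at the 50% boundary
  a3 <- aggregate_video(mk_windows(c(rep(1L, 29), rep(0L, 31))))
  expect_equal(a3$decision, 0L)
})

test_that("score weighting reduces ambiguous windows but preserves equal-weight identity", {
  w_eq <- mk_windows(rep(c(1L, 0L), 10), scores = rep(c(3, -3), 10))
  expect_equal(aggregate_video(w_eq, weighted = TRUE)$proportion,
               aggregate_video(w_eq, weighted = FALSE)$proportion)
  # confident negatives outweigh borderline positives
  w <- mk_windows(rep(c(1L, 0L), 10), scores = rep(c(0.1, -5), 10))
  expect_lt(aggregate_video(w, weighted = TRUE)$proportion, 0.5)
})

test_that("confusion metrics reproduce exact binomial intervals and edge cases", {
  cm <- confusion_metrics(10, 0, 10, 0)
  expect_true(all(cm$value[cm$metric %in% c("sensitivity", "specificity", "ppv", "npv")] == 100))
  # Clopper-Pearson against the independent exact binomial test oracle
  cm2 <- confusion_metrics(38, 62, 274, 3)
  sens <- cm2[cm2$metric == "sensitivity", ]
  oracle <- binom.test(38, 41)$conf.int * 100
  expect_lt(abs(sens$lo - oracle[1]), 0.1)
  expect_lt(abs(sens$hi - oracle[2]), 0.1)
  # undefined PPV is absent, not fabricated
  cm3 <- confusion_metrics(0, 0, 10, 5)
  expect_true(is.na(cm3$value[cm3$metric == "ppv"]))
  expect_error(confusion_metrics(0, 5, 10, 0), "positives")
  expect_error(confusion_metrics(-1, 5, 10, 2), "non-negative")
})

test_that("sensitivity/specificity complement their error rates exactly", {
  cm <- confusion_metrics(7, 13, 55, 2)
  v <- setNames(cm$value, cm$metric)
  expect_equal(v[["sensitivity"]] + v[["fnr"]], 100, tolerance = 1e-13)
  expect_equal(v[["specificity"]] + v[["fpr"]], 100, tolerance = 1e-13)
})

test_that("trapezoidal AUC equals the rank formulation and reference results", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), n_boot = 0)$auc, 1)
  set.seed(5)
  for (i in 1:20) {
    n <- 50
    sc <- round(runif(n), 2) # duplicates force tie handling
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- roc_auc(sc, y, n_boot = 0)
    u <- unname(wilcox.test(sc[y == 1], sc[y == 0], exact = FALSE)$statistic)
    expect_equal(r$auc, u / (sum(y == 1) * sum(y == 0)), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(6)
  sc <- runif(100)
  y <- rbinom(100, 1, 0.5)
  r <- roc_auc(sc, y, n_boot = 0)
  expect_equal(r$auc,
               as.numeric(suppressMessages(pROC::auc(y, sc, direction = "<"))),
               tolerance = 1e-12)
})

test_that("labels independent of the scores give a chance-level AUC", {
  set.seed(7)
  sc <- runif(400)
  y <- rbinom(400, 1, 0.5)
  r <- roc_auc(sc, y, n_boot = 500, seed = 1)
  expect_gt(r$auc, 0.45)
  expect_lt(r$auc, 0.55)
  expect_true(r$ci[1] < r$auc & r$auc < r$ci[2])
  expect_error(roc_auc(sc, rep(1, 400)), "both classes")
})

test_that("raising the video threshold never increases the positive count", {
  set.seed(8)
  prop <- runif(200)
  pos <- vapply(seq(0, 1, by = 0.05), function(th) sum(prop >= th), numeric(1))
  expect_true(all(diff(pos) <= 0))
  # proportion conservation at the 50% threshold
  win <- do.call(rbind, lapply(1:30, function(v) {
    mk_windows(rbinom(10, 1, runif(1)), video_id = sprintf("V%02d", v))
  }))
  agg <- aggregate_videos(win, threshold = 0.5)
  expect_equal(sum(agg$decision), sum(agg$proportion >= 0.5))
})

test_that("rank-based group tests match enumeration and Bonferroni arithmetic", {
  # no-effect case
  gt0 <- group_tests(c(1:8, 1:8), rep(c("a", "b"), each = 8))
  expect_gt(gt0$pairwise$p[1], 0.9)
  # exact two-sided rank-sum p for {1..5} vs {6..10}: full enumeration oracle
  vals <- c(1:5, 6:10)
  grp <- rep(c("lo", "hi"), each = 5)
  gt <- group_tests(vals, grp)
  combos <- combn(10, 5)
  stat <- colSums(matrix(vals[combos], nrow = 5)) # rank sums of group 1
  obs <- sum(1:5)
  p_enum <- mean(stat <= obs | stat >= sum(6:10)) * 1 # two-sided by symmetry
  p_enum2 <- 2 * mean(stat <= obs)
  expect_equal(gt$pairwise$p[1], p_enum2, tolerance = 1e-12)
  expect_equal(round(gt$pairwise$p[1], 4), 0.0079)
  # three groups: Bonferroni multiplies raw p by 3, capped at 1
  set.seed(9)
  v3 <- c(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  g3 <- rep(c("a", "b", "c"), each = 10)
  gt3 <- group_tests(v3, g3)
  expect_equal(nrow(gt3$pairwise), 3L)
  expect_equal(gt3$pairwise$p_bonferroni, pmin(1, gt3$pairwise$p * 3))
  expect_lt(gt3$kruskal$p, 0.05)
  # tiny group excluded with warning
  expect_warning(group_tests(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "excluding")
  # summary carries medians and IQR bounds
  expect_equal(gt3$summary$n, rep(10L, 3))
})

test_that("the center-of-motion baseline is translation-invariant with closed-form values", {
  # motionless recording
  M <- matrix(rep(cima:::BODY_LAYOUT, each = 200), 200, 12)
  colnames(M) <- cima:::CHANNEL_NAMES
  tr0 <- trajectory_set(M, fps = 30, video_id = "STILL")
  expect_equal(csd_baseline(tr0, normalize = FALSE)$c_sd, 0)
  # rigid circular translation of radius r: per-axis sd = r/sqrt(2)
  r <- 7
  n <- 3000
  th <- 2 * pi * (0:(n - 1)) / n
  Mc <- matrix(rep(cima:::BODY_LAYOUT, each = n), n, 12)
  Mc[, seq(1, 11, 2)] <- Mc[, seq(1, 11, 2)] + r * cos(th)
  Mc[, seq(2, 12, 2)] <- Mc[, seq(2, 12, 2)] + r * sin(th)
  colnames(Mc) <- cima:::CHANNEL_NAMES
  trc <- trajectory_set(Mc, fps = 30)
  expect_equal(csd_baseline(trc, normalize = FALSE)$c_sd, r / sqrt(2),
               tolerance = 1e-3)
  # adding a constant offset changes nothing
  tr_off <- trajectory_set(Mc + 100, fps = 30)
  expect_equal(csd_baseline(tr_off, normalize = FALSE)$c_sd,
               csd_baseline(trc, normalize = FALSE)$c_sd, tolerance = 1e-12)
  # normalization divides by the mean head-trunk distance (80 px here)
  expect_equal(csd_baseline(trc, normalize = TRUE)$c_sd,
               (r / sqrt(2)) / 80, tolerance = 1e-3)
})
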