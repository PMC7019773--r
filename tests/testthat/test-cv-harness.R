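test_that("folds group subjects, stratify CP status, and are reproducible", {
  coh <- simulate_cohort(377, cp_fraction = 0.11, seed = 7, duration_s = 60)
  lab <- coh$labels
  # force exactly the study's class split for the allocation check
  lab$cp_status <- 0L
  lab$cp_status[1:41] <- 1L
  cfg <- cv_config(outer_folds = 10, seed = 3)
  f <- make_folds(lab, cfg)
  expect_equal(sort(unique(f$fold)), 1:10)
  expect_false(any(duplicated(f$subject_id)))
  per_fold_cp <- vapply(1:10, function(k) {
    sum(lab$cp_status[lab$subject_id %in% f$subject_id[f$fold == k]])
  }, numeric(1))
  expect_true(all(per_fold_cp >= 3 & per_fold_cp <= 6))
  expect_identical(f, make_folds(lab, cfg))
  # too few CP subjects for the requested folds
  lab2 <- lab
  lab2$cp_status <- 0L
  lab2$cp_status[1:4] <- 1L
  expect_error(make_folds(lab2, cfg), "reduce outer_folds")
})

test_that("subjects with several videos stay in one fold", {
  lab <- data.frame(video_id = sprintf("V%02d", 1:40),
                    subject_id = sprintf("S%02d", rep(1:20, each = 2)),
                    cp_status = rep(c(1L, 1L, 0L, 0L, 0L), 8))
  f <- make_folds(lab, cv_config(outer_folds = 4, seed = 1))
  expect_equal(nrow(f), 20L)
  merged <- merge(lab, f)
  folds_per_subject <- tapply(merged$fold, merged$subject_id,
                              function(x) length(unique(x)))
  expect_true(all(folds_per_subject == 1))
})

test_that("double CV produces one out-of-fold prediction per video, reproducibly", {
  d <- planted_features(600, p = 200, informative = 10, shift = 1.2,
                        windows_per_video = 10, seed = 20, balance = 0.3)
  cv1 <- run_double_cv(d$features, d$labels,
                       cv_config(outer_folds = 5, inner_folds = 3, seed = 4,
                                 refit_final = FALSE),
                       cima_cfg(drop_frac = 0.5, min_features = 10,
                                inner_folds = 3, seed = 1))
  expect_equal(sort(cv1$videos$video_id), sort(d$labels$video_id))
  expect_false(any(duplicated(cv1$videos$video_id)))
  cv2 <- run_double_cv(d$features, d$labels,
                       cv_config(outer_folds = 5, inner_folds = 3, seed = 4,
                                 refit_final = FALSE),
                       cima_cfg(drop_frac = 0.5, min_features = 10,
                                inner_folds = 3, seed = 1))
  expect_identical(cv1$videos, cv2$videos)
  expect_identical(cv1$folds, cv2$folds)
  # a separable design is recovered out of fold
  expect_gt(cv1$auc$auc, 0.9)
  # missing features are reported by id
  expect_error(
    run_double_cv(list(features = d$features$features[-(1:10), ],
                       meta = d$features$meta[-(1:10), ]),
                  d$labels, cv_config(outer_folds = 5, seed = 4)),
    "V001")
})

test_that("outer-test windows never influence the fold model (leakage guard)", {
  d <- planted_features(400, p = 150, informative = 8, shift = 1.2,
                        windows_per_video = 10, seed = 21, balance = 0.3)
  cvc <- cv_config(outer_folds = 4, inner_folds = 3, seed = 5, refit_final = FALSE)
  mcfg <- cima_cfg(drop_frac = 0.5, min_features = 10, inner_folds = 3, seed = 2)
  cv1 <- run_double_cv(d$features, d$labels, cvc, mcfg)
  # corrupt every window of the videos in outer fold 1, retrain
  folds <- make_folds(d$labels, cvc)
  fold1_subj <- folds$subject_id[folds$fold == 1]
  fold1_vids <- d$labels$video_id[d$labels$subject_id %in% fold1_subj]
  corrupted <- d$features
  rows <- corrupted$meta$video_id %in% fold1_vids
  set.seed(99)
  corrupted$features[rows, ] <- corrupted$features[rows, ] * 100 +
    rnorm(sum(rows) * ncol(corrupted$features))
  cv2 <- run_double_cv(corrupted, d$labels, cvc, mcfg)
  # the fold-1 model was trained without those videos: identical parameters
  expect_identical(cv2$fold_models[[1]]$selected, cv1$fold_models[[1]]$selected)
  expect_equal(cv2$fold_models[[1]]$lda$means, cv1$fold_models[[1]]$lda$means,
               tolerance = 1e-12)
  expect_equal(cv2$fold_models[[1]]$mu, cv1$fold_models[[1]]$mu,
               tolerance = 1e-12)
  # (fold-1 videos are training data for the other folds, so their models
  # legitimately change; the guard is that fold 1's own model does not)
})

test_that("an information-free cohort degenerates to majority-class decisions", {
  n_videos <- 30
  X <- matrix(2, nrow = n_videos * 5, ncol = 50)
  colnames(X) <- sprintf("f%04d", 1:50)
  feats <- list(features = X,
                meta = data.frame(video_id = rep(sprintf("V%02d", 1:n_videos), each = 5),
                                  window_index = rep(1:5, n_videos)))
  labels <- data.frame(video_id = sprintf("V%02d", 1:n_videos),
                       subject_id = sprintf("S%02d", 1:n_videos),
                       cp_status = rep(c(1L, 0L, 0L), 10))
  cv <- run_double_cv(feats, labels,
                      cv_config(outer_folds = 3, inner_folds = 2, seed = 1,
                                refit_final = FALSE),
                      cima_cfg(inner_folds = 2, seed = 1))
  expect_true(all(cv$folds$degenerate))
  expect_true(cv$zero_variance_any)
  # majority class is non-CP in every training split
  expect_true(all(cv$videos$decision == 0))
})
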