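# Double (nested) cross-validation with strict subject-level grouping:
# feature selection and all model parameters are learned inside each outer
# training set; outer-test videos only ever meet a frozen model.

#' Cross-validation configuration
#'
#' @param outer_folds number of outer test folds.
#' @param inner_folds folds of the inner CV that drives backward selection.
#' @param seed RNG seed for fold assignment.
#' @param refit_final refit a deployable model on all data afterwards, with
#'   the backward elimination targeting the modal outer-fold feature count.
#' @export
cv_config <- function(outer_folds = 10, inner_folds = 5, seed = 1,
                      refit_final = TRUE) {
  stopifnot(outer_folds >= 2, inner_folds >= 2)
  list(outer_folds = as.integer(outer_folds),
       inner_folds = as.integer(inner_folds),
       seed = as.integer(seed), refit_final = isTRUE(refit_final))
}

#' Subject-grouped, outcome-stratified outer folds
#'
#' Every subject (all of their videos) lands in exactly one outer test fold;
#' subjects are stratified by CP status so each fold carries its share of CP
#' cases. Deterministic given the seed.
#'
#' @param labels label table with `subject_id`, `cp_status` per video.
#' @param cfg a [cv_config()].
#' @return data.frame `subject_id`, `fold`.
#' @export
make_folds <- function(labels, cfg = cv_config()) {
  u <- !duplicated(labels$subject_id)
  subj <- labels$subject_id[u]
  # subject-level status: CP if any of the subject's videos is CP
  status <- vapply(subj, function(s) max(labels$cp_status[labels$subject_id == s]),
                   numeric(1))
  n_cp <- sum(status == 1)
  if (n_cp < cfg$outer_folds) {
    stop_cima("make_folds: only %d CP subjects for %d folds; reduce outer_folds",
              n_cp, cfg$outer_folds)
  }
  fold <- grouped_folds(status, subj, cfg$outer_folds, cfg$seed)
  data.frame(subject_id = subj, fold = fold, stringsAsFactors = FALSE)
}

#' Double cross-validation of the full assessment pipeline
#'
#' For each outer fold, a model is trained on the outer-training subjects
#' ([train_cima()]: standardization, backward PLS selection driven by the
#' inner CV, LDA), then frozen and applied to the outer-test windows; window
#' labels are aggregated into each test video's proportion of risk periods.
#' Pooled out-of-fold predictions (exactly one per video) are scored with
#' the evaluation module.
#'
#' @param features bound feature table covering every labeled video.
#' @param labels label table (`video_id`, `subject_id`, `cp_status`).
#' @param cfg a [cv_config()].
#' @param model_cfg a [cima_cfg()]; its seed is offset per fold.
#' @param n_boot bootstrap replicates for the pooled AUC interval (0 skips).
#' @return object of class `cv_report`: `videos` (per-video out-of-fold
#'   proportion, decision, truth, fold), `folds` (per-fold selected feature
#'   count and inner AUC), `metrics` (pooled confusion metrics), `auc`
#'   (pooled [roc_auc()]), `zero_variance_any` flag, and optionally
#'   `final_model`.
#' @export
run_double_cv <- function(features, labels, cfg = cv_config(),
                          model_cfg = cima_cfg(), n_boot = 0) {
  if (inherits(features, "window_features")) features <- bind_features(list(features))
  have <- unique(features$meta$video_id)
  missing_vids <- setdiff(labels$video_id, have)
  if (length(missing_vids)) {
    stop_cima("run_double_cv: no features for video(s): %s",
              paste(missing_vids, collapse = ", "))
  }
  folds <- make_folds(labels, cfg)
  fold_of_video <- folds$fold[match(labels$subject_id, folds$subject_id)]
  video_rows <- lapply(seq_len(cfg$outer_folds), function(f) {
    test_videos <- labels$video_id[fold_of_video == f]
    train_videos <- labels$video_id[fold_of_video != f]
    tr_rows <- features$meta$video_id %in% train_videos
    te_rows <- features$meta$video_id %in% test_videos
    tr <- list(features = features$features[tr_rows, , drop = FALSE],
               meta = features$meta[tr_rows, , drop = FALSE])
    te <- list(features = features$features[te_rows, , drop = FALSE],
               meta = features$meta[te_rows, , drop = FALSE])
    mcfg <- model_cfg
    mcfg$inner_folds <- cfg$inner_folds
    mcfg$seed <- model_cfg$seed + f
    model <- suppressWarnings(train_cima(tr, labels[labels$video_id %in% train_videos, ], mcfg))
    win <- classify_windows(te, model)
    agg <- aggregate_videos(win, threshold = model$video_threshold)
    agg$fold <- f
    list(videos = agg,
         fold_summary = data.frame(
           fold = f,
           n_selected = length(model$selected),
           inner_auc = if (model$degenerate) NA_real_ else model$inner_auc,
           degenerate = model$degenerate,
           zero_variance = length(model$zero_variance %||% integer(0)) > 0
         ),
         model = model)
  })
  videos <- do.call(rbind, lapply(video_rows, `[[`, "videos"))
  fold_summary <- do.call(rbind, lapply(video_rows, `[[`, "fold_summary"))
  videos$cp_status <- labels$cp_status[match(videos$video_id, labels$video_id)]
  stopifnot(!anyNA(videos$cp_status), nrow(videos) == nrow(labels))
  tp <- sum(videos$decision == 1 & videos$cp_status == 1)
  fp <- sum(videos$decision == 1 & videos$cp_status == 0)
  tn <- sum(videos$decision == 0 & videos$cp_status == 0)
  fn <- sum(videos$decision == 0 & videos$cp_status == 1)
  metrics <- confusion_metrics(tp, fp, tn, fn)
  auc <- if (length(unique(videos$cp_status)) == 2L) {
    roc_auc(videos$proportion, videos$cp_status, n_boot = n_boot,
            seed = cfg$seed)
  } else NULL
  final_model <- NULL
  if (cfg$refit_final) {
    n_sel <- fold_summary$n_selected[!fold_summary$degenerate]
    target <- if (length(n_sel)) {
      as.integer(names(sort(table(n_sel), decreasing = TRUE))[1L])
    } else NA_integer_
    mcfg <- model_cfg
    mcfg$inner_folds <- cfg$inner_folds
    final_model <- suppressWarnings(
      train_cima_fixed_size(features, labels, mcfg, target))
  }
  structure(list(videos = videos, folds = fold_summary, metrics = metrics,
                 auc = auc, fold_models = lapply(video_rows, `[[`, "model"),
                 zero_variance_any = any(fold_summary$zero_variance),
                 final_model = final_model, cfg = cfg),
            class = "cv_report")
}

# Deployment refit: run the same backward elimination on all data but pick
# the iterate whose feature count is closest to the modal outer-fold count
# (standard double-CV deployment convention).
train_cima_fixed_size <- function(features, labels, cfg, target_n) {
  model <- train_cima(features, labels, cfg)
  if (model$degenerate || is.na(target_n)) return(model)
  X <- features$features
  idx <- match(features$meta$video_id, labels$video_id)
  y <- labels$cp_status[idx]
  sel <- fit_pls_backward(X, y, cfg, groups = labels$subject_id[idx])
  pick <- which.min(abs(sel$trace$n_features - target_n))
  # rebuild the chosen iterate by replaying the elimination
  if (sel$trace$n_features[pick] != length(sel$selected)) {
    keep <- setdiff(seq_len(ncol(X)), sel$zero_variance)
    Xs <- sweep(sweep(X, 2L, sel$mu), 2L, sel$sigma, "/")
    active <- replay_vip_path(Xs, y - mean(y), keep, cfg,
                              sel$trace$n_features[pick])
    pls <- pls1_fit(Xs[, active, drop = FALSE], y - mean(y), cfg$ncomp)
    sc <- composite_scores(Xs[, active, drop = FALSE], pls)
    lda <- fit_lda(sc, y, priors = cfg$priors)
    model$selected <- active
    model$pls <- pls[c("W", "P", "q", "R", "ncomp", "ncomp_used")]
    model$lda <- lda
    model$inner_auc <- sel$trace$inner_auc[pick]
  }
  model
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d videos, %d outer folds\n",
              nrow(x$videos), nrow(x$folds)))
  print(x$metrics)
  if (!is.null(x$auc)) cat(sprintf("pooled AUC %.3f\n", x$auc$auc))
  invisible(x)
}
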