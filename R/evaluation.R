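# Video-level aggregation, diagnostic accuracy statistics, rank-based group
# comparisons, and the spatial center-of-motion baseline.

#' Aggregate window labels into per-video risk proportions
#'
#' The proportion of 5-s windows labeled as containing CP risk-related
#' movements; the video decision is positive when the proportion reaches the
#' threshold (ties at exactly the threshold classify positive). The weighted
#' variant uses the absolute discriminant score of each window as its
#' weight, reducing the influence of ambiguous windows.
#'
#' @param windows data.frame from [classify_windows()] (columns `video_id`,
#'   `label`, `lda_score`).
#' @param threshold video decision threshold on the proportion (0.5).
#' @param weighted use `|lda_score|`-weighted mean of labels.
#' @return data.frame `video_id`, `n_windows`, `proportion`, `decision`.
#' @export
aggregate_videos <- function(windows, threshold = 0.5, weighted = FALSE) {
  if (nrow(windows) == 0L) stop_cima("aggregate_videos: empty window set")
  sp <- split(windows, windows$video_id)
  out <- do.call(rbind, lapply(sp, function(w) {
    prop <- if (weighted) {
      wt <- abs(w$lda_score)
      if (sum(wt) > 0) sum(wt * w$label) / sum(wt) else mean(w$label)
    } else mean(w$label)
    data.frame(video_id = w$video_id[1L], n_windows = nrow(w),
               proportion = prop, decision = as.integer(prop >= threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname aggregate_videos
#' @export
aggregate_video <- function(windows, threshold = 0.5, weighted = FALSE) {
  out <- aggregate_videos(windows, threshold, weighted)
  if (nrow(out) != 1L) stop_cima("aggregate_video: windows from %d videos", nrow(out))
  out
}

#' Diagnostic accuracy from a 2x2 confusion table
#'
#' Sensitivity, specificity, positive and negative predictive values, false
#' negative/positive rates, accuracy and prevalence, each in percent with
#' 95% Clopper-Pearson (exact binomial) confidence intervals. PPV is absent
#' (`NA`) when there are no positive calls.
#'
#' @param tp,fp,tn,fn non-negative integer confusion counts; `tp + fn > 0`
#'   and `tn + fp > 0`.
#' @param conf_level confidence level for the intervals.
#' @return object of class `confusion_metrics`: data.frame with `metric`,
#'   `value`, `lo`, `hi` (percent) plus the counts as attributes.
#' @export
confusion_metrics <- function(tp, fp, tn, fn, conf_level = 0.95) {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_cima("confusion_metrics: counts must be non-negative integers")
  }
  if (tp + fn == 0) stop_cima("confusion_metrics: no positives (tp + fn = 0)")
  if (tn + fp == 0) stop_cima("confusion_metrics: no negatives (tn + fp = 0)")
  n <- tp + fp + tn + fn
  row <- function(metric, x, m) {
    if (m == 0) {
      return(data.frame(metric = metric, value = NA_real_, lo = NA_real_,
                        hi = NA_real_))
    }
    ci <- clopper_pearson(x, m, conf_level)
    data.frame(metric = metric, value = 100 * x / m,
               lo = 100 * ci[1L], hi = 100 * ci[2L])
  }
  out <- rbind(
    row("sensitivity", tp, tp + fn),
    row("specificity", tn, tn + fp),
    row("ppv", tp, tp + fp),
    row("npv", tn, tn + fn),
    row("fnr", fn, tp + fn),
    row("fpr", fp, tn + fp),
    row("accuracy", tp + tn, n),
    row("prevalence", tp + fn, n)
  )
  structure(out, class = c("confusion_metrics", "data.frame"), counts = cnt)
}

# Exact (Clopper-Pearson) binomial interval via beta quantiles.
clopper_pearson <- function(x, n, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n",
              cnt["tp"], cnt["fp"], cnt["tn"], cnt["fn"]))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$value[i])) {
      cat(sprintf("  %-11s --\n", x$metric[i]))
    } else {
      cat(sprintf("  %-11s %5.1f%% [%.1f, %.1f]\n", x$metric[i], x$value[i],
                  x$lo[i], x$hi[i]))
    }
  }
  invisible(x)
}

#' ROC curve and AUC of per-video risk proportions
#'
#' Sweeps the decision threshold over all distinct score values, computes
#' the ROC curve, and the area under it by the trapezoidal rule (with ties
#' this equals the rank / Mann-Whitney formulation). The confidence interval
#' is a stratified percentile bootstrap over videos.
#'
#' @param scores per-video proportions (or any risk score).
#' @param labels 0/1 video outcomes; both classes must be present.
#' @param n_boot bootstrap replicates (0 skips the interval).
#' @param conf_level confidence level.
#' @param seed seed for the bootstrap.
#' @return list with `auc`, `ci`, `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000, conf_level = 0.95, seed = 1) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_cima("roc_auc: both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    i1 <- which(labels == 1L)
    i0 <- which(labels == 0L)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      s1 <- scores[sample(i1, n1, replace = TRUE)]
      s0 <- scores[sample(i0, n0, replace = TRUE)]
      auc_rank(c(s1, s0), c(rep(1L, n1), rep(0L, n0)))
    }, numeric(1)))
    a <- (1 - conf_level) / 2
    ci <- unname(quantile(boots, c(a, 1 - a), na.rm = TRUE))
  }
  list(auc = auc, ci = ci,
       curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       n_pos = n1, n_neg = n0, n_boot = n_boot)
}

#' Rank-based comparison of risk proportions across groups
#'
#' Kruskal-Wallis test across all groups followed by pairwise two-sided
#' Wilcoxon rank-sum tests (exact enumeration when both groups have at most
#' 20 untied observations, normal approximation with tie correction
#' otherwise) with Bonferroni correction (raw p times the number of pairs,
#' capped at 1). Groups with fewer than 2 members are excluded with a
#' warning.
#'
#' @param values numeric per-video proportions.
#' @param groups group membership (factor or character).
#' @return list with `kruskal` (statistic, df, p), `pairwise` (data.frame
#'   `group1`, `group2`, `statistic`, `p`, `p_bonferroni`), `summary`
#'   (per-group n, median, IQR bounds).
#' @export
group_tests <- function(values, groups) {
  groups <- as.character(groups)
  keep_groups <- names(which(table(groups) >= 2L))
  dropped <- setdiff(unique(groups), keep_groups)
  if (length(dropped)) {
    warning(sprintf("group_tests: excluding group(s) with < 2 members: %s",
                    paste(dropped, collapse = ", ")))
  }
  sel <- groups %in% keep_groups
  values <- values[sel]
  groups <- factor(groups[sel])
  if (nlevels(groups) < 2L) stop_cima("group_tests: need >= 2 groups with >= 2 members")
  kw <- kruskal.test(values, groups)
  pairs <- combn(levels(groups), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    x <- values[groups == pairs[1L, k]]
    y <- values[groups == pairs[2L, k]]
    use_exact <- length(x) <= 20L && length(y) <= 20L &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = use_exact, correct = !use_exact))
    data.frame(group1 = pairs[1L, k], group2 = pairs[2L, k],
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$p_bonferroni <- p.adjust(pw$p, method = "bonferroni")
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = q[2L], q1 = q[1L], q3 = q[3L],
               stringsAsFactors = FALSE)
  }))
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw, summary = summ)
}

#' Spatial center-of-motion variability baseline
#'
#' Single-feature baseline from earlier automated movement assessment work,
#' adapted to tracked trajectories: the center of motion of each frame is
#' the mean of the six body-part positions; its variability is the mean of
#' the standard deviations over time of the center's x and y series
#' (pixels), optionally divided by the mean head-trunk distance to remove
#' body-size/zoom scale.
#'
#' @param traj a [trajectory_set()].
#' @param normalize divide by mean head-trunk distance (default).
#' @return data.frame `video_id`, `c_sd`.
#' @export
csd_baseline <- function(traj, normalize = TRUE) {
  stopifnot(inherits(traj, "cima_trajectory"))
  X <- traj$channels
  xi <- seq(1L, 11L, by = 2L)
  cx <- rowMeans(X[, xi, drop = FALSE])
  cy <- rowMeans(X[, xi + 1L, drop = FALSE])
  c_sd <- (sd(cx) + sd(cy)) / 2
  if (normalize) {
    d <- sqrt((X[, "head_x"] - X[, "trunk_x"])^2 +
              (X[, "head_y"] - X[, "trunk_y"])^2)
    md <- mean(d)
    if (md <= .Machine$double.eps) {
      warning("csd_baseline: zero head-trunk distance; skipping normalization")
    } else {
      c_sd <- c_sd / md
    }
  }
  data.frame(video_id = traj$video_id, c_sd = c_sd, stringsAsFactors = FALSE)
}
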