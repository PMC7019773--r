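# Window-level CP-risk classifier: standardization -> PLS1 (5 latent
# components) with VIP-ranked backward feature elimination tracked by
# inner-validation AUC -> composite scores -> Gaussian linear discriminant.

#' Model configuration
#'
#' @param ncomp number of PLS components / composite scores (5).
#' @param drop_frac fraction of remaining features dropped per backward
#'   elimination step (lowest VIP first).
#' @param min_features stop eliminating below this many features.
#' @param inner_folds folds for the inner-validation AUC that drives the
#'   choice of feature set (grouped by subject when grouping is available).
#' @param priors `"equal"` (default, counters the ~10:1 window class
#'   imbalance) or `"empirical"` LDA class priors.
#' @param window_threshold posterior threshold labelling a 5-s window as
#'   containing CP risk-related movements.
#' @param video_threshold proportion threshold for the per-video decision.
#' @param seed RNG seed for fold assignment.
#' @export
cima_cfg <- function(ncomp = 5, drop_frac = 0.2, min_features = 10,
                     inner_folds = 5, priors = c("equal", "empirical"),
                     window_threshold = 0.5, video_threshold = 0.5, seed = 1) {
  priors <- match.arg(priors)
  stopifnot(ncomp >= 1, drop_frac > 0, drop_frac < 1, inner_folds >= 2,
            window_threshold >= 0, window_threshold <= 1,
            video_threshold >= 0, video_threshold <= 1)
  list(ncomp = as.integer(ncomp), drop_frac = drop_frac,
       min_features = as.integer(min_features),
       inner_folds = as.integer(inner_folds), priors = priors,
       window_threshold = window_threshold, video_threshold = video_threshold,
       seed = as.integer(seed))
}

# PLS1 regression by NIPALS on an already standardized X and centered y.
# Returns unit weight vectors W, loadings P, inner coefficients q, rotation
# R = W (P'W)^-1, regression coefficients, and per-component explained
# y-variation (for VIP).
pls1_fit <- function(X, y, ncomp = 5L) {
  n <- nrow(X)
  p <- ncol(X)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  ssy <- numeric(ncomp)
  Xd <- X
  yd <- y
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pv <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pv)
    yd <- yd - qa * t
    W[, a] <- w
    P[, a] <- pv
    q[a] <- qa
    ssy[a] <- qa^2 * tt
    a_used <- a
  }
  if (a_used == 0L) stop_cima("pls1_fit: X carries no covariance with y")
  Wu <- W[, seq_len(a_used), drop = FALSE]
  Pu <- P[, seq_len(a_used), drop = FALSE]
  Ru <- Wu %*% solve(crossprod(Pu, Wu))
  R <- matrix(0, p, ncomp)
  R[, seq_len(a_used)] <- Ru
  coef <- Ru %*% q[seq_len(a_used)]
  list(W = W, P = P, q = q, R = R, coef = coef, ncomp = ncomp,
       ncomp_used = a_used, ssy = ssy)
}

# Variable importance in projection for a PLS1 fit.
pls_vip <- function(fit) {
  a <- seq_len(fit$ncomp_used)
  ss <- fit$ssy[a]
  W2 <- fit$W[, a, drop = FALSE]^2
  sqrt(nrow(W2) * as.vector(W2 %*% ss) / sum(ss))
}

# Rank-based AUC of score against binary y (Mann-Whitney formulation).
auc_rank <- function(score, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified, group-respecting fold assignment. `groups` maps each row to a
# grouping unit (subject/video); every unit lands in exactly one fold, units
# shuffled within outcome class and dealt round-robin.
grouped_folds <- function(y, groups, k, seed) {
  u <- !duplicated(groups)
  tab <- data.frame(group = groups[u], y = y[u])
  with_seed(seed, {
    fold_of <- setNames(integer(nrow(tab)), tab$group)
    offset <- 0L
    for (cls in unique(tab$y)) {
      g <- tab$group[tab$y == cls]
      g <- sample(g)
      fold_of[g] <- ((seq_along(g) + offset - 1L) %% k) + 1L
      offset <- offset + length(g)
    }
    unname(fold_of[groups])
  })
}

#' Backward feature selection around a PLS1 regression
#'
#' Standardizes the feature matrix (zero-variance columns are excluded with
#' a warning), fits a 5-component PLS1 regression of the window class
#' labels, and repeatedly drops the `drop_frac` fraction of remaining
#' features with the lowest VIP scores. At each set size the
#' inner-validation AUC (grouped cross-validation of the PLS prediction) is
#' recorded; the feature set with the best inner AUC wins, ties going to the
#' smaller set. Deterministic given data and `cfg$seed`.
#'
#' @param X windows x features numeric matrix (990 columns in production).
#' @param y per-window class labels 0/1 (inherited from the video CP
#'   status).
#' @param cfg a [cima_cfg()] list.
#' @param groups optional grouping vector (one entry per window, e.g.
#'   subject id) keeping a group's windows in one inner fold.
#' @return list with `selected` (column indices into `X`), `pls` (fit on the
#'   selected set), `mu`, `sigma` (standardization of all columns),
#'   `trace` (data.frame `n_features`, `inner_auc`), `zero_variance`
#'   (excluded columns), `inner_auc` (of the winning set).
#' @export
fit_pls_backward <- function(X, y, cfg = cima_cfg(), groups = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) {
    stop_cima("fit_pls_backward: window labels are single-class; need both classes")
  }
  if (min(table(y)) < 2L) stop_cima("fit_pls_backward: need >= 2 windows per class")
  mu <- colMeans(X)
  sigma <- apply(X, 2L, sd)
  zero_var <- which(sigma == 0)
  if (length(zero_var)) {
    warning(sprintf("fit_pls_backward: excluding %d zero-variance feature(s)",
                    length(zero_var)))
  }
  keep <- setdiff(seq_len(ncol(X)), zero_var)
  if (!length(keep)) stop_cima("fit_pls_backward: all features have zero variance")
  sigma_safe <- ifelse(sigma > 0, sigma, 1)
  Xs <- sweep(sweep(X, 2L, mu), 2L, sigma_safe, "/")
  yc <- y - mean(y)
  if (is.null(groups)) groups <- seq_along(y)
  folds <- grouped_folds(y, groups, cfg$inner_folds, cfg$seed)
  sizes <- elimination_schedule(length(keep), cfg$drop_frac,
                                max(cfg$min_features, cfg$ncomp + 1L))
  # Honest selection curve: the elimination path (VIP ranking) is replayed
  # inside every inner-training fold, so the validation windows never
  # influence the feature sets they score.
  pred <- matrix(NA_real_, length(y), length(sizes))
  for (f in seq_len(cfg$inner_folds)) {
    tr <- folds != f
    if (!any(!tr) || length(unique(y[tr])) < 2L) next
    yt <- y[tr] - mean(y[tr])
    active <- keep
    for (si in seq_along(sizes)) {
      fit_f <- pls1_fit(Xs[tr, active, drop = FALSE], yt, cfg$ncomp)
      pred[!tr, si] <- Xs[!tr, active, drop = FALSE] %*% fit_f$coef
      if (si < length(sizes)) {
        vip <- pls_vip(fit_f)
        active <- sort(active[order(vip, decreasing = TRUE)[seq_len(sizes[si + 1L])]])
      }
    }
  }
  trace_auc <- apply(pred, 2L, function(p) {
    ok <- !is.na(p)
    auc_rank(p[ok], y[ok])
  })
  best_auc <- max(trace_auc, na.rm = TRUE)
  cand <- which(trace_auc >= best_auc - 1e-12)
  best <- cand[which.max(cand)] # ties -> smallest set (sizes decrease)
  selected <- replay_vip_path(Xs, yc, keep, cfg, sizes[best])
  pls <- pls1_fit(Xs[, selected, drop = FALSE], yc, cfg$ncomp)
  list(selected = selected, pls = pls, mu = mu, sigma = sigma_safe,
       trace = data.frame(n_features = sizes, inner_auc = trace_auc),
       zero_variance = zero_var, inner_auc = trace_auc[best])
}

# Set sizes visited by the backward elimination: start at p, drop
# `drop_frac` of the remainder each step, stop before going below floor_n.
elimination_schedule <- function(p, drop_frac, floor_n) {
  sizes <- p
  repeat {
    cur <- sizes[length(sizes)]
    nxt <- cur - max(1L, floor(drop_frac * cur))
    if (nxt < floor_n) break
    sizes <- c(sizes, nxt)
  }
  sizes
}

# Deterministic VIP elimination on the full (standardized) data down to
# exactly `stop_at` features.
replay_vip_path <- function(Xs, yc, keep, cfg, stop_at) {
  active <- keep
  while (length(active) > stop_at) {
    n_drop <- max(1L, floor(cfg$drop_frac * length(active)))
    if (length(active) - n_drop < stop_at) n_drop <- length(active) - stop_at
    fit <- pls1_fit(Xs[, active, drop = FALSE], yc, cfg$ncomp)
    vip <- pls_vip(fit)
    active <- sort(active[order(vip, decreasing = TRUE)[seq_len(length(active) - n_drop)]])
  }
  active
}

#' Composite scores: projection onto the PLS latent directions
#'
#' The selected, standardized features of each window are reduced to the 5
#' latent-variable scores of the PLS fit (`T = X R`). Over the training set
#' the score columns are mutually orthogonal and have zero mean.
#'
#' @param X_selected standardized feature matrix restricted to the selected
#'   features (windows x p_selected).
#' @param pls a fit from [pls1_fit()] on those features.
#' @return windows x 5 score matrix.
#' @export
composite_scores <- function(X_selected, pls) {
  X_selected <- as.matrix(X_selected)
  if (ncol(X_selected) != nrow(pls$R)) {
    stop_cima("composite_scores: feature count %d does not match PLS fit (%d)",
              ncol(X_selected), nrow(pls$R))
  }
  X_selected %*% pls$R
}

#' Linear discriminant analysis of composite scores
#'
#' Gaussian discriminant with class means and a pooled covariance; priors
#' default to equal (countering the ~10:1 window class imbalance). A
#' singular pooled covariance is ridge-regularized with
#' `lambda = 1e-6 * trace / ncol` and a warning.
#'
#' @param scores windows x 5 composite score matrix.
#' @param y 0/1 window labels, at least 6 windows per class.
#' @param priors `"equal"`, `"empirical"`, or numeric length-2 (class 0, 1).
#' @return list with `means` (2 x ncomp; rows class 0, 1), `cov`, `priors`.
#' @export
fit_lda <- function(scores, y, priors = "equal") {
  scores <- as.matrix(scores)
  y <- as.integer(y)
  n0 <- sum(y == 0L)
  n1 <- sum(y == 1L)
  if (min(n0, n1) < max(6L, ncol(scores) + 1L)) {
    stop_cima("fit_lda: need at least %d windows per class (got %d / %d)",
              max(6L, ncol(scores) + 1L), n0, n1)
  }
  m0 <- colMeans(scores[y == 0L, , drop = FALSE])
  m1 <- colMeans(scores[y == 1L, , drop = FALSE])
  S0 <- stats::cov(scores[y == 0L, , drop = FALSE])
  S1 <- stats::cov(scores[y == 1L, , drop = FALSE])
  S <- ((n0 - 1) * S0 + (n1 - 1) * S1) / (n0 + n1 - 2)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || !is.finite(rcond_est(S)) || rcond_est(S) < 1e-12) {
    lam <- 1e-6 * sum(diag(S)) / ncol(S)
    if (lam <= 0) lam <- 1e-8
    warning("fit_lda: singular pooled covariance; ridge-regularized")
    S <- S + diag(lam, ncol(S))
  }
  pr <- if (identical(priors, "equal")) c(0.5, 0.5)
        else if (identical(priors, "empirical")) c(n0, n1) / (n0 + n1)
        else as.numeric(priors) / sum(priors)
  list(means = rbind(`0` = m0, `1` = m1), cov = S, priors = pr)
}

rcond_est <- function(S) {
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(e) <= 0) return(0)
  min(e) / max(e)
}

# Posterior of class 1 and the discriminant (log-odds) score.
lda_predict <- function(lda, scores) {
  scores <- as.matrix(scores)
  Sinv <- solve(lda$cov)
  d0 <- -0.5 * mahalanobis(scores, lda$means[1L, ], Sinv, inverted = TRUE) +
    log(lda$priors[1L])
  d1 <- -0.5 * mahalanobis(scores, lda$means[2L, ], Sinv, inverted = TRUE) +
    log(lda$priors[2L])
  list(posterior = 1 / (1 + exp(d0 - d1)), lda_score = d1 - d0)
}

#' Train the full window classifier
#'
#' Labels every 5-s window with its video's CP status, runs
#' [fit_pls_backward()] (inner folds grouped by subject), reduces the
#' selected features to composite scores and fits the discriminant. When no
#' feature carries any variance the model degenerates to a majority-class
#' classifier (flagged in the result).
#'
#' @param features a bound feature table (`list(features, meta)`, e.g. from
#'   [bind_features()] or [read_features()]) or a single `window_features`
#'   object.
#' @param labels label table with `video_id`, `subject_id`, `cp_status`.
#' @param cfg a [cima_cfg()].
#' @return object of class `cima_model` (serializable via [write_model()]).
#' @export
train_cima <- function(features, labels, cfg = cima_cfg()) {
  if (inherits(features, "window_features")) features <- bind_features(list(features))
  X <- features$features
  meta <- features$meta
  idx <- match(meta$video_id, labels$video_id)
  if (anyNA(idx)) {
    stop_cima("train_cima: no label for video(s): %s",
              paste(unique(meta$video_id[is.na(idx)]), collapse = ", "))
  }
  y <- labels$cp_status[idx]
  subj <- labels$subject_id[idx]
  fps <- attr(features, "fps") %||% NA_real_
  degenerate <- all(apply(X, 2L, sd) == 0)
  base <- list(
    format_version = MODEL_FORMAT_VERSION,
    fps = fps,
    feature_names = colnames(X) %||% sprintf("f%04d", seq_len(ncol(X))),
    window_threshold = cfg$window_threshold,
    video_threshold = cfg$video_threshold
  )
  if (degenerate) {
    warning("train_cima: all features have zero variance; majority-class model")
    model <- c(base, list(
      degenerate = TRUE, majority_class = as.integer(mean(y) >= 0.5),
      class_share = mean(y), selected = integer(0),
      mu = colMeans(X), sigma = rep(1, ncol(X)),
      pls = NULL, lda = NULL, zero_variance = seq_len(ncol(X))
    ))
    return(structure(model, class = "cima_model"))
  }
  sel <- fit_pls_backward(X, y, cfg, groups = subj)
  Xs <- sweep(sweep(X, 2L, sel$mu), 2L, sel$sigma, "/")
  sc <- composite_scores(Xs[, sel$selected, drop = FALSE], sel$pls)
  lda <- fit_lda(sc, y, priors = cfg$priors)
  model <- c(base, list(
    degenerate = FALSE, majority_class = NA_integer_, class_share = mean(y),
    selected = sel$selected, mu = sel$mu, sigma = sel$sigma,
    pls = sel$pls[c("W", "P", "q", "R", "ncomp", "ncomp_used")],
    lda = lda, zero_variance = sel$zero_variance,
    inner_auc = sel$inner_auc,
    trace = as.list(sel$trace)
  ))
  structure(model, class = "cima_model")
}

#' @export
print.cima_model <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<cima_model> degenerate majority-class model (class %d)\n",
                x$majority_class))
  } else {
    cat(sprintf("<cima_model> %d selected features, %d composite scores, inner AUC %.3f\n",
                length(x$selected), x$pls$ncomp, x$inner_auc))
  }
  invisible(x)
}

#' Classify 5-second windows with a frozen model
#'
#' Applies the frozen standardization, feature selection, PLS projection and
#' discriminant to a feature table whose manifest must match the model's
#' (first mismatching feature is named otherwise). Each window receives a
#' binary label (1 = CP risk-related movements present), the class-1
#' posterior, and the discriminant log-odds score.
#'
#' @param features feature table as in [train_cima()].
#' @param model a `cima_model`.
#' @return data.frame `video_id`, `window_index`, `label`, `posterior`,
#'   `lda_score`.
#' @export
classify_windows <- function(features, model) {
  stopifnot(inherits(model, "cima_model"))
  if (inherits(features, "window_features")) features <- bind_features(list(features))
  X <- features$features
  nm <- colnames(X) %||% sprintf("f%04d", seq_len(ncol(X)))
  if (!identical(nm, model$feature_names)) {
    k <- min(length(nm), length(model$feature_names))
    diff1 <- which(nm[seq_len(k)] != model$feature_names[seq_len(k)])
    bad <- if (length(diff1)) diff1[1L] else k + 1L
    stop_cima("classify_windows: feature manifest mismatch at column %d ('%s' vs model '%s')",
              bad,
              if (bad <= length(nm)) nm[bad] else "<missing>",
              if (bad <= length(model$feature_names)) model$feature_names[bad] else "<extra>")
  }
  meta <- features$meta
  if (model$degenerate) {
    post <- rep(model$class_share, nrow(X))
    return(data.frame(video_id = meta$video_id, window_index = meta$window_index,
                      label = rep(model$majority_class, nrow(X)),
                      posterior = post, lda_score = rep(0, nrow(X)),
                      stringsAsFactors = FALSE))
  }
  Xs <- sweep(sweep(X, 2L, model$mu), 2L, model$sigma, "/")
  sc <- Xs[, model$selected, drop = FALSE] %*% model$pls$R
  pr <- lda_predict(model$lda, sc)
  data.frame(video_id = meta$video_id, window_index = meta$window_index,
             label = as.integer(pr$posterior >= model$window_threshold),
             posterior = pr$posterior, lda_score = pr$lda_score,
             stringsAsFactors = FALSE)
}
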