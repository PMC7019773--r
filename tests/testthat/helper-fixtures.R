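# Shared fixtures. Heavy objects (the synthetic evaluation cohort and a
# model trained on it) are built lazily once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Trajectory whose 12 channels are given sinusoid mixtures (plus the static
# body layout offsets so the object validates).
tone_trajectory <- function(freqs, amps = rep(1, length(freqs)),
                            duration_s = 60, fps = 30, phases = NULL,
                            video_id = "TONE") {
  n <- duration_s * fps
  t <- (seq_len(n) - 1) / fps
  if (is.null(phases)) phases <- rep(0, length(freqs))
  x <- rowSums(mapply(function(f, a, ph) a * cos(2 * pi * f * t + ph),
                      freqs, amps, phases))
  M <- matrix(rep(x, 12), ncol = 12)
  colnames(M) <- cima:::CHANNEL_NAMES
  M <- sweep(M, 2, cima:::BODY_LAYOUT, "+")
  trajectory_set(M, fps = fps, video_id = video_id, subject_id = video_id)
}

# Smooth random multichannel trajectory (low-pass filtered noise).
random_trajectory <- function(n = 400, fps = 30, seed = 1, video_id = "RND") {
  set.seed(seed)
  M <- matrix(rnorm(n * 12), n, 12)
  for (c in 1:12) {
    M[, c] <- 10 * cima:::moving_average(M[, c], 7) +
      3 * cos(2 * pi * runif(1, 0.5, 3) * (seq_len(n) - 1) / fps)
  }
  colnames(M) <- cima:::CHANNEL_NAMES
  M <- sweep(M, 2, cima:::BODY_LAYOUT, "+")
  trajectory_set(M, fps = fps, video_id = video_id, subject_id = video_id)
}

# Feature-level synthetic design: `informative` columns get a mean shift of
# `shift` (in SD units) in class-1 windows; windows are grouped into videos
# of `windows_per_video`.
planted_features <- function(n_windows, p = 990, informative = 20,
                             shift = 1, windows_per_video = 10, seed = 1,
                             balance = 0.5) {
  set.seed(seed)
  n_videos <- ceiling(n_windows / windows_per_video)
  video_cp <- rbinom(n_videos, 1, balance)
  vid <- rep(seq_len(n_videos), each = windows_per_video)[seq_len(n_windows)]
  y <- video_cp[vid]
  X <- matrix(rnorm(n_windows * p), n_windows, p)
  inf_idx <- seq_len(informative)
  X[y == 1, inf_idx] <- X[y == 1, inf_idx] + shift
  colnames(X) <- sprintf("f%04d", seq_len(p))
  labels <- data.frame(video_id = sprintf("V%03d", seq_len(n_videos)),
                       subject_id = sprintf("S%03d", seq_len(n_videos)),
                       cp_status = video_cp, stringsAsFactors = FALSE)
  list(features = list(features = X,
                       meta = data.frame(video_id = sprintf("V%03d", vid),
                                         window_index = sequence(rle(vid)$lengths),
                                         stringsAsFactors = FALSE)),
       labels = labels, y = y, informative = inf_idx)
}

# Evaluation cohort: 200 one-minute videos, 15% CP at severity 0.9, and its
# extracted window features. Built once; used by the double-CV and
# severity-ordering checks.
cohort_features <- function(coh) {
  fl <- lapply(coh$trajectories, extract_features, n_dirs = 24)
  fb <- cima:::bind_features(fl)
  fb
}

get_eval_cohort <- function() {
  memo("eval_cohort", function() {
    coh <- simulate_cohort(200, cp_fraction = 0.15,
                           severity_dist = function(n) rep(0.9, n),
                           seed = 2024, duration_s = 60)
    list(labels = coh$labels, features = cohort_features(coh))
  })
}

# Fast model configuration for cohort-scale runs: coarser elimination
# schedule and 3 inner folds (problem-size choice, same algorithm).
fast_cfg <- function(seed = 1) {
  cima_cfg(drop_frac = 0.5, min_features = 20, inner_folds = 3, seed = seed)
}

fast_cv <- function(seed = 1) {
  cv_config(outer_folds = 10, inner_folds = 3, seed = seed, refit_final = FALSE)
}

# Model trained on the full evaluation cohort (used as a frozen classifier
# for severity/phenotype ordering checks).
get_trained_model <- function() {
  memo("trained_model", function() {
    co <- get_eval_cohort()
    suppressWarnings(train_cima(co$features, co$labels, fast_cfg(seed = 42)))
  })
}

# Proportion of risk windows for a fresh batch of videos under the frozen
# model; each trajectory gets a distinct video id.
model_proportions <- function(trajectories, model) {
  fl <- lapply(seq_along(trajectories), function(i) {
    wf <- extract_features(trajectories[[i]], n_dirs = 24)
    wf$meta$video_id <- sprintf("T%04d", i)
    wf
  })
  win <- classify_windows(cima:::bind_features(fl), model)
  aggregate_videos(win, threshold = model$video_threshold)
}
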