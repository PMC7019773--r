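# Synthetic infant-trajectory generator. Emulates the statistical structure
# the assessment pipeline assumes: 12 correlated oscillatory pixel channels
# with two movement phenotypes. "Typical" movements are complex and variable
# (several active frequency scales, continual stochastic frequency/amplitude
# modulation, moderate time-varying inter-channel correlation); "cp_risk"
# movements have fewer active scales, weak modulation and strong static
# cross-channel synchrony, with a continuous severity knob.

# Static body layout (pixels, image convention) used as channel baselines so
# head-trunk distance is defined for the center-of-motion baseline.
BODY_LAYOUT <- c(
  head_x = 160, head_y = 60, trunk_x = 160, trunk_y = 140,
  armL_x = 100, armL_y = 120, armR_x = 220, armR_y = 120,
  legL_x = 120, legL_y = 220, legR_x = 200, legR_y = 220
)

#' Simulation parameters for one synthetic trajectory
#'
#' @param phenotype `"typical"` (complex, variable, fidgety-like movements)
#'   or `"cp_risk"` (reduced-variability movements).
#' @param severity in `[0, 1]`; for `cp_risk` the fraction of the recording
#'   spent in risk-phenotype dynamics (0 mild/ambulatory-like, 1
#'   severe/non-ambulatory-like). Ignored for `typical`.
#' @param duration_s recording length in seconds, 60-300.
#' @param fps frames per second.
#' @param base_freq_bands list of `c(low, high)` Hz bands, one per movement
#'   scale; edges must satisfy `0 < low < high < fps/2`.
#' @param mod_depth depth in `[0, 1]` of within-recording frequency and
#'   amplitude modulation (Ornstein-Uhlenbeck driven).
#' @param cross_corr target mean inter-channel covariation in `[0, 1]` for
#'   typical dynamics.
#' @param noise_sd pixel-scale Gaussian observation noise.
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical trajectories.
#' @return a `sim_params` list, validated.
#' @export
sim_params <- function(phenotype = c("typical", "cp_risk"), severity = 0.5,
                       duration_s = 300, fps = 30,
                       base_freq_bands = list(c(0.1, 0.5), c(0.5, 1.5),
                                              c(1.5, 3), c(3, 6)),
                       mod_depth = 0.6, cross_corr = 0.3, noise_sd = 0.5,
                       seed = 1) {
  phenotype <- match.arg(phenotype)
  if (!is.numeric(duration_s) || duration_s < 60 || duration_s > 300) {
    stop_cima("sim_params: duration_s must lie in [60, 300] (got %s)", format(duration_s))
  }
  if (!is.numeric(fps) || fps <= 0 || fps != round(fps)) {
    stop_cima("sim_params: fps must be a positive integer")
  }
  n <- duration_s * fps
  if (abs(n - round(n)) > 1e-9 || n <= 0) {
    stop_cima("sim_params: duration_s * fps must be a positive integer")
  }
  for (b in base_freq_bands) {
    if (length(b) != 2L || !(0 < b[1L] && b[1L] < b[2L] && b[2L] < fps / 2)) {
      stop_cima("sim_params: band edges must satisfy 0 < low < high < fps/2 (got [%s, %s])",
                format(b[1L]), format(b[2L]))
    }
  }
  if (severity < 0 || severity > 1) stop_cima("sim_params: severity must be in [0, 1]")
  if (mod_depth < 0 || mod_depth > 1) stop_cima("sim_params: mod_depth must be in [0, 1]")
  if (cross_corr < 0 || cross_corr > 1) stop_cima("sim_params: cross_corr must be in [0, 1]")
  if (noise_sd < 0) stop_cima("sim_params: noise_sd must be >= 0")
  structure(list(
    phenotype = phenotype, severity = severity, duration_s = duration_s,
    fps = as.integer(fps), base_freq_bands = base_freq_bands,
    mod_depth = mod_depth, cross_corr = cross_corr, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_params")
}

# Stationary AR(1) (discretized Ornstein-Uhlenbeck) with unit variance.
ou_process <- function(n, fps, theta = 0.5) {
  a <- exp(-theta / fps)
  e <- rnorm(n, sd = sqrt(1 - a^2))
  x <- numeric(n)
  x[1L] <- rnorm(1L)
  for (i in 2:n) x[i] <- a * x[i - 1L] + e[i]
  x
}

# One modulated band-limited oscillator: OU-driven frequency inside the band
# and non-negative OU-driven amplitude around amp0.
oscillator <- function(n, fps, band, amp0, mod_depth) {
  f0 <- sqrt(band[1L] * band[2L])
  f <- f0 * (1 + 0.5 * mod_depth * ou_process(n, fps, theta = 0.3))
  f <- pmin(pmax(f, band[1L]), band[2L])
  phase <- 2 * pi * cumsum(f) / fps + runif(1L, 0, 2 * pi)
  a <- amp0 * pmax(0, 1 + mod_depth * ou_process(n, fps, theta = 0.2))
  a * cos(phase)
}

# Band signals for all channels under one dynamic regime. Channel c in band b
# is w * shared_b + sqrt(1 - w^2) * own_cb, giving pairwise correlation ~ w^2.
regime_signal <- function(n, fps, bands, amps, mod_depth, sync_w) {
  X <- matrix(0, n, N_CHANNELS)
  for (b in seq_along(bands)) {
    if (amps[b] <= 0) next
    shared <- oscillator(n, fps, bands[[b]], 1, mod_depth)
    for (c in seq_len(N_CHANNELS)) {
      own <- oscillator(n, fps, bands[[b]], 1, mod_depth)
      X[, c] <- X[, c] + amps[b] * (sync_w * shared + sqrt(1 - sync_w^2) * own)
    }
  }
  X
}

#' Simulate one 12-channel infant movement trajectory
#'
#' Typical dynamics: all frequency bands active with amplitudes decreasing
#' toward fast scales, full modulation depth, and moderate inter-channel
#' synchrony that drifts slowly over the recording. Risk dynamics: only the
#' two slowest bands active, modulation depth shrunk by `(1 - 0.8 severity)`,
#' and strong static synchrony `0.6 + 0.35 severity`. For the `cp_risk`
#' phenotype a fraction `severity` of the 5-second blocks (window-aligned)
#' is generated from risk dynamics and spliced with half-second cosine
#' crossfades; the remainder uses typical dynamics.
#'
#' @param params a [sim_params()] object.
#' @param video_id,subject_id identifiers stored in the result.
#' @return a [trajectory_set()] object.
#' @export
simulate_trajectory <- function(params, video_id = "V0001", subject_id = "S0001") {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    n <- as.integer(round(params$duration_s * params$fps))
    fps <- params$fps
    bands <- params$base_freq_bands
    nb <- length(bands)
    amps_typ <- 24 / (1.6^(seq_len(nb) - 1L))
    typ <- regime_signal(n, fps, bands, amps_typ, params$mod_depth,
                         sync_w = sqrt(params$cross_corr))
    # slow drift of typical synchrony: blend in a second, more synchronous
    # realization with a slowly varying weight
    drift <- moving_average(ou_process(n, fps, theta = 0.05), max(3L, fps))
    drift <- 0.5 + 0.25 * tanh(drift)
    typ2 <- regime_signal(n, fps, bands, amps_typ, params$mod_depth,
                          sync_w = sqrt(min(1, params$cross_corr * 1.5)))
    typ <- drift * typ + (1 - drift) * typ2
    X <- typ
    if (params$phenotype == "cp_risk" && params$severity > 0) {
      s <- params$severity
      amps_risk <- c(amps_typ[1L], amps_typ[2L] * (1 - 0.5 * s), rep(0, nb - 2L))
      risk <- regime_signal(n, fps, bands[1:2], amps_risk[1:2],
                            params$mod_depth * (1 - 0.8 * s),
                            sync_w = sqrt(0.6 + 0.35 * s))
      block <- 5L * fps
      n_blocks <- n %/% block
      n_risk <- round(s * n_blocks)
      risk_blocks <- sort(sample.int(n_blocks, n_risk))
      w <- numeric(n) # 1 inside risk blocks
      for (bl in risk_blocks) w[((bl - 1L) * block + 1L):(bl * block)] <- 1
      ramp <- max(2L, as.integer(fps / 2))
      w <- moving_average(w, ramp) # half-second crossfade at block edges
      X <- (1 - w) * typ + w * risk
    }
    X <- X + matrix(rnorm(n * N_CHANNELS, sd = params$noise_sd), n, N_CHANNELS)
    X <- sweep(X, 2L, BODY_LAYOUT, "+")
    colnames(X) <- CHANNEL_NAMES
    trajectory_set(X, fps = fps, video_id = video_id, subject_id = subject_id)
  })
}

#' Simulate a labeled cohort of videos
#'
#' Each subject contributes exactly one video. CP status is Bernoulli with
#' probability `cp_fraction`; CP videos use the `cp_risk` phenotype with a
#' severity drawn from `severity_dist` and a GMFCS level derived from it
#' (quintiles of severity map to levels I-V; levels I-III are flagged
#' ambulatory). Video durations are drawn from 60-300 s with mode/median
#' 300 s (60% of videos run the full 5 minutes). Fidgety-movement classes
#' are attached as plausible categorical metadata (mostly absent/sporadic
#' in CP, mostly intermittent otherwise).
#'
#' @param n_videos number of videos (= subjects).
#' @param cp_fraction expected CP prevalence in `[0, 1]`.
#' @param severity_dist function of `n` returning severities in `[0, 1]`.
#'   The default `rbeta(n, 4, 1.5)` is right-skewed (mean ~0.73, ~13% of
#'   draws below 0.5), reflecting a cohort where most CP videos spend the
#'   majority of their recording in risk-phenotype dynamics and only a
#'   small minority would fall below a 50% risk-period threshold.
#' @param seed integer seed controlling labels and trajectories.
#' @param duration_s fixed duration override; `NULL` draws from the cohort
#'   length distribution.
#' @param fps frames per second.
#' @param ... further arguments passed to [sim_params()] (e.g. `mod_depth`).
#' @return list with `trajectories` (list of [trajectory_set()]) and
#'   `labels` (data.frame `video_id`, `subject_id`, `cp_status`, `gmfcs`,
#'   `fm_class`, `ambulatory`, `severity`, `duration_s`).
#' @export
simulate_cohort <- function(n_videos, cp_fraction = 0.11,
                            severity_dist = function(n) rbeta(n, 4, 1.5),
                            seed = 1, duration_s = NULL, fps = 30, ...) {
  if (!is.numeric(n_videos) || n_videos <= 0) {
    stop_cima("simulate_cohort: n_videos must be positive")
  }
  if (cp_fraction < 0 || cp_fraction > 1) {
    stop_cima("simulate_cohort: cp_fraction must be in [0, 1]")
  }
  n_videos <- as.integer(n_videos)
  labels <- with_seed(seed, {
    cp <- rbinom(n_videos, 1L, cp_fraction)
    sev <- rep(NA_real_, n_videos)
    if (sum(cp) > 0) sev[cp == 1L] <- pmin(1, pmax(0, severity_dist(sum(cp))))
    gmfcs <- as.integer(ifelse(cp == 1L, pmin(5, 1 + floor(sev * 5)), NA))
    dur <- if (is.null(duration_s)) {
      ifelse(runif(n_videos) < 0.6, 300, round(runif(n_videos, 60, 300)))
    } else rep(duration_s, n_videos)
    fm <- character(n_videos)
    fm_cp <- c("FM-", "FM-/+", "FM+", "FM++", "FMa")
    for (i in seq_len(n_videos)) {
      fm[i] <- if (cp[i] == 1L) {
        sample(fm_cp, 1L, prob = c(0.55, 0.15, 0.25, 0.02, 0.03))
      } else {
        sample(fm_cp, 1L, prob = c(0.08, 0.06, 0.70, 0.14, 0.02))
      }
    }
    data.frame(
      video_id = sprintf("V%04d", seq_len(n_videos)),
      subject_id = sprintf("S%04d", seq_len(n_videos)),
      cp_status = cp, gmfcs = gmfcs, fm_class = fm,
      ambulatory = ifelse(is.na(gmfcs), NA, gmfcs <= 3L),
      severity = sev, duration_s = dur,
      stringsAsFactors = FALSE
    )
  })
  trajectories <- lapply(seq_len(n_videos), function(i) {
    p <- sim_params(
      phenotype = if (labels$cp_status[i] == 1L) "cp_risk" else "typical",
      severity = if (labels$cp_status[i] == 1L) labels$severity[i] else 0,
      duration_s = labels$duration_s[i], fps = fps,
      seed = seed + 7919L * i, ...
    )
    simulate_trajectory(p, video_id = labels$video_id[i],
                        subject_id = labels$subject_id[i])
  })
  list(trajectories = trajectories, labels = labels)
}
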