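# Windowed movement-repertoire features: 990 per 5-second window.

#' Feature manifest for the 990-column window feature vector
#'
#' One row per feature, in column order: for each scale k = 1..11, the 12
#' amplitude-weighted mean frequencies (Hz), the 12 mean amplitudes (pixels),
#' then the 66 within-window Pearson correlations of same-scale IMF channel
#' pairs. Column names are `f0001`..`f0990`; the manifest maps them to kind,
#' scale and channel(s). The manifest is part of the model file contract:
#' a frozen model refuses feature matrices whose names differ.
#'
#' @return data.frame with columns `name`, `kind` (`meanfreq`, `meanamp`,
#'   `cov`), `scale`, `channel_a`, `channel_b` (`NA` except for `cov`).
#' @export
feature_manifest <- function() {
  pr <- channel_pairs()
  per_scale <- rbind(
    data.frame(kind = "meanfreq", channel_a = CHANNEL_NAMES, channel_b = NA_character_),
    data.frame(kind = "meanamp", channel_a = CHANNEL_NAMES, channel_b = NA_character_),
    data.frame(kind = "cov", channel_a = CHANNEL_NAMES[pr$i], channel_b = CHANNEL_NAMES[pr$j])
  )
  out <- do.call(rbind, lapply(seq_len(N_SCALES), function(k) {
    cbind(per_scale, scale = k)
  }))
  out <- out[, c("kind", "scale", "channel_a", "channel_b")]
  out$name <- sprintf("f%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("name", "kind", "scale", "channel_a", "channel_b")]
}

#' Per-window movement features from an IMF stack and its Hilbert spectra
#'
#' Splits the recording into non-overlapping windows of `window_s` seconds
#' (a trailing partial window is discarded) and computes, per window and
#' scale: the amplitude-weighted mean instantaneous frequency and the mean
#' instantaneous amplitude of each channel, and the Pearson correlation of
#' each unordered channel pair's IMF segments. A correlation is 0 whenever
#' either segment has zero variance (including zero-padded scales); a mean
#' frequency is 0 when the window carries no amplitude.
#'
#' @param stack [memd_decompose()] output.
#' @param spectra matching [hilbert_spectra()] output.
#' @param fps frames per second; `window_s * fps` must be a whole number.
#' @param window_s window length in seconds (5 in the assessment model).
#' @return object of class `window_features`: list with `features`
#'   (windows x 990 matrix, columns `f0001`..`f0990`), `meta` (data.frame
#'   `video_id`, `window_index`, `start_s`) and `fps`.
#' @export
extract_window_features <- function(stack, spectra, fps = stack$fps,
                                    window_s = 5) {
  stopifnot(inherits(stack, "imf_stack"), inherits(spectra, "inst_spectra"))
  L <- window_s * fps
  if (abs(L - round(L)) > 1e-9) {
    stop_cima("extract_window_features: window_s * fps must be an integer (got %g)", L)
  }
  L <- as.integer(round(L))
  n <- nrow(stack$residue)
  if (n < L) stop_cima("extract_window_features: recording shorter than one window")
  n_w <- n %/% L
  pr <- channel_pairs()
  feats <- matrix(0, n_w, N_FEATURES)
  colnames(feats) <- sprintf("f%04d", seq_len(N_FEATURES))
  for (w in seq_len(n_w)) {
    rows <- ((w - 1L) * L + 1L):(w * L)
    col <- 1L
    for (k in seq_len(N_SCALES)) {
      A <- spectra$amp[[k]][rows, , drop = FALSE]
      Fq <- spectra$freq[[k]][rows, , drop = FALSE]
      asum <- colSums(A)
      mf <- ifelse(asum > 0, colSums(A * Fq) / asum, 0)
      ma <- colMeans(A)
      seg <- stack$imfs[[k]][rows, , drop = FALSE]
      sds <- apply(seg, 2L, sd)
      ok <- sds > 0
      cv <- numeric(N_PAIRS)
      if (any(ok)) {
        C <- suppressWarnings(cor(seg))
        C[!is.finite(C)] <- 0
        C[!ok, ] <- 0
        C[, !ok] <- 0
        cv <- C[cbind(pr$i, pr$j)]
      }
      feats[w, col:(col + 11L)] <- mf
      feats[w, (col + 12L):(col + 23L)] <- ma
      feats[w, (col + 24L):(col + 89L)] <- cv
      col <- col + 90L
    }
  }
  meta <- data.frame(
    video_id = rep(stack$video_id %||% NA_character_, n_w),
    window_index = seq_len(n_w),
    start_s = (seq_len(n_w) - 1L) * window_s,
    stringsAsFactors = FALSE
  )
  structure(list(features = feats, meta = meta, fps = fps,
                 window_s = window_s),
            class = "window_features")
}

#' Full feature-extraction pipeline for one trajectory
#'
#' Convenience wrapper: MEMD decomposition, Hilbert spectra, and windowed
#' feature extraction with the model's defaults.
#'
#' @inheritParams memd_decompose
#' @inheritParams extract_window_features
#' @return a `window_features` object (see [extract_window_features()]).
#' @export
extract_features <- function(traj, n_dirs = 64, max_sift = 10, max_imfs = 11,
                             sd_stop = 0.2, window_s = 5) {
  stack <- memd_decompose(traj, n_dirs = n_dirs, max_sift = max_sift,
                          max_imfs = max_imfs, sd_stop = sd_stop)
  spec <- hilbert_spectra(stack)
  extract_window_features(stack, spec, window_s = window_s)
}

#' @export
print.window_features <- function(x, ...) {
  cat(sprintf("<window_features> %d windows x %d features (%g s windows, %g fps)\n",
              nrow(x$features), ncol(x$features), x$window_s, x$fps))
  invisible(x)
}

# Bind several window_features objects into one feature table (matrix + meta).
bind_features <- function(flist) {
  stopifnot(length(flist) > 0L)
  list(
    features = do.call(rbind, lapply(flist, `[[`, "features")),
    meta = do.call(rbind, lapply(flist, `[[`, "meta"))
  )
}
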