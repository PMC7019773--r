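# File formats: trajectory CSV (with "# fps=" header comment), label CSV,
# window-feature CSV, and the JSON model container. All readers validate and
# reject malformed input, naming the offending field or row.

MODEL_FORMAT_VERSION <- 1L

#' Construct and validate a 12-channel trajectory
#'
#' @param channels numeric matrix, samples x 12, columns named
#'   `head_x, head_y, trunk_x, trunk_y, armL_x, armL_y, armR_x, armR_y,
#'   legL_x, legL_y, legR_x, legR_y` (image convention, pixels).
#' @param fps frames per second.
#' @param video_id,subject_id identity metadata.
#' @return object of class `cima_trajectory` with fields `video_id`,
#'   `subject_id`, `fps`, `n_samples`, `channels`.
#' @export
trajectory_set <- function(channels, fps, video_id = NA_character_,
                           subject_id = NA_character_) {
  channels <- as.matrix(channels)
  if (ncol(channels) != N_CHANNELS) {
    stop_cima("trajectory_set: expected %d channels, got %d", N_CHANNELS, ncol(channels))
  }
  if (is.null(colnames(channels))) colnames(channels) <- CHANNEL_NAMES
  if (!identical(colnames(channels), CHANNEL_NAMES)) {
    bad <- setdiff(CHANNEL_NAMES, colnames(channels))[1L]
    stop_cima("trajectory_set: channel columns must be (%s); missing or misordered: %s",
              paste(CHANNEL_NAMES, collapse = ", "), bad)
  }
  if (!all(is.finite(channels))) {
    idx <- which(!is.finite(channels), arr.ind = TRUE)[1L, ]
    stop_cima("trajectory_set: non-finite value at row %d, channel %s",
              idx[1L], colnames(channels)[idx[2L]])
  }
  if (!is.numeric(fps) || fps <= 0) stop_cima("trajectory_set: fps must be positive")
  if (nrow(channels) < 5 * fps) {
    stop_cima("trajectory_set: recording too short: %d samples < 5*fps = %g",
              nrow(channels), 5 * fps)
  }
  structure(list(video_id = video_id, subject_id = subject_id,
                 fps = fps, n_samples = nrow(channels), channels = channels),
            class = "cima_trajectory")
}

#' @export
print.cima_trajectory <- function(x, ...) {
  cat(sprintf("<cima_trajectory> %s (subject %s): %d samples @ %g fps (%.1f s)\n",
              x$video_id, x$subject_id, x$n_samples, x$fps, x$n_samples / x$fps))
  invisible(x)
}

#' Write / read a trajectory CSV
#'
#' Format: a `# fps=<value>` comment line, then a header
#' `frame,time_s,head_x,...,legR_y` with frames as consecutive integers from
#' 0 and `time_s = frame / fps`. Reading validates columns, frame numbering,
#' finiteness and minimum length (at least one full 5-s window). Short gaps
#' of missing values (at most 0.5 s) can optionally be linearly
#' interpolated; by default any missing value is an error.
#'
#' @param traj a [trajectory_set()] object.
#' @param path file path.
#' @param fps frame rate override if the file lacks a `# fps=` line.
#' @param interpolate_gaps if `TRUE`, linearly fill missing-value runs of at
#'   most 0.5 s per channel before validation.
#' @return `read_trajectory` returns a [trajectory_set()];
#'   `write_trajectory` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cima_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%.10g", traj$fps), con)
  writeLines(sprintf("# video_id=%s", traj$video_id), con)
  writeLines(sprintf("# subject_id=%s", traj$subject_id), con)
  df <- data.frame(frame = seq_len(traj$n_samples) - 1L,
                   time_s = (seq_len(traj$n_samples) - 1L) / traj$fps)
  df <- cbind(df, as.data.frame(traj$channels))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, fps = NULL, interpolate_gaps = FALSE) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "# ")]
  get_meta <- function(key) {
    ln <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (length(ln)) sub(sprintf("^# %s=", key), "", ln[1L]) else NULL
  }
  fps_line <- get_meta("fps")
  if (!is.null(fps_line)) fps <- as.numeric(fps_line)
  if (is.null(fps) || !is.finite(fps)) {
    stop_cima("read_trajectory: no '# fps=' header line in %s and no fps argument", path)
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "time_s", CHANNEL_NAMES)
  missing_col <- setdiff(need, names(df))
  if (length(missing_col)) {
    stop_cima("read_trajectory: missing column '%s' in %s", missing_col[1L], path)
  }
  if (!identical(as.integer(df$frame), seq_len(nrow(df)) - 1L)) {
    stop_cima("read_trajectory: frames must be consecutive integers from 0")
  }
  M <- as.matrix(df[, CHANNEL_NAMES])
  if (interpolate_gaps) M <- fill_short_gaps(M, max_gap = ceiling(0.5 * fps))
  if (!all(is.finite(M))) {
    idx <- which(!is.finite(M), arr.ind = TRUE)[1L, ]
    stop_cima("read_trajectory: non-finite value at row %d, column %s",
              idx[1L], CHANNEL_NAMES[idx[2L]])
  }
  if (nrow(M) < 5 * fps) {
    stop_cima("read_trajectory: recording too short: %d samples < 5*fps = %g",
              nrow(M), 5 * fps)
  }
  trajectory_set(M, fps = fps,
                 video_id = get_meta("video_id") %||% NA_character_,
                 subject_id = get_meta("subject_id") %||% NA_character_)
}

# Linear interpolation of interior NA runs of length <= max_gap samples.
fill_short_gaps <- function(M, max_gap) {
  for (c in seq_len(ncol(M))) {
    x <- M[, c]
    if (!anyNA(x)) next
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths <= max_gap)) {
      if (starts[k] == 1L || ends[k] == length(x)) next
      idx <- starts[k]:ends[k]
      x[idx] <- approx(c(starts[k] - 1L, ends[k] + 1L),
                       x[c(starts[k] - 1L, ends[k] + 1L)], xout = idx)$y
    }
    M[, c] <- x
  }
  M
}

#' Write / read a label table CSV
#'
#' Columns `video_id,subject_id,cp_status,gmfcs,fm_class`; the derived
#' `ambulatory` flag (GMFCS I-III) is recomputed on read. Non-CP rows must
#' have no GMFCS level.
#'
#' @param labels data.frame with at least `video_id`, `subject_id`,
#'   `cp_status`; optional `gmfcs`, `fm_class`.
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  need <- c("video_id", "subject_id", "cp_status")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop_cima("write_labels: missing column '%s'", miss[1L])
  out <- labels[, need]
  out$gmfcs <- if ("gmfcs" %in% names(labels)) labels$gmfcs else NA_integer_
  out$fm_class <- if ("fm_class" %in% names(labels)) labels$fm_class else NA_character_
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("video_id", "subject_id", "cp_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_cima("read_labels: missing column '%s' in %s", miss[1L], path)
  if (!all(df$cp_status %in% c(0L, 1L))) {
    bad <- which(!df$cp_status %in% c(0L, 1L))[1L]
    stop_cima("read_labels: cp_status must be 0/1 (row %d)", bad)
  }
  if (!"gmfcs" %in% names(df)) df$gmfcs <- NA_integer_
  if (!"fm_class" %in% names(df)) df$fm_class <- NA_character_
  bad <- which(df$cp_status == 0L & !is.na(df$gmfcs))
  if (length(bad)) {
    stop_cima("read_labels: non-CP row %d has a GMFCS level", bad[1L])
  }
  df$ambulatory <- ifelse(is.na(df$gmfcs), NA, df$gmfcs <= 3L)
  df
}

#' Write / read a window feature table CSV
#'
#' Columns `video_id,window_index,f0001..f0990`. `write_features` accepts a
#' `window_features` object or a bound feature table (list with `features`
#' and `meta`).
#'
#' @param x features to write.
#' @param path file path.
#' @export
write_features <- function(x, path) {
  if (inherits(x, "window_features")) x <- bind_features(list(x))
  dt <- data.table::data.table(video_id = x$meta$video_id,
                               window_index = x$meta$window_index)
  dt <- cbind(dt, data.table::as.data.table(x$features))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  dt <- data.table::fread(path)
  need <- c("video_id", "window_index", sprintf("f%04d", seq_len(N_FEATURES)))
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop_cima("read_features: missing column '%s' in %s", miss[1L], path)
  feats <- as.matrix(dt[, sprintf("f%04d", seq_len(N_FEATURES)), with = FALSE])
  if (!all(is.finite(feats))) {
    idx <- which(!is.finite(feats), arr.ind = TRUE)[1L, ]
    stop_cima("read_features: non-finite value at row %d, column f%04d", idx[1L], idx[2L])
  }
  list(features = feats,
       meta = data.frame(video_id = dt$video_id,
                         window_index = dt$window_index,
                         stringsAsFactors = FALSE))
}

#' Write / read a frozen assessment model
#'
#' The model is a single self-describing JSON container (diffable,
#' versioned) holding the feature manifest, standardization vectors,
#' selected feature indices, PLS weight/loading/rotation matrices (5
#' components), LDA class means, pooled covariance and priors, and the
#' window/video decision thresholds. Writing validates invariants (selected
#' indices within 1..990, 5 components, thresholds in `[0, 1]`); reading
#' refuses any other `format_version`.
#'
#' @param model a `cima_model` object from [train_cima()].
#' @param path file path.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  # digits = I(17): 17 significant digits round-trip doubles bit-exactly
  jsonlite::write_json(unclass(model), path, digits = I(17), auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(m$format_version) || m$format_version != MODEL_FORMAT_VERSION) {
    stop_cima("read_model: format_version %s not supported (reader version %d)",
              format(m$format_version %||% NA), MODEL_FORMAT_VERSION)
  }
  p_sel <- length(m$selected)
  as_mat <- function(x, nr, nc) matrix(as.numeric(x), nr, nc)
  if (!m$degenerate) {
    m$pls$W <- as_mat(m$pls$W, p_sel, m$pls$ncomp)
    m$pls$P <- as_mat(m$pls$P, p_sel, m$pls$ncomp)
    m$pls$R <- as_mat(m$pls$R, p_sel, m$pls$ncomp)
    m$pls$q <- as.numeric(m$pls$q)
    m$lda$means <- as_mat(m$lda$means, 2L, m$pls$ncomp)
    m$lda$cov <- as_mat(m$lda$cov, m$pls$ncomp, m$pls$ncomp)
  }
  m$selected <- as.integer(m$selected)
  model <- structure(m, class = "cima_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  stopifnot(inherits(model, "cima_model"))
  if (length(model$feature_names) != N_FEATURES) {
    stop_cima("model: feature manifest must have %d names", N_FEATURES)
  }
  if (length(model$selected) &&
      (min(model$selected) < 1L || max(model$selected) > N_FEATURES)) {
    stop_cima("model: selected feature index out of range 1..%d (got %d)",
              N_FEATURES, model$selected[which(model$selected < 1L | model$selected > N_FEATURES)][1L])
  }
  if (!model$degenerate && model$pls$ncomp != 5L) {
    stop_cima("model: number of PLS components must be 5 (got %s)", model$pls$ncomp)
  }
  for (th in c(model$window_threshold, model$video_threshold)) {
    if (!is.numeric(th) || th < 0 || th > 1) {
      stop_cima("model: thresholds must lie in [0, 1]")
    }
  }
  invisible(model)
}
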