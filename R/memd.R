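#' Low-discrepancy direction set on the unit hypersphere
#'
#' Generates `n_dirs` unit vectors in `dim` dimensions from a Hammersley
#' point set: the first coordinate of point i is (i - 1/2)/n and the
#' remaining coordinates are radical-inverse (van der Corput) values in the
#' first `dim - 1` prime bases. The cube points are mapped to the sphere by
#' coordinate-wise Gaussian quantile transform followed by normalization,
#' which sends a uniform low-discrepancy set to a well-spread set of
#' directions. Deterministic: repeated calls return the identical matrix.
#'
#' @param n_dirs number of directions; must be at least `2 * dim`.
#' @param dim dimension of the ambient space (12 for the full channel set).
#' @return a `dim` x `n_dirs` matrix with unit-norm columns.
#' @export
hammersley_directions <- function(n_dirs, dim) {
  if (!is.numeric(dim) || dim < 2) {
    stop_cima("hammersley_directions: dim must be >= 2 (got %s)", format(dim))
  }
  if (!is.numeric(n_dirs) || n_dirs < 2 * dim) {
    stop_cima("hammersley_directions: n_dirs must be >= 2*dim (= %d)", 2L * as.integer(dim))
  }
  n_dirs <- as.integer(n_dirs)
  dim <- as.integer(dim)
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  if (dim - 1L > length(primes)) {
    stop_cima("hammersley_directions: dim too large (max %d)", length(primes) + 1L)
  }
  u <- matrix(0, nrow = dim, ncol = n_dirs)
  u[1L, ] <- (seq_len(n_dirs) - 0.5) / n_dirs
  for (d in seq_len(dim - 1L)) {
    u[d + 1L, ] <- vapply(seq_len(n_dirs), radical_inverse, numeric(1), base = primes[d])
  }
  z <- stats::qnorm(u)
  nrm <- sqrt(colSums(z^2))
  sweep(z, 2L, nrm, "/")
}

# Van der Corput radical inverse of integer i in the given prime base; always
# in (0, 1) for i >= 1.
radical_inverse <- function(i, base) {
  r <- 0
  f <- 1 / base
  while (i > 0) {
    r <- r + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  r
}

#' Multivariate empirical mode decomposition of a trajectory
#'
#' Decomposes the 12 trajectory channels jointly into scale-aligned intrinsic
#' mode functions (IMFs). Each sifting step projects the signal onto a fixed
#' low-discrepancy set of directions, interpolates upper/lower envelopes of
#' each projection with natural cubic splines (mirrored boundary extrema),
#' averages the envelope midlines over directions, and subtracts. Sifting for
#' one IMF stops after `max_sift` iterations or when the Cauchy-type
#' stoppage ratio falls below `sd_stop`. Extraction stops when fewer than
#' half the direction projections still carry two maxima and two minima.
#'
#' Channels are mean-centered before decomposition; the trend stays in the
#' residue. The stack is zero-padded (or the surplus folded into the residue)
#' so that exactly `max_imfs` scales are always present, giving a fixed-size
#' feature vector downstream. By construction the per-channel sum of all IMFs
#' plus the residue reproduces the centered input to floating-point accuracy.
#'
#' @param traj a [trajectory_set()] object.
#' @param n_dirs number of projection directions (>= 2 x channels).
#' @param max_sift maximum sifting iterations per IMF.
#' @param max_imfs fixed number of retained scales (11).
#' @param sd_stop Cauchy stoppage threshold on the mean relative change
#'   between consecutive sifts.
#' @return an object of class `imf_stack`: list with `imfs` (list of
#'   `max_imfs` matrices, samples x channels, finest scale first), `residue`,
#'   `K` (= `max_imfs`), `K_natural` (scales actually extracted),
#'   `sift_meta` (iteration counts), `fps`, `video_id`.
#' @export
memd_decompose <- function(traj, n_dirs = 64, max_sift = 10, max_imfs = 11,
                           sd_stop = 0.2) {
  stopifnot(inherits(traj, "cima_trajectory"))
  X <- traj$channels
  n <- nrow(X)
  d <- ncol(X)
  ctr <- colMeans(X)
  r <- sweep(X, 2L, ctr)
  D <- hammersley_directions(n_dirs, d)
  imfs <- vector("list", 0L)
  iters <- integer(0)
  for (k in seq_len(max_imfs)) {
    h <- r
    it <- 0L
    repeat {
      me <- .memd_mean_envelope(h, D)
      if (me$n_usable < ceiling(n_dirs / 2)) break
      hn <- h - me$env
      it <- it + 1L
      denom <- sum(h^2)
      sd_val <- if (denom > 0) sum((h - hn)^2) / denom else 0
      h <- hn
      if (it >= max_sift || sd_val < sd_stop) break
    }
    if (it == 0L) break
    imfs[[length(imfs) + 1L]] <- h
    iters[length(iters) + 1L] <- it
    r <- r - h
  }
  k_nat <- length(imfs)
  if (k_nat == 0L) {
    warning("memd_decompose: input has no oscillatory content; returning zero IMFs")
  }
  zero <- matrix(0, n, d, dimnames = dimnames(X))
  if (k_nat < max_imfs) {
    # pad with silent coarse scales so every stack has the same depth
    imfs <- c(imfs, rep(list(zero), max_imfs - k_nat))
  } else if (k_nat > max_imfs) {
    for (k in seq(max_imfs + 1L, k_nat)) r <- r + imfs[[k]]
    imfs <- imfs[seq_len(max_imfs)]
  }
  structure(
    list(
      imfs = imfs, residue = r, K = as.integer(max_imfs),
      K_natural = min(k_nat, as.integer(max_imfs)),
      sift_meta = iters, fps = traj$fps, video_id = traj$video_id,
      center = ctr
    ),
    class = "imf_stack"
  )
}

#' @export
print.imf_stack <- function(x, ...) {
  cat(sprintf(
    "<imf_stack> video %s: %d scales retained (%d natural), %d channels x %d samples\n",
    x$video_id %||% "?", x$K, x$K_natural, ncol(x$residue), nrow(x$residue)
  ))
  invisible(x)
}

# Maximum absolute per-channel reconstruction error of sum(IMFs) + residue
# against the centered input; used by tests and sanity checks.
reconstruction_error <- function(stack, traj) {
  X <- sweep(traj$channels, 2L, colMeans(traj$channels))
  rec <- Reduce(`+`, stack$imfs) + stack$residue
  max(abs(rec - X))
}
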