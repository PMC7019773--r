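# Hilbert spectral analysis of an IMF stack.

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(ph[1L], d))
}

#' Instantaneous amplitude and frequency of an IMF stack
#'
#' Computes, per scale and channel, the analytic signal of the IMF via the
#' Hilbert transform. Amplitude is its modulus (pixels). Instantaneous
#' frequency is the centered-difference derivative of the unwrapped phase,
#' scaled to Hz, smoothed with a half-second moving average and clipped to
#' `[0, fps/2]`. Samples whose amplitude is below `1e-12` of the scale's peak
#' amplitude get frequency 0 by convention (phase is meaningless there); an
#' all-zero IMF yields zero amplitude and frequency.
#'
#' @param stack an [memd_decompose()] result.
#' @param fps sampling rate in frames per second; defaults to the stack's.
#' @return object of class `inst_spectra`: lists `amp` and `freq` of
#'   samples x channels matrices, one per scale, plus `fps`.
#' @export
hilbert_spectra <- function(stack, fps = stack$fps) {
  stopifnot(inherits(stack, "imf_stack"))
  w <- max(1L, as.integer(round(fps / 2)))
  if (w %% 2L == 0L) w <- w + 1L
  amp <- vector("list", stack$K)
  freq <- vector("list", stack$K)
  for (k in seq_len(stack$K)) {
    M <- stack$imfs[[k]]
    A <- matrix(0, nrow(M), ncol(M))
    Fq <- matrix(0, nrow(M), ncol(M))
    for (c in seq_len(ncol(M))) {
      x <- M[, c]
      if (all(x == 0)) next
      z <- analytic_signal(x)
      a <- Mod(z)
      ph <- unwrap_phase(Arg(z))
      n <- length(ph)
      f <- numeric(n)
      if (n >= 3L) {
        f[2L:(n - 1L)] <- (ph[3L:n] - ph[1L:(n - 2L)]) / 2
        f[1L] <- ph[2L] - ph[1L]
        f[n] <- ph[n] - ph[n - 1L]
      }
      f <- f * fps / (2 * pi)
      f <- moving_average(f, w)
      f <- pmin(pmax(f, 0), fps / 2)
      f[a < 1e-12 * max(a)] <- 0
      A[, c] <- a
      Fq[, c] <- f
    }
    amp[[k]] <- A
    freq[[k]] <- Fq
  }
  structure(list(amp = amp, freq = freq, fps = fps, K = stack$K),
            class = "inst_spectra")
}
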