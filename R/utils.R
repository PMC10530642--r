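#' @importFrom stats rnorm runif setNames aov var sd median mad cor qnorm
#'   quantile t.test p.adjust TukeyHSD complete.cases fft
#' @importFrom utils head write.table read.table
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average with edge-shrunk window
#'
#' Boxcar smoothing that shrinks the window at the series edges instead of
#' padding, so the overall mean of the trace is preserved.
#' @keywords internal
#' @noRd
moving_average <- function(x, n) {
  if (n <= 1) return(x)
  half <- floor(n / 2)
  cs <- cumsum(c(0, x))
  len <- length(x)
  i <- seq_len(len)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half, len)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth a trials x electrodes x time array along time
#' @keywords internal
#' @noRd
smooth_tensor_array <- function(arr, window_ms, fs) {
  n <- max(1L, round(window_ms / 1000 * fs))
  if (n <= 1) return(arr)
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  m <- t(apply(m, 1, moving_average, n = n))
  array(m, dim = d)
}

#' Analytic-signal amplitude via FFT
#'
#' Instantaneous amplitude (envelope) of a real signal, i.e. the modulus of
#' the analytic signal obtained by zeroing negative frequencies.
#' @keywords internal
#' @noRd
analytic_amplitude <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Derive a reproducible 32-bit sub-seed from a master seed
#' @keywords internal
#' @noRd
sub_seed <- function(seed, k) {
  (as.integer(seed) + 1000003L * as.integer(k)) %% 2147483647L
}
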