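#' Estimate broadband high-frequency activity from voltage traces
#'
#' Band-pass filters the whole recording in `n_subbands` equal sub-bands
#' spanning `band` (default eight 10-Hz bands between 70 and 150 Hz,
#' zero-phase FIR with a Hamming window), extracts the instantaneous
#' amplitude of each band via the analytic signal, normalizes each band by
#' dividing by its mean amplitude over the whole recording (compensating the
#' 1/f spectrum), and averages the normalized amplitude traces across bands.
#'
#' @param voltage numeric matrix, electrodes x samples (a single trace may be
#'   passed as a vector).
#' @param sampling_rate sampling rate in Hz; must exceed twice the upper band
#'   edge.
#' @param band numeric length-2: lower and upper band edge in Hz.
#' @param n_subbands number of equal sub-bands.
#' @param transition_hz FIR transition width; the filter order follows the
#'   standard Hamming-window heuristic 3.3 / (transition / fs).
#' @return matrix electrodes x samples of normalized HFA amplitude (each
#'   band's whole-recording mean is 1 before averaging).
#' @export
extract_hfa <- function(voltage, sampling_rate, band = c(70, 150),
                        n_subbands = 8, transition_hz = 2.5) {
  if (is.vector(voltage)) voltage <- matrix(voltage, nrow = 1)
  if (band[2] >= sampling_rate / 2)
    stop("band upper edge (", band[2], " Hz) is at or above Nyquist")
  ord <- ceiling(3.3 * sampling_rate / transition_hz)
  if (ord %% 2 == 1) ord <- ord + 1
  if (ncol(voltage) <= 3 * ord)
    stop("recording too short for the filter order (need > ",
         3 * ord, " samples)")
  edges <- seq(band[1], band[2], length.out = n_subbands + 1)
  out <- matrix(0, nrow(voltage), ncol(voltage))
  for (b in seq_len(n_subbands)) {
    w <- c(edges[b], edges[b + 1]) / (sampling_rate / 2)
    coef <- signal::fir1(ord, w, type = "pass")
    for (e in seq_len(nrow(voltage))) {
      filt <- signal::filtfilt(as.numeric(coef), 1, voltage[e, ])
      amp <- analytic_amplitude(filt)
      out[e, ] <- out[e, ] + amp / mean(amp)
    }
  }
  out / n_subbands
}

#' Epoch continuous HFA traces with baseline correction and smoothing
#'
#' Cuts trial segments around each stimulus onset, subtracts the mean HFA in
#' the pre-onset baseline from the entire segment (per trial and electrode),
#' drops trials containing excessive noise, and finally smooths with a
#' centered moving window (window shrunk at the epoch edges, applied after
#' baseline correction). Events whose epoch would exceed the recording
#' bounds are dropped with a warning.
#'
#' @param hfa matrix electrodes x samples of continuous HFA (from
#'   [extract_hfa()] or the generator).
#' @param sampling_rate Hz.
#' @param events tibble with `onset_sample` plus the trial metadata columns
#'   of [trial_tensor()].
#' @param electrodes electrode metadata tibble.
#' @param window_ms epoch window in ms relative to onset.
#' @param baseline_ms length of the pre-onset baseline (ms).
#' @param smooth_ms smoothing window (ms); 0 disables.
#' @param reject_k trials whose peak absolute amplitude exceeds
#'   `reject_k` robust SDs (MAD) of that electrode's trial-peak distribution
#'   are excluded as excessive noise; NULL disables rejection.
#' @return a [trial_tensor()]; the number of rejected trials is reported via
#'   `message()` and stored in attribute `n_rejected`.
#' @export
epoch_baseline_smooth <- function(hfa, sampling_rate, events, electrodes,
                                  window_ms = c(-300, 1600),
                                  baseline_ms = 300, smooth_ms = 50,
                                  reject_k = 5) {
  if (is.vector(hfa)) hfa <- matrix(hfa, nrow = 1)
  events <- tibble::as_tibble(events)
  stopifnot("onset_sample" %in% names(events))
  step <- round(window_ms / 1000 * sampling_rate)
  rel <- seq(step[1], step[2])
  time_ms <- rel / sampling_rate * 1000
  ok <- events$onset_sample + step[1] >= 1 &
    events$onset_sample + step[2] <= ncol(hfa)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
    events <- events[ok, , drop = FALSE]
  }
  n_tr <- nrow(events)
  n_el <- nrow(hfa)
  arr <- array(0, dim = c(n_tr, n_el, length(rel)))
  for (k in seq_len(n_tr))
    arr[k, , ] <- hfa[, events$onset_sample[k] + rel, drop = FALSE]

  bl <- time_ms >= -baseline_ms & time_ms < 0
  blm <- apply(arr[, , bl, drop = FALSE], c(1, 2), mean)
  arr <- arr - array(rep(blm, length(rel)), dim(arr))

  n_rej <- 0L
  if (!is.null(reject_k) && n_tr >= 3) {
    peaks <- apply(abs(arr), c(1, 2), max)       # trials x electrodes
    med <- apply(peaks, 2, median)
    md <- apply(peaks, 2, mad)
    z <- sweep(sweep(peaks, 2, med), 2, pmax(md, 1e-12), "/")
    z[, md == 0] <- 0
    bad <- apply(z > reject_k, 1, any)
    n_rej <- sum(bad)
    if (n_rej > 0) {
      message(n_rej, " trial(s) excluded by the noise-rejection rule (K = ",
              reject_k, ")")
      arr <- arr[!bad, , , drop = FALSE]
      events <- events[!bad, , drop = FALSE]
    }
  }
  smoothed <- smooth_tensor_array(arr, smooth_ms, sampling_rate)
  meta <- events[, setdiff(names(events), c("onset_sample", "onset_s")),
                 drop = FALSE]
  out <- trial_tensor(smoothed, time_ms, meta, electrodes,
                      sampling_rate = sampling_rate,
                      smoothing_window_ms = smooth_ms,
                      hfa_unsmoothed = arr)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Re-reference epochs to the mean of adjacent grid electrodes
#'
#' Subtracts from each electrode the mean HFA of all electrodes adjacent to
#' it on the same grid (a bipolar-style montage used to control for shared
#' far-field artifacts such as ocular muscle activity). Electrodes without
#' any neighbor are passed through unchanged with a warning.
#'
#' @param x a [trial_tensor()].
#' @param layout tibble mapping every electrode to a grid position:
#'   columns `electrode_id`, `grid`, `row`, `col`. Adjacency is sharing a
#'   grid and differing by one row or one column (4-connectivity).
#' @return a [trial_tensor()] with re-referenced `hfa` (and
#'   `hfa_unsmoothed`, when present).
#' @export
neighbor_rereference <- function(x, layout) {
  stopifnot(inherits(x, "trial_tensor"))
  layout <- tibble::as_tibble(layout)
  miss <- setdiff(x$electrodes$electrode_id, layout$electrode_id)
  if (length(miss))
    stop("layout missing electrodes: ", paste(miss, collapse = ", "))
  lay <- layout[match(x$electrodes$electrode_id, layout$electrode_id), ]
  n_el <- nrow(lay)
  nb <- lapply(seq_len(n_el), function(i) {
    same <- lay$grid == lay$grid[i]
    adj <- same & (abs(lay$row - lay$row[i]) + abs(lay$col - lay$col[i]) == 1)
    which(adj)
  })
  lonely <- lengths(nb) == 0
  if (any(lonely))
    warning(sum(lonely), " electrode(s) have no grid neighbor; ",
            "passed through unreferenced")
  reref <- function(arr) {
    out <- arr
    for (i in which(!lonely)) {
      m <- apply(arr[, nb[[i]], , drop = FALSE], c(1, 3), mean)
      out[, i, ] <- arr[, i, ] - m
    }
    out
  }
  x$hfa <- reref(x$hfa)
  if (!is.null(x$hfa_unsmoothed)) x$hfa_unsmoothed <- reref(x$hfa_unsmoothed)
  x
}

#' Downsample a trial tensor by decimation
#'
#' Keeps every k-th sample after smoothing (the moving-average smoothing
#' acts as the anti-alias step for envelope data). Used to bring epochs to
#' the 200 Hz analysis rate of the decoding and RSA stages.
#'
#' @param x a [trial_tensor()].
#' @param rate_hz target rate; the current rate must be an integer multiple.
#' @return a [trial_tensor()] at `rate_hz`.
#' @export
downsample_tensor <- function(x, rate_hz = 200) {
  stopifnot(inherits(x, "trial_tensor"))
  fac <- x$sampling_rate / rate_hz
  if (fac == 1) return(x)
  if (fac < 1 || abs(fac - round(fac)) > 1e-9)
    stop("current rate (", x$sampling_rate,
         " Hz) is not an integer multiple of ", rate_hz, " Hz")
  keep <- seq(1, length(x$time_ms), by = round(fac))
  out <- tt_index(x, time_idx = keep)
  out$sampling_rate <- rate_hz
  out
}
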