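#' Trial tensor: epoched HFA with trial and electrode metadata
#'
#' The universal exchange object of the package: a 3-D array of
#' baseline-corrected high-frequency activity (HFA) amplitude, dimensions
#' trials x electrodes x time, together with one tibble of trial metadata and
#' one of electrode metadata. All downstream analyses (electrode selection,
#' state-space trajectories, decoding, RSA) consume this object.
#'
#' @param hfa numeric array, trials x electrodes x time. Values are HFA
#'   amplitude in normalized units (1 = mean band amplitude), baseline
#'   subtracted.
#' @param time_ms numeric vector of time stamps in ms relative to stimulus
#'   onset; strictly increasing, length = dim(hfa)[3].
#' @param trials tibble with one row per trial: `trial_id`, `patient`,
#'   `category`, `exemplar_id`, `duration_ms`, `repetition`. Extra columns
#'   are preserved.
#' @param electrodes tibble with one row per electrode: `electrode_id`,
#'   `patient`, `region`. Extra columns (e.g. `sign`) are preserved.
#' @param sampling_rate sampling rate of the time axis in Hz.
#' @param smoothing_window_ms width of the moving-average smoothing already
#'   applied to `hfa` (0 if unsmoothed).
#' @param hfa_unsmoothed optional array of identical shape holding the
#'   baseline-corrected but unsmoothed signal. Electrode selection uses it so
#'   that window means are computed prior to smoothing.
#' @return object of class `trial_tensor`.
#' @export
trial_tensor <- function(hfa, time_ms, trials, electrodes,
                         sampling_rate, smoothing_window_ms = 0,
                         hfa_unsmoothed = NULL) {
  stopifnot(is.array(hfa), length(dim(hfa)) == 3)
  if (length(time_ms) != dim(hfa)[3])
    stop("time_ms length must equal the third dimension of hfa")
  if (any(diff(time_ms) <= 0)) stop("time axis must be strictly increasing")
  trials <- tibble::as_tibble(trials)
  electrodes <- tibble::as_tibble(electrodes)
  if (nrow(trials) != dim(hfa)[1])
    stop("trials metadata rows (", nrow(trials), ") != trials in hfa (",
         dim(hfa)[1], ")")
  if (nrow(electrodes) != dim(hfa)[2])
    stop("electrode metadata rows != electrodes in hfa")
  need_t <- c("trial_id", "patient", "category", "exemplar_id",
              "duration_ms", "repetition")
  miss <- setdiff(need_t, names(trials))
  if (length(miss)) stop("trials metadata missing columns: ",
                         paste(miss, collapse = ", "))
  need_e <- c("electrode_id", "patient", "region")
  miss <- setdiff(need_e, names(electrodes))
  if (length(miss)) stop("electrode metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(hfa_unsmoothed) && !identical(dim(hfa_unsmoothed), dim(hfa)))
    stop("hfa_unsmoothed must have the same dimensions as hfa")
  structure(
    list(hfa = hfa, time_ms = as.numeric(time_ms),
         trials = trials, electrodes = electrodes,
         sampling_rate = sampling_rate,
         smoothing_window_ms = smoothing_window_ms,
         hfa_unsmoothed = hfa_unsmoothed),
    class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$hfa)
  cat("<trial_tensor> ", d[1], " trials x ", d[2], " electrodes x ", d[3],
      " time points\n", sep = "")
  cat("  time: [", min(x$time_ms), ", ", max(x$time_ms), "] ms @ ",
      x$sampling_rate, " Hz; smoothing ", x$smoothing_window_ms, " ms\n",
      sep = "")
  cat("  patients: ", length(unique(x$electrodes$patient)),
      "; regions: ", paste(sort(unique(x$electrodes$region)), collapse = ", "),
      "\n", sep = "")
  cat("  categories: ",
      paste(names(sort(table(x$trials$category), decreasing = TRUE)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$hfa)

#' Subset a trial tensor
#'
#' `tt_subset()` restricts a [trial_tensor()] to trials and/or electrodes.
#' Trial and electrode predicates are tidy expressions evaluated on the
#' respective metadata tibbles, so the object composes with dplyr-style
#' filtering.
#'
#' @param x a `trial_tensor`.
#' @param trials expression on the trial metadata (e.g.
#'   `duration_ms >= 900`), or NULL to keep all.
#' @param electrodes expression on the electrode metadata (e.g.
#'   `region == "VT"`), or NULL.
#' @return a `trial_tensor` restricted to the matching rows.
#' @export
tt_subset <- function(x, trials = NULL, electrodes = NULL) {
  ti <- seq_len(nrow(x$trials))
  ei <- seq_len(nrow(x$electrodes))
  tq <- rlang::enquo(trials)
  eq <- rlang::enquo(electrodes)
  if (!rlang::quo_is_null(tq)) {
    keep <- rlang::eval_tidy(tq, data = x$trials)
    ti <- ti[keep]
  }
  if (!rlang::quo_is_null(eq)) {
    keep <- rlang::eval_tidy(eq, data = x$electrodes)
    ei <- ei[keep]
  }
  tt_index(x, ti, ei)
}

#' Index a trial tensor by position
#' @param x a `trial_tensor`.
#' @param trial_idx integer trial indices.
#' @param electrode_idx integer electrode indices.
#' @param time_idx integer time indices.
#' @return a `trial_tensor`.
#' @export
tt_index <- function(x, trial_idx = seq_len(dim(x$hfa)[1]),
                     electrode_idx = seq_len(dim(x$hfa)[2]),
                     time_idx = seq_len(dim(x$hfa)[3])) {
  trial_tensor(
    hfa = x$hfa[trial_idx, electrode_idx, time_idx, drop = FALSE],
    time_ms = x$time_ms[time_idx],
    trials = x$trials[trial_idx, , drop = FALSE],
    electrodes = x$electrodes[electrode_idx, , drop = FALSE],
    sampling_rate = x$sampling_rate,
    smoothing_window_ms = x$smoothing_window_ms,
    hfa_unsmoothed = if (!is.null(x$hfa_unsmoothed))
      x$hfa_unsmoothed[trial_idx, electrode_idx, time_idx, drop = FALSE])
}

#' Long-format view of a trial tensor
#'
#' Unfolds the HFA array into a tibble with one row per
#' trial x electrode x time sample, joined to the trial and electrode
#' metadata. Convenient for ggplot2 and dplyr summaries; the array form
#' remains the computational representation.
#'
#' @param x a `trial_tensor`.
#' @param ... unused.
#' @return tibble with columns trial_id, electrode_id, time_ms, hfa and the
#'   metadata columns.
#' @export
tidy.trial_tensor <- function(x, ...) {
  d <- dim(x$hfa)
  out <- tibble::tibble(
    trial_id = rep(x$trials$trial_id, times = d[2] * d[3]),
    electrode_id = rep(rep(x$electrodes$electrode_id, each = d[1]),
                       times = d[3]),
    time_ms = rep(x$time_ms, each = d[1] * d[2]),
    hfa = as.vector(x$hfa))
  out <- dplyr::left_join(out, x$trials, by = "trial_id")
  dplyr::left_join(out, x$electrodes,
                   by = "electrode_id", suffix = c("", "_electrode"))
}

#' Nearest time-axis index for a time in ms
#' @keywords internal
#' @noRd
tt_time_index <- function(x, t_ms) {
  vapply(t_ms, function(t) which.min(abs(x$time_ms - t)), integer(1))
}

#' Logical mask over the time axis for an interval [from, to) ms
#' @keywords internal
#' @noRd
tt_time_mask <- function(x, from, to, closed = FALSE) {
  if (closed) x$time_ms >= from & x$time_ms <= to
  else x$time_ms >= from & x$time_ms < to
}
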