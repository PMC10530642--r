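#' Select visually responsive electrodes
#'
#' Tests each electrode for a response to each stimulus category in four
#' non-overlapping stimulus-on windows (default 100-300, 300-500, 500-700,
#' 700-900 ms), using only trials of at least 900 ms duration. For every
#' category and window the mean signal in the window is compared to the mean
#' signal in the 200 ms before onset with a two-tailed paired t test; window
#' means are taken on the unsmoothed signal so smoothing cannot leak
#' information between windows. P values are Bonferroni-corrected across the
#' four windows implicitly by thresholding at `alpha / 4`, and
#' Benjamini-Hochberg FDR-corrected across electrodes within each
#' category-window family. An electrode is responsive if any test reaches
#' q < alpha/4; its response sign is the sign of the sum of t statistics
#' over all tests (all categories and windows).
#'
#' @param x a [trial_tensor()].
#' @param windows list of length-2 windows in ms.
#' @param baseline_ms pre-onset baseline length for the paired comparison.
#' @param alpha nominal level (threshold applied as `alpha / n_windows`).
#' @param min_duration_ms only trials at least this long are used.
#' @return tibble, one row per electrode x category x window: `t`, `p`, `q`,
#'   `window_significant`, plus electrode-level `responsive` and `sign`
#'   (+1/-1, NA for non-responsive electrodes). Categories with fewer than
#'   2 trials are skipped with a message.
#' @export
select_responsive <- function(x, windows = list(c(100, 300), c(300, 500),
                                                c(500, 700), c(700, 900)),
                              baseline_ms = 200, alpha = 0.05,
                              min_duration_ms = 900) {
  stopifnot(inherits(x, "trial_tensor"))
  xx <- tt_subset(x, trials = duration_ms >= min_duration_ms)
  arr <- xx$hfa_unsmoothed %||% xx$hfa
  time_ms <- xx$time_ms
  bl <- time_ms >= -baseline_ms & time_ms < 0
  cats <- sort(unique(xx$trials$category))
  n_el <- nrow(xx$electrodes)
  base_mean <- apply(arr[, , bl, drop = FALSE], c(1, 2), mean)

  rows <- list()
  for (cat in cats) {
    tri <- which(xx$trials$category == cat)
    if (length(tri) < 2) {
      message("category '", cat, "' has < 2 trials; tests skipped")
      next
    }
    for (wi in seq_along(windows)) {
      w <- windows[[wi]]
      tm <- time_ms >= w[1] & time_ms < w[2]
      wmean <- apply(arr[tri, , tm, drop = FALSE], c(1, 2), mean)
      tt <- vapply(seq_len(n_el), function(e) {
        r <- t.test(wmean[, e], base_mean[tri, e], paired = TRUE)
        c(r$statistic, r$p.value)
      }, numeric(2))
      rows[[length(rows) + 1]] <- tibble::tibble(
        electrode_id = xx$electrodes$electrode_id,
        category = cat,
        window = paste0(w[1], "-", w[2]),
        t = tt[1, ], p = tt[2, ],
        q = p.adjust(tt[2, ], method = "BH"))
    }
  }
  res <- dplyr::bind_rows(rows)
  res$window_significant <- res$q < alpha / length(windows)
  flags <- res |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::summarise(responsive = any(.data$window_significant),
                     t_sum = sum(.data$t), .groups = "drop") |>
    dplyr::mutate(sign = ifelse(.data$responsive, sign(.data$t_sum), NA))
  out <- dplyr::left_join(res, flags[, c("electrode_id", "responsive",
                                         "sign")], by = "electrode_id")
  out <- dplyr::left_join(out, x$electrodes, by = "electrode_id")
  class(out) <- c("electrode_selection", class(out))
  out
}

#' Select category-selective electrodes
#'
#' Same windowed scheme as [select_responsive()], but the per-window test is
#' a one-way ANOVA of the window means across the stimulus categories
#' (differential response), Bonferroni-corrected across windows and
#' FDR-corrected across electrodes.
#'
#' @inheritParams select_responsive
#' @return tibble, one row per electrode x window with `F`, `p`, `q`,
#'   `window_significant`, and electrode-level `selective`.
#' @export
select_selective <- function(x, windows = list(c(100, 300), c(300, 500),
                                               c(500, 700), c(700, 900)),
                             alpha = 0.05, min_duration_ms = 900) {
  stopifnot(inherits(x, "trial_tensor"))
  xx <- tt_subset(x, trials = duration_ms >= min_duration_ms)
  arr <- xx$hfa_unsmoothed %||% xx$hfa
  time_ms <- xx$time_ms
  grp <- factor(xx$trials$category)
  if (nlevels(grp) < 2) stop("need >= 2 categories")
  rows <- list()
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    tm <- time_ms >= w[1] & time_ms < w[2]
    wmean <- apply(arr[, , tm, drop = FALSE], c(1, 2), mean)
    st <- vapply(seq_len(ncol(wmean)), function(e) {
      a <- stats::anova(stats::lm(wmean[, e] ~ grp))
      c(a$`F value`[1], a$`Pr(>F)`[1])
    }, numeric(2))
    rows[[wi]] <- tibble::tibble(
      electrode_id = xx$electrodes$electrode_id,
      window = paste0(w[1], "-", w[2]),
      F = st[1, ], p = st[2, ],
      q = p.adjust(st[2, ], method = "BH"))
  }
  res <- dplyr::bind_rows(rows)
  res$window_significant <- res$q < alpha / length(windows)
  flags <- res |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::summarise(selective = any(.data$window_significant),
                     .groups = "drop")
  dplyr::left_join(res, flags, by = "electrode_id")
}

#' Point-by-point category selectivity (percent variance explained)
#'
#' For each electrode and time point, runs a one-way ANOVA across the
#' stimulus categories and reports 100 * eta-squared, the percent of
#' response variance explained by category. Computed on the smoothed traces
#' (matching plotted selectivity time courses). Time points with zero total
#' variance yield 0.
#'
#' @param x a [trial_tensor()].
#' @param electrode_ids electrodes to include (default all).
#' @param min_duration_ms restrict to trials at least this long.
#' @return tibble with `electrode_id`, `time_ms`, `eta2_pct` in [0, 100].
#' @export
selectivity_timecourse <- function(x, electrode_ids = NULL,
                                   min_duration_ms = 900) {
  stopifnot(inherits(x, "trial_tensor"))
  xx <- tt_subset(x, trials = duration_ms >= min_duration_ms)
  if (!is.null(electrode_ids))
    xx <- tt_subset(xx, electrodes = electrode_id %in% electrode_ids)
  grp <- factor(xx$trials$category)
  lv <- levels(grp)
  if (length(lv) < 2 || any(table(grp) < 2))
    stop("need >= 2 categories with >= 2 trials each")
  d <- dim(xx$hfa)
  out <- vector("list", d[2])
  for (e in seq_len(d[2])) {
    m <- xx$hfa[, e, ]                      # trials x time
    gm <- colMeans(m)
    sst <- colSums(sweep(m, 2, gm)^2)
    ssb <- numeric(d[3])
    for (g in lv) {
      i <- grp == g
      ssb <- ssb + sum(i) * (colMeans(m[i, , drop = FALSE]) - gm)^2
    }
    eta <- ifelse(sst > 0, 100 * ssb / sst, 0)
    out[[e]] <- tibble::tibble(
      electrode_id = xx$electrodes$electrode_id[e],
      time_ms = xx$time_ms, eta2_pct = eta)
  }
  dplyr::bind_rows(out)
}

#' Peak response and post-onset attenuation of a mean response
#'
#' Summarizes one mean HFA time course: the peak response `Presp` is the
#' maximal value between 0 and 900 ms after onset, `Eresp` is the mean
#' response 800-900 ms after onset, and the relative attenuation is
#' `100 * (Presp - Eresp) / Presp` (may exceed 100% when the late response
#' falls below baseline).
#'
#' @param response numeric vector, a mean HFA time course.
#' @param time_ms matching time axis in ms.
#' @param peak_window window for the peak search (ms).
#' @param end_window window for the late response (ms).
#' @return one-row tibble: `peak`, `peak_time_ms`, `end_mean`,
#'   `attenuation_pct`.
#' @export
response_summary <- function(response, time_ms,
                             peak_window = c(0, 900),
                             end_window = c(800, 900)) {
  stopifnot(length(response) == length(time_ms))
  pk <- time_ms >= peak_window[1] & time_ms <= peak_window[2]
  en <- time_ms >= end_window[1] & time_ms <= end_window[2]
  presp <- max(response[pk])
  pt <- time_ms[pk][which.max(response[pk])]
  eresp <- mean(response[en])
  tibble::tibble(peak = presp, peak_time_ms = pt, end_mean = eresp,
                 attenuation_pct = 100 * (presp - eresp) / presp)
}

#' Per-electrode response summaries for responsive electrodes
#'
#' For each responsive electrode, averages trials (duration >= 900 ms) of
#' the categories the electrode responds to and summarizes the mean time
#' course with [response_summary()]. Negative responders are sign-flipped
#' before summarizing so peak/attenuation refer to response magnitude.
#'
#' @param x a [trial_tensor()].
#' @param selection output of [select_responsive()] on the same data.
#' @return tibble, one row per responsive electrode, with region metadata.
#' @export
summarize_responses <- function(x, selection) {
  stopifnot(inherits(x, "trial_tensor"))
  resp_el <- selection |>
    dplyr::filter(.data$responsive) |>
    dplyr::distinct(.data$electrode_id, .data$sign)
  resp_cat <- selection |>
    dplyr::filter(.data$window_significant) |>
    dplyr::distinct(.data$electrode_id, .data$category)
  xx <- tt_subset(x, trials = duration_ms >= 900)
  out <- purrr::pmap_dfr(resp_el, function(electrode_id, sign) {
    cats <- resp_cat$category[resp_cat$electrode_id == electrode_id]
    ei <- match(electrode_id, xx$electrodes$electrode_id)
    tri <- xx$trials$category %in% cats
    m <- colMeans(xx$hfa[tri, ei, , drop = FALSE][, 1, ]) * sign
    dplyr::bind_cols(tibble::tibble(electrode_id = electrode_id,
                                    sign = sign),
                     response_summary(m, xx$time_ms))
  })
  dplyr::left_join(out, x$electrodes, by = "electrode_id")
}

#' Compare a per-electrode measure between regions
#'
#' One-way ANOVA of a value (e.g. attenuation, peak latency) across regions,
#' followed by Tukey-Kramer post-hoc pairwise comparisons and Cohen's d
#' (pooled-SD standardized mean difference) for each pair.
#'
#' @param data data frame with one row per electrode.
#' @param value column with the measure (tidy-eval).
#' @param group column with the group label (tidy-eval).
#' @return list of class `group_comparison`: `anova` (one-row tibble with
#'   `F`, `df_between`, `df_within`, `p`) and `posthoc` (tibble per pair
#'   with Tukey-adjusted p and Cohen's d).
#' @export
group_comparison <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data = data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data = data))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups with >= 2 members each")
  fit <- aov(v ~ g)
  a <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(F = a$`F value`[1],
                              df_between = a$Df[1], df_within = a$Df[2],
                              p = a$`Pr(>F)`[1])
  tk <- TukeyHSD(fit)$g
  pairs <- rownames(tk)
  d <- vapply(pairs, function(pr) {
    ab <- strsplit(pr, "-", fixed = TRUE)[[1]]
    x1 <- v[g == ab[1]]; x2 <- v[g == ab[2]]
    sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
                 (length(x1) + length(x2) - 2))
    (mean(x1) - mean(x2)) / sp
  }, numeric(1))
  posthoc <- tibble::tibble(pair = pairs, diff = tk[, "diff"],
                            p_adj = tk[, "p adj"], cohens_d = unname(d))
  structure(list(anova = anova_tbl, posthoc = posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("One-way ANOVA: F(", x$anova$df_between, ",", x$anova$df_within,
      ") = ", signif(x$anova$F, 4), ", p = ", signif(x$anova$p, 3), "\n",
      sep = "")
  print(x$posthoc)
  invisible(x)
}
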