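#' Condition-averaged state-space trajectory
#'
#' Averages the HFA of all trials matching a condition filter, per electrode
#' and time point, yielding the neural state vector sequence (electrodes x
#' time). Trajectories from multiple patients are merged automatically
#' because the electrode axis already concatenates all patients' electrodes.
#'
#' @param x a [trial_tensor()].
#' @param trials tidy expression selecting trials (e.g.
#'   `category == "face"`), or NULL for all.
#' @param electrodes tidy expression selecting electrodes, or NULL.
#' @param label optional condition label stored on the trajectory.
#' @return object of class `trajectory`: `states` (electrodes x time),
#'   `time_ms`, `electrode_id`, `label`, `n_trials`.
#' @export
condition_trajectory <- function(x, trials = NULL, electrodes = NULL,
                                 label = NULL) {
  xx <- tt_subset(x, trials = {{ trials }}, electrodes = {{ electrodes }})
  if (dim(xx$hfa)[1] < 1) stop("no trials match the condition filter")
  states <- apply(xx$hfa, c(2, 3), mean)
  structure(list(states = states, time_ms = xx$time_ms,
                 electrode_id = xx$electrodes$electrode_id,
                 label = label, n_trials = dim(xx$hfa)[1]),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$states), " electrodes x ", ncol(x$states),
      " time points", if (!is.null(x$label)) paste0(" [", x$label, "]"),
      "; ", x$n_trials, " trials\n", sep = "")
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(a$electrode_id, b$electrode_id))
    stop("trajectories have different electrode sets/order")
  if (!isTRUE(all.equal(a$time_ms, b$time_ms)))
    stop("trajectories have different time axes")
}

#' Multivariate response magnitude (distance from baseline)
#'
#' The L2 norm of the state vector at each time point. Because trials are
#' baseline corrected, the pre-stimulus state is the origin, so this is the
#' point-by-point Euclidean distance of the trajectory from baseline.
#'
#' @param traj a [condition_trajectory()].
#' @return tibble with `time_ms`, `distance` (>= 0).
#' @export
baseline_distance <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  tibble::tibble(time_ms = traj$time_ms,
                 distance = sqrt(colSums(traj$states^2)))
}

#' State transition speed
#'
#' Distance traveled by the state-space trajectory per millisecond:
#' `||s_t - s_(t-1)||`, rescaled by the sample step so that the value is
#' per-ms even on a decimated time axis.
#'
#' @param traj a [condition_trajectory()].
#' @param per_ms rescale to distance per 1 ms (default); otherwise distance
#'   per sample step.
#' @return tibble with `time_ms` (from the second sample) and `speed`.
#' @export
transition_speed <- function(traj, per_ms = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  d <- sqrt(colSums((traj$states[, -1, drop = FALSE] -
                       traj$states[, -ncol(traj$states), drop = FALSE])^2))
  if (per_ms) d <- d / diff(traj$time_ms)
  tibble::tibble(time_ms = traj$time_ms[-1], speed = d)
}

#' Distance between two trajectories
#'
#' Point-by-point Euclidean distance `||s1_t - s2_t||` between two
#' trajectories over the same electrodes and time axis (e.g. responses to
#' different stimulus durations). Symmetric in its arguments.
#'
#' @param a,b [condition_trajectory()] objects with identical electrode
#'   order and time axis.
#' @return tibble with `time_ms`, `distance`.
#' @export
trajectory_distance <- function(a, b) {
  stopifnot(inherits(a, "trajectory"), inherits(b, "trajectory"))
  check_aligned(a, b)
  tibble::tibble(time_ms = a$time_ms,
                 distance = sqrt(colSums((a$states - b$states)^2)))
}

#' Category selectivity index of state-space trajectories
#'
#' Dispersion of the per-category trajectories around their common mean:
#' at each time point, the square root of the mean (over categories) of the
#' squared Euclidean distance of each category trajectory from the mean
#' trajectory across categories - the multivariate analogue of a standard
#' deviation. Use [build_null()] with category shuffling and
#' [max_stat_test()] to z-score it against a permutation null.
#'
#' @param trajs list of [condition_trajectory()] objects, one per category.
#' @return tibble with `time_ms`, `index` (>= 0).
#' @export
category_selectivity_index <- function(trajs) {
  stopifnot(length(trajs) >= 2)
  for (t2 in trajs[-1]) check_aligned(trajs[[1]], t2)
  arr <- vapply(trajs, function(tr) tr$states,
                trajs[[1]]$states)                   # elec x time x cat
  m <- apply(arr, c(1, 2), mean)
  sq <- vapply(seq_along(trajs), function(ci)
    colSums((arr[, , ci] - m)^2), numeric(ncol(m)))  # time x cat
  tibble::tibble(time_ms = trajs[[1]]$time_ms,
                 index = sqrt(rowMeans(sq)))
}

#' Max-statistic permutation test for duration tracking
#'
#' Tests whether the state-space trajectory distance between two stimulus
#' durations exceeds chance, restricted to the interval where only the
#' longer stimulus is still on (default [short, long] ms, the only period
#' where a difference is expected). The null shuffles duration labels
#' across trials, rebuilds both surrogate trajectories, and recomputes the
#' distance series; family-wise control is by the max-statistic over time
#' points (one-sided).
#'
#' @param x a [trial_tensor()] (typically restricted to one region's
#'   responsive electrodes).
#' @param dur_pair the two durations in ms, short first.
#' @param window test window in ms (default `c(short, long)`).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param alpha family-wise level.
#' @return tibble from [max_stat_test()] with an added `time_ms` column.
#' @export
duration_test <- function(x, dur_pair = c(300, 900), window = dur_pair,
                          n_perm = 1000, seed = 1, alpha = 0.05) {
  stopifnot(inherits(x, "trial_tensor"))
  xx <- tt_subset(x, trials = duration_ms %in% dur_pair)
  labs <- xx$trials$duration_ms
  if (!all(dur_pair %in% labs)) stop("both durations must be present")
  tm <- which(xx$time_ms >= window[1] & xx$time_ms <= window[2])
  hfa <- xx$hfa[, , tm, drop = FALSE]
  d <- dim(hfa)
  flat <- matrix(hfa, nrow = d[1])          # trials x (electrode*time)
  stat_fn <- function(labels) {
    a <- colMeans(flat[labels == dur_pair[1], , drop = FALSE])
    b <- colMeans(flat[labels == dur_pair[2], , drop = FALSE])
    sqrt(colSums(matrix((a - b)^2, nrow = d[2])))
  }
  null <- build_null(stat_fn, labs, n_perm = n_perm, seed = seed,
                     scheme = "duration-label shuffle")
  out <- max_stat_test(null, stat_fn(labs), alpha = alpha)
  out$time_ms <- xx$time_ms[tm]
  out
}

#' Jackknife confidence interval for a trajectory statistic
#'
#' Leave-one-trial-out jackknife: in each iteration, one random trial per
#' patient and condition is dropped, the statistic is recomputed on the
#' remaining trials (per-patient trajectories merge automatically through
#' the concatenated electrode axis), and the distribution across iterations
#' is returned as the confidence interval. Iterations sample the
#' combinatorially many leave-one-out sets uniformly at random under a
#' fixed seed.
#'
#' @param x a [trial_tensor()].
#' @param statistic function `trial_tensor -> numeric` (scalar or vector).
#' @param condition_var name of the trial column defining conditions within
#'   which one trial is dropped per patient (default `"category"`).
#' @param n_iter number of jackknife iterations.
#' @param seed RNG seed.
#' @param probs CI quantiles.
#' @return list of class `jackknife_ci`: `values` (n_iter x statistic
#'   length), `ci` tibble with `index`, `lower`, `upper`, `median`.
#' @export
jackknife_ci <- function(x, statistic, condition_var = "category",
                         n_iter = 1000, seed = 1,
                         probs = c(0.025, 0.975)) {
  stopifnot(inherits(x, "trial_tensor"))
  set.seed(seed)
  grp <- interaction(x$trials$patient, x$trials[[condition_var]],
                     drop = TRUE)
  if (any(table(grp) < 2))
    stop("each patient must have >= 2 trials per condition")
  groups <- split(seq_along(grp), grp)
  vals <- NULL
  for (it in seq_len(n_iter)) {
    drop <- vapply(groups, function(g) g[sample.int(length(g), 1)],
                   integer(1))
    keep <- setdiff(seq_along(grp), drop)
    v <- statistic(tt_index(x, trial_idx = keep))
    if (is.null(vals)) vals <- matrix(0, n_iter, length(v))
    vals[it, ] <- v
  }
  ci <- tibble::tibble(
    index = seq_len(ncol(vals)),
    lower = apply(vals, 2, quantile, probs[1], names = FALSE),
    median = apply(vals, 2, median),
    upper = apply(vals, 2, quantile, probs[2], names = FALSE))
  structure(list(values = vals, ci = ci), class = "jackknife_ci")
}

#' PCA visualization helper for trajectories
#'
#' Projects one or more trajectories onto the leading principal components
#' of their pooled states. For visualization only; no inference uses it.
#'
#' @param trajs list of [condition_trajectory()] objects.
#' @param n_components components to keep (default 3).
#' @return tibble with `label`, `time_ms`, `PC1..PCk`.
#' @export
trajectory_pca <- function(trajs, n_components = 3) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  for (t2 in trajs[-1]) check_aligned(trajs[[1]], t2)
  pooled <- do.call(cbind, lapply(trajs, function(tr) tr$states))
  pc <- stats::prcomp(t(pooled), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  labs <- unlist(lapply(seq_along(trajs), function(i)
    rep(trajs[[i]]$label %||% paste0("traj", i), ncol(trajs[[i]]$states))))
  out <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  out$label <- labs
  out$time_ms <- unlist(lapply(trajs, function(tr) tr$time_ms))
  dplyr::relocate(out, "label", "time_ms")
}
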