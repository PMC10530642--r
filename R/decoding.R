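#' Prepare a balanced exemplar-level design for decoding
#'
#' Averages repetitions of each unique image into a single trial (so an
#' image can never appear in both training and testing sets), then
#' undersamples the category with more exemplars to balance the two
#' classes. Undersampling is random under the supplied RNG state, so
#' repeats of the cross-validation redraw the subset.
#'
#' @param x a [trial_tensor()].
#' @param pair character length-2: the two categories to decode.
#' @param min_duration_ms restrict to trials at least this long.
#' @return a [trial_tensor()] with one (averaged) trial per kept exemplar;
#'   both its arrays are repetition averages.
#' @export
prepare_exemplar_trials <- function(x, pair, min_duration_ms = 0) {
  stopifnot(inherits(x, "trial_tensor"), length(pair) == 2)
  xx <- tt_subset(x, trials = category %in% pair &
                    duration_ms >= min_duration_ms)
  if (!all(pair %in% xx$trials$category))
    stop("both categories must be present")
  ex <- unique(xx$trials$exemplar_id)
  d <- dim(xx$hfa)
  avg <- array(0, dim = c(length(ex), d[2], d[3]))
  meta <- vector("list", length(ex))
  for (i in seq_along(ex)) {
    rows <- which(xx$trials$exemplar_id == ex[i])
    avg[i, , ] <- apply(xx$hfa[rows, , , drop = FALSE], c(2, 3), mean)
    meta[[i]] <- xx$trials[rows[1], ]
    meta[[i]]$repetition <- NA_integer_
    meta[[i]]$trial_id <- ex[i]
  }
  meta <- dplyr::bind_rows(meta)
  out <- trial_tensor(avg, xx$time_ms, meta, xx$electrodes,
                      sampling_rate = xx$sampling_rate,
                      smoothing_window_ms = xx$smoothing_window_ms)
  n_by <- table(factor(meta$category, levels = pair))
  n_min <- min(n_by)
  keep <- unlist(lapply(pair, function(cat) {
    i <- which(meta$category == cat)
    if (length(i) > n_min) sort(sample(i, n_min)) else i
  }))
  tt_index(out, trial_idx = sort(keep))
}

# Ledoit-Wolf shrinkage weight toward the scaled identity nu*I
# (Schaefer-Strimmer form of the estimator on class-centered data)
ledoit_wolf_lambda <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  if (n < 2) return(1)
  Wbar <- crossprod(Xc) / n                 # mean of W_k = xc xc'
  S <- Wbar * n / (n - 1)
  nu <- sum(diag(S)) / p
  # Var(S_ij) = n/(n-1)^3 * sum_k (W_kij - Wbar_ij)^2
  sum_sq_dev <- matrix(0, p, p)
  for (k in seq_len(n)) {
    W <- tcrossprod(Xc[k, ])
    sum_sq_dev <- sum_sq_dev + (W - Wbar)^2
  }
  varS <- sum_sq_dev * n / (n - 1)^3
  target <- diag(nu, p)
  denom <- sum((S - target)^2)
  if (denom <= 0) return(0)
  min(1, max(0, sum(varS) / denom))
}

#' Fit a shrinkage-regularized LDA classifier
#'
#' Linear discriminant analysis for two classes with covariance shrinkage
#' toward the scaled identity: the pooled covariance (class covariances
#' weighted by their trial counts) is replaced by
#' `(1 - lambda) * Sigma + lambda * (trace(Sigma)/p) * I`, which preserves
#' the trace of the covariance. The classifier weights are
#' `w = Sigma_hat^{-1} (mu1 - mu2)`. With `lambda = "auto"` the shrinkage
#' weight is estimated by the Ledoit-Wolf formula from the training data.
#'
#' @param X numeric matrix trials x features (electrodes).
#' @param y two-level factor/vector of class labels; the first level is the
#'   positive class (higher decision values).
#' @param lambda `"auto"` or a number in [0, 1].
#' @return object of class `shrinkage_lda`: `w`, `mu1`, `mu2`, `Sigma`,
#'   `Sigma_hat`, `lambda`, `theta` (midpoint threshold), `levels`.
#' @export
fit_shrinkage_lda <- function(X, y, lambda = "auto") {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly 2 classes")
  if (any(table(y) < 2)) stop("need >= 2 trials per class")
  if (!all(is.finite(X))) stop("X contains non-finite values")
  lev <- levels(y)
  X1 <- X[y == lev[1], , drop = FALSE]
  X2 <- X[y == lev[2], , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X)
  Xc <- rbind(sweep(X1, 2, mu1), sweep(X2, 2, mu2))
  S1 <- crossprod(sweep(X1, 2, mu1)) / (n1 - 1)
  S2 <- crossprod(sweep(X2, 2, mu2)) / (n2 - 1)
  Sigma <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  lam <- if (identical(lambda, "auto")) ledoit_wolf_lambda(Xc)
         else as.numeric(lambda)
  if (lam < 0 || lam > 1) stop("lambda must be in [0, 1]")
  nu <- sum(diag(Sigma)) / p
  if (nu <= .Machine$double.eps) {
    # degenerate zero-variance data: fall back to the mean-difference
    # direction (scores are constant anyway when means also coincide)
    Sigma_hat <- diag(1, p)
  } else Sigma_hat <- (1 - lam) * Sigma + lam * nu * diag(p)
  w <- tryCatch(solve(Sigma_hat, mu1 - mu2),
                error = function(e)
                  stop("covariance is singular; use shrinkage ",
                       "(lambda = \"auto\" or > 0)", call. = FALSE))
  structure(list(w = w, mu1 = mu1, mu2 = mu2, Sigma = Sigma,
                 Sigma_hat = Sigma_hat, lambda = lam,
                 theta = sum(w * (mu1 + mu2)) / 2, levels = lev),
            class = "shrinkage_lda")
}

#' @export
predict.shrinkage_lda <- function(object, newdata, ...) {
  as.vector(as.matrix(newdata) %*% object$w)
}

#' Area under the ROC curve
#'
#' Threshold-free classifier performance: the probability that a randomly
#' drawn positive-class score outranks a randomly drawn negative-class
#' score, with ties counting one half. Computed by the rank statistic
#' (equivalent to integrating the ROC curve). 0.5 is chance, 1 perfect.
#'
#' @param scores numeric decision values.
#' @param labels logical (TRUE = positive class) or two-level factor whose
#'   first level is the positive class.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (!is.logical(labels)) {
    labels <- factor(labels)
    if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
    labels <- labels == levels(labels)[1]
  }
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 == 0 || n2 == 0) stop("both classes must be present")
  r <- rank(scores)                 # average ranks resolve ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# stratified fold assignment: both classes spread roughly equally over folds
stratified_folds <- function(y, n_folds) {
  f <- integer(length(y))
  for (lev in unique(y)) {
    i <- which(y == lev)
    f[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  f
}

# core CV engine: per repeat, undersampled + stratified folds; fits LDA per
# train time point per fold; returns AUC as train x test matrix (TGM) or
# only its diagonal (time-resolved), averaged over folds and repeats.
cv_lda_auc <- function(x, pair, n_folds = 5, n_repeats = 5,
                       lambda = "auto", seed = 1, tgm = FALSE,
                       label_shuffle = FALSE) {
  d <- dim(x$hfa)
  n_time <- d[3]
  acc <- if (tgm) matrix(0, n_time, n_time) else numeric(n_time)
  set.seed(seed)
  for (rep_i in seq_len(n_repeats)) {
    y <- factor(x$trials$category, levels = pair)
    if (label_shuffle) y <- y[sample(length(y))]   # same shuffle, all times
    folds <- stratified_folds(y, n_folds)
    fold_acc <- if (tgm) matrix(0, n_time, n_time) else numeric(n_time)
    for (f in seq_len(n_folds)) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) next
      Xte_all <- x$hfa[te, , , drop = FALSE]
      for (t1 in seq_len(n_time)) {
        m <- fit_shrinkage_lda(x$hfa[tr, , t1], y[tr], lambda = lambda)
        if (tgm) {
          sc <- apply(Xte_all, 3, function(M) M %*% m$w)  # n_te x n_time
          if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
          fold_acc[t1, ] <- fold_acc[t1, ] +
            apply(sc, 2, roc_auc, labels = y[te] == pair[1])
        } else {
          sc <- Xte_all[, , t1, drop = FALSE][, , 1] %*% m$w
          fold_acc[t1] <- fold_acc[t1] +
            roc_auc(as.vector(sc), y[te] == pair[1])
        }
      }
    }
    acc <- acc + fold_acc / n_folds
  }
  acc / n_repeats
}

new_decoding_result <- function(kind, auc, tgm = NULL, time_ms, pair,
                               n_per_class, cv, clusters = NULL) {
  structure(list(kind = kind, auc = auc, tgm = tgm, time_ms = time_ms,
                 pair = pair, n_per_class = n_per_class, cv = cv,
                 clusters = clusters), class = "decoding_result")
}

#' Time-resolved pairwise category decoding
#'
#' Trains one shrinkage-LDA classifier per time point to distinguish two
#' stimulus categories from the multi-electrode HFA pattern, scoring with
#' cross-validated AUC. Repetitions of each image are averaged, the larger
#' class is undersampled (redrawn at each repeat), folds are stratified,
#' and the five-fold cross-validation is repeated five times and averaged.
#' The shrinkage weight is estimated on training folds only.
#'
#' @param x a [trial_tensor()] (subset to the electrodes of interest first,
#'   e.g. one region's responsive electrodes).
#' @param pair character length-2: categories to decode; the first is the
#'   positive class.
#' @param n_folds,n_repeats cross-validation scheme (default 5 x 5).
#' @param lambda `"auto"` (Ledoit-Wolf) or fixed shrinkage in [0, 1].
#' @param downsample_hz analysis rate; data are decimated to this rate
#'   first (NULL to keep the input rate).
#' @param min_duration_ms restrict to trials at least this long.
#' @param seed RNG seed (fold assignment and undersampling).
#' @return `decoding_result` with `auc` tibble (`time_ms`, `auc`), peak AUC
#'   and peak time via [glance.decoding_result()].
#' @export
time_resolved_decoding <- function(x, pair, n_folds = 5, n_repeats = 5,
                                   lambda = "auto", downsample_hz = 200,
                                   min_duration_ms = 0, seed = 1) {
  if (!is.null(downsample_hz) && x$sampling_rate != downsample_hz)
    x <- downsample_tensor(x, downsample_hz)
  set.seed(sub_seed(seed, 1L))
  prep <- prepare_exemplar_trials(x, pair, min_duration_ms)
  auc <- cv_lda_auc(prep, pair, n_folds, n_repeats, lambda,
                    seed = sub_seed(seed, 2L), tgm = FALSE)
  new_decoding_result(
    "timecourse",
    auc = tibble::tibble(time_ms = prep$time_ms, auc = auc),
    time_ms = prep$time_ms, pair = pair,
    n_per_class = unname(table(prep$trials$category)[pair]),
    cv = list(n_folds = n_folds, n_repeats = n_repeats, seed = seed))
}

#' Temporal generalization matrix (TGM)
#'
#' Trains a classifier at every time point and tests it at every time
#' point, under the same cross-validation folds for all test times. A
#' "rectangular" TGM (off-diagonal performance close to the diagonal)
#' indicates a stable coding direction; a diagonal-limited TGM indicates a
#' dynamic code. The TGM diagonal equals the time-resolved AUC under
#' identical folds.
#'
#' @inheritParams time_resolved_decoding
#' @return `decoding_result` with `tgm` (train x test AUC matrix) and
#'   `auc` (its diagonal as a tibble).
#' @export
temporal_generalization <- function(x, pair, n_folds = 5, n_repeats = 5,
                                    lambda = "auto", downsample_hz = 200,
                                    min_duration_ms = 0, seed = 1) {
  if (!is.null(downsample_hz) && x$sampling_rate != downsample_hz)
    x <- downsample_tensor(x, downsample_hz)
  set.seed(sub_seed(seed, 1L))
  prep <- prepare_exemplar_trials(x, pair, min_duration_ms)
  tgm <- cv_lda_auc(prep, pair, n_folds, n_repeats, lambda,
                    seed = sub_seed(seed, 2L), tgm = TRUE)
  dimnames(tgm) <- list(train = prep$time_ms, test = prep$time_ms)
  new_decoding_result(
    "tgm",
    auc = tibble::tibble(time_ms = prep$time_ms, auc = diag(tgm)),
    tgm = tgm, time_ms = prep$time_ms, pair = pair,
    n_per_class = unname(table(prep$trials$category)[pair]),
    cv = list(n_folds = n_folds, n_repeats = n_repeats, seed = seed))
}

#' Permutation null for decoding time courses or TGMs
#'
#' Builds the label-shuffle null for significance testing: in each
#' permutation the category labels are permuted across (exemplar-averaged)
#' trials, the same permuted labels are used for all time points, and the
#' full cross-validated decoding is re-run (reusing the observed fold
#' scheme policy). The result feeds [max_stat_test()] (peak decoding) or
#' [cluster_test()] (time courses and TGMs, first-level AUC 0.60).
#'
#' @inheritParams time_resolved_decoding
#' @param n_perm number of permutations.
#' @param tgm build the null over the full train x test matrix.
#' @return a `perm_null` object (rows are flattened column-major for TGMs).
#' @export
decoding_null <- function(x, pair, n_perm = 200, n_folds = 5,
                          n_repeats = 1, lambda = "auto",
                          downsample_hz = 200, min_duration_ms = 0,
                          seed = 1, tgm = FALSE) {
  if (!is.null(downsample_hz) && x$sampling_rate != downsample_hz)
    x <- downsample_tensor(x, downsample_hz)
  set.seed(sub_seed(seed, 1L))
  prep <- prepare_exemplar_trials(x, pair, min_duration_ms)
  n_stat <- if (tgm) length(prep$time_ms)^2 else length(prep$time_ms)
  pm <- matrix(0, n_perm, n_stat)
  for (i in seq_len(n_perm)) {
    v <- cv_lda_auc(prep, pair, n_folds, n_repeats, lambda,
                    seed = sub_seed(seed, 100L + i), tgm = tgm,
                    label_shuffle = TRUE)
    pm[i, ] <- as.vector(v)
  }
  structure(list(perm_matrix = pm, col_mean = colMeans(pm),
                 col_sd = apply(pm, 2, sd), n_perm = n_perm,
                 scheme = "category-label shuffle", seed = seed),
            class = "perm_null")
}

#' Mean generalization curves per training block
#'
#' Averages TGM rows within consecutive training-time blocks (default
#' 200 ms), giving one generalization-over-test-time curve per block.
#'
#' @param result a `decoding_result` with a TGM.
#' @param block_ms training-block width in ms.
#' @return tibble with `train_block`, `test_time_ms`, `auc`.
#' @export
tgm_block_curves <- function(result, block_ms = 200) {
  stopifnot(inherits(result, "decoding_result"), !is.null(result$tgm))
  t_ms <- result$time_ms
  blk <- floor((t_ms - min(t_ms)) / block_ms)
  purrr::map_dfr(unique(blk), function(b) {
    rows <- blk == b
    tibble::tibble(
      train_block = sprintf("%g-%g ms", min(t_ms[rows]), max(t_ms[rows])),
      test_time_ms = t_ms,
      auc = colMeans(result$tgm[rows, , drop = FALSE]))
  })
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> ", x$kind, ": ", paste(x$pair, collapse = " vs "),
      "; n/class = ", paste(x$n_per_class, collapse = "/"),
      "; CV ", x$cv$n_folds, "x", x$cv$n_repeats, "\n", sep = "")
  pk <- which.max(x$auc$auc)
  cat("  peak AUC ", round(x$auc$auc[pk], 3), " at ",
      x$auc$time_ms[pk], " ms\n", sep = "")
  invisible(x)
}
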