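#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a decoding result
#'
#' Time courses unfold to one row per time point; TGMs to one row per
#' train x test cell.
#'
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return tibble.
#' @method tidy decoding_result
#' @export
tidy.decoding_result <- function(x, ...) {
  if (!is.null(x$tgm)) {
    tibble::tibble(
      train_time_ms = rep(x$time_ms, times = length(x$time_ms)),
      test_time_ms = rep(x$time_ms, each = length(x$time_ms)),
      auc = as.vector(x$tgm))
  } else x$auc
}

#' One-row summary of a decoding result
#' @param x a `decoding_result`.
#' @param ... unused.
#' @return tibble with peak AUC, its time, class sizes and CV scheme.
#' @method glance decoding_result
#' @export
glance.decoding_result <- function(x, ...) {
  pk <- which.max(x$auc$auc)
  tibble::tibble(pair = paste(x$pair, collapse = " vs "),
                 peak_auc = x$auc$auc[pk],
                 peak_time_ms = x$auc$time_ms[pk],
                 n_class_1 = x$n_per_class[1], n_class_2 = x$n_per_class[2],
                 n_folds = x$cv$n_folds, n_repeats = x$cv$n_repeats)
}

#' @method tidy reliability_result
#' @export
tidy.reliability_result <- function(x, ...) x$timecourse

#' @method glance reliability_result
#' @export
glance.reliability_result <- function(x, ...) {
  pk <- which.max(x$timecourse$z)
  tibble::tibble(statistic = x$statistic, metric = x$metric,
                 peak_z = x$timecourse$z[pk],
                 peak_time_ms = x$timecourse$time_ms[pk],
                 n_exemplars = x$n_exemplars, n_perm = x$n_perm,
                 partialed = !is.null(x$model))
}

#' @method tidy stability_matrix
#' @export
tidy.stability_matrix <- function(x, ...) {
  Tn <- length(x$time_ms)
  tibble::tibble(
    t1_ms = rep(x$time_ms, times = Tn),
    t2_ms = rep(x$time_ms, each = Tn),
    raw = as.vector(x$raw), z = as.vector(x$z), p = as.vector(x$p),
    significant = as.vector(x$fdr_mask))
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$posthoc

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) x$anova

#' @method tidy jackknife_ci
#' @export
tidy.jackknife_ci <- function(x, ...) x$ci

#' @method tidy model_correlation
#' @export
tidy.model_correlation <- function(x, ...) x$timecourse
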