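#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_hline
#'   geom_ribbon labs scale_fill_gradient2 theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a decoding result
#'
#' Time courses are drawn as AUC against time with the chance line; TGMs
#' as a train x test heat map centered on chance.
#'
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  if (!is.null(object$tgm)) {
    ggplot(tidy(object),
           aes(x = .data$test_time_ms, y = .data$train_time_ms,
               fill = .data$auc)) +
      geom_tile() +
      scale_fill_gradient2(midpoint = 0.5, low = "steelblue",
                           mid = "white", high = "firebrick") +
      labs(x = "test time (ms)", y = "train time (ms)", fill = "AUC",
           title = paste(object$pair, collapse = " vs ")) +
      theme_minimal()
  } else {
    ggplot(object$auc, aes(x = .data$time_ms, y = .data$auc)) +
      geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
      geom_line() +
      labs(x = "time (ms)", y = "AUC",
           title = paste(object$pair, collapse = " vs ")) +
      theme_minimal()
  }
}

#' Plot a reliability time course
#' @param object a `reliability_result`.
#' @param threshold first-level z threshold drawn as a reference line.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot reliability_result
#' @export
autoplot.reliability_result <- function(object, threshold = 1.5, ...) {
  ggplot(object$timecourse, aes(x = .data$time_ms, y = .data$z)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_hline(yintercept = threshold, linetype = 2, colour = "grey50") +
    geom_line() +
    labs(x = "time (ms)", y = paste0(object$statistic, " (z)")) +
    theme_minimal()
}

#' Plot a temporal stability matrix
#' @param object a `stability_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot stability_matrix
#' @export
autoplot.stability_matrix <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$t2_ms, y = .data$t1_ms,
                           fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick") +
    labs(x = "t2 (ms)", y = "t1 (ms)", fill = paste0(object$statistic,
                                                     " z")) +
    theme_minimal()
}

#' Plot state-space trajectories in PCA space
#'
#' @param trajs list of [condition_trajectory()] objects.
#' @param ... passed to [trajectory_pca()].
#' @return a ggplot of PC1 vs PC2 paths (visualization only).
#' @export
plot_trajectories <- function(trajs, ...) {
  d <- trajectory_pca(trajs, ...)
  ggplot(d, aes(x = .data$PC1, y = .data$PC2, colour = .data$label)) +
    geom_line() +
    labs(colour = "condition") +
    theme_minimal()
}
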