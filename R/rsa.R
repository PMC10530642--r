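#' Extract per-presentation response patterns for exemplar-level analyses
#'
#' Restricts the data to unique images presented at least twice for at
#' least `min_duration_ms`, keeps the first two repetitions of each, and
#' returns the multi-electrode response pattern of every presentation at
#' every (downsampled) time point.
#'
#' @param x a [trial_tensor()].
#' @param min_duration_ms minimal stimulus duration (default 900 ms).
#' @param downsample_hz analysis rate (NULL keeps the input rate).
#' @param time_window optional c(from, to) ms to restrict the time axis.
#' @param time_step keep every `time_step`-th sample of the (downsampled)
#'   axis, to bound the cost of permutation-heavy analyses.
#' @param smooth_ms optional extra smoothing (e.g. 100 ms for
#'   single-category analyses) applied before extraction.
#' @return list of class `rsa_presentations`: `pat` array
#'   [exemplar, repetition (2), electrode, time], `exemplars` tibble,
#'   `time_ms`, `metric_size` (number of exemplar pairs).
#' @export
rsa_presentations <- function(x, min_duration_ms = 900,
                              downsample_hz = 200, time_window = NULL,
                              time_step = 1, smooth_ms = NULL) {
  stopifnot(inherits(x, "trial_tensor"))
  if (!is.null(smooth_ms)) {
    x$hfa <- smooth_tensor_array(x$hfa_unsmoothed %||% x$hfa, smooth_ms,
                                 x$sampling_rate)
    x$smoothing_window_ms <- smooth_ms
  }
  if (!is.null(downsample_hz) && x$sampling_rate != downsample_hz)
    x <- downsample_tensor(x, downsample_hz)
  if (!is.null(time_window))
    x <- tt_index(x, time_idx = which(x$time_ms >= time_window[1] &
                                        x$time_ms <= time_window[2]))
  if (time_step > 1)
    x <- tt_index(x, time_idx = seq(1, length(x$time_ms), by = time_step))
  ok <- x$trials$duration_ms >= min_duration_ms
  tr <- x$trials[ok, ]
  counts <- table(tr$exemplar_id)
  keep_ex <- names(counts)[counts >= 2]
  if (length(keep_ex) < 4)
    stop("need >= 4 exemplars viewed at least twice for >= ",
         min_duration_ms, " ms")
  exemplars <- dplyr::distinct(tr[tr$exemplar_id %in% keep_ex, ],
                               .data$exemplar_id, .data$category)
  exemplars <- dplyr::arrange(exemplars, .data$exemplar_id)
  N <- nrow(exemplars)
  d <- dim(x$hfa)
  pat <- array(0, dim = c(N, 2, d[2], d[3]))
  all_idx <- which(ok)
  for (i in seq_len(N)) {
    rows <- all_idx[tr$exemplar_id == exemplars$exemplar_id[i]]
    rows <- rows[order(x$trials$repetition[rows])][1:2]
    pat[i, 1, , ] <- x$hfa[rows[1], , ]
    pat[i, 2, , ] <- x$hfa[rows[2], , ]
  }
  structure(list(pat = pat, exemplars = exemplars, time_ms = x$time_ms,
                 n_pairs = N * (N - 1) / 2),
            class = "rsa_presentations")
}

#' Representational dissimilarity matrix at one time point
#'
#' Pairwise dissimilarities between multi-electrode response patterns:
#' correlation dissimilarity `1 - r` (Pearson; range [0, 2]) or Euclidean
#' distance. Symmetric with a zero diagonal.
#'
#' @param patterns matrix presentations x electrodes.
#' @param metric `"correlation"` or `"euclidean"`.
#' @return square dissimilarity matrix.
#' @export
compute_rdm <- function(patterns, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(patterns) < 2) stop("need >= 2 presentations")
  m <- if (metric == "correlation") 1 - cor(t(patterns))
       else as.matrix(dist(patterns))
  diag(m) <- 0
  m
}

# cross-repetition dissimilarities: D[i, j] = d(P1_i, P2_j)
cross_rdm <- function(P1, P2, metric) {
  if (metric == "correlation") 1 - cor(t(P1), t(P2))
  else {
    s1 <- rowSums(P1^2); s2 <- rowSums(P2^2)
    sqrt(pmax(outer(s1, s2, "+") - 2 * tcrossprod(P1, P2), 0))
  }
}

sp_cor <- function(a, b) cor(a, b, method = "spearman")

# Spearman partial correlation of a and b given covariate z
# (Pearson on average ranks)
sp_partial <- function(a, b, z) {
  ra <- rank(a); rb <- rank(b); rz <- rank(z)
  if (sd(rz) == 0) return(cor(ra, rb))
  rab <- cor(ra, rb); raz <- cor(ra, rz); rbz <- cor(rb, rz)
  den <- sqrt((1 - raz^2) * (1 - rbz^2))
  if (den == 0) return(NA_real_)
  (rab - raz * rbz) / den
}

# Item Reliability core: mean over all 2N presentations of the Spearman
# (partial) correlation between the anchor's within-repetition and
# between-repetition dissimilarity vectors. pi1/pi2 permute the identity of
# the exemplars of repetition 1 / 2 when building the *other*-repetition
# vector (the anchor itself is never permuted).
ir_core <- function(W1, W2, B, pi1 = NULL, pi2 = NULL, model = NULL) {
  N <- nrow(W1)
  if (is.null(pi1)) pi1 <- seq_len(N)
  if (is.null(pi2)) pi2 <- seq_len(N)
  tot <- 0
  for (i in seq_len(N)) {
    j <- setdiff(seq_len(N), i)
    a1 <- W1[i, j]; b1 <- B[i, pi2[j]]
    a2 <- W2[i, j]; b2 <- B[pi1[j], i]
    if (is.null(model)) {
      tot <- tot + sp_cor(a1, b1) + sp_cor(a2, b2)
    } else {
      m <- model[i, j]
      tot <- tot + sp_partial(a1, b1, m) + sp_partial(a2, b2, m)
    }
  }
  tot / (2 * N)
}

# Geometry Reliability core: Geometry 1 pairs the within-repetition-1
# dissimilarities with one between-repetition set, Geometry 2 pairs
# within-repetition-2 with the other; the two averaged geometries are
# Spearman-correlated (unfolded over exemplar pairs). pi2 relabels the
# repetition-2 exemplars (the shuffle null).
gr_core <- function(W1, W2, B, pi2 = NULL, model = NULL) {
  N <- nrow(W1)
  if (!is.null(pi2)) {
    W2 <- W2[pi2, pi2]
    B <- B[, pi2]
  }
  ut <- upper.tri(W1)
  g1 <- (W1[ut] + B[ut]) / 2
  g2 <- (W2[ut] + t(B)[ut]) / 2
  if (is.null(model)) sp_cor(g1, g2) else sp_partial(g1, g2, model[ut])
}

reliability_engine <- function(pres, statistic, metric, n_perm, seed,
                               model = NULL) {
  pat <- pres$pat
  N <- dim(pat)[1]; Tn <- dim(pat)[4]
  if (N < 4) stop("need >= 4 exemplars (correlation degenerate below that)")
  set.seed(seed)
  perms1 <- replicate(n_perm, sample.int(N))
  perms2 <- replicate(n_perm, sample.int(N))
  raw <- numeric(Tn)
  pm <- matrix(0, n_perm, Tn)
  for (t in seq_len(Tn)) {
    P1 <- pat[, 1, , t]; P2 <- pat[, 2, , t]
    W1 <- compute_rdm(P1, metric); W2 <- compute_rdm(P2, metric)
    B <- cross_rdm(P1, P2, metric)
    if (statistic == "IR") {
      raw[t] <- ir_core(W1, W2, B, model = model)
      for (p in seq_len(n_perm))
        pm[p, t] <- ir_core(W1, W2, B, pi1 = perms1[, p],
                            pi2 = perms2[, p], model = model)
    } else {
      raw[t] <- gr_core(W1, W2, B, model = model)
      for (p in seq_len(n_perm))
        pm[p, t] <- gr_core(W1, W2, B, pi2 = perms2[, p], model = model)
    }
  }
  mu <- colMeans(pm); sdv <- apply(pm, 2, sd)
  zdiv <- ifelse(sdv > 0, sdv, Inf)
  z <- (raw - mu) / zdiv
  perm_z <- sweep(sweep(pm, 2, mu), 2, zdiv, "/")
  structure(list(
    statistic = statistic, metric = metric,
    timecourse = tibble::tibble(time_ms = pres$time_ms, raw = raw, z = z),
    perm_z = perm_z, perm_raw = pm, n_perm = n_perm, seed = seed,
    model = model, n_exemplars = N), class = "reliability_result")
}

#' Item Reliability across stimulus repetitions
#'
#' For each stimulus presentation, correlates (Spearman) the vector of its
#' dissimilarities to all other images within its own repetition with the
#' vector of its dissimilarities to all other images of the other
#' repetition, averages across images and repetitions, and z-scores the
#' result per time point against a null built by shuffling the stimulus
#' identity of the other repetition's images (the anchor presentation is
#' never permuted). High values mean each exemplar keeps its location in
#' the representational geometry across repetitions.
#'
#' @param pres an [rsa_presentations()] object.
#' @param metric dissimilarity metric, `"correlation"` or `"euclidean"`.
#' @param n_perm permutations for the null (default 1000).
#' @param seed RNG seed.
#' @param partial_model optional [category_model_rdm()] matrix (or model
#'   name) to partial out: the plain correlation is replaced by a Spearman
#'   partial correlation given the model's dissimilarity row (IR) so that
#'   reliability beyond category structure is measured.
#' @return `reliability_result`: `timecourse` tibble (`time_ms`, `raw`,
#'   `z`), the z-scored permutation matrix (for cluster testing), and
#'   metadata.
#' @export
item_reliability <- function(pres, metric = "correlation", n_perm = 1000,
                             seed = 1, partial_model = NULL) {
  model <- resolve_model(partial_model, pres)
  reliability_engine(pres, "IR", metric, n_perm, seed, model)
}

#' Geometry Reliability across stimulus repetitions
#'
#' Compares the full dissimilarity structure across repetitions: the
#' cross-repetition RDM over all presentations is split into within- and
#' between-repetition dissimilarity sets, each within set is paired with
#' one between set and averaged (Geometry 1 and Geometry 2), and the two
#' geometries are Spearman-correlated, z-scored against a null that
#' shuffles the identity of all single exemplars in repetition 2. When
#' exemplars within a category are represented identically, GR is expected
#' to be insignificant even if the geometry is maintained - it tests both
#' reliability and exemplar discriminability.
#'
#' @inheritParams item_reliability
#' @param partial_model optional model RDM to partial out (full unfolded
#'   vector for GR).
#' @return `reliability_result` (see [item_reliability()]).
#' @export
geometry_reliability <- function(pres, metric = "correlation",
                                 n_perm = 1000, seed = 1,
                                 partial_model = NULL) {
  model <- resolve_model(partial_model, pres)
  reliability_engine(pres, "GR", metric, n_perm, seed, model)
}

resolve_model <- function(model, pres) {
  if (is.null(model)) return(NULL)
  if (is.character(model))
    model <- category_model_rdm(model, pres$exemplars$category)
  stopifnot(is.matrix(model), nrow(model) == nrow(pres$exemplars))
  model
}

#' Cluster-based significance of a reliability time course
#'
#' Clusters the z-scored reliability time course at a first-level
#' threshold (z = 1.5 for 50-ms smoothed analyses, 0.75 for 100-ms
#' single-category analyses), with the sum of reliability indices as the
#' cluster statistic, against the null of maximal cluster statistics from
#' the z-scored permutation series (one-sided).
#'
#' @param rel a `reliability_result`.
#' @param threshold first-level z threshold.
#' @param alpha family-wise level.
#' @return tibble of clusters (see [cluster_test()]).
#' @export
reliability_clusters <- function(rel, threshold = 1.5, alpha = 0.05) {
  stopifnot(inherits(rel, "reliability_result"))
  out <- cluster_test(rel$timecourse$z, rel$perm_z, threshold,
                      alpha = alpha)
  attr(out, "time_ms") <- rel$timecourse$time_ms
  out
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("<reliability_result> ", x$statistic, " (", x$metric, "), ",
      x$n_exemplars, " exemplars, ", x$n_perm, " permutations",
      if (!is.null(x$model)) ", model partialed out", "\n", sep = "")
  cat("  max z = ", round(max(x$timecourse$z), 2), " at ",
      x$timecourse$time_ms[which.max(x$timecourse$z)], " ms\n", sep = "")
  invisible(x)
}

#' Temporal stability matrix of exemplar representation
#'
#' Generalizes the reliability statistics across time: entry (t1, t2)
#' correlates the dissimilarity structure of one repetition at t1 with the
#' between-repetition structure at t2 (IR variant anchors each
#' presentation; GR variant correlates Geometry 1 at t1 with Geometry 2 at
#' t2). Because the two structures always involve different repetitions,
#' spontaneous temporally-correlated fluctuations cannot inflate the
#' off-diagonal. The diagonal equals the corresponding reliability time
#' course. Cells are z-scored against the same shuffle nulls; point-by-
#' point p values are FDR-corrected.
#'
#' @param pres an [rsa_presentations()] object.
#' @param statistic `"IR"` or `"GR"`.
#' @param metric dissimilarity metric.
#' @param n_perm permutations per cell's null.
#' @param seed RNG seed.
#' @param q FDR level for the significance mask.
#' @param partial_model optional model RDM to partial out.
#' @return list of class `stability_matrix`: `raw`, `z`, `p` (T x T
#'   matrices), `fdr_mask`, `time_ms`, `statistic`.
#' @export
stability_matrix <- function(pres, statistic = c("IR", "GR"),
                             metric = "correlation", n_perm = 200,
                             seed = 1, q = 0.05, partial_model = NULL) {
  statistic <- match.arg(statistic)
  model <- resolve_model(partial_model, pres)
  pat <- pres$pat
  N <- dim(pat)[1]; Tn <- dim(pat)[4]
  set.seed(seed)
  perms1 <- replicate(n_perm, sample.int(N))
  perms2 <- replicate(n_perm, sample.int(N))
  W1l <- vector("list", Tn); W2l <- W1l; Bl <- W1l
  for (t in seq_len(Tn)) {
    P1 <- pat[, 1, , t]; P2 <- pat[, 2, , t]
    W1l[[t]] <- compute_rdm(P1, metric)
    W2l[[t]] <- compute_rdm(P2, metric)
    Bl[[t]] <- cross_rdm(P1, P2, metric)
  }
  raw <- matrix(0, Tn, Tn); zm <- raw; pm_p <- raw
  ut <- upper.tri(W1l[[1]])
  for (t1 in seq_len(Tn)) for (t2 in seq_len(Tn)) {
    if (statistic == "IR") {
      obs <- ir_stab(W1l[[t1]], W2l[[t1]], Bl[[t2]], model = model)
      nulls <- vapply(seq_len(n_perm), function(p)
        ir_stab(W1l[[t1]], W2l[[t1]], Bl[[t2]], perms1[, p], perms2[, p],
                model = model), numeric(1))
    } else {
      g1 <- (W1l[[t1]][ut] + Bl[[t1]][ut]) / 2
      obs <- gr_stab(g1, W2l[[t2]], Bl[[t2]], NULL, ut, model)
      nulls <- vapply(seq_len(n_perm), function(p)
        gr_stab(g1, W2l[[t2]], Bl[[t2]], perms2[, p], ut, model),
        numeric(1))
    }
    raw[t1, t2] <- obs
    s <- sd(nulls)
    zm[t1, t2] <- if (s > 0) (obs - mean(nulls)) / s else 0
    pm_p[t1, t2] <- (1 + sum(nulls >= obs)) / (n_perm + 1)
  }
  mask <- matrix(fdr_bh(as.vector(pm_p), q), Tn, Tn)
  structure(list(raw = raw, z = zm, p = pm_p, fdr_mask = mask,
                 time_ms = pres$time_ms, statistic = statistic),
            class = "stability_matrix")
}

# IR stability cell: within-repetition structure at t1 vs between-repetition
# structure at t2
ir_stab <- function(W1_t1, W2_t1, B_t2, pi1 = NULL, pi2 = NULL,
                    model = NULL) {
  ir_core(W1_t1, W2_t1, B_t2, pi1 = pi1, pi2 = pi2, model = model)
}

# GR stability cell: Geometry 1 at t1 vs Geometry 2 at t2
gr_stab <- function(g1, W2_t2, B_t2, pi2, ut, model) {
  if (!is.null(pi2)) {
    W2_t2 <- W2_t2[pi2, pi2]
    B_t2 <- B_t2[, pi2]
  }
  g2 <- (W2_t2[ut] + t(B_t2)[ut]) / 2
  if (is.null(model)) sp_cor(g1, g2) else sp_partial(g1, g2, model[ut])
}

#' Category-model RDM
#'
#' Model dissimilarity matrices encoding category structure over a set of
#' presentations: 0 within a category, 0.5 between categories that belong
#' to the same higher-order group, 1 otherwise. Models: `"single-category"`
#' (no relation between categories), `"low-level"` (faces+watches vs
#' objects+animals, grouping by low-level visual similarity), `"semantic"`
#' (animate faces+animals vs inanimate watches+objects), `"face-vs-rest"`
#' (faces distinct from all other categories, which form one group).
#'
#' @param model model id.
#' @param categories character vector of the category of each presentation
#'   (values among face, watch, object, animal).
#' @return symmetric matrix with entries in {0, 0.5, 1}, zero diagonal.
#' @export
category_model_rdm <- function(model = c("single-category", "low-level",
                                         "semantic", "face-vs-rest"),
                               categories) {
  model <- match.arg(model)
  groups <- switch(model,
    "single-category" = list(),
    "low-level" = list(c("face", "watch"), c("object", "animal")),
    "semantic" = list(c("face", "animal"), c("watch", "object")),
    "face-vs-rest" = list("face", c("watch", "object", "animal")))
  grp_of <- function(cat) {
    g <- which(vapply(groups, function(g) cat %in% g, logical(1)))
    if (length(g)) g[1] else NA_integer_
  }
  g <- vapply(categories, grp_of, integer(1))
  n <- length(categories)
  same_cat <- outer(categories, categories, "==")
  same_grp <- outer(g, g, function(a, b) !is.na(a) & !is.na(b) & a == b)
  m <- matrix(1, n, n)
  m[same_grp] <- 0.5
  m[same_cat] <- 0
  diag(m) <- 0
  m
}

#' Analytic cluster-forming threshold for Spearman correlations
#'
#' The correlation magnitude whose one-sided p value equals `alpha` under
#' the large-sample normal approximation `z = rho * sqrt(n)`:
#' `qnorm(1 - alpha) / sqrt(n_pairs)`. With the 60-image geometry
#' (1770 exemplar pairs) and alpha 0.05 this is 0.0391.
#'
#' @param n_pairs number of dissimilarity pairs entering the correlation.
#' @param alpha one-sided level.
#' @return the threshold rho.
#' @export
rho_cluster_threshold <- function(n_pairs, alpha = 0.05) {
  qnorm(1 - alpha) / sqrt(n_pairs)
}

#' Time course of neural-RDM / model-RDM correlation
#'
#' Spearman correlation between the neural RDM and a category-model RDM at
#' every time point (averaged over the two repetitions' within-repetition
#' RDMs), with cluster-based significance: the first-level threshold is
#' the analytic rho from [rho_cluster_threshold()] for the geometry size,
#' the cluster statistic is the sum of correlations, and the null shuffles
#' exemplar identities (same shuffle for all time points).
#'
#' @param pres an [rsa_presentations()] object.
#' @param model model id or model RDM matrix.
#' @param metric dissimilarity metric.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param alpha cluster-level (and first-level) alpha.
#' @return list of class `model_correlation`: `timecourse` tibble
#'   (`time_ms`, `rho`, `significant`), `clusters`, `threshold`.
#' @export
model_correlation_timecourse <- function(pres, model,
                                         metric = "correlation",
                                         n_perm = 1000, seed = 1,
                                         alpha = 0.05) {
  if (is.character(model))
    model <- category_model_rdm(model, pres$exemplars$category)
  pat <- pres$pat
  N <- dim(pat)[1]; Tn <- dim(pat)[4]
  ut <- upper.tri(model)
  mv <- rank(model[ut])
  rho_of <- function(W1, W2) {
    (cor(rank(W1[ut]), mv) + cor(rank(W2[ut]), mv)) / 2
  }
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(N))
  rho <- numeric(Tn)
  pm <- matrix(0, n_perm, Tn)
  for (t in seq_len(Tn)) {
    W1 <- compute_rdm(pat[, 1, , t], metric)
    W2 <- compute_rdm(pat[, 2, , t], metric)
    rho[t] <- rho_of(W1, W2)
    for (p in seq_len(n_perm)) {
      pi <- perms[, p]
      pm[p, t] <- rho_of(W1[pi, pi], W2[pi, pi])
    }
  }
  thr <- rho_cluster_threshold(pres$n_pairs, alpha)
  cl <- cluster_test(rho, pm, thr, alpha = alpha)
  sig <- attr(cl, "mask")
  structure(list(
    timecourse = tibble::tibble(time_ms = pres$time_ms, rho = rho,
                                significant = sig),
    clusters = cl, threshold = thr, model = model),
    class = "model_correlation")
}

#' Pick the category model that best explains the neural RDM
#'
#' Runs [model_correlation_timecourse()] for each candidate model and
#' returns the one with the largest total significant cluster mass
#' (falling back to the largest peak correlation when nothing is
#' significant).
#'
#' @inheritParams model_correlation_timecourse
#' @param models character vector of model ids to compare.
#' @return tibble with one row per model (`model`, `peak_rho`,
#'   `cluster_mass`, `best`).
#' @export
strongest_model <- function(pres, models = c("single-category", "low-level",
                                             "semantic", "face-vs-rest"),
                            metric = "correlation", n_perm = 200,
                            seed = 1, alpha = 0.05) {
  res <- purrr::map_dfr(models, function(m) {
    mc <- model_correlation_timecourse(pres, m, metric, n_perm, seed, alpha)
    mass <- sum(mc$clusters$stat[mc$clusters$significant])
    tibble::tibble(model = m, peak_rho = max(mc$timecourse$rho),
                   cluster_mass = mass)
  })
  score <- ifelse(res$cluster_mass > 0, res$cluster_mass, -Inf)
  best <- if (all(is.infinite(score))) which.max(res$peak_rho)
          else which.max(score)
  res$best <- seq_len(nrow(res)) == best
  res
}
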