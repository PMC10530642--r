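#' Build a permutation null distribution for a time-resolved statistic
#'
#' Repeatedly shuffles the trial labels and re-evaluates a statistic
#' function, producing an `N_perm x N_stat` matrix of surrogate statistic
#' series. The same permuted label assignment is applied to every time point
#' within one permutation, preserving the temporal structure of the data.
#'
#' @param statistic_fn function taking a label vector and returning the
#'   statistic as a numeric vector (one value per time point / cell); must
#'   be pure given data and labels.
#' @param labels the true label vector; permutations shuffle it.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for reproducible shuffles.
#' @param scheme free-text descriptor of what is shuffled (recorded).
#' @return object of class `perm_null`: `perm_matrix`, `col_mean`,
#'   `col_sd`, `n_perm`, `scheme`, `seed`.
#' @export
build_null <- function(statistic_fn, labels, n_perm = 1000, seed = 1,
                       scheme = "label shuffle") {
  set.seed(seed)
  first <- statistic_fn(sample(labels))
  pm <- matrix(0, n_perm, length(first))
  pm[1, ] <- first
  if (n_perm > 1) for (i in 2:n_perm) pm[i, ] <- statistic_fn(sample(labels))
  structure(list(perm_matrix = pm,
                 col_mean = colMeans(pm),
                 col_sd = apply(pm, 2, sd),
                 n_perm = n_perm, scheme = scheme, seed = seed),
            class = "perm_null")
}

#' Max-statistic permutation test with column z-scoring
#'
#' Standardizes the observed statistic series and every permutation series
#' by the column means and SDs of the permutation matrix (under the null the
#' observed statistic comes from the same distribution as the permutation
#' statistics), extracts the maximal z across time points from each
#' standardized permutation series, and flags observed time points whose
#' family-wise p value against that max-z null is at most `alpha`
#' (one-sided; the observed statistic is included in the null, so
#' p >= 1/(n_perm + 1)). Columns with zero permutation SD get z = 0.
#'
#' @param null a [build_null()] result (>= 100 permutations recommended).
#' @param observed observed statistic series, same length as the null
#'   columns.
#' @param alpha family-wise level.
#' @return tibble with `index`, `observed`, `z`, `p` (family-wise adjusted,
#'   observed included in the null: p >= 1/(n_perm+1)) and `significant`;
#'   attribute `max_z_null` carries the null max-z distribution.
#' @export
max_stat_test <- function(null, observed, alpha = 0.05) {
  stopifnot(inherits(null, "perm_null"),
            length(observed) == length(null$col_mean))
  sdz <- null$col_sd
  zdiv <- ifelse(sdz > 0, sdz, Inf)
  z_obs <- (observed - null$col_mean) / zdiv
  z_perm <- sweep(sweep(null$perm_matrix, 2, null$col_mean), 2, zdiv, "/")
  max_z <- apply(z_perm, 1, max)
  thr <- quantile(max_z, 1 - alpha, names = FALSE, type = 7)
  p <- vapply(z_obs, function(z) (1 + sum(max_z >= z)) / (null$n_perm + 1),
              numeric(1))
  out <- tibble::tibble(index = seq_along(observed), observed = observed,
                        z = z_obs, p = p, significant = p <= alpha)
  attr(out, "max_z_null") <- max_z
  attr(out, "threshold") <- thr
  out
}

# contiguous supra-threshold clusters of a vector (runs) or matrix
# (4-connected components); returns list(members = list of index vectors,
# stat = sums of member values)
clusterize <- function(x, threshold) {
  if (is.matrix(x)) return(clusterize_2d(x, threshold))
  above <- x >= threshold
  if (!any(above)) return(list(members = list(), stat = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  members <- lapply(keep, function(i) starts[i]:ends[i])
  list(members = members,
       stat = vapply(members, function(m) sum(x[m]), numeric(1)))
}

clusterize_2d <- function(x, threshold) {
  above <- x >= threshold
  if (!any(above)) return(list(members = list(), stat = numeric(0)))
  lab <- matrix(0L, nrow(x), ncol(x))
  cur <- 0L
  idx <- which(above, arr.ind = TRUE)
  above_m <- above
  for (k in seq_len(nrow(idx))) {
    i0 <- idx[k, 1]; j0 <- idx[k, 2]
    if (lab[i0, j0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- p[1] + d[1]; jj <- p[2] + d[2]
        if (ii >= 1 && ii <= nrow(x) && jj >= 1 && jj <= ncol(x) &&
            above_m[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  members <- lapply(seq_len(cur), function(cl) which(lab == cl))
  list(members = members,
       stat = vapply(members, function(m) sum(x[m]), numeric(1)))
}

max_cluster_stat <- function(x, threshold, two_sided = FALSE) {
  s <- clusterize(x, threshold)$stat
  m <- if (length(s)) max(s) else 0
  if (two_sided) {
    neg <- if (is.matrix(x)) -x else -x
    s2 <- clusterize(neg, threshold)$stat
    m <- max(m, if (length(s2)) max(s2) else 0)
  }
  m
}

#' Cluster-based permutation test
#'
#' Clusters supra-threshold samples of the observed statistic by temporal
#' adjacency (1-D series) or 4-connectivity over the train x test plane
#' (matrices, e.g. temporal generalization matrices), takes the sum of the
#' member values as the cluster statistic, and compares each observed
#' cluster to the null distribution of the maximal cluster statistic across
#' permutations. Two-sided tests additionally cluster the negated statistic
#' (sub-threshold troughs) and pool both signs into the null maximum.
#'
#' @param observed numeric vector or matrix of the statistic (e.g. AUC,
#'   AUC difference, reliability z, model correlation).
#' @param null a [build_null()] object, or a permutation matrix whose rows
#'   flatten to the shape of `observed` (column-major for matrices).
#' @param threshold cluster-forming threshold in the statistic's units
#'   (e.g. AUC 0.60, AUC difference 0.10, z 1.5, the analytic Spearman rho
#'   threshold from [rho_cluster_threshold()]).
#' @param alpha family-wise level.
#' @param two_sided cluster both signs (used for between-region contrasts).
#' @return tibble, one row per observed cluster: `cluster`, `stat`, `p`,
#'   `significant`, `members` (list column of indices into `observed`).
#'   Attribute `mask`: logical like `observed`, TRUE inside significant
#'   clusters. An empty tibble (no supra-threshold samples) is valid.
#' @export
cluster_test <- function(observed, null, threshold, alpha = 0.05,
                         two_sided = FALSE) {
  pm <- if (inherits(null, "perm_null")) null$perm_matrix else null
  stopifnot(ncol(pm) == length(observed))
  shape <- function(v) if (is.matrix(observed))
    matrix(v, nrow(observed), ncol(observed)) else v
  null_max <- apply(pm, 1, function(r)
    max_cluster_stat(shape(r), threshold, two_sided))
  cl <- clusterize(observed, threshold)
  if (two_sided) {
    cl_neg <- clusterize(shape(-as.vector(observed)), threshold)
    cl$members <- c(cl$members, cl_neg$members)
    cl$stat <- c(cl$stat, cl_neg$stat)
  }
  n_perm <- nrow(pm)
  p <- vapply(cl$stat, function(s) (1 + sum(null_max >= s)) / (n_perm + 1),
              numeric(1))
  out <- tibble::tibble(cluster = seq_along(cl$stat), stat = cl$stat,
                        p = p, significant = p <= alpha,
                        members = cl$members)
  mask <- array(FALSE, dim = if (is.matrix(observed)) dim(observed)
                else length(observed))
  for (i in which(out$significant)) mask[out$members[[i]]] <- TRUE
  attr(out, "mask") <- mask
  attr(out, "null_max") <- null_max
  out
}

#' Benjamini-Hochberg FDR rejections
#'
#' Step-up Benjamini-Hochberg procedure (via [stats::p.adjust()]) returning
#' the rejection mask at level `q`.
#'
#' @param pvals p values in [0, 1].
#' @param q FDR level.
#' @return logical vector, TRUE where rejected.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p.adjust(pvals, method = "BH") < q
}
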