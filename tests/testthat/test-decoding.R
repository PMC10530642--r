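test_that("exemplar preparation averages repetitions and balances classes", {
  # exemplar with reps {x, y} -> single trial (x+y)/2
  arr <- array(0, c(4, 2, 3))
  arr[1, , ] <- 1; arr[2, , ] <- 3   # same exemplar, two repetitions
  arr[3, , ] <- 5; arr[4, , ] <- 7
  x <- toy_tensor(arr, categories = c("face", "face", "watch", "watch"),
                  exemplar_id = c("f1", "f1", "w1", "w2"),
                  repetition = c(1L, 2L, 1L, 1L))
  set.seed(1)
  prep <- prepare_exemplar_trials(x, c("face", "watch"))
  f1 <- prep$hfa[prep$trials$exemplar_id == "f1", , ]
  expect_equal(unname(f1), matrix(2, 2, 3))
  # 1 face vs 2 watches -> balanced to 1 vs 1
  expect_equal(unname(table(prep$trials$category)[c("face", "watch")]),
               c(1L, 1L), ignore_attr = TRUE)

  # undersampling subsets differ across RNG states
  sim <- sim_clean()
  set.seed(1); a <- prepare_exemplar_trials(sim$tensor, c("face", "object"))
  set.seed(2); b <- prepare_exemplar_trials(sim$tensor, c("face", "object"))
  expect_false(identical(a$trials$exemplar_id, b$trials$exemplar_id))
})

test_that("shrinkage LDA follows the regularization formula", {
  set.seed(7)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(c("a", "b"), 30)
  X[y == "a", 1] <- X[y == "a", 1] + 2

  m1 <- fit_shrinkage_lda(X, y, lambda = 1)
  nu <- sum(diag(m1$Sigma)) / 3
  expect_equal(m1$Sigma_hat, diag(nu, 3))

  m0 <- fit_shrinkage_lda(X, y, lambda = 0)
  expect_equal(m0$Sigma_hat, m0$Sigma)

  # trace is preserved for any lambda
  for (lam in c(0, 0.3, 0.7, 1)) {
    m <- fit_shrinkage_lda(X, y, lambda = lam)
    expect_equal(sum(diag(m$Sigma_hat)), sum(diag(m$Sigma)))
  }

  # identity covariance, means (1,0) vs (0,0) -> w proportional to (1,0)
  set.seed(8)
  Z <- matrix(rnorm(4000 * 2), 4000, 2)
  yz <- rep(c("a", "b"), 2000)
  Z[yz == "a", 1] <- Z[yz == "a", 1] + 1
  mz <- fit_shrinkage_lda(Z, yz, lambda = 0)
  expect_gt(abs(mz$w[1]) / sqrt(sum(mz$w^2)), 0.99)

  # singular covariance without shrinkage is refused with advice
  Xs <- matrix(rnorm(4 * 10), 4, 10)
  expect_error(fit_shrinkage_lda(Xs, c("a", "a", "b", "b"), lambda = 0),
               "shrinkage")
  # auto lambda lands in [0, 1] and fixes the singularity
  ma <- fit_shrinkage_lda(Xs, c("a", "a", "b", "b"), lambda = "auto")
  expect_true(ma$lambda >= 0 && ma$lambda <= 1)
  expect_true(all(is.finite(ma$w)))
})

test_that("fitted weights converge to the population discriminant", {
  set.seed(11)
  p <- 6; n <- 2000
  A <- matrix(rnorm(p * p), p); Sigma <- crossprod(A) / p + diag(p)
  mu <- c(1, 0.5, 0, -0.5, 0, 0.2)
  L <- chol(Sigma)
  X <- rbind(matrix(rnorm(n * p), n) %*% L + rep(mu, each = n),
             matrix(rnorm(n * p), n) %*% L)
  y <- rep(c("a", "b"), each = n)
  m <- fit_shrinkage_lda(X, y, lambda = "auto")
  w_pop <- solve(Sigma, mu)
  cosine <- sum(m$w * w_pop) / sqrt(sum(m$w^2) * sum(w_pop^2))
  expect_gt(cosine, 0.95)
})

test_that("AUC equals brute-force pair counting and its invariances hold", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.2), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_equal(roc_auc(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  set.seed(13)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    s <- round(rnorm(n), 1)            # rounding forces ties
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(l) || all(l)) next
    expect_identical(roc_auc(s, l), auc_brute(s, l))
    expect_equal(roc_auc(s, !l), 1 - roc_auc(s, l))
    expect_equal(roc_auc(exp(3 * s), l), roc_auc(s, l))  # monotone map
  }
  # independent library oracle
  skip_if_not_installed("pROC")
  set.seed(14)
  s <- rnorm(40); l <- rep(c(TRUE, FALSE), 20)
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, direction = "<",
                                              quiet = TRUE))))
})

test_that("noiseless separable classes decode perfectly, null at chance", {
  sim <- sim_clean()
  xx <- tt_subset(sim$tensor, electrodes = region == "VT")
  xx <- tt_index(xx, time_idx = which(xx$time_ms >= -100 &
                                        xx$time_ms <= 600))
  dr <- time_resolved_decoding(xx, c("face", "watch"),
                               min_duration_ms = 900, seed = 2,
                               downsample_hz = 50)
  coding <- dr$auc$time_ms >= 200 & dr$auc$time_ms <= 500
  expect_true(all(dr$auc$auc[coding] == 1))
  expect_equal(mean(dr$auc$auc[dr$auc$time_ms < 0]), 0.5, tolerance = 0.05)
})

test_that("TGM diagonal equals the time-resolved AUC under shared folds", {
  sim <- sim_clean()
  xx <- tt_subset(sim$tensor, electrodes = region == "VT")
  xx <- tt_index(xx, time_idx = which(xx$time_ms >= 0 & xx$time_ms <= 400))
  tr <- time_resolved_decoding(xx, c("face", "watch"), n_repeats = 2,
                               min_duration_ms = 900, seed = 9,
                               downsample_hz = 50)
  tg <- temporal_generalization(xx, c("face", "watch"), n_repeats = 2,
                                min_duration_ms = 900, seed = 9,
                                downsample_hz = 50)
  expect_equal(unname(diag(tg$tgm)), tr$auc$auc, tolerance = 1e-12)
})

test_that("null decoding stays at chance under the peak max-stat test", {
  cfg <- sim_config(seed = 17, n_patients = 1,
                    electrodes_per_region = c(VT = 8),
                    n_exemplars_per_category = c(face = 24, watch = 24),
                    n_repetitions_per_exemplar = 1, durations_ms = 900,
                    region_profiles = list(
                      VT = coding_profile(tuning_strength = 0,
                                          exemplar_gain_sd = 0)),
                    noise_sd = 1)
  sim <- generate_dataset(cfg)
  xx <- tt_index(sim$tensor,
                 time_idx = which(sim$tensor$time_ms >= 0 &
                                    sim$tensor$time_ms <= 600))
  dr <- time_resolved_decoding(xx, c("face", "watch"), seed = 3,
                               downsample_hz = 25)
  expect_equal(mean(dr$auc$auc), 0.5, tolerance = 0.06)
  nul <- decoding_null(xx, c("face", "watch"), n_perm = 100, seed = 3,
                       downsample_hz = 25)
  ms <- max_stat_test(nul, dr$auc$auc)
  expect_false(any(ms$significant))
})

test_that("tidy/glance/autoplot expose decoding results", {
  sim <- sim_clean()
  xx <- tt_subset(sim$tensor, electrodes = region == "VT")
  xx <- tt_index(xx, time_idx = which(xx$time_ms >= 0 & xx$time_ms <= 300))
  tg <- temporal_generalization(xx, c("face", "watch"), n_repeats = 1,
                                min_duration_ms = 900, seed = 1,
                                downsample_hz = 50)
  td <- tidy(tg)
  expect_true(all(c("train_time_ms", "test_time_ms", "auc") %in% names(td)))
  expect_equal(nrow(td), length(tg$time_ms)^2)
  gl <- glance(tg)
  expect_true(gl$peak_auc >= 0.5 && gl$peak_auc <= 1)
  expect_s3_class(autoplot(tg), "ggplot")
  bc <- tgm_block_curves(tg, block_ms = 200)
  expect_true(all(c("train_block", "test_time_ms", "auc") %in% names(bc)))
})

test_that("a sustained dynamic code generalizes within but not across epochs", {
  # high sustained fraction keeps the late code decodable; its patterns are
  # orthogonal to the early ones, so cross-epoch generalization is at chance
  cfg <- sim_config(seed = 23, n_patients = 1,
                    electrodes_per_region = c(PFC = 16),
                    n_exemplars_per_category = c(face = 10, watch = 10),
                    n_repetitions_per_exemplar = 2, durations_ms = 1500,
                    region_profiles = list(
                      PFC = coding_profile(sustained_fraction = 0.6,
                                           tuning_strength = 0.6,
                                           stationarity = "dynamic",
                                           switch_time_ms = 500,
                                           responsive_fraction = 1)),
                    noise_sd = 0.25)
  sim <- generate_dataset(cfg)
  xx <- tt_index(sim$tensor,
                 time_idx = which(sim$tensor$time_ms >= 0 &
                                    sim$tensor$time_ms <= 1400))
  tg <- temporal_generalization(xx, c("face", "watch"), seed = 3,
                                downsample_hz = 50)
  tm <- tg$time_ms
  early <- tm >= 200 & tm <= 400
  late <- tm >= 700 & tm <= 1300
  expect_gt(mean(diag(tg$tgm)[early]), 0.85)
  expect_gt(mean(diag(tg$tgm)[late]), 0.85)
  cross <- (mean(tg$tgm[early, late]) + mean(tg$tgm[late, early])) / 2
  expect_lt(abs(cross - 0.5), 0.15)
})
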