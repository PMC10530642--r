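test_that("a constant-amplitude tone yields a near-constant unit envelope", {
  fs <- 500
  x <- sin(2 * pi * 100 * seq(0, 20, by = 1 / fs))
  h <- extract_hfa(x, fs)
  expect_equal(mean(h), 1, tolerance = 0.02)
  mid <- h[1, 2000:8000]        # away from filter edge transients
  expect_lt(sd(mid) / mean(mid), 0.05)
})

test_that("extraction is invariant to a positive rescaling of the input", {
  fs <- 500
  set.seed(1)
  x <- rnorm(8000)
  expect_equal(extract_hfa(x, fs), extract_hfa(7.3 * x, fs),
               tolerance = 1e-10)
})

test_that("band and length preconditions are enforced", {
  expect_error(extract_hfa(rnorm(10000), sampling_rate = 250), "Nyquist")
  expect_error(extract_hfa(rnorm(500), sampling_rate = 500), "too short")
})

test_that("an amplitude-modulated carrier's envelope is recovered", {
  cfg <- sim_config(seed = 11, sampling_rate_hz = 500, n_patients = 1,
                    electrodes_per_region = c(VT = 2),
                    region_profiles = list(VT = coding_profile()))
  raw <- generate_raw_traces(cfg, n_electrodes = 1, n_trials = 6)
  h <- extract_hfa(raw$voltage, raw$sampling_rate)
  tt <- epoch_baseline_smooth(h, raw$sampling_rate, raw$events,
                              raw$electrodes)
  # the extracted epochs are 50-ms smoothed; smooth the planted envelope
  # identically so the comparison measures envelope recovery, not smoothing
  pl <- t(apply(raw$planted_env, 1, hfadyn:::moving_average,
                n = round(0.05 * raw$sampling_rate)))
  r <- vapply(seq_len(dim(tt$hfa)[1]), function(k)
    cor(tt$hfa[k, 1, ], pl[k, ]), numeric(1))
  expect_true(all(r > 0.95))
})

test_that("epoching baseline-corrects, zeroes constants, keeps steps", {
  fs <- 1000
  n <- 6000
  onsets <- c(2000, 4000)
  ev <- tibble::tibble(onset_sample = onsets,
                       trial_id = c("a", "b"), patient = "P1",
                       category = "face", exemplar_id = c("x", "y"),
                       duration_ms = 900, repetition = 1L)
  el <- tibble::tibble(electrode_id = "e1", patient = "P1", region = "VT")

  cst <- matrix(3.2, 1, n)
  t1 <- epoch_baseline_smooth(cst, fs, ev, el, window_ms = c(-300, 900))
  expect_true(all(abs(t1$hfa) < 1e-12))

  stp <- matrix(0, 1, n)
  for (o in onsets) stp[1, o:n] <- stp[1, o:n] + 5
  t2 <- epoch_baseline_smooth(stp, fs, ev, el, window_ms = c(-300, 900),
                              reject_k = NULL)
  mid <- t2$time_ms > 100 & t2$time_ms < 800
  expect_equal(unname(t2$hfa[1, 1, mid]),
               rep(5, sum(mid)), tolerance = 1e-9)
  # baseline correction is idempotent: the baseline mean is already ~0,
  # so re-subtracting it changes nothing (checked pre-smoothing, where the
  # onset step cannot leak into the baseline window)
  bl <- t2$time_ms >= -300 & t2$time_ms < 0
  expect_lt(abs(mean(t2$hfa_unsmoothed[1, 1, bl])), 1e-9)
})

test_that("events at the recording edge are dropped with a warning", {
  ev <- tibble::tibble(onset_sample = c(100, 2000),
                       trial_id = c("a", "b"), patient = "P1",
                       category = "face", exemplar_id = c("x", "y"),
                       duration_ms = 900, repetition = 1L)
  el <- tibble::tibble(electrode_id = "e1", patient = "P1", region = "VT")
  expect_warning(
    tt <- epoch_baseline_smooth(matrix(rnorm(4000), 1), 1000, ev, el,
                                window_ms = c(-300, 900), reject_k = NULL),
    "edge")
  expect_equal(dim(tt$hfa)[1], 1)
})

test_that("trials with a planted artifact are excluded and counted", {
  fs <- 1000
  set.seed(4)
  sig <- matrix(rnorm(20000, sd = 0.2), 1)
  onsets <- seq(1000, 18000, by = 1500)
  sig[1, onsets[3] + 150] <- 80          # gross artifact in trial 3
  ev <- tibble::tibble(onset_sample = onsets,
                       trial_id = sprintf("t%d", seq_along(onsets)),
                       patient = "P1", category = "face",
                       exemplar_id = sprintf("x%d", seq_along(onsets)),
                       duration_ms = 900, repetition = 1L)
  el <- tibble::tibble(electrode_id = "e1", patient = "P1", region = "VT")
  expect_message(
    tt <- epoch_baseline_smooth(sig, fs, ev, el, window_ms = c(-300, 900)),
    "noise-rejection")
  expect_equal(attr(tt, "n_rejected"), 1L)
  expect_equal(dim(tt$hfa)[1], length(onsets) - 1L)
})

test_that("smoothing preserves the mean of interior-supported traces", {
  # with edge-shrunk windows, mass is conserved exactly wherever the full
  # window fits; signals supported a full window away from the edges
  # therefore keep their mean bit-exactly
  set.seed(2)
  arr <- array(0, c(5, 2, 200))
  arr[, , 60:140] <- rnorm(5 * 2 * 81)
  x <- toy_tensor(arr, categories = rep(c("face", "watch"), c(3, 2)))
  sm <- hfadyn:::smooth_tensor_array(x$hfa, 50, 1000)
  expect_equal(apply(sm, c(1, 2), mean), apply(x$hfa, c(1, 2), mean),
               tolerance = 1e-12)
})

test_that("neighbor re-referencing removes shared components", {
  # 4 electrodes on one 2x2 grid
  n_tr <- 3; n_t <- 50
  set.seed(9)
  common <- array(rep(rnorm(n_tr * n_t), each = 1), c(n_tr, 1, n_t))
  arr <- array(0, c(n_tr, 4, n_t))
  private <- array(rnorm(n_tr * n_t), c(n_tr, 1, n_t))
  for (e in 1:4) arr[, e, ] <- common[, 1, ]
  arr[, 1, ] <- arr[, 1, ] + private[, 1, ]
  x <- toy_tensor(arr, categories = rep("face", n_tr))
  layout <- tibble::tibble(
    electrode_id = sprintf("e%02d", 1:4), grid = "g1",
    row = c(1, 1, 2, 2), col = c(1, 2, 1, 2))
  rr <- neighbor_rereference(x, layout)
  # identical traces in electrodes 2-4: their referenced signal loses the
  # common component entirely except for electrode 1's private leakage
  expect_equal(rr$hfa[, 4, ], arr[, 4, ] - (arr[, 2, ] + arr[, 3, ]) / 2,
               tolerance = 1e-12)
  # electrode 1 keeps its private signal (neighbors carry only common part)
  expect_equal(rr$hfa[, 1, ], private[, 1, ], tolerance = 1e-12)

  # identical traces everywhere -> all zeros
  arr2 <- array(0, c(n_tr, 4, n_t))
  for (e in 1:4) arr2[, e, ] <- common[, 1, ]
  x2 <- toy_tensor(arr2, categories = rep("face", n_tr))
  expect_true(all(abs(neighbor_rereference(x2, layout)$hfa) < 1e-12))

  expect_error(neighbor_rereference(x, layout[-2, ]), "missing electrodes")
  lay2 <- layout; lay2$grid[4] <- "g2"    # electrode 4 now isolated
  expect_warning(neighbor_rereference(x, lay2), "no grid neighbor")
})

test_that("downsampling decimates the time axis consistently", {
  sim <- sim_clean()
  d <- downsample_tensor(sim$tensor, 50)
  expect_equal(d$sampling_rate, 50)
  expect_equal(d$time_ms, sim$tensor$time_ms[seq(1, 381, by = 4)])
  expect_equal(d$hfa[2, 3, ], sim$tensor$hfa[2, 3, seq(1, 381, by = 4)])
  expect_error(downsample_tensor(sim$tensor, 60), "integer multiple")
})
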