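#' Region coding profile for the synthetic-data generator
#'
#' Describes how electrodes in one region respond to a stimulus: a transient
#' onset peak that decays to a sustained plateau while the stimulus is on,
#' then decays back to baseline after offset. Category and exemplar structure
#' enter as per-electrode gains.
#'
#' @param onset_latency_ms response onset latency (ms after stimulus onset).
#' @param rise_ms time from onset to the transient peak.
#' @param decay_ms decay constant of the transient (gamma-like kernel).
#' @param peak_amplitude transient peak height in normalized HFA units.
#' @param sustained_fraction proportion of the peak maintained while the
#'   stimulus is on; 0.2 reproduces an ~80% (about five-fold) attenuation
#'   from peak to late response.
#' @param offset_decay_ms exponential decay constant after stimulus offset.
#' @param tuning_strength SD of the per-electrode category gain modulation
#'   (0 = no category information).
#' @param exemplar_gain_sd SD of the isotropic per-exemplar perturbation
#'   around the category centroid pattern (0 = exemplars identical within
#'   category, i.e. category structure only).
#' @param stationarity `"stable"` (one tuning pattern throughout) or
#'   `"dynamic"` (the tuning pattern rotates to an orthogonal one mid-trial,
#'   producing a diagonal temporal generalization matrix).
#' @param switch_time_ms for dynamic profiles, the time at which the early
#'   pattern is replaced by the orthogonal late pattern.
#' @param responsive_fraction fraction of electrodes in the region that carry
#'   a stimulus response at all; the rest are pure noise.
#' @return a list of class `coding_profile`.
#' @export
coding_profile <- function(onset_latency_ms = 100, rise_ms = 60,
                           decay_ms = 150, peak_amplitude = 3,
                           sustained_fraction = 0.2, offset_decay_ms = 100,
                           tuning_strength = 0.5, exemplar_gain_sd = 0.3,
                           stationarity = c("stable", "dynamic"),
                           switch_time_ms = 500,
                           responsive_fraction = 0.9) {
  stationarity <- match.arg(stationarity)
  if (sustained_fraction < 0 || sustained_fraction > 1)
    stop("sustained_fraction must be in [0, 1]")
  structure(list(
    onset_latency_ms = onset_latency_ms, rise_ms = rise_ms,
    decay_ms = decay_ms, peak_amplitude = peak_amplitude,
    sustained_fraction = sustained_fraction,
    offset_decay_ms = offset_decay_ms,
    tuning_strength = tuning_strength,
    exemplar_gain_sd = exemplar_gain_sd,
    stationarity = stationarity, switch_time_ms = switch_time_ms,
    responsive_fraction = responsive_fraction), class = "coding_profile")
}

#' Simulation configuration
#'
#' Study-design parameters for the synthetic generator. Defaults mirror the
#' experimental design the package targets: four stimulus categories with
#' relative frequencies face 0.30, watch 0.30, object 0.18, animal 0.10,
#' durations drawn uniformly from {300, 900, 1500} ms, epochs spanning
#' -300..1600 ms, sustained coding in visual regions (ventral temporal "VT",
#' occipital "Occ") and transient, dynamic coding in frontoparietal regions
#' ("PFC", "Par"). Under 20% of responsive electrodes respond negatively.
#'
#' @param n_patients number of simulated patients; electrodes are replicated
#'   per patient, trials are shared (exemplars are aligned across patients as
#'   in multi-patient merged-electrode analyses).
#' @param electrodes_per_region named integer vector: electrodes per region
#'   for each patient.
#' @param n_exemplars_per_category named integer vector of unique images per
#'   category; the default keeps the study's relative category frequencies.
#' @param n_repetitions_per_exemplar repetitions of each unique image (>= 1;
#'   reliability analyses need >= 2).
#' @param durations_ms stimulus durations (subset of {300, 900, 1500}),
#'   assigned uniformly to presentations.
#' @param isi_ms inter-stimulus intervals used when laying out continuous
#'   raw traces.
#' @param sampling_rate_hz sampling rate of the epoch time axis.
#' @param epoch_window_ms epoch window, ms relative to onset.
#' @param region_profiles named list of [coding_profile()]s, one per region.
#' @param fraction_negative_responders fraction of responsive electrodes with
#'   sign-flipped (suppressed) responses.
#' @param noise_sd SD of additive Gaussian noise on each HFA sample.
#' @param trial_gain_jitter_sd SD of the multiplicative trial-level gain
#'   jitter (gain ~ 1 + N(0, sd)).
#' @param smoothing_window_ms smoothing applied to the generated epochs.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(
    n_patients = 2,
    electrodes_per_region = c(VT = 12, PFC = 10),
    n_exemplars_per_category = c(face = 9, watch = 9, object = 5, animal = 3),
    n_repetitions_per_exemplar = 2,
    durations_ms = c(300, 900, 1500),
    isi_ms = c(600, 750, 900, 1050, 1200),
    sampling_rate_hz = 200,
    epoch_window_ms = c(-300, 1600),
    region_profiles = list(
      VT = coding_profile(onset_latency_ms = 110, peak_amplitude = 3,
                          sustained_fraction = 0.25, tuning_strength = 0.6,
                          stationarity = "stable"),
      PFC = coding_profile(onset_latency_ms = 180, peak_amplitude = 2,
                           sustained_fraction = 0.05, tuning_strength = 0.5,
                           stationarity = "dynamic")),
    fraction_negative_responders = 0.15,
    noise_sd = 0.5,
    trial_gain_jitter_sd = 0.1,
    smoothing_window_ms = 50,
    seed = 1L) {
  if (n_repetitions_per_exemplar < 1)
    stop("n_repetitions_per_exemplar must be >= 1")
  # keep only profiles for regions that are actually simulated
  region_profiles <- region_profiles[names(region_profiles) %in%
                                       names(electrodes_per_region)]
  if (any(!names(electrodes_per_region) %in% names(region_profiles)))
    stop("every region needs a coding profile")
  if (max(durations_ms) > epoch_window_ms[2])
    stop("epoch window must contain the longest stimulus duration")
  structure(list(
    n_patients = n_patients,
    electrodes_per_region = electrodes_per_region,
    n_exemplars_per_category = n_exemplars_per_category,
    n_repetitions_per_exemplar = n_repetitions_per_exemplar,
    durations_ms = durations_ms, isi_ms = isi_ms,
    sampling_rate_hz = sampling_rate_hz,
    epoch_window_ms = epoch_window_ms,
    region_profiles = region_profiles,
    fraction_negative_responders = fraction_negative_responders,
    noise_sd = noise_sd, trial_gain_jitter_sd = trial_gain_jitter_sd,
    smoothing_window_ms = smoothing_window_ms,
    seed = seed), class = "sim_config")
}

# Noiseless response envelope for one duration: gamma-like transient peaking
# at `peak_amplitude`, sustained plateau at sustained_fraction * peak while
# the stimulus is on, exponential return to baseline after offset.
response_envelope <- function(time_ms, duration_ms, profile) {
  s <- time_ms - profile$onset_latency_ms
  # quadratic rise to the peak at `rise_ms`, exponential decay with time
  # constant `decay_ms` afterwards
  kern <- numeric(length(s))
  rising <- s > 0 & s <= profile$rise_ms
  falling <- s > profile$rise_ms
  kern[rising] <- (s[rising] / profile$rise_ms)^2
  kern[falling] <- exp(-(s[falling] - profile$rise_ms) / profile$decay_ms)
  kern <- kern / max(kern, 1e-12)
  plateau <- profile$sustained_fraction *
    as.numeric(s > 0 & time_ms <= duration_ms)
  env <- pmax(kern * as.numeric(time_ms <= duration_ms), plateau)
  post <- time_ms > duration_ms
  if (any(post)) {
    env_off <- env[which(!post)[sum(!post)]]
    env[post] <- pmax(env[post], env_off *
                        exp(-(time_ms[post] - duration_ms) /
                              profile$offset_decay_ms))
  }
  env * profile$peak_amplitude
}

# Per-region latent structure: tuning gains per electrode x category and
# exemplar pattern vectors (category centroid + isotropic perturbation).
# Dynamic regions get a second, orthogonalized pattern set for late times.
build_region_code <- function(n_elec, categories, exemplar_tbl, profile) {
  n_cat <- length(categories)
  draw_patterns <- function() {
    tun <- matrix(rnorm(n_elec * n_cat, sd = profile$tuning_strength),
                  n_elec, n_cat, dimnames = list(NULL, categories))
    ex <- sapply(seq_len(nrow(exemplar_tbl)), function(i) {
      tun[, exemplar_tbl$category[i]] +
        rnorm(n_elec, sd = profile$exemplar_gain_sd)
    })
    list(tuning = tun, exemplar = ex)  # exemplar: electrodes x exemplars
  }
  p1 <- draw_patterns()
  p2 <- NULL
  if (profile$stationarity == "dynamic") {
    p2 <- draw_patterns()
    # late code must share no linear readout with the early one: project
    # the late category tuning out of the span of the early tuning columns
    # (so class-mean differences are orthogonal across epochs), then
    # rebuild the late exemplar vectors and orthogonalize each against its
    # early counterpart (so exemplar identity does not generalize either)
    if (profile$tuning_strength > 0 && n_cat > 1 && n_elec > n_cat + 1) {
      # project the late tuning out of the span of the early tuning and the
      # common response mode, rebuild the late exemplar vectors, then also
      # remove the realized early category means so the class contrasts of
      # the two epochs are exactly orthogonal in electrode space
      Q <- qr.Q(qr(cbind(1, p1$tuning)))
      p2$tuning <- p2$tuning - Q %*% crossprod(Q, p2$tuning)
      p2$exemplar <- sapply(seq_len(nrow(exemplar_tbl)), function(i) {
        p2$tuning[, exemplar_tbl$category[i]] +
          rnorm(n_elec, sd = profile$exemplar_gain_sd)
      })
      m1 <- sapply(categories, function(cc)
        rowMeans(p1$exemplar[, exemplar_tbl$category == cc, drop = FALSE]))
      Qm <- qr.Q(qr(cbind(1, m1)))
      p2$exemplar <- p2$exemplar - Qm %*% crossprod(Qm, p2$exemplar)
    }
    for (i in seq_len(ncol(p2$exemplar))) {
      v1 <- p1$exemplar[, i]
      v2 <- p2$exemplar[, i]
      v2 <- v2 - sum(v2 * v1) / sum(v1 * v1) * v1
      p2$exemplar[, i] <- v2 * sqrt(sum(p1$exemplar[, i]^2) /
                                      max(sum(v2^2), 1e-12))
    }
  }
  list(early = p1, late = p2)
}

#' Generate a synthetic epoched dataset with known ground truth
#'
#' Simulates multi-patient HFA epochs (trials x electrodes x time) following
#' the configured study design: each unique image is presented
#' `n_repetitions_per_exemplar` times with a uniformly drawn duration,
#' regions respond with transient-then-sustained envelopes, category and
#' exemplar information is carried by per-electrode gain patterns, and
#' additive Gaussian noise plus trial-level gain jitter corrupt the signal.
#'
#' @param config a [sim_config()].
#' @return list with elements `tensor` (a [trial_tensor()]; `hfa` smoothed,
#'   `hfa_unsmoothed` raw) and `truth` (ground-truth record: per-electrode
#'   sign/responsiveness, region stationarity flags, tuning and exemplar
#'   patterns, the noiseless envelopes, and the config).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate_hz
  time_ms <- seq(config$epoch_window_ms[1], config$epoch_window_ms[2],
                 by = 1000 / fs)

  # --- stimulus set ---------------------------------------------------------
  nex <- config$n_exemplars_per_category
  exemplars <- tibble::tibble(
    exemplar_id = paste0(rep(names(nex), nex), "_",
                         unlist(lapply(nex, seq_len))),
    category = rep(names(nex), nex))
  nrep <- config$n_repetitions_per_exemplar
  trials <- tidyr::expand_grid(exemplar_id = exemplars$exemplar_id,
                               repetition = seq_len(nrep))
  trials <- dplyr::left_join(trials, exemplars, by = "exemplar_id")
  durs <- config$durations_ms
  trials$duration_ms <- durs[sample.int(length(durs), nrow(trials),
                                        replace = TRUE)]
  trials <- trials[sample(nrow(trials)), ]   # randomized sequence
  trials$trial_id <- sprintf("tr%03d", seq_len(nrow(trials)))
  trials$patient <- "all"                    # shared sequence across patients
  trials$is_target <- FALSE
  trials <- trials[, c("trial_id", "patient", "category", "exemplar_id",
                       "duration_ms", "repetition", "is_target")]

  # --- electrodes -----------------------------------------------------------
  epr <- config$electrodes_per_region
  electrodes <- tidyr::expand_grid(
    patient = paste0("P", seq_len(config$n_patients)),
    region = names(epr))
  electrodes$n <- as.integer(epr[electrodes$region])
  electrodes <- tidyr::uncount(electrodes, weights = .data$n, .id = "chan")
  electrodes$electrode_id <- sprintf("%s_%s_e%02d", electrodes$patient,
                                     electrodes$region, electrodes$chan)
  electrodes <- electrodes[, c("electrode_id", "patient", "region")]
  n_elec_tot <- nrow(electrodes)
  n_trials <- nrow(trials)
  n_time <- length(time_ms)

  responsive <- logical(n_elec_tot)
  sign_vec <- rep(1, n_elec_tot)
  codes <- list()
  envelopes <- lapply(config$durations_ms, function(d) NULL)

  hfa <- array(0, dim = c(n_trials, n_elec_tot, n_time))
  trial_gain <- 1 + rnorm(n_trials, sd = config$trial_gain_jitter_sd)
  ex_index <- match(trials$exemplar_id, exemplars$exemplar_id)

  for (pat in unique(electrodes$patient)) {
    for (reg in names(epr)) {
      idx <- which(electrodes$patient == pat & electrodes$region == reg)
      prof <- config$region_profiles[[reg]]
      resp <- runif(length(idx)) < prof$responsive_fraction
      sgn <- ifelse(runif(length(idx)) < config$fraction_negative_responders,
                    -1, 1)
      sgn[!resp] <- 1
      responsive[idx] <- resp
      sign_vec[idx] <- sgn
      code <- build_region_code(length(idx), names(nex), exemplars, prof)
      codes[[paste(pat, reg, sep = ".")]] <- code

      env_by_dur <- lapply(config$durations_ms, response_envelope,
                           time_ms = time_ms, profile = prof)
      names(env_by_dur) <- as.character(config$durations_ms)

      # time-varying pattern weight for dynamic codes (crossfade over 200 ms)
      if (prof$stationarity == "dynamic") {
        w_early <- pmin(1, pmax(0, 1 - (time_ms - prof$switch_time_ms + 100) /
                                  200))
      } else w_early <- rep(1, n_time)

      for (k in seq_len(n_trials)) {
        env <- env_by_dur[[as.character(trials$duration_ms[k])]]
        pat1 <- code$early$exemplar[, ex_index[k]]
        base <- 1 + pat1            # positive mean response, tuned gain
        sig <- outer(base, env * w_early)
        if (!is.null(code$late)) {
          pat2 <- 1 + code$late$exemplar[, ex_index[k]]
          sig <- sig + outer(pat2, env * (1 - w_early))
        }
        sig <- sig * trial_gain[k]
        sig[!resp, ] <- 0
        sig <- sig * sgn
        hfa[k, idx, ] <- hfa[k, idx, ] + sig
      }
      if (is.null(envelopes[[1]])) envelopes <- env_by_dur
    }
  }

  if (config$noise_sd > 0)
    hfa <- hfa + array(rnorm(length(hfa), sd = config$noise_sd), dim(hfa))

  # baseline correction (mean over the pre-onset window) as real epochs get
  bl <- time_ms < 0
  blm <- apply(hfa[, , bl, drop = FALSE], c(1, 2), mean)
  hfa <- hfa - array(rep(blm, n_time), dim(hfa))

  smoothed <- smooth_tensor_array(hfa, config$smoothing_window_ms, fs)
  tensor <- trial_tensor(smoothed, time_ms, trials, electrodes,
                         sampling_rate = fs,
                         smoothing_window_ms = config$smoothing_window_ms,
                         hfa_unsmoothed = hfa)
  truth <- structure(list(
    dataset_id = paste0("sim-", config$seed, "-", n_trials, "x", n_elec_tot),
    electrodes = dplyr::mutate(electrodes,
                               responsive = responsive, sign = sign_vec),
    exemplars = exemplars,
    region_stationarity = vapply(config$region_profiles,
                                 function(p) p$stationarity, character(1)),
    codes = codes, envelopes = envelopes,
    config = config), class = "sim_truth")
  list(tensor = tensor, truth = truth)
}

#' Generate continuous raw voltage traces with embedded HFA responses
#'
#' Builds a continuous multi-electrode voltage recording in which eight
#' carriers at the centers of the 70-150 Hz sub-bands are amplitude-modulated
#' by the planted per-trial response envelope, on top of broadband Gaussian
#' noise. Used to validate the HFA extraction stage against a known envelope.
#'
#' @param config a [sim_config()]; `sampling_rate_hz` must be >= 500 (well
#'   above twice the highest carrier).
#' @param n_electrodes number of electrodes to simulate.
#' @param n_trials number of stimulus presentations.
#' @param carrier_depth modulation depth: carrier amplitude is
#'   `1 + carrier_depth * envelope`.
#' @param noise_sd SD of the additive broadband noise on the voltage.
#' @param pad_s quiet padding (s) at both ends of the recording.
#' @return list with `voltage` (electrodes x samples), `sampling_rate`,
#'   `events` tibble (onset_s, onset_sample, duration_ms + trial metadata),
#'   `electrodes` tibble, and `planted_env` (trials x samples-per-epoch
#'   envelope on the epoch window, for oracle comparison) plus `epoch_time_ms`.
#' @export
generate_raw_traces <- function(config, n_electrodes = 2, n_trials = 12,
                                carrier_depth = 1, noise_sd = 0.05,
                                pad_s = 2) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate_hz
  if (fs < 500) stop("sampling_rate_hz must be >= 500 for raw traces")
  if (fs < 2 * 150) stop("sampling rate below 2 x 150 Hz would alias the band")
  set.seed(sub_seed(config$seed, 7L))
  prof <- config$region_profiles[[1]]
  durations <- config$durations_ms[sample.int(length(config$durations_ms),
                                               n_trials, replace = TRUE)]
  isi <- config$isi_ms[sample.int(length(config$isi_ms), n_trials,
                                  replace = TRUE)]
  onsets_s <- pad_s + cumsum(c(0, head(durations + isi, -1))) / 1000 +
    seq(0, by = 2, length.out = n_trials)  # generous spacing for epochs
  total_s <- max(onsets_s) + 2 + pad_s
  n_samp <- ceiling(total_s * fs)
  tvec <- (seq_len(n_samp) - 1) / fs

  # continuous modulation envelope shared by all electrodes
  env <- numeric(n_samp)
  ep_time <- seq(config$epoch_window_ms[1], config$epoch_window_ms[2],
                 by = 1000 / fs)
  planted <- matrix(0, n_trials, length(ep_time))
  for (k in seq_len(n_trials)) {
    e_t <- response_envelope(ep_time, durations[k], prof) /
      prof$peak_amplitude
    planted[k, ] <- e_t
    i0 <- round(onsets_s[k] * fs) + 1
    idx <- i0 + round(ep_time / 1000 * fs)
    ok <- idx >= 1 & idx <= n_samp
    env[idx[ok]] <- env[idx[ok]] + e_t[ok]
  }

  centers <- seq(75, 145, by = 10)
  voltage <- matrix(0, n_electrodes, n_samp)
  for (e in seq_len(n_electrodes)) {
    carrier <- rowSums(sapply(centers, function(f)
      sin(2 * pi * f * tvec + runif(1, 0, 2 * pi))))
    voltage[e, ] <- carrier * (1 + carrier_depth * env) / length(centers) +
      rnorm(n_samp, sd = noise_sd)
  }
  events <- tibble::tibble(
    trial_id = sprintf("tr%03d", seq_len(n_trials)),
    patient = "P1", category = "face",
    exemplar_id = sprintf("face_%d", seq_len(n_trials)),
    duration_ms = durations, repetition = 1L, is_target = FALSE,
    onset_s = onsets_s, onset_sample = round(onsets_s * fs) + 1)
  electrodes <- tibble::tibble(
    electrode_id = sprintf("P1_raw_e%02d", seq_len(n_electrodes)),
    patient = "P1", region = names(config$electrodes_per_region)[1])
  list(voltage = voltage, sampling_rate = fs, events = events,
       electrodes = electrodes, planted_env = planted,
       epoch_time_ms = ep_time)
}

#' Score recovery of planted structure by a pipeline run
#'
#' Compares pipeline outputs against the generator's ground truth and
#' returns recovery scores: sensitivity/specificity of electrode
#' responsiveness, sign accuracy among true responders, and (optionally)
#' decoding and reliability recovery checks.
#'
#' @param truth the `truth` element returned by [generate_dataset()].
#' @param selection an electrode-selection tibble from [select_responsive()]
#'   (must come from the matching dataset).
#' @param decoding optional `decoding_result` for a tuned region; recovery
#'   is the peak AUC minus chance.
#' @param reliability optional `reliability_result`; recovery flag is
#'   whether the planted exemplar structure yields a significant cluster.
#' @return tibble with columns `metric`, `value` (NA when undefined, e.g.
#'   sensitivity with no planted responders).
#' @export
ground_truth_report <- function(truth, selection, decoding = NULL,
                                reliability = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(attr(selection, "dataset_id")) &&
      !identical(attr(selection, "dataset_id"), truth$dataset_id))
    stop("selection was computed on a different dataset than this truth")
  tr <- truth$electrodes
  sel <- dplyr::distinct(selection, .data$electrode_id, .data$responsive,
                         .data$sign)
  j <- dplyr::left_join(tr, sel, by = "electrode_id",
                        suffix = c("_true", "_est"))
  pos <- j$responsive_true
  sens <- if (any(pos)) mean(j$responsive_est[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!j$responsive_est[!pos]) else NA_real_
  both <- pos & j$responsive_est
  sign_acc <- if (any(both))
    mean(j$sign_true[both] == j$sign_est[both]) else NA_real_
  out <- tibble::tibble(
    metric = c("responsiveness_sensitivity", "responsiveness_specificity",
               "sign_accuracy"),
    value = c(sens, spec, sign_acc))
  if (!is.null(decoding)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "decoding_peak_auc_minus_chance",
      value = max(decoding$auc$auc) - 0.5))
  }
  if (!is.null(reliability)) {
    sig <- any(reliability$timecourse$significant)
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "reliability_cluster_recovered", value = as.numeric(sig)))
  }
  out
}
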