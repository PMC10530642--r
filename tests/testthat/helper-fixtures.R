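# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# default two-region simulation (VT stable/sustained, PFC dynamic/transient)
sim_default <- function() fixture("sim_default", function()
  generate_dataset(sim_config(seed = 42)))

# noiseless, jitter-free single-region simulation
sim_clean <- function() fixture("sim_clean", function()
  generate_dataset(sim_config(
    seed = 7, noise_sd = 0, trial_gain_jitter_sd = 0, n_patients = 1,
    electrodes_per_region = c(VT = 10),
    region_profiles = list(VT = coding_profile(responsive_fraction = 1)),
    fraction_negative_responders = 0)))

# hand-built trial tensor: values is trials x electrodes x time (or a
# trials x time matrix for one electrode); constant metadata unless given
toy_tensor <- function(values, categories, durations = NULL,
                       exemplar_id = NULL, repetition = NULL,
                       patient = NULL, time_ms = NULL, fs = 1000,
                       region = "VT") {
  if (length(dim(values)) == 2)
    values <- array(values, dim = c(nrow(values), 1, ncol(values)))
  d <- dim(values)
  if (is.null(time_ms)) time_ms <- seq_len(d[3]) * 1000 / fs
  trials <- tibble::tibble(
    trial_id = sprintf("t%02d", seq_len(d[1])),
    patient = patient %||% rep("P1", d[1]),
    category = categories,
    exemplar_id = exemplar_id %||% sprintf("ex%02d", seq_len(d[1])),
    duration_ms = durations %||% rep(900, d[1]),
    repetition = repetition %||% rep(1L, d[1]))
  electrodes <- tibble::tibble(
    electrode_id = sprintf("e%02d", seq_len(d[2])),
    patient = "P1", region = region)
  trial_tensor(values, time_ms, trials, electrodes, sampling_rate = fs,
               hfa_unsmoothed = values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built rsa_presentations object from a pattern array
# pat: exemplar x 2 x electrode x time
toy_presentations <- function(pat, categories) {
  structure(list(
    pat = pat,
    exemplars = tibble::tibble(
      exemplar_id = sprintf("ex%02d", seq_len(dim(pat)[1])),
      category = categories),
    time_ms = seq_len(dim(pat)[4]) * 5,
    n_pairs = dim(pat)[1] * (dim(pat)[1] - 1) / 2),
    class = "rsa_presentations")
}

# brute-force AUC by pair counting (independent oracle)
auc_brute <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
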