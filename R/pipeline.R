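#' Write epoched data to a plain-text container
#'
#' Serializes a [trial_tensor()] to a directory: a JSON header (time axis,
#' rates), the HFA array as a full-precision TSV ((trial, electrode) rows x
#' time columns), and trial/electrode metadata TSVs. The round trip through
#' [read_epochs()] is lossless (17 significant digits).
#'
#' @param x a [trial_tensor()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "trial_tensor"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(format = "hfadyn-epochs", version = 1L,
              dim = dim(x$hfa), time_ms = x$time_ms,
              sampling_rate = x$sampling_rate,
              smoothing_window_ms = x$smoothing_window_ms,
              has_unsmoothed = !is.null(x$hfa_unsmoothed))
  jsonlite::write_json(hdr, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array <- function(arr, file) {
    d <- dim(arr)
    m <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
    ch <- formatC(m, format = "g", digits = 17)
    write.table(ch, file.path(path, file), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  write_array(x$hfa, "hfa.tsv")
  if (!is.null(x$hfa_unsmoothed))
    write_array(x$hfa_unsmoothed, "hfa_unsmoothed.tsv")
  write.table(x$trials, file.path(path, "trials.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(x$electrodes, file.path(path, "electrodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read epoched data from a plain-text container
#'
#' Inverse of [write_epochs()]. Unknown metadata columns are preserved with
#' a warning; a malformed container raises a format error.
#'
#' @param path container directory.
#' @return a [trial_tensor()].
#' @export
read_epochs <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf))
    stop("not an hfadyn epochs container (missing header.json): ", path)
  hdr <- tryCatch(jsonlite::read_json(hf, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupted epochs container header: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(hdr$format, "hfadyn-epochs"))
    stop("not an hfadyn epochs container: format field is ",
         deparse(hdr$format))
  d <- as.integer(hdr$dim)
  read_array <- function(file) {
    m <- as.matrix(read.table(file.path(path, file), sep = "\t",
                              header = FALSE))
    if (!identical(dim(m), c(d[1] * d[2], d[3])))
      stop("corrupted epochs container: array shape mismatch in ", file)
    array(as.numeric(m), dim = d)
  }
  trials <- tibble::as_tibble(read.table(
    file.path(path, "trials.tsv"), sep = "\t", header = TRUE))
  electrodes <- tibble::as_tibble(read.table(
    file.path(path, "electrodes.tsv"), sep = "\t", header = TRUE))
  known <- c("trial_id", "patient", "category", "exemplar_id",
             "duration_ms", "repetition", "is_target")
  extra <- setdiff(names(trials), known)
  if (length(extra))
    warning("unknown trial metadata column(s) preserved: ",
            paste(extra, collapse = ", "))
  trial_tensor(
    read_array("hfa.tsv"), as.numeric(hdr$time_ms), trials, electrodes,
    sampling_rate = hdr$sampling_rate,
    smoothing_window_ms = hdr$smoothing_window_ms,
    hfa_unsmoothed = if (isTRUE(hdr$has_unsmoothed))
      read_array("hfa_unsmoothed.tsv"))
}

#' Run the full analysis pipeline on simulated (or loaded) epochs
#'
#' Orchestrates simulate -> electrode selection -> state-space duration
#' test -> pairwise decoding -> exemplar reliability, writing each stage's
#' result as TSV plus a provenance JSON (package version, master seed,
#' per-stage sub-seeds, parameter hash). Stages run in dependency order;
#' when `out_dir` already contains an epochs container and `"simulate"` is
#' not requested, epochs are read from disk instead.
#'
#' @param config a [sim_config()] (used by the simulate stage).
#' @param out_dir output directory.
#' @param stages subset of `c("simulate", "select", "statespace",
#'   "decode", "rsa")`.
#' @param seed master seed; every stochastic stage gets a recorded derived
#'   sub-seed.
#' @param profile `"standard"` (1000 permutations, 5x5 CV) or `"fast"`
#'   (200 permutations, 3x3 CV) parameter profile.
#' @param decode_pair category pair for the decoding stage.
#' @return named list of stage results, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         stages = c("simulate", "select", "statespace",
                                    "decode", "rsa"),
                         seed = 1, profile = c("standard", "fast"),
                         decode_pair = c("face", "watch")) {
  profile <- match.arg(profile)
  pp <- if (profile == "standard")
    list(n_perm = 1000, n_folds = 5, n_repeats = 5)
  else list(n_perm = 200, n_folds = 3, n_repeats = 3)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  epochs_dir <- file.path(out_dir, "epochs")

  if ("simulate" %in% stages) {
    config$seed <- sub_seed(seed, 1L)
    sim <- generate_dataset(config)
    tensor <- sim$tensor
    results$truth <- sim$truth
    write_epochs(tensor, epochs_dir)
  } else {
    if (!file.exists(file.path(epochs_dir, "header.json")))
      stop("stage 'select': no epochs found in ", epochs_dir,
           " and simulation was not requested")
    tensor <- read_epochs(epochs_dir)
  }
  results$tensor <- tensor

  if ("select" %in% stages) {
    sel <- select_responsive(tensor)
    results$selection <- sel
    write.table(sel[, setdiff(names(sel), "t_sum")],
                file.path(out_dir, "selection.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  resp_ids <- if (!is.null(results$selection))
    unique(results$selection$electrode_id[results$selection$responsive])
  else tensor$electrodes$electrode_id

  if ("statespace" %in% stages) {
    durs <- sort(unique(tensor$trials$duration_ms))
    if (length(durs) >= 2) {
      reg <- tensor$electrodes$region[1]
      xx <- tt_subset(tensor, electrodes = region == reg &
                        electrode_id %in% resp_ids)
      dt <- duration_test(xx, dur_pair = durs[1:2],
                          n_perm = pp$n_perm, seed = sub_seed(seed, 2L))
      results$duration_test <- dt
      write.table(dt, file.path(out_dir, "duration_test.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  if ("decode" %in% stages) {
    results$decoding <- list()
    for (reg in unique(tensor$electrodes$region)) {
      xx <- tt_subset(tensor, electrodes = region == reg &
                        electrode_id %in% resp_ids)
      dr <- time_resolved_decoding(
        xx, decode_pair, n_folds = pp$n_folds, n_repeats = pp$n_repeats,
        min_duration_ms = 900, seed = sub_seed(seed, 3L))
      results$decoding[[reg]] <- dr
      write.table(dr$auc, file.path(out_dir, paste0("decoding_", reg,
                                                    ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("rsa" %in% stages) {
    pres <- rsa_presentations(tensor, time_step = 4)
    ir <- item_reliability(pres, n_perm = pp$n_perm,
                           seed = sub_seed(seed, 4L))
    gr <- geometry_reliability(pres, n_perm = pp$n_perm,
                               seed = sub_seed(seed, 5L))
    results$ir <- ir
    results$gr <- gr
    write.table(ir$timecourse, file.path(out_dir, "item_reliability.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(gr$timecourse,
                file.path(out_dir, "geometry_reliability.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  prov <- list(
    package = "hfadyn",
    version = as.character(utils::packageVersion("hfadyn")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = seed,
    sub_seeds = list(simulate = sub_seed(seed, 1L),
                     statespace = sub_seed(seed, 2L),
                     decode = sub_seed(seed, 3L),
                     rsa_ir = sub_seed(seed, 4L),
                     rsa_gr = sub_seed(seed, 5L)),
    profile = profile,
    stages = stages,
    config_hash = rlang::hash(config))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(results)
}
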