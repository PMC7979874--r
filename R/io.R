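# File-format plumbing: BIDS-events-style schedule TSVs, long-format
# probability tables, spectra/results TSVs, and a flat YAML/JSON run
# configuration.

#' Write a trial schedule as a BIDS-events-style TSV
#'
#' @param schedule A `trial_schedule` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  df <- as.data.frame(schedule)
  names(df)[names(df) == "condition"] <- "trial_type"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial schedule TSV
#'
#' @param path File written by [write_schedule_tsv()].
#' @return A `trial_schedule` data.frame.
#' @export
read_schedule_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "trial_type"] <- "condition"
  class(df) <- c("trial_schedule", "data.frame")
  df
}

#' Write probability time courses as long-format TSV
#'
#' One row per (participant, run, trial, TR, class) with the probability,
#' the class's serial position in the trial's true order, and the speed.
#'
#' @param tcs List of [probability_timecourse()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timecourses_tsv <- function(tcs, path) {
  rows <- lapply(tcs, function(tc) {
    nt <- n_trs(tc)
    nc <- ncol(tc$probs)
    data.frame(participant = tc$participant_id, run = tc$run_id,
               trial = tc$trial_id, tr = rep(seq_len(nt), nc),
               class = rep(seq_len(nc), each = nt),
               serial_position = rep(tc$position_map, each = nt),
               speed_ms = tc$speed_ms,
               probability = as.numeric(tc$probs))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read probability time courses from long-format TSV
#'
#' @param path File written by [write_timecourses_tsv()].
#' @return List of [probability_timecourse()]s, ordered by trial id.
#' @export
read_timecourses_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  trials <- split(df, df$trial)
  out <- lapply(trials, function(tr) {
    tr <- tr[order(tr$class, tr$tr), ]
    nt <- max(tr$tr)
    nc <- max(tr$class)
    probs <- matrix(tr$probability, nt, nc)
    pm <- tr$serial_position[match(seq_len(nc), tr$class)]
    probability_timecourse(probs, position_map = pm,
                           speed_ms = tr$speed_ms[1L],
                           trial_id = tr$trial[1L], run_id = tr$run[1L],
                           participant_id = tr$participant[1L])
  })
  out[order(as.integer(names(out)))]
}

#' Write a spectrum (or any tidy results table) as TSV
#'
#' @param df A data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Flat key-value configuration covering acquisition timing, response
#' parameters, the speed list, noise settings, classifier and spectral
#' configuration.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(seed = 1L,
       tr_seconds = 1.25, n_trs_trial = 13L,
       lambda = 5.24, d = 0.56, A = 0.5, b = 0.1,
       isi_ms = c(32, 64, 128, 512, 2048),
       stim_duration_seconds = 0.1,
       noise = "none", noise_sd = 0.02,
       rest_concentration = 0.5, rest_ar_coef = 0.75,
       voxel_noise_sd = 1.0, n_voxels = 200L,
       cost_C = 1.0, max_iterations = 4000L,
       smoothing_width_hz = 0.005, band_halfwidth_hz = 0.01,
       oversample_factor = 2,
       output_dir = ".")
}

#' Read a run configuration (YAML or JSON)
#'
#' Unknown keys raise an error; missing keys fall back to
#' [default_config()].
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return Named list merging the file over the defaults.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, cfg)
}

#' Write a run configuration as YAML
#'
#' @param config Named list (see [default_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_params <- function(cfg) {
  list(params = response_params(A = cfg$A, lambda = cfg$lambda, d = cfg$d,
                                b = cfg$b),
       acq = acquisition_params(tr_seconds = cfg$tr_seconds,
                                n_trs_trial = cfg$n_trs_trial),
       spectral = spectral_config(smoothing_width_hz = cfg$smoothing_width_hz,
                                  band_halfwidth_hz = cfg$band_halfwidth_hz,
                                  oversample_factor = cfg$oversample_factor))
}
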