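# Frequency-domain detection of sequential events. The sequentiality-slope
# time series of rest or concatenated trial data is analyzed with a
# Lomb-Scargle periodogram (valid for the unevenly sampled timestamps that
# concatenation produces), normalized, smoothed with a running average, and
# summarized as mean power in the band around the predicted difference-wave
# frequency. Timestamps are in TR units; following the reference analysis
# convention the frequency axis of per-TR-sampled series is labelled Hz.

#' Spectral analysis configuration
#'
#' @param smoothing_width_hz Width of the running-average smoother on the
#'   frequency axis (default 0.005).
#' @param band_halfwidth_hz Half-width of the predicted-frequency band
#'   (default 0.01, matched to the smoothing).
#' @param oversample_factor Frequency-grid oversampling factor (default 2).
#' @param normalization `"total"` (divide by total power, the default) or
#'   `"none"`.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(smoothing_width_hz = 0.005,
                            band_halfwidth_hz = 0.01,
                            oversample_factor = 2,
                            normalization = c("total", "none")) {
  stopifnot(smoothing_width_hz > 0, band_halfwidth_hz > 0,
            oversample_factor > 0)
  structure(list(smoothing_width_hz = smoothing_width_hz,
                 band_halfwidth_hz = band_halfwidth_hz,
                 oversample_factor = oversample_factor,
                 normalization = match.arg(normalization)),
            class = "spectral_config")
}

#' Mean per-TR standard deviation of class probabilities
#'
#' Rest data are spiky (one class dominating each TR, high SD across
#' classes) whereas fast near-simultaneous sequences pull the class
#' probabilities together (low SD); the mean per-TR SD therefore separates
#' the two regimes.
#'
#' @param tc A [probability_timecourse()] or probability matrix.
#' @return Mean over TRs of the (population) standard deviation across the
#'   classes of each TR row; a one-hot row contributes sqrt(0.8/5) = 0.4.
#' @export
probability_sd_per_tr <- function(tc) {
  probs <- if (inherits(tc, "probability_timecourse")) tc$probs else as.matrix(tc)
  row_sd <- apply(probs, 1L, function(p) sqrt(mean((p - mean(p))^2)))
  mean(row_sd)
}

#' Sequentiality-slope time series
#'
#' Computes the per-TR (sign-flipped) regression slope of probability on
#' serial position under a given ordering, for a single time course or a
#' list of concatenated trial time courses. Concatenation preserves each
#' trial's position on a global TR grid, so the series is unevenly sampled
#' (gaps between trial windows) and strictly increasing in time.
#'
#' @param x A [probability_timecourse()] or a list of them (concatenated in
#'   order).
#' @param position_map Optional ordering to impose on all trials (integer
#'   vector, class -> position); defaults to each trial's own map.
#' @param trs_use TRs used from each trial when `x` is a list (default 2:13,
#'   the relevant window).
#' @param trial_stride TR spacing of consecutive trial windows on the global
#'   grid (default 13).
#' @param source Label for the series (`"rest"`, `"seq32"`, ...).
#' @return A data.frame of class `slope_series`: `time` (TR units, strictly
#'   increasing), `slope`, `source`.
#' @export
slope_series <- function(x, position_map = NULL, trs_use = 2:13,
                         trial_stride = 13L, source = "series") {
  if (inherits(x, "probability_timecourse")) {
    tc <- x
    if (!is.null(position_map)) tc$position_map <- as.integer(position_map)
    out <- data.frame(time = seq_len(n_trs(tc)) - 1,
                      slope = tr_slope(tc), source = source)
  } else {
    stopifnot(is.list(x), length(x) >= 1L)
    rows <- lapply(seq_along(x), function(j) {
      tc <- x[[j]]
      stopifnot(inherits(tc, "probability_timecourse"),
                max(trs_use) <= n_trs(tc))
      if (!is.null(position_map)) tc$position_map <- as.integer(position_map)
      sl <- vapply(trs_use, function(k) tr_slope(tc, k), numeric(1))
      data.frame(time = (j - 1L) * trial_stride + trs_use - 1,
                 slope = sl, source = source)
    })
    out <- do.call(rbind, rows)
  }
  stopifnot(all(diff(out$time) > 0))
  class(out) <- c("slope_series", "data.frame")
  out
}

#' Lomb-Scargle periodogram of a slope series
#'
#' Classical normalized Lomb-Scargle periodogram (with the phase-shift tau
#' that makes the estimate invariant to time translation), evaluated on a
#' frequency grid oversampled by `oversample_factor` up to the pseudo-
#' Nyquist frequency of the median sampling interval, then normalized and
#' smoothed with a running average of width `smoothing_width_hz` (the window
#' shrinks at the grid edges).
#'
#' @param series A `slope_series` data.frame (or any data.frame with `time`
#'   and `slope`), or a numeric vector of values with `times` given.
#' @param config A [spectral_config()].
#' @param times Optional explicit timestamps when `series` is a vector.
#' @param freqs Optional explicit frequency grid (overrides the
#'   oversampled default grid).
#' @return A data.frame of class `spectrum_df`: `frequency_hz`, `power`
#'   (smoothed, normalized), `power_raw` (unsmoothed, normalized);
#'   attributes record the config. A constant series yields zero power with
#'   a warning.
#' @export
lomb_scargle <- function(series, config = spectral_config(), times = NULL,
                         freqs = NULL) {
  if (is.data.frame(series)) {
    t <- series$time
    y <- series$slope
  } else {
    y <- as.numeric(series)
    t <- if (is.null(times)) seq_along(y) - 1 else times
  }
  stopifnot(length(y) >= 8L, length(t) == length(y), all(diff(t) > 0))

  span <- max(t) - min(t)
  dt_med <- stats::median(diff(t))
  f_nyq <- 1 / (2 * dt_med)
  df <- 1 / (span * config$oversample_factor)
  if (is.null(freqs)) freqs <- seq(df, f_nyq, by = df)
  else df <- freqs[2L] - freqs[1L]

  yc <- y - mean(y)
  var_y <- sum(yc^2) / (length(y) - 1L)
  if (var_y == 0) {
    warning("constant series: returning zero spectrum")
    power <- rep(0, length(freqs))
  } else {
    power <- vapply(freqs, function(f) {
      w <- 2 * pi * f
      tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
      ct <- cos(w * (t - tau))
      st <- sin(w * (t - tau))
      (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / (2 * var_y)
    }, numeric(1))
  }
  if (config$normalization == "total" && sum(power) > 0)
    power <- power / sum(power)
  smoothed <- running_mean(power, width_bins(config$smoothing_width_hz, df))
  out <- data.frame(frequency_hz = freqs, power = smoothed,
                    power_raw = power)
  attr(out, "config") <- config
  class(out) <- c("spectrum_df", "data.frame")
  out
}

# half-window in bins for a total width in Hz; a requested smoother always
# covers at least the adjacent bins
width_bins <- function(width_hz, df) max(1L, floor((width_hz / 2) / df))

# running mean with shrinking windows at the edges
running_mean <- function(x, halfwidth) {
  if (halfwidth == 0L) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - halfwidth)
    hi <- min(n, i + halfwidth)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Mean power in a frequency band
#'
#' @param spectrum A `spectrum_df` from [lomb_scargle()].
#' @param center_hz Band center.
#' @param halfwidth_hz Band half-width (default 0.01).
#' @return Mean of the (smoothed) power bins inside the closed band.
#' @export
band_power <- function(spectrum, center_hz, halfwidth_hz = 0.01) {
  stopifnot(inherits(spectrum, "spectrum_df"))
  f <- spectrum$frequency_hz
  if (center_hz - halfwidth_hz < min(f) - 1e-12 ||
      center_hz + halfwidth_hz > max(f) + 1e-12)
    stop("band extends beyond the frequency grid", call. = FALSE)
  eps <- 1e-9 * max(1, abs(center_hz))   # guard against grid round-off
  sel <- f >= center_hz - halfwidth_hz - eps & f <= center_hz + halfwidth_hz + eps
  mean(spectrum$power[sel])
}

#' Permutation-averaged spectrum of rest data
#'
#' When the true ordering of potential replay events is unknown, the slope
#' series and its spectrum are computed under every one of the 120 possible
#' orderings of the five classes and the spectra are averaged.
#'
#' @param rest A [probability_timecourse()].
#' @param config A [spectral_config()].
#' @return A `spectrum_df` holding the mean spectrum over all orderings.
#' @export
permutation_averaged_spectrum <- function(rest, config = spectral_config()) {
  stopifnot(inherits(rest, "probability_timecourse"),
            ncol(rest$probs) == 5L)
  perms <- all_orderings(5L)
  acc <- NULL
  for (i in seq_len(nrow(perms))) {
    sp <- lomb_scargle(slope_series(rest, position_map = perms[i, ]), config)
    if (is.null(acc)) {
      acc <- sp
    } else {
      acc$power <- acc$power + sp$power
      acc$power_raw <- acc$power_raw + sp$power_raw
    }
  }
  acc$power <- acc$power / nrow(perms)
  acc$power_raw <- acc$power_raw / nrow(perms)
  acc
}

#' Insertion sweep: metrics over kappa and insert-count grids
#'
#' For each combination of signal fraction `kappa` and number of inserted
#' events, repeatedly blends randomly chosen trial segments into the rest
#' run ([insert_events()]) and records the mean per-TR probability SD and
#' the band power at the fast and slow predicted frequencies of the
#' resulting slope-series spectrum.
#'
#' @param rest A [probability_timecourse()] rest run.
#' @param trial_segments List of 12-TR probability matrices (see
#'   [sequence_insert_segment()]).
#' @param kappas Signal-fraction grid (default the reference grid).
#' @param n_inserts_grid Insert-count grid (default 1:6).
#' @param n_reps Seeded replicates per cell.
#' @param seed Base seed; each cell/replicate derives its own sub-seed.
#' @param band_centers Named vector of band-center frequencies (default the
#'   predicted fast and slow frequencies with lambda = 5.24).
#' @param config A [spectral_config()].
#' @return Tidy data.frame: `kappa`, `n_inserts`, `replicate`, `metric`,
#'   `value`.
#' @export
insertion_sweep <- function(rest, trial_segments,
                            kappas = c(4/5, 1/2, 1/4, 1/8, 0),
                            n_inserts_grid = 1:6, n_reps = 10L, seed = 1L,
                            band_centers = c(
                              fast = predicted_frequency(5.24, 0.628),
                              slow = predicted_frequency(5.24, 8.692)),
                            config = spectral_config()) {
  stopifnot(inherits(rest, "probability_timecourse"))
  rows <- list()
  for (kap in kappas) for (ni in n_inserts_grid) {
    for (rep_i in seq_len(n_reps)) {
      # sub-seed independent of kappa: cells differing only in kappa share
      # insertion geometry and trial choices, so comparisons are paired
      sub_seed <- (seed * 10007L + ni * 101L + rep_i) %% .Machine$integer.max
      ins <- insert_events(rest, trial_segments,
                           blend_spec(kappa = kap, n_inserts = ni,
                                      seed = sub_seed))
      spec <- lomb_scargle(slope_series(ins$tc), config)
      vals <- c(probability_sd = probability_sd_per_tr(ins$tc),
                vapply(names(band_centers), function(nm)
                  band_power(spec, band_centers[[nm]],
                             config$band_halfwidth_hz), numeric(1)))
      names(vals) <- c("probability_sd",
                       paste0("band_power_", names(band_centers)))
      rows[[length(rows) + 1L]] <-
        data.frame(kappa = kap, n_inserts = ni, replicate = rep_i,
                   metric = names(vals), value = unname(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
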