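#' Probability time course of one trial
#'
#' The universal currency of all sequence metrics: a TR x class matrix of
#' classifier probabilities for one trial, together with the class-to-serial-
#' position map of the trial's true order and identifying metadata.
#'
#' @param probs Numeric matrix, TRs in rows, classes in columns.
#' @param position_map Integer vector, one entry per class column:
#'   `position_map[k]` is the serial position of class `k` in the trial's
#'   true order. Must be a bijection onto `1..ncol(probs)` for full sequence
#'   trials; partial maps (with `NA`) are allowed for reduced variants.
#' @param speed_ms Sequence speed label (ISI in ms), or `NA` for rest.
#' @param trial_id,run_id,participant_id Optional identifiers.
#' @return An object of class `probability_timecourse`.
#' @export
probability_timecourse <- function(probs, position_map = seq_len(ncol(probs)),
                                   speed_ms = NA_real_, trial_id = NA_integer_,
                                   run_id = NA_integer_,
                                   participant_id = NA_integer_) {
  probs <- as.matrix(probs)
  stopifnot(is.numeric(probs), nrow(probs) >= 1L, ncol(probs) >= 2L)
  if (any(probs < -1e-9 | probs > 1 + 1e-9, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  stopifnot(length(position_map) == ncol(probs))
  pm <- as.integer(position_map)
  known <- pm[!is.na(pm)]
  if (anyDuplicated(known))
    stop("'position_map' must not assign one position twice", call. = FALSE)
  structure(list(probs = probs, position_map = pm,
                 speed_ms = speed_ms, trial_id = trial_id, run_id = run_id,
                 participant_id = participant_id),
            class = "probability_timecourse")
}

#' @export
print.probability_timecourse <- function(x, ...) {
  cat(sprintf("Probability time course: %d TRs x %d classes (speed %s ms, trial %s)\n",
              nrow(x$probs), ncol(x$probs), format(x$speed_ms), format(x$trial_id)))
  invisible(x)
}

#' Number of TRs of a probability time course
#' @param tc A [probability_timecourse()].
#' @return Integer TR count.
#' @export
n_trs <- function(tc) {
  stopifnot(inherits(tc, "probability_timecourse"))
  nrow(tc$probs)
}
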