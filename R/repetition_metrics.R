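# Interference metrics for two-class nine-item repetition trials: mean
# probabilities of the event types (first, second, non-sequence) over the
# relevant window, and classification of transitions between consecutively
# decoded classes. The relevant window TRs 2-7 is a fixed constant of the
# reference analysis (it is not derived from the period rule).

REPETITION_WINDOW <- 2:7

transition_categories <- c("forward", "backward", "repetition_first",
                           "repetition_second", "outward", "inward",
                           "outside", "repetition_nonseq")

#' Mean probabilities of repetition-trial event types
#'
#' @param tc A [probability_timecourse()] of a repetition trial.
#' @param first_class,second_class Class indices of the first and second
#'   sequence item (distinct).
#' @param window TRs to average over (default the relevant window 2-7).
#' @return Named numeric vector: `first`, `second`, `non_sequence` (the
#'   latter averaged over all TRs and all absent classes).
#' @export
event_type_probabilities <- function(tc, first_class, second_class,
                                     window = REPETITION_WINDOW) {
  stopifnot(inherits(tc, "probability_timecourse"),
            first_class != second_class,
            max(window) <= n_trs(tc))
  other <- setdiff(seq_len(ncol(tc$probs)), c(first_class, second_class))
  sub <- tc$probs[window, , drop = FALSE]
  c(first = mean(sub[, first_class]),
    second = mean(sub[, second_class]),
    non_sequence = mean(sub[, other]))
}

#' Classify transitions between consecutively decoded classes
#'
#' Each consecutive pair of decoded labels is assigned exactly one category:
#' `forward` (first -> second), `backward` (second -> first),
#' `repetition_first`/`repetition_second` (a sequence item repeating),
#' `outward` (sequence item -> non-sequence item), `inward` (non-sequence ->
#' sequence), `outside` (between two distinct non-sequence items) and
#' `repetition_nonseq` (a non-sequence item repeating).
#'
#' @param labels Integer vector of decoded class labels per TR (>= 2 TRs,
#'   values in 1..5).
#' @param first_class,second_class The trial's two sequence classes.
#' @return List of class `transition_tally`: `counts` (named integer),
#'   `proportions` (counts / number of transitions), `proportions_no_rep`
#'   (denominator excluding all repetition pairs; `NaN` if none remain),
#'   `n_transitions`.
#' @export
classify_transitions <- function(labels, first_class, second_class) {
  labels <- as.integer(labels)
  stopifnot(length(labels) >= 2L, first_class != second_class)
  if (any(labels < 1L | labels > 5L))
    stop("decoded labels must be classes 1..5", call. = FALSE)
  a <- labels[-length(labels)]
  b <- labels[-1L]
  seq_cls <- c(first_class, second_class)
  cat <- character(length(a))
  for (i in seq_along(a)) {
    cat[i] <- if (a[i] == b[i]) {
      if (a[i] == first_class) "repetition_first"
      else if (a[i] == second_class) "repetition_second"
      else "repetition_nonseq"
    } else if (a[i] == first_class && b[i] == second_class) "forward"
    else if (a[i] == second_class && b[i] == first_class) "backward"
    else if (a[i] %in% seq_cls) "outward"
    else if (b[i] %in% seq_cls) "inward"
    else "outside"
  }
  counts <- table(factor(cat, levels = transition_categories))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- length(a)
  is_rep <- grepl("^repetition", names(counts))
  n_no_rep <- n - sum(counts[is_rep])
  prop_no_rep <- counts / n_no_rep
  prop_no_rep[is_rep] <- 0
  structure(list(counts = counts,
                 proportions = counts / n,
                 proportions_no_rep = prop_no_rep,
                 n_transitions = n),
            class = "transition_tally")
}

#' Per-condition repetition-trial contrasts
#'
#' Aggregates event-type probabilities and transition proportions across
#' repetition trials: participant-level means first, then condition means.
#'
#' @param trials List, one element per trial, each a list with `tc`
#'   (a [probability_timecourse()]), `first_class`, `second_class`,
#'   `condition` (e.g. `"forward_interference"`), and optionally
#'   `participant_id`.
#' @param window TRs used for event-type means and decoded transitions.
#' @return List with `event_types` and `transitions`: data.frames of
#'   condition-level means.
#' @export
condition_contrast <- function(trials, window = REPETITION_WINDOW) {
  stopifnot(length(trials) >= 1L)
  per_trial <- lapply(trials, function(tr) {
    ep <- event_type_probabilities(tr$tc, tr$first_class, tr$second_class,
                                   window)
    labels <- decoded_class(tr$tc)[window]
    tally <- classify_transitions(labels, tr$first_class, tr$second_class)
    pid <- if (is.null(tr$participant_id)) 1L else tr$participant_id
    data.frame(participant_id = pid, condition = tr$condition,
               first = ep[["first"]], second = ep[["second"]],
               non_sequence = ep[["non_sequence"]],
               t(tally$proportions))
  })
  df <- do.call(rbind, per_trial)
  value_cols <- setdiff(names(df), c("participant_id", "condition"))
  participant_means <- stats::aggregate(df[value_cols],
                                        df[c("participant_id", "condition")],
                                        mean)
  event_types <- stats::aggregate(
    participant_means[c("first", "second", "non_sequence")],
    participant_means["condition"], mean)
  transitions <- stats::aggregate(
    participant_means[transition_categories],
    participant_means["condition"], mean)
  list(event_types = event_types, transitions = transitions)
}

#' Transition matrix of decoded classes
#'
#' 5 x 5 matrix of mean per-trial transition proportions between decoded
#' classes (rows: from, columns: to).
#'
#' @param label_list List of integer label vectors (one per trial).
#' @return 5 x 5 numeric matrix; proportions within each trial sum to 1.
#' @export
transition_matrix <- function(label_list) {
  mats <- lapply(label_list, function(labels) {
    a <- labels[-length(labels)]
    b <- labels[-1L]
    m <- matrix(0, 5L, 5L)
    for (i in seq_along(a)) m[a[i], b[i]] <- m[a[i], b[i]] + 1
    m / length(a)
  })
  Reduce(`+`, mats) / length(mats)
}
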