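# TR-wise sequentiality statistics on five-item sequence-trial probability
# time courses: regression slope of probability on serial position
# (sign-flipped so positive = forward ordering), Kendall rank correlation,
# mean step size of probability-ordered events, decoded position and its
# transitions, and aggregation over the speed-adjusted forward/backward
# periods.

#' Normalize probabilities by trial-wise class sums
#'
#' Divides each class column by its sum over the trial's TRs, so each
#' class's evidence integrates to 1 across the trial.
#'
#' @param tc A [probability_timecourse()].
#' @return The normalized time course; zero columns are left as zeros with a
#'   warning.
#' @export
normalize_trialwise <- function(tc) {
  stopifnot(inherits(tc, "probability_timecourse"))
  sums <- colSums(tc$probs)
  if (any(sums == 0)) {
    warning("zero-sum class column(s) left unnormalized")
    sums[sums == 0] <- 1
  }
  out <- tc
  # column-normalized evidence shares; values stay in [0, 1]
  out$probs <- sweep(tc$probs, 2L, sums, "/")
  out
}

#' Normalize each TR's probabilities to the simplex
#'
#' @param tc A [probability_timecourse()].
#' @return Time course with rows rescaled to sum to 1 (zero rows left with a
#'   warning).
#' @export
normalize_per_tr <- function(tc) {
  stopifnot(inherits(tc, "probability_timecourse"))
  rs <- rowSums(tc$probs, na.rm = TRUE)
  if (any(rs == 0)) {
    warning("zero-sum TR row(s) left unnormalized")
    rs[rs == 0] <- 1
  }
  out <- tc
  out$probs <- tc$probs / rs
  out
}

# probabilities and positions at one TR, dropping classes with NA in either
tr_xy <- function(tc, tr) {
  stopifnot(inherits(tc, "probability_timecourse"),
            tr >= 1L, tr <= n_trs(tc))
  x <- tc$probs[tr, ]
  p <- tc$position_map
  keep <- !is.na(p) & !is.na(x)
  list(probs = x[keep], pos = as.numeric(p[keep]), class = which(keep))
}

#' Sequentiality slope at one TR
#'
#' Least-squares slope of class probability on serial position, with the
#' sign flipped so that positive values indicate forward ordering (earlier
#' items more active).
#'
#' @param tc A [probability_timecourse()].
#' @param tr TR index (1-based); if missing, all TRs.
#' @return Numeric slope(s).
#' @export
tr_slope <- function(tc, tr = NULL) {
  if (is.null(tr)) return(vapply(seq_len(n_trs(tc)), function(k)
    tr_slope(tc, k), numeric(1)))
  z <- tr_xy(tc, tr)
  pc <- z$pos - mean(z$pos)
  -sum(pc * z$probs) / sum(pc^2)
}

#' Sequentiality rank correlation at one TR
#'
#' Kendall's tau between serial position and probability, sign-flipped to
#' match the slope convention (strictly decreasing probabilities over
#' positions give +1).
#'
#' @inheritParams tr_slope
#' @return Tau value(s) in \[-1, 1\].
#' @export
tr_rank_corr <- function(tc, tr = NULL) {
  if (is.null(tr)) return(vapply(seq_len(n_trs(tc)), function(k)
    tr_rank_corr(tc, k), numeric(1)))
  z <- tr_xy(tc, tr)
  if (stats::sd(z$probs) == 0) return(0)   # no ordering evidence
  -stats::cor(z$pos, z$probs, method = "kendall")
}

#' Mean step size of probability-ordered events at one TR
#'
#' Classes are sorted by descending probability (ties broken by lowest
#' class index); the metric is the mean of successive differences of their
#' serial positions. A perfectly forward-ordered TR gives +1, a perfectly
#' backward-ordered TR -1.
#'
#' @inheritParams tr_slope
#' @return Mean ordered step(s).
#' @export
tr_mean_step <- function(tc, tr = NULL) {
  if (is.null(tr)) return(vapply(seq_len(n_trs(tc)), function(k)
    tr_mean_step(tc, k), numeric(1)))
  z <- tr_xy(tc, tr)
  ord <- order(-z$probs, z$class)
  mean(diff(z$pos[ord]))
}

#' Serial position of the decoded (argmax) class at one TR
#'
#' @inheritParams tr_slope
#' @return Integer position(s); ties are broken deterministically by lowest
#'   class index.
#' @export
decoded_position <- function(tc, tr = NULL) {
  if (is.null(tr)) return(vapply(seq_len(n_trs(tc)), function(k)
    decoded_position(tc, k), integer(1)))
  z <- tr_xy(tc, tr)
  as.integer(z$pos[which.max(z$probs)])
}

#' Decoded class label at one TR
#'
#' @inheritParams tr_slope
#' @return Integer class index(es) of the most probable class (ties broken
#'   by lowest class index).
#' @export
decoded_class <- function(tc, tr = NULL) {
  if (is.null(tr)) return(vapply(seq_len(n_trs(tc)), function(k)
    decoded_class(tc, k), integer(1)))
  stopifnot(inherits(tc, "probability_timecourse"))
  as.integer(which.max(tc$probs[tr, ]))
}

#' Step sizes between consecutively decoded positions
#'
#' A 2 -> 4 transition between consecutive TRs is a forward step of +2, a
#' 3 -> 2 transition a backward step of -1.
#'
#' @param positions Integer vector of decoded serial positions per TR
#'   (length >= 2).
#' @return Numeric vector of position differences, length `n - 1`; element
#'   `i` is the step from TR `i` to TR `i + 1`.
#' @export
transition_steps <- function(positions) {
  stopifnot(length(positions) >= 2L)
  diff(as.numeric(positions))
}

# literal TR-pair sets per speed for the early/late transition analysis
transition_tr_sets <- function(speed_ms) {
  key <- as.character(speed_ms)
  if (key %in% c("32", "64", "128")) {
    list(early_forward = 2L, late_forward = 3L,
         early_backward = 5L, late_backward = 6L)
  } else if (key == "512") {
    list(early_forward = 2L, late_forward = 4L,
         early_backward = 6L, late_backward = 8L)
  } else if (key == "2048") {
    list(early_forward = 2:3, late_forward = 5:6,
         early_backward = 8:9, late_backward = 11:12)
  } else {
    stop("unknown speed: ", speed_ms, call. = FALSE)
  }
}

#' Early/late transition means per period
#'
#' Means of decoded-position steps over the literal TR pairs assigned to the
#' early and late halves of the forward and backward periods. At 32-128 ms
#' these are the 2->3, 3->4, 5->6 and 6->7 transitions; at 512 ms 2->3,
#' 4->5, 6->7 and 8->9; at 2048 ms the triplets 2->3->4, 5->6->7, 8->9->10
#' and 11->12->13.
#'
#' @param steps Step-size vector from [transition_steps()]; element `i` is
#'   the TR `i` -> `i + 1` step.
#' @param speed_ms Sequence speed (32, 64, 128, 512 or 2048).
#' @return Named numeric vector: `early_forward`, `late_forward`,
#'   `early_backward`, `late_backward`.
#' @export
early_late_transition_means <- function(steps, speed_ms) {
  sets <- transition_tr_sets(speed_ms)
  need <- max(unlist(sets))
  if (length(steps) < need)
    stop(sprintf("need steps up to TR pair %d -> %d, got %d steps",
                 need, need + 1L, length(steps)), call. = FALSE)
  vapply(sets, function(idx) mean(steps[idx]), numeric(1))
}

#' Aggregate a per-TR metric over forward/backward periods
#'
#' @param metric Numeric vector, one value per TR.
#' @param windows A `period_windows` object from [compute_periods()].
#' @return Named numeric vector `c(forward = ..., backward = ...)` of
#'   inclusive-window means.
#' @export
period_aggregate <- function(metric, windows) {
  stopifnot(inherits(windows, "period_windows"),
            windows$backward_end_tr <= length(metric))
  c(forward = mean(metric[windows$forward_start_tr:windows$forward_end_tr]),
    backward = mean(metric[windows$backward_start_tr:windows$backward_end_tr]))
}

#' Item-removal control variants
#'
#' Removes the probability of selected items and renormalizes, emulating the
#' control analyses that drop the per-TR maximum, the first, or the last
#' sequence item. For the first/last modes the forward/backward periods are
#' recomputed with the event offset of the shortened span (one fewer item).
#'
#' @param tc A [probability_timecourse()] with a complete position map.
#' @param mode `"drop_max_per_tr"`, `"drop_first_item"` or
#'   `"drop_last_item"`.
#' @param params,acq Used to recompute periods for the first/last modes.
#' @return List with `tc` (the reduced time course; dropped entries are
#'   `NA` for the per-TR mode, a dropped column for the others) and
#'   `windows` (recomputed `period_windows`, or `NULL` for the per-TR mode).
#' @export
item_removal_variant <- function(tc, mode = c("drop_max_per_tr",
                                              "drop_first_item",
                                              "drop_last_item"),
                                 params = response_params(),
                                 acq = acquisition_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(tc, "probability_timecourse"),
            !anyNA(tc$position_map))
  if (mode == "drop_max_per_tr") {
    probs <- tc$probs
    for (k in seq_len(nrow(probs))) {
      probs[k, which.max(probs[k, ])] <- NA_real_
      s <- sum(probs[k, ], na.rm = TRUE)
      if (s > 0) probs[k, ] <- probs[k, ] / s
    }
    out <- tc
    out$probs <- probs
    return(list(tc = out, windows = NULL))
  }
  drop_pos <- if (mode == "drop_first_item") min(tc$position_map)
              else max(tc$position_map)
  keep <- which(tc$position_map != drop_pos)
  probs <- tc$probs[, keep, drop = FALSE]
  rs <- rowSums(probs)
  rs[rs == 0] <- 1
  probs <- probs / rs
  out <- probability_timecourse(probs,
                                position_map = rank(tc$position_map[keep]),
                                speed_ms = tc$speed_ms,
                                trial_id = tc$trial_id, run_id = tc$run_id,
                                participant_id = tc$participant_id)
  n_left <- length(keep)
  sp <- speed_condition(isi_seconds = if (is.na(tc$speed_ms)) 0
                        else tc$speed_ms / 1000,
                        n_items = n_left)
  windows <- compute_periods(params$lambda, params$d,
                             delta_trs(sp, acq), acq$n_trs_trial)
  list(tc = out, windows = windows)
}

#' Per-trial sequentiality summary
#'
#' Computes the per-TR slope, rank correlation, mean step and decoded
#' position of one trial, plus the period means of the slope under the
#' trial's speed-adjusted windows.
#'
#' @param tc A [probability_timecourse()] for a full sequence trial.
#' @param params,acq Model and acquisition parameters for the windows.
#' @return List of class `sequentiality_result`: `slope`, `rank_corr`,
#'   `mean_step`, `decoded_position` (per-TR vectors), `windows`,
#'   `period_slope` (named forward/backward means).
#' @export
sequentiality_metrics <- function(tc, params = response_params(),
                                  acq = acquisition_params()) {
  stopifnot(inherits(tc, "probability_timecourse"))
  sp <- speed_condition(isi_seconds = tc$speed_ms / 1000,
                        n_items = sum(!is.na(tc$position_map)))
  windows <- compute_periods(params$lambda, params$d, delta_trs(sp, acq),
                             n_trs(tc))
  slope <- tr_slope(tc)
  structure(list(slope = slope,
                 rank_corr = tr_rank_corr(tc),
                 mean_step = tr_mean_step(tc),
                 decoded_position = decoded_position(tc),
                 windows = windows,
                 period_slope = period_aggregate(slope, windows)),
            class = "sequentiality_result")
}
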