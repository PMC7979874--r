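# Synthetic trial schedules and data. The schedules reproduce the
# counterbalancing structure of the reference design: slow trials covering
# all 120 orderings of the five classes with 20% oddballs, 15 speed-crossed
# sequence trials with balanced first/last positions, and two-class
# nine-item repetition trials. Data are generated at two tiers: classifier
# probability level (forward simulation of the flattened-sine response) and
# voxel level (class template patterns convolved with the same response).

N_CLASSES <- 5L

# shifted exponential: lower limit + Exp(mean - lower); matches a truncated
# exponential with the stated mean by memorylessness
riti <- function(n, mean_s = 2.5, lower_s = 1) {
  lower_s + stats::rexp(n, rate = 1 / (mean_s - lower_s))
}

# truncated Poisson on [lo, hi] via renormalized pmf
rtrunc_pois <- function(n, lambda = 1.9, lo = 1L, hi = 5L) {
  support <- lo:hi
  sample(support, n, replace = TRUE, prob = stats::dpois(support, lambda))
}

all_orderings <- function(n = N_CLASSES) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_orderings(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- (seq_len(n))[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

schedule_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  class(df) <- c("trial_schedule", "data.frame")
  df
}

#' Slow-trial schedule
#'
#' All 120 orderings of the five classes, each presented exactly once as a
#' set of five single-item events (600 events total); 20% of events are
#' upside-down oddballs, balanced to exactly 24 per class; inter-trial
#' intervals are drawn from a truncated exponential (mean 2.5 s, lower limit
#' 1 s); trials are partitioned into 8 runs of 15 trials each.
#'
#' @param seed Integer seed; the schedule is a deterministic function of it.
#' @param stim_duration_seconds Per-item presentation duration (default 0.5).
#' @return A `trial_schedule` data.frame with one row per stimulus event:
#'   `trial_id`, `condition`, `run_id`, `onset`, `duration`, `item_class`,
#'   `serial_position`, `orientation`, `isi_seconds`, `target_position`.
#' @export
make_slow_schedule <- function(seed = 1L, stim_duration_seconds = 0.5) {
  withr_seed(seed)
  ord <- all_orderings()
  ord <- ord[sample.int(nrow(ord)), , drop = FALSE]
  n_trials <- nrow(ord)                      # 120
  n_events <- n_trials * N_CLASSES           # 600
  runs <- rep(seq_len(8L), each = n_trials / 8L)

  cls <- as.integer(t(ord))
  # exactly 24 oddballs per class, positions sampled within each class
  odd <- logical(n_events)
  for (k in seq_len(N_CLASSES)) {
    idx <- which(cls == k)
    odd[sample(idx, 24L)] <- TRUE
  }

  iti <- riti(n_events)
  onset <- numeric(n_events)
  trial <- rep(seq_len(n_trials), each = N_CLASSES)
  tcur <- 0
  prev_run <- 1L
  for (i in seq_len(n_events)) {
    run_i <- runs[trial[i]]
    if (run_i != prev_run) { tcur <- 0; prev_run <- run_i }
    tcur <- tcur + 0.3                        # fixation dot
    onset[i] <- tcur
    tcur <- tcur + stim_duration_seconds + iti[i]
  }

  schedule_df(
    trial_id = trial,
    condition = "slow",
    run_id = runs[trial],
    onset = onset,
    duration = stim_duration_seconds,
    item_class = cls,
    serial_position = rep(seq_len(N_CLASSES), n_trials),
    orientation = ifelse(odd, "upside_down", "upright"),
    isi_seconds = iti,
    target_position = NA_integer_
  )
}

# 15 orders with each class first in exactly 3 and last in exactly 3;
# rejection-sample the first/last pairing, then random middles, retrying
# until the 15 orders are distinct
select_sequence_orders <- function() {
  repeat {
    firsts <- sample(rep(seq_len(N_CLASSES), 3L))
    ok <- FALSE
    for (i in 1:200) {
      lasts <- sample(rep(seq_len(N_CLASSES), 3L))
      if (all(lasts != firsts)) { ok <- TRUE; break }
    }
    if (!ok) next
    orders <- matrix(0L, 15L, N_CLASSES)
    for (j in seq_len(15L)) {
      mid <- sample(setdiff(seq_len(N_CLASSES), c(firsts[j], lasts[j])))
      orders[j, ] <- c(firsts[j], mid, lasts[j])
    }
    if (!anyDuplicated(orders)) return(orders)
  }
}

#' Sequence-trial schedule
#'
#' 15 five-item orders, chosen so that each class appears first in exactly 3
#' and last in exactly 3 of the 15; each order is crossed with the five ISI
#' levels (32, 64, 128, 512, 2048 ms), giving 75 trials. The cued target
#' position is drawn from a Poisson(1.9) truncated to 1..5. Stimuli last
#' 100 ms; each trial window spans 16 s from sequence onset.
#'
#' @param participant_seed Integer seed (order selection is per participant).
#' @param isi_ms ISI levels in milliseconds.
#' @return A `trial_schedule` data.frame, one row per stimulus event, with
#'   the same columns as [make_slow_schedule()].
#' @export
make_sequence_schedule <- function(participant_seed = 1L,
                                   isi_ms = c(32, 64, 128, 512, 2048)) {
  withr_seed(participant_seed)
  orders <- select_sequence_orders()
  grid <- expand.grid(order_idx = seq_len(15L), isi_ms = isi_ms)
  grid <- grid[sample.int(nrow(grid)), ]
  n_trials <- nrow(grid)                     # 75
  runs <- rep(seq_len(8L), length.out = n_trials)[sample.int(n_trials)]
  targets <- rtrunc_pois(n_trials)

  rows <- vector("list", n_trials)
  trial_window_s <- 16
  run_clock <- rep(0, 8L)
  for (i in seq_len(n_trials)) {
    isi <- grid$isi_ms[i] / 1000
    ord <- orders[grid$order_idx[i], ]
    run_i <- runs[i]
    seq_onset <- run_clock[run_i] + 1 + 3.85 + 0.3   # cue + blank + fixation
    run_clock[run_i] <- seq_onset + trial_window_s + 1.5
    rows[[i]] <- schedule_df(
      trial_id = i,
      condition = "sequence",
      run_id = run_i,
      onset = seq_onset + (seq_len(N_CLASSES) - 1L) * (isi + 0.1),
      duration = 0.1,
      item_class = ord,
      serial_position = seq_len(N_CLASSES),
      orientation = "upright",
      isi_seconds = isi,
      target_position = targets[i]
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$run_id, out$onset), ]
  rownames(out) <- NULL
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Repetition-trial schedule
#'
#' Two-class nine-item trials at a fixed 32 ms ISI: for each of the five
#' first classes, 8 trials with the switch to the second class at serial
#' positions 2 through 9 (each exactly once; each of the four possible
#' second classes follows twice, with switch-position pairs 9&2, 8&3, 7&4,
#' 6&5 so every second class has mean first-occurrence position 5.5). Five
#' additional 16-item trials switch at the last position, each class
#' preceding once and following once. 45 trials total. A switch at position
#' 2 is the forward-interference condition (single first item, 8 repeats of
#' the second), a switch at position 9 the backward-interference condition.
#'
#' @param seed Integer seed.
#' @return A `trial_schedule` data.frame, one row per stimulus event, with
#'   the columns of [make_slow_schedule()] plus `switch_position`.
#' @export
make_repetition_schedule <- function(seed = 1L) {
  withr_seed(seed)
  pos_pairs <- list(c(9L, 2L), c(8L, 3L), c(7L, 4L), c(6L, 5L))
  trials <- list()
  tid <- 0L
  for (first in seq_len(N_CLASSES)) {
    seconds <- sample(setdiff(seq_len(N_CLASSES), first))
    for (j in seq_along(seconds)) {
      for (sw in pos_pairs[[j]]) {
        tid <- tid + 1L
        trials[[tid]] <- list(first = first, second = seconds[j],
                              switch = sw, n_items = 9L)
      }
    }
  }
  # five long 16-item trials: each class precedes once, follows once
  repeat {
    seconds16 <- sample.int(N_CLASSES)
    if (all(seconds16 != seq_len(N_CLASSES))) break
  }
  for (first in seq_len(N_CLASSES)) {
    tid <- tid + 1L
    trials[[tid]] <- list(first = first, second = seconds16[first],
                          switch = 16L, n_items = 16L)
  }
  trials <- trials[sample.int(length(trials))]

  isi <- 0.032
  rows <- vector("list", length(trials))
  runs <- rep(seq_len(8L), length.out = length(trials))
  run_clock <- rep(0, 8L)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    cls <- c(rep(tr$first, tr$switch - 1L),
             rep(tr$second, tr$n_items - tr$switch + 1L))
    run_i <- runs[i]
    seq_onset <- run_clock[run_i] + 0.5 + 3.85 + 0.3
    run_clock[run_i] <- seq_onset + 16 + 1.5
    rows[[i]] <- schedule_df(
      trial_id = i,
      condition = "repetition",
      run_id = run_i,
      onset = seq_onset + (seq_len(tr$n_items) - 1L) * (isi + 0.1),
      duration = 0.1,
      item_class = cls,
      serial_position = seq_len(tr$n_items),
      orientation = "upright",
      isi_seconds = isi,
      target_position = tr$switch
    )
  }
  out <- do.call(rbind, rows)
  out$switch_position <- out$target_position
  out <- out[order(out$run_id, out$onset), ]
  rownames(out) <- NULL
  class(out) <- c("trial_schedule", "data.frame")
  out
}

# class-wise response at the 13-TR grid for one trial's events; baseline
# counted once per class so repeated items do not stack baselines
trial_signal_matrix <- function(item_class, onset_trs, params, n_trs,
                                n_classes = N_CLASSES) {
  tgrid <- seq_len(n_trs) - 1
  sig <- matrix(params$b, n_trs, n_classes)
  for (e in seq_along(item_class)) {
    k <- item_class[e]
    sig[, k] <- sig[, k] + (eval_response(params, tgrid - onset_trs[e]) - params$b)
  }
  pmax(sig, 0)
}

#' Forward-simulate classifier probability time courses
#'
#' For each trial of a schedule, every stimulus event contributes a copy of
#' the flattened-sine response shifted to its onset; per-TR class
#' probabilities are the normalized class contributions, optionally
#' perturbed by noise. TR 1 is acquired at sequence onset and TR `k` samples
#' time `k - 1` TRs.
#'
#' @param schedule A `trial_schedule` (sequence, repetition or slow).
#' @param params A [response_params()].
#' @param noise `"none"`, `"gaussian"` (additive, then clipped and
#'   renormalized) or `"dirichlet"` (rows resampled from a Dirichlet centred
#'   on the noiseless probabilities).
#' @param noise_sd Gaussian noise SD (probability units).
#' @param concentration Dirichlet concentration multiplier (higher = less
#'   noise; 3 matches the per-TR probability SD reported for fast sequence
#'   data).
#' @param readout `"softmax"` (default): per-TR probabilities are a
#'   multinomial-logistic readout `p = softmax(gain * signal)` of the summed
#'   class responses, emulating the winner-take-most behavior of a logistic
#'   classifier (single classes reach dominant probabilities, as observed);
#'   `"linear"`: plain division by the row sum (compresses probabilities
#'   toward uniform).
#' @param gain Softmax gain; the default 4 makes an isolated event at its
#'   response peak reach a probability near 0.65, consistent with observed
#'   single-event decoding peaks.
#' @param acq An [acquisition_params()]; defines the TR and the 13-TR window.
#' @param seed Integer seed used when `noise != "none"`.
#' @return List of [probability_timecourse()] objects, one per trial.
#' @export
simulate_probabilities <- function(schedule, params = response_params(),
                                   noise = c("none", "gaussian", "dirichlet"),
                                   noise_sd = 0.02, concentration = 3,
                                   readout = c("softmax", "linear"), gain = 4,
                                   acq = acquisition_params(), seed = 1L) {
  readout <- match.arg(readout)
  noise <- match.arg(noise)
  stopifnot(inherits(schedule, "data.frame"), inherits(params, "response_params"))
  bad <- setdiff(unique(schedule$condition), c("slow", "sequence", "repetition"))
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (noise != "none") withr_seed(seed)

  out <- lapply(split(schedule, schedule$trial_id), function(tr) {
    onset0 <- min(tr$onset)
    onset_trs <- (tr$onset - onset0) / acq$tr_seconds
    sig <- trial_signal_matrix(tr$item_class, onset_trs, params,
                               acq$n_trs_trial)
    if (readout == "softmax") {
      ex <- exp(gain * (sig - apply(sig, 1L, max)))
      probs <- ex / rowSums(ex)
    } else {
      probs <- sig / rowSums(sig)
    }
    if (noise == "gaussian") {
      probs <- probs + matrix(stats::rnorm(length(probs), 0, noise_sd),
                              nrow(probs))
      probs <- pmax(probs, 0)
      rs <- rowSums(probs)
      rs[rs == 0] <- 1
      probs <- probs / rs
    } else if (noise == "dirichlet") {
      probs <- t(apply(probs, 1L, function(p) {
        g <- stats::rgamma(length(p), shape = concentration * p + 1e-6)
        g / sum(g)
      }))
    }
    pm <- rep(NA_integer_, N_CLASSES)
    first_pos <- tapply(tr$serial_position, tr$item_class, min)
    pm[as.integer(names(first_pos))] <- rank(first_pos)
    probability_timecourse(probs, position_map = pm,
                           speed_ms = tr$isi_seconds[1L] * 1000,
                           trial_id = tr$trial_id[1L],
                           run_id = tr$run_id[1L])
  })
  out[order(as.integer(names(out)))]
}

#' Voxel pattern specification
#'
#' @param n_voxels Number of voxels (>= number of classes).
#' @param noise_sd Gaussian voxel noise SD, relative to unit-norm templates.
#' @param n_runs Number of runs.
#' @param negative_correlation If `TRUE` (default) the class templates are
#'   centred across classes, giving small negative pairwise correlations as
#'   observed between mean class patterns in occipito-temporal cortex.
#' @return An object of class `voxel_pattern_spec`.
#' @export
voxel_pattern_spec <- function(n_voxels = 200L, noise_sd = 1.0, n_runs = 8L,
                               negative_correlation = TRUE) {
  n_voxels <- as.integer(n_voxels)
  stopifnot(n_voxels >= N_CLASSES, noise_sd >= 0, n_runs >= 1L)
  structure(list(n_voxels = n_voxels, noise_sd = noise_sd,
                 n_runs = as.integer(n_runs),
                 negative_correlation = negative_correlation),
            class = "voxel_pattern_spec")
}

make_templates <- function(spec) {
  tmpl <- matrix(stats::rnorm(spec$n_voxels * N_CLASSES), spec$n_voxels)
  # orthonormalize, then center across classes: pairwise template
  # correlations become -1/4 (small and negative, as observed between mean
  # class patterns)
  tmpl <- qr.Q(qr(tmpl))
  if (spec$negative_correlation)
    tmpl <- tmpl - rowMeans(tmpl)
  sweep(tmpl, 2L, sqrt(colSums(tmpl^2)), "/")
}

#' Simulate voxel-tier data for a schedule
#'
#' Each stimulus event adds its class's template pattern scaled by the
#' flattened-sine response amplitude at every TR; Gaussian noise is added on
#' top. Returns one samples-by-features matrix per run plus the event table
#' with ground-truth labels and peak-TR indices.
#'
#' @param schedule A `trial_schedule`.
#' @param spec A [voxel_pattern_spec()].
#' @param params A [response_params()]; the baseline `b` is ignored at the
#'   voxel tier.
#' @param acq An [acquisition_params()].
#' @param seed Integer seed (templates and noise).
#' @return A list of class `voxel_data`: `runs` (list of TR x voxel
#'   matrices), `events` (schedule with `run_tr` = 1-based TR at event onset
#'   and `peak_tr` = 1-based TR of the expected response peak),
#'   `templates` (voxel x class matrix), `tr_seconds`.
#' @export
simulate_voxels <- function(schedule, spec = voxel_pattern_spec(),
                            params = response_params(),
                            acq = acquisition_params(), seed = 1L) {
  stopifnot(inherits(spec, "voxel_pattern_spec"))
  withr_seed(seed)
  tmpl <- make_templates(spec)
  p0 <- response_params(A = params$A, lambda = params$lambda, d = params$d, b = 0)

  runs <- sort(unique(schedule$run_id))
  run_mats <- vector("list", length(runs))
  names(run_mats) <- as.character(runs)
  ev <- schedule
  ev$run_tr <- NA_integer_
  ev$peak_tr <- NA_integer_
  for (ri in seq_along(runs)) {
    sub_i <- which(schedule$run_id == runs[ri])
    sub <- schedule[sub_i, ]
    n_tr_run <- ceiling((max(sub$onset) + 16) / acq$tr_seconds) + 1L
    tgrid <- (seq_len(n_tr_run) - 1) * acq$tr_seconds
    mat <- matrix(0, n_tr_run, spec$n_voxels)
    for (e in seq_len(nrow(sub))) {
      amp <- eval_response(p0, (tgrid - sub$onset[e]) / acq$tr_seconds)
      mat <- mat + outer(amp, tmpl[, sub$item_class[e]])
    }
    if (spec$noise_sd > 0)
      mat <- mat + matrix(stats::rnorm(length(mat), 0, spec$noise_sd),
                          n_tr_run)
    run_mats[[ri]] <- mat
    ev$run_tr[sub_i] <- as.integer(round(sub$onset / acq$tr_seconds)) + 1L
    ev$peak_tr[sub_i] <- peak_tr_index(sub$onset, acq$tr_seconds) + 1L
  }
  structure(list(runs = run_mats, events = ev, templates = tmpl,
                 tr_seconds = acq$tr_seconds),
            class = "voxel_data")
}

#' Simulate a resting-state probability time course
#'
#' Rest probabilities fluctuate wildly, often with one class dominating a
#' TR. This is emulated by drawing per-TR probability rows from a
#' low-concentration Dirichlet and imposing temporal autocorrelation via an
#' AR(1) filter on the centred log-probabilities (re-normalized through a
#' softmax). The distributional form is a stand-in: the reference analyses
#' used real scanner rest data, for which no generative model is available.
#'
#' @param n_trs Number of TRs (default 233, a 5-min run at TR = 1.25 s).
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration (lower = spikier rows).
#' @param ar_coef AR(1) coefficient on the logits, in \[0, 1).
#' @return A [probability_timecourse()] with a random (but seeded) pseudo
#'   position map.
#' @export
simulate_rest <- function(n_trs = 233L, seed = 1L, concentration = 0.5,
                          ar_coef = 0.75) {
  n_trs <- as.integer(n_trs)
  stopifnot(n_trs >= 1L, concentration > 0, ar_coef >= 0, ar_coef < 1)
  withr_seed(seed)
  raw <- matrix(stats::rgamma(n_trs * N_CLASSES, shape = concentration),
                n_trs)
  raw <- pmax(raw, 1e-12)
  logit <- log(raw / rowSums(raw))
  logit <- logit - rowMeans(logit)
  z <- apply(logit, 2L, function(x)
    as.numeric(stats::filter(x * sqrt(1 - ar_coef^2), ar_coef,
                             method = "recursive")))
  z <- matrix(z, n_trs)
  ex <- exp(z - apply(z, 1L, max))
  probs <- ex / rowSums(ex)
  probability_timecourse(probs, position_map = sample.int(N_CLASSES),
                         speed_ms = NA_real_)
}

#' Blending specification for sequence insertion
#'
#' @param kappa Signal fraction in \[0, 1\] (reference grid: 4/5, 1/2, 1/4,
#'   1/8, 0).
#' @param n_inserts Number of inserted sequence events (1..6).
#' @param insert_len_trs Length of each inserted segment in TRs (default 12,
#'   the relevant window TRs 2-13 of one trial).
#' @param seed Integer seed for placement and donor sampling.
#' @return An object of class `blend_spec`.
#' @export
blend_spec <- function(kappa, n_inserts = 1L, insert_len_trs = 12L, seed = 1L) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa >= 0, kappa <= 1)
  n_inserts <- as.integer(n_inserts)
  insert_len_trs <- as.integer(insert_len_trs)
  stopifnot(n_inserts >= 1L, insert_len_trs >= 1L)
  structure(list(kappa = kappa, n_inserts = n_inserts,
                 insert_len_trs = insert_len_trs, seed = as.integer(seed)),
            class = "blend_spec")
}

sample_nonoverlapping_starts <- function(n, len, max_start, forbidden = integer(),
                                         max_tries = 2000L) {
  occupied <- rep(FALSE, max_start + len)
  for (s in forbidden) occupied[s:(s + len - 1L)] <- TRUE
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place non-overlapping segments after bounded retries",
           call. = FALSE)
    cand <- sample.int(max_start, 1L)
    span <- cand:(cand + len - 1L)
    if (!any(occupied[span])) {
      occupied[span] <- TRUE
      starts <- c(starts, cand)
    }
  }
  starts
}

#' Insert sequence events into a rest time course
#'
#' At each of `n_inserts` randomly placed, non-overlapping segments the
#' output rows are `kappa * trial + (1 - kappa) * donor`, where the donor
#' rows come from further non-overlapping random locations of the same rest
#' run. Blending against relocated rest rows (rather than the segment's own
#' rows) means the `kappa = 0` condition still carries the concatenation
#' artifacts of insertion, so SNR levels stay comparable.
#'
#' @param rest A [probability_timecourse()] (the rest run).
#' @param trials List of [probability_timecourse()]s or matrices supplying
#'   the inserted segments; each must have at least `insert_len_trs` rows
#'   (use [sequence_insert_segment()] to slice the relevant 12-TR window of
#'   a 13-TR trial). Trials are drawn without replacement.
#' @param blend A [blend_spec()].
#' @return A list of class `inserted_rest`: `tc` (the blended
#'   [probability_timecourse()]), `insert_starts`, `donor_starts`,
#'   `trial_idx` (which trials were used), `kappa`.
#' @export
insert_events <- function(rest, trials, blend) {
  stopifnot(inherits(rest, "probability_timecourse"),
            inherits(blend, "blend_spec"), is.list(trials))
  len <- blend$insert_len_trs
  n <- blend$n_inserts
  if (n > length(trials))
    stop("not enough trials to draw without replacement", call. = FALSE)
  if (n * len > n_trs(rest))
    stop("inserted segments do not fit into the rest run", call. = FALSE)
  withr_seed(blend$seed)
  trial_idx <- sample(seq_along(trials), n)
  max_start <- n_trs(rest) - len + 1L
  insert_starts <- sample_nonoverlapping_starts(n, len, max_start)
  donor_starts <- sample_nonoverlapping_starts(n, len, max_start,
                                               forbidden = integer())
  probs <- rest$probs
  for (j in seq_len(n)) {
    tr <- trials[[trial_idx[j]]]
    seg <- if (inherits(tr, "probability_timecourse")) tr$probs else as.matrix(tr)
    if (nrow(seg) < len)
      stop("trial segment shorter than 'insert_len_trs'", call. = FALSE)
    seg <- seg[seq_len(len), , drop = FALSE]
    donor <- rest$probs[donor_starts[j]:(donor_starts[j] + len - 1L), ,
                        drop = FALSE]
    span <- insert_starts[j]:(insert_starts[j] + len - 1L)
    probs[span, ] <- blend$kappa * seg + (1 - blend$kappa) * donor
  }
  tc <- probability_timecourse(probs, position_map = rest$position_map,
                               speed_ms = rest$speed_ms)
  structure(list(tc = tc, insert_starts = insert_starts,
                 donor_starts = donor_starts, trial_idx = trial_idx,
                 kappa = blend$kappa),
            class = "inserted_rest")
}

#' Relevant insertion window of a sequence trial
#'
#' Slices the 12-TR relevant window (TRs 2-13) used when blending sequence
#' trials into rest data.
#'
#' @param tc A [probability_timecourse()] with at least 13 TRs.
#' @param trs TRs to keep (default 2:13).
#' @return Probability matrix of the selected TRs.
#' @export
sequence_insert_segment <- function(tc, trs = 2:13) {
  stopifnot(inherits(tc, "probability_timecourse"), max(trs) <= n_trs(tc))
  tc$probs[trs, , drop = FALSE]
}

# validate and set an integer RNG seed
withr_seed <- function(seed) {
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  set.seed(seed)
  invisible(seed)
}
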