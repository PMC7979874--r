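#' Acquisition timing parameters
#'
#' Bundles the repetition time (TR) and the per-trial analysis window length.
#' Defaults correspond to a 1.25 s TR and a 16 s trial window of 13 TRs.
#'
#' @param tr_seconds Duration of one TR in seconds (> 0).
#' @param n_trs_trial Number of TRs in the per-trial analysis window (>= 1).
#' @return An object of class `acquisition_params`.
#' @export
#' @examples
#' acquisition_params()
acquisition_params <- function(tr_seconds = 1.25, n_trs_trial = 13L) {
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  n_trs_trial <- as.integer(n_trs_trial)
  stopifnot(length(n_trs_trial) == 1L, n_trs_trial >= 1L)
  structure(list(tr_seconds = tr_seconds, n_trs_trial = n_trs_trial),
            class = "acquisition_params")
}

#' Single-event response parameters
#'
#' Parameters of the flattened single-cycle sine model of the probabilistic
#' decoding time course following a single visual event: amplitude `A` (peak
#' deviation from baseline, probability units), response duration `lambda`
#' (one full cycle, in TRs; the model frequency is `f = 1/lambda`), onset
#' delay `d` (TRs) and baseline `b` (probability units).
#'
#' @param A Amplitude, >= 0.
#' @param lambda Response duration in TRs, > 0.
#' @param d Onset delay in TRs, >= 0.
#' @param b Baseline probability, >= 0.
#' @return An object of class `response_params`.
#' @export
#' @examples
#' response_params(A = 0.5, lambda = 5.24, d = 0.56, b = 0.1)
response_params <- function(A = 0.5, lambda = 5.24, d = 0.56, b = 0.1) {
  if (!is.numeric(A) || length(A) != 1L || is.na(A) || A < 0)
    stop("'A' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda <= 0)
    stop("'lambda' must be a single positive number", call. = FALSE)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("'d' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b < 0)
    stop("'b' must be a single non-negative number", call. = FALSE)
  structure(list(A = A, lambda = lambda, d = d, b = b),
            class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat(sprintf("Single-event response: A = %.4g, lambda = %.4g TRs, d = %.4g TRs, b = %.4g\n",
              x$A, x$lambda, x$d, x$b))
  invisible(x)
}

#' Sequence speed condition
#'
#' Geometry of one stimulus sequence: the inter-stimulus interval (ISI), the
#' per-item presentation duration, and the item count. The five speed
#' conditions of the reference design use ISIs of 32, 64, 128, 512 and
#' 2048 ms with 100 ms stimuli and 5 items.
#'
#' @param isi_seconds Inter-stimulus interval in seconds, >= 0.
#' @param stim_duration_seconds Per-item presentation time in seconds, > 0.
#' @param n_items Items per sequence, >= 2.
#' @return An object of class `speed_condition`.
#' @export
#' @examples
#' speed_condition(0.032)
speed_condition <- function(isi_seconds, stim_duration_seconds = 0.1,
                            n_items = 5L) {
  stopifnot(is.numeric(isi_seconds), length(isi_seconds) == 1L, isi_seconds >= 0,
            is.numeric(stim_duration_seconds), length(stim_duration_seconds) == 1L,
            stim_duration_seconds > 0)
  n_items <- as.integer(n_items)
  stopifnot(n_items >= 2L)
  structure(list(isi_seconds = isi_seconds,
                 stim_duration_seconds = stim_duration_seconds,
                 n_items = n_items),
            class = "speed_condition")
}

#' The five reference speed conditions
#'
#' @param isi_ms ISIs in milliseconds.
#' @return Named list of [speed_condition()] objects (names are the ISI in ms).
#' @export
default_speed_conditions <- function(isi_ms = c(32, 64, 128, 512, 2048)) {
  out <- lapply(isi_ms, function(ms) speed_condition(ms / 1000))
  names(out) <- as.character(isi_ms)
  out
}

# round-half-up; base round() is half-even and Table-1 style reporting
# conventions assume .5 rounds away from zero for positive values
round_half_up <- function(x) floor(x + 0.5)

#' Evaluate the flattened single-cycle sine response
#'
#' The response to a single event is a sine wave scaled to amplitude `A`,
#' shifted to baseline `b` and delayed by `d`, flattened to the baseline
#' outside its single cycle of duration `lambda`:
#' `h(t) = A/2 * sin(2*pi*f*t - 2*pi*f*d - pi/2) + b + A/2` for
#' `d <= t <= d + lambda` (with `f = 1/lambda`), and `b` otherwise.
#'
#' @param params A [response_params()] object.
#' @param t Time(s) in TRs; vectorized.
#' @return Numeric vector of response values, same length as `t`.
#' @export
#' @examples
#' eval_response(response_params(A = 1, lambda = 4, d = 0, b = 0), t = 2)
eval_response <- function(params, t) {
  stopifnot(inherits(params, "response_params"), is.numeric(t), all(is.finite(t)))
  f <- 1 / params$lambda
  h <- params$A / 2 * sin(2 * pi * f * t - 2 * pi * f * params$d - 0.5 * pi) +
    params$b + params$A / 2
  inside <- t >= params$d & t <= params$d + params$lambda
  ifelse(inside, h, params$b)
}

#' Event offset delta in TR units (onset-to-onset)
#'
#' Interval between the onsets of the first and last sequence item, in TRs:
#' `(n_items - 1) * (isi + stim_duration) / tr_seconds`. This is the delta
#' used for deriving forward/backward periods.
#'
#' @param speed A [speed_condition()].
#' @param acq An [acquisition_params()].
#' @return Delta in TRs (full precision; round only when reporting).
#' @export
#' @examples
#' delta_trs(speed_condition(0.032), acquisition_params())  # ~0.42
delta_trs <- function(speed, acq = acquisition_params()) {
  stopifnot(inherits(speed, "speed_condition"), inherits(acq, "acquisition_params"))
  (speed$n_items - 1) * (speed$isi_seconds + speed$stim_duration_seconds) /
    acq$tr_seconds
}

#' Event offset delta in seconds (onset-to-offset)
#'
#' Interval from the onset of the first to the offset of the last sequence
#' item, in seconds: `(n_items - 1) * isi + n_items * stim_duration`. This is
#' the total sequence span used for frequency prediction.
#'
#' @param speed A [speed_condition()].
#' @return Delta in seconds.
#' @export
#' @examples
#' delta_seconds_total(speed_condition(0.032))  # 0.628
delta_seconds_total <- function(speed) {
  stopifnot(inherits(speed, "speed_condition"))
  (speed$n_items - 1) * speed$isi_seconds +
    speed$n_items * speed$stim_duration_seconds
}

#' Predicted difference-wave frequency
#'
#' The difference between two single-event responses shifted by `delta` is
#' itself (approximately) a single sine cycle with frequency
#' `f_delta = f / (1 + f * delta)` where `f = 1/lambda`. Two unit
#' conventions are offered. The default (`"paper"`) plugs `delta` in seconds
#' into `f` in per-TR units, i.e. computes `1 / (lambda + delta_seconds)` and
#' labels the result Hz; this is the convention under which the reference
#' frequencies 0.17 Hz (32 ms) and 0.07 Hz (2048 ms) are obtained, and
#' matches a spectral analysis whose time axis is in TR units. The
#' `"strict"` convention keeps everything in TR units
#' (`delta` interpreted as TRs) and converts to true Hz via `tr_seconds`.
#'
#' @param lambda_trs Response duration lambda in TRs, > 0.
#' @param delta Event offset; seconds for `convention = "paper"`, TRs for
#'   `"strict"`. Must be >= 0.
#' @param convention `"paper"` (default) or `"strict"`.
#' @param tr_seconds TR duration in seconds (used by `"strict"` only).
#' @return Frequency (Hz under the chosen convention), full precision.
#' @export
#' @examples
#' predicted_frequency(5.24, delta_seconds_total(speed_condition(0.032)))  # ~0.17
predicted_frequency <- function(lambda_trs, delta,
                                convention = c("paper", "strict"),
                                tr_seconds = 1.25) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(lambda_trs), lambda_trs > 0, is.numeric(delta))
  if (any(delta < 0)) stop("'delta' must be non-negative", call. = FALSE)
  if (convention == "paper") {
    1 / (lambda_trs + delta)
  } else {
    (1 / (lambda_trs + delta)) / tr_seconds
  }
}

#' Difference waveform of two time-shifted responses
#'
#' Closed-form approximation of `h(t) - h(t - delta)` for the flattened sine
#' response: `A * sin(2*pi*f*delta/2) * sin(2*pi*f_d*t - 2*pi*f_d*d)` with
#' `f = 1/lambda` and `f_d = f/(1 + f*delta)`; zero outside
#' `[d, d + lambda + delta]`. Positive over the first half of the stretched
#' cycle (forward period) and negative over the second half (backward
#' period). The magnitude of the trigonometric amplitude factor is used:
#' for offsets beyond one response duration the factor `sin(2*pi*f*delta/2)`
#' changes sign, although the ordering of two non-overlapping responses
#' (first positive, then negative) does not; taking the magnitude keeps the
#' predicted sign pattern for all offsets.
#'
#' @param params A [response_params()].
#' @param delta_trs Event offset in TRs, >= 0.
#' @param t Time(s) in TRs; vectorized.
#' @return Numeric vector of difference values.
#' @export
difference_waveform <- function(params, delta_trs, t) {
  stopifnot(inherits(params, "response_params"),
            is.numeric(delta_trs), length(delta_trs) == 1L, delta_trs >= 0,
            is.numeric(t))
  f <- 1 / params$lambda
  fd <- f / (1 + f * delta_trs)
  amp <- params$A * abs(sin(2 * pi * f * delta_trs / 2))
  val <- amp * sin(2 * pi * fd * t - 2 * pi * fd * params$d)
  inside <- t >= params$d & t <= params$d + params$lambda + delta_trs
  ifelse(inside, val, 0)
}

#' Forward and backward period TR windows
#'
#' Derives the inclusive 1-based TR windows of the forward and backward
#' periods for a given event offset. In continuous time the forward period is
#' `[d, 0.5*(lambda + delta) + d]` and the backward period
#' `[0.5*(lambda + delta) + d, lambda + delta + d]` (TR 1 acquired at
#' sequence onset). Boundaries are mapped to TR indices by:
#' `forward_start = round(d) + 1`,
#' `backward_start = ceiling(0.5*(lambda + delta) + d) + 1`,
#' `forward_end = backward_start - 1`, and
#' `backward_end = min(round(lambda + delta + d) + 1, n_trs)`
#' (round = half-up). With lambda = 5.24 and d = 0.56 this reproduces the
#' speed-adjusted windows of all five reference ISI conditions.
#'
#' @param lambda_trs Response duration in TRs.
#' @param onset_delay_d Onset delay in TRs.
#' @param delta_trs Onset-to-onset event offset in TRs (see [delta_trs()]).
#' @param n_trs Length of the trial window in TRs.
#' @return A list of class `period_windows` with elements `forward_start_tr`,
#'   `forward_end_tr`, `backward_start_tr`, `backward_end_tr`.
#' @export
#' @examples
#' compute_periods(5.24, 0.56, 0.42, 13)  # forward TRs 2-4, backward TRs 5-7
compute_periods <- function(lambda_trs, onset_delay_d, delta_trs, n_trs = 13L) {
  stopifnot(is.numeric(lambda_trs), lambda_trs > 0,
            is.numeric(onset_delay_d), onset_delay_d >= 0,
            is.numeric(delta_trs), delta_trs >= 0)
  n_trs <- as.integer(n_trs)
  lam_d <- lambda_trs + delta_trs
  forward_start <- round_half_up(onset_delay_d) + 1L
  backward_start <- as.integer(ceiling(0.5 * lam_d + onset_delay_d)) + 1L
  forward_end <- backward_start - 1L
  backward_end <- min(as.integer(round_half_up(lam_d + onset_delay_d)) + 1L, n_trs)
  if (forward_start > n_trs)
    stop("trial window too short to contain the forward period", call. = FALSE)
  structure(list(forward_start_tr = as.integer(forward_start),
                 forward_end_tr = as.integer(forward_end),
                 backward_start_tr = as.integer(backward_start),
                 backward_end_tr = as.integer(backward_end)),
            class = "period_windows")
}

#' @export
print.period_windows <- function(x, ...) {
  cat(sprintf("Forward period: TRs %d-%d; backward period: TRs %d-%d\n",
              x$forward_start_tr, x$forward_end_tr,
              x$backward_start_tr, x$backward_end_tr))
  invisible(x)
}

#' Speed-adjusted period table
#'
#' Convenience wrapper computing delta (TRs, rounded to two decimals for
#' reporting) and the forward/backward windows for a set of speed conditions.
#'
#' @param speeds List of [speed_condition()]s (e.g. [default_speed_conditions()]).
#' @param params A [response_params()]; only `lambda` and `d` are used.
#' @param acq An [acquisition_params()].
#' @return A data.frame with one row per condition: `speed_ms`, `delta_trs`,
#'   forward/backward start and end TRs.
#' @export
period_table <- function(speeds = default_speed_conditions(),
                         params = response_params(),
                         acq = acquisition_params()) {
  rows <- lapply(names(speeds), function(nm) {
    sp <- speeds[[nm]]
    dl <- delta_trs(sp, acq)
    pw <- compute_periods(params$lambda, params$d, dl, acq$n_trs_trial)
    data.frame(speed_ms = as.numeric(nm),
               delta_trs = round(dl, 2),
               forward_start_tr = pw$forward_start_tr,
               forward_end_tr = pw$forward_end_tr,
               backward_start_tr = pw$backward_start_tr,
               backward_end_tr = pw$backward_end_tr)
  })
  do.call(rbind, rows)
}

#' Fit the single-event response model to a decoding time course
#'
#' Least-squares fit of the four parameters (A, lambda, d, b) of the
#' flattened-sine response to one class's probability time course, under box
#' constraints, using a derivative-based box-constrained optimizer
#' ([stats::nlminb()]). Initial values: `A` from max - min, `b` from the
#' first sample, `d = 0.5` TRs, `lambda = 2 * (argmax - d)` clipped to
#' bounds. Default bounds: A in \[0, 1\], lambda in \[1, 13\] TRs, d in
#' \[0, 3\] TRs, b in \[0, 1\].
#'
#' @param y Numeric vector: the probability value at each TR (TR k sampled at
#'   `t = k - 1` TRs from trial onset). Length >= 5.
#' @param t Optional time grid in TRs; default `seq_along(y) - 1`.
#' @param init Optional [response_params()] with starting values.
#' @param lower,upper Named numeric vectors with elements `A`, `lambda`, `d`,
#'   `b` giving the box constraints.
#' @return A list of class `response_fit`: `params` ([response_params()]),
#'   `loss` (final sum of squared residuals), `converged` (logical; a
#'   non-converged optimizer is flagged, not an error), `message`.
#' @export
fit_response <- function(y, t = seq_along(y) - 1, init = NULL,
                         lower = c(A = 0, lambda = 1, d = 0, b = 0),
                         upper = c(A = 1, lambda = 13, d = 3, b = 1)) {
  stopifnot(is.numeric(y), length(y) >= 5L, length(t) == length(y))
  nm <- c("A", "lambda", "d", "b")
  stopifnot(all(nm %in% names(lower)), all(nm %in% names(upper)))
  lower <- lower[nm]; upper <- upper[nm]

  if (is.null(init)) {
    A0 <- max(y) - min(y)
    b0 <- y[1L]
    d0 <- 0.5
    l0 <- 2 * (t[which.max(y)] - d0)
    init <- c(A = A0, lambda = l0, d = d0, b = b0)
  } else {
    stopifnot(inherits(init, "response_params"))
    init <- c(A = init$A, lambda = init$lambda, d = init$d, b = init$b)
  }
  init <- pmin(pmax(init, lower), upper)

  obj <- function(p) {
    pr <- response_params(A = p[1L], lambda = max(p[2L], .Machine$double.eps),
                          d = p[3L], b = p[4L])
    sum((y - eval_response(pr, t))^2)
  }
  run_fit <- function(start) {
    stats::nlminb(start = start, objective = obj, lower = lower,
                  upper = upper,
                  control = list(iter.max = 500L, eval.max = 1000L))
  }
  res <- run_fit(init)
  # deterministic multistart guards against local minima of the piecewise
  # objective; keep the best solution
  scale <- max(sum((y - mean(y))^2), .Machine$double.eps)
  if (res$objective > 1e-6 * scale) {
    for (d0 in c(0, 1)) for (l0 in c(4, 6, 8)) {
      alt <- init
      alt["d"] <- d0
      alt["lambda"] <- l0
      cand <- run_fit(pmin(pmax(alt, lower), upper))
      if (cand$objective < res$objective) res <- cand
    }
  }
  par <- unname(res$par)
  structure(list(
    params = response_params(A = par[1L], lambda = par[2L],
                             d = par[3L], b = par[4L]),
    loss = res$objective,
    # a zero-residual fit can stop with a spurious "false convergence"
    # code because the numerical gradient vanishes; count it as converged
    converged = res$convergence == 0L || res$objective <= 1e-10 * scale,
    message = res$message
  ), class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  SSR = %.6g; converged: %s\n", x$loss, x$converged))
  invisible(x)
}
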