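test_that("eval_response follows the flattened single-cycle sine", {
  # peak at half cycle
  expect_equal(eval_response(response_params(A = 1, lambda = 4, d = 0, b = 0), 2),
               1.0)
  # baseline outside the cycle
  expect_equal(eval_response(response_params(A = 1, lambda = 4, d = 0, b = 0.1), 5),
               0.1)
  # vectorized evaluation matches an independent direct transcription
  pr <- response_params(A = 0.6, lambda = 5.24, d = 0.56, b = 0.05)
  tgrid <- seq(0, 13, by = 0.25)
  direct <- vapply(tgrid, function(t) {
    f <- 1 / 5.24
    if (t >= 0.56 && t <= 0.56 + 5.24)
      0.6 / 2 * sin(2 * pi * f * t - 2 * pi * f * 0.56 - 0.5 * pi) + 0.05 + 0.6 / 2
    else 0.05
  }, numeric(1))
  expect_equal(eval_response(pr, tgrid), direct)
})

test_that("eval_response is continuous at the cycle boundaries", {
  pr <- response_params(A = 0.7, lambda = 5.24, d = 0.56, b = 0.12)
  eps <- 1e-9
  expect_equal(eval_response(pr, pr$d), pr$b, tolerance = 1e-9)
  expect_equal(eval_response(pr, pr$d + pr$lambda), pr$b, tolerance = 1e-9)
  expect_lt(abs(eval_response(pr, pr$d - eps) - eval_response(pr, pr$d + eps)),
            1e-8)
  expect_lt(abs(eval_response(pr, pr$d + pr$lambda - eps) -
                eval_response(pr, pr$d + pr$lambda + eps)), 1e-8)
})

test_that("invalid response parameters are rejected", {
  expect_error(response_params(A = -0.1), "A")
  expect_error(response_params(lambda = 0), "lambda")
  expect_error(response_params(d = -1), "d")
  expect_error(response_params(b = -0.5), "b")
})

test_that("delta in TR units is onset-of-first to onset-of-last", {
  acq <- acquisition_params()
  expect_equal(round(delta_trs(speed_condition(0.032), acq), 2), 0.42)
  expect_equal(round(delta_trs(speed_condition(2.048), acq), 2), 6.87)
  # degenerate zero-gap, zero-ish-duration condition
  expect_equal(delta_trs(speed_condition(0, stim_duration_seconds = 1e-12), acq),
               4 * 1e-12 / 1.25)
})

test_that("delta in seconds is onset-of-first to offset-of-last", {
  expect_equal(delta_seconds_total(speed_condition(0.032)), 0.628)
  expect_equal(delta_seconds_total(speed_condition(2.048)), 8.692)
  expect_equal(delta_seconds_total(speed_condition(0.5, n_items = 2)),
               0.5 + 2 * 0.1)
})

test_that("predicted frequency reproduces the printed values and is monotone", {
  expect_equal(round(predicted_frequency(5.24, 0.628), 2), 0.17)
  expect_equal(round(predicted_frequency(5.24, 8.692), 2), 0.07)
  # delta = 0 limit
  expect_equal(predicted_frequency(5.24, 0), 1 / 5.24)
  expect_equal(predicted_frequency(5.24, 0, convention = "strict"),
               (1 / 5.24) / 1.25)
  # strictly decreasing in delta, both conventions
  deltas <- seq(0, 10, by = 0.5)
  for (conv in c("paper", "strict")) {
    f <- vapply(deltas, function(d)
      predicted_frequency(5.24, d, convention = conv), numeric(1))
    expect_true(all(diff(f) < 0))
  }
  expect_error(predicted_frequency(5.24, -1), "non-negative")
})

test_that("difference waveform has the predicted structure", {
  pr <- response_params(A = 0.8, lambda = 5.24, d = 0.56, b = 0.1)
  tgrid <- seq(0, 13, by = 0.01)
  # delta = 0: identically zero
  expect_true(all(difference_waveform(pr, 0, tgrid) == 0))
  # sign pattern: positive forward half, negative backward half, all offsets
  for (dl in c(0.42, 1.96, 6.87)) {
    h <- difference_waveform(pr, dl, tgrid)
    half <- pr$d + 0.5 * (pr$lambda + dl)
    expect_true(all(h[tgrid > pr$d & tgrid < half] >= -1e-12))
    expect_true(all(h[tgrid > half & tgrid < pr$d + pr$lambda + dl] <= 1e-12))
    expect_true(all(h[tgrid < pr$d | tgrid > pr$d + pr$lambda + dl] == 0))
  }
  # closed-form maximum A*sin(pi*delta/lambda) for delta <= lambda/2
  for (dl in c(0.3, 1.0, 2.0, 5.24 / 2)) {
    grid_max <- max(abs(difference_waveform(pr, dl, seq(0, 13, by = 1e-4))))
    expect_equal(grid_max, pr$A * sin(pi * dl / pr$lambda), tolerance = 1e-6)
  }
})

test_that("numeric response difference is a sinusoid of the predicted amplitude", {
  # for t in [d + delta, d + lambda] both responses are inside their cycle and
  # h(t) - h(t - delta) is a sinusoid with amplitude A*sin(pi*delta/lambda)
  pr <- response_params(A = 0.5, lambda = 5.24, d = 0.56, b = 0.1)
  for (dl in c(0.42, 0.73, 1.96)) {
    tgrid <- seq(pr$d + dl, pr$d + pr$lambda, length.out = 4000)
    diffs <- eval_response(pr, tgrid) - eval_response(pr, tgrid - dl)
    pred_amp <- pr$A * sin(pi * dl / pr$lambda)
    expect_equal(max(abs(diffs)), pred_amp, tolerance = 1e-6)
  }
})

test_that("period windows reproduce the reference table for every speed", {
  # delta values and forward/backward windows for lambda = 5.24, d = 0.56
  expected <- data.frame(
    speed_ms = c(32, 64, 128, 512, 2048),
    delta = c(0.42, 0.52, 0.73, 1.96, 6.87),
    fs = rep(2L, 5), fe = c(4L, 4L, 4L, 5L, 7L),
    bs = c(5L, 5L, 5L, 6L, 8L), be = c(7L, 7L, 8L, 9L, 13L))
  acq <- acquisition_params()
  for (i in seq_len(nrow(expected))) {
    sp <- speed_condition(expected$speed_ms[i] / 1000)
    dl <- delta_trs(sp, acq)
    expect_equal(round(dl, 2), expected$delta[i])
    pw <- compute_periods(5.24, 0.56, dl, 13)
    expect_identical(pw$forward_start_tr, expected$fs[i])
    expect_identical(pw$forward_end_tr, expected$fe[i])
    expect_identical(pw$backward_start_tr, expected$bs[i])
    expect_identical(pw$backward_end_tr, expected$be[i])
    # backward period starts right after the forward period ends
    expect_identical(pw$backward_start_tr, pw$forward_end_tr + 1L)
  }
  expect_error(compute_periods(5.24, 20, 0.42, 13), "too short")
})

test_that("response fit recovers parameters from noiseless curves", {
  truth <- response_params(A = 0.5, lambda = 5.0, d = 0.5, b = 0.1)
  y <- eval_response(truth, 0:12)
  fit <- fit_response(y)
  expect_true(fit$converged)
  expect_equal(fit$params$A, truth$A, tolerance = 1e-3)
  expect_equal(fit$params$lambda, truth$lambda, tolerance = 1e-3)
  expect_equal(fit$params$d, truth$d, tolerance = 1e-3)
  expect_equal(fit$params$b, truth$b, tolerance = 1e-3)
  # a second noiseless geometry
  truth2 <- response_params(A = 0.3, lambda = 6.5, d = 1.0, b = 0.05)
  fit2 <- fit_response(eval_response(truth2, 0:12))
  expect_equal(fit2$params$lambda, truth2$lambda, tolerance = 1e-3)
  expect_equal(fit2$params$d, truth2$d, tolerance = 1e-3)
})

test_that("response fit of a constant series puts A at the lower bound", {
  fit <- fit_response(rep(0.2, 13))
  expect_lt(fit$params$A, 1e-6)
  expect_equal(fit$params$b, 0.2, tolerance = 1e-6)
})

test_that("response fit has small error and bias under noise", {
  truth <- response_params(A = 0.5, lambda = 5.0, d = 0.5, b = 0.1)
  y <- eval_response(truth, 0:12)
  set.seed(202)
  fits <- replicate(200, {
    f <- fit_response(y + stats::rnorm(13, 0, 0.02))
    c(f$params$A, f$params$lambda, f$params$d, f$params$b)
  })
  lam_err <- abs(fits[2, ] - truth$lambda)
  expect_lt(median(lam_err), 0.3)
  # parameter bias below 5% of the true values
  truth_vec <- c(truth$A, truth$lambda, truth$d, truth$b)
  bias <- abs(rowMeans(fits) - truth_vec) / truth_vec
  expect_true(all(bias < 0.05))
})

test_that("period table rounds delta only at the reporting layer", {
  tab <- period_table()
  expect_equal(tab$delta_trs, c(0.42, 0.52, 0.73, 1.96, 6.87))
  # internal arithmetic keeps full precision
  expect_false(isTRUE(all.equal(delta_trs(speed_condition(0.032)), 0.42)))
})
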