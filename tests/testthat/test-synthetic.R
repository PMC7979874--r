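test_that("slow schedule reproduces the counterbalanced design", {
  s <- make_slow_schedule(7L)
  expect_equal(nrow(s), 600L)
  expect_equal(length(unique(s$trial_id)), 120L)
  # every ordering of the five classes appears exactly once
  orders <- do.call(rbind, lapply(split(s$item_class, s$trial_id), identity))
  expect_equal(nrow(unique(orders)), 120L)
  # exactly 24 oddballs per class
  odd_by_class <- table(s$item_class[s$orientation == "upside_down"])
  expect_true(all(odd_by_class == 24L))
  # class frequencies exactly equal
  expect_true(all(table(s$item_class) == 120L))
  # 8 runs, onsets non-decreasing within run, ITIs respect the 1 s floor
  expect_equal(sort(unique(s$run_id)), 1:8)
  for (r in 1:8) expect_true(all(diff(s$onset[s$run_id == r]) >= 0))
  expect_true(all(s$isi_seconds >= 1))
})

test_that("sequence schedule balances first and last positions", {
  s <- make_sequence_schedule(11L)
  expect_equal(length(unique(s$trial_id)), 75L)
  trials <- split(s, s$trial_id)
  firsts <- vapply(trials, function(tr) tr$item_class[tr$serial_position == 1L],
                   integer(1))
  lasts <- vapply(trials, function(tr) tr$item_class[tr$serial_position == 5L],
                  integer(1))
  # 15 orders x 5 speeds: each class first in 3 of 15 orders => 15 of 75 trials
  expect_true(all(table(firsts) == 15L))
  expect_true(all(table(lasts) == 15L))
  # each order crossed with all five speeds
  speeds <- vapply(trials, function(tr) tr$isi_seconds[1L], numeric(1))
  expect_equal(sort(unique(round(speeds * 1000))), c(32, 64, 128, 512, 2048))
  expect_true(all(table(round(speeds * 1000)) == 15L))
  # every trial contains each class exactly once
  for (tr in trials[1:10]) expect_equal(sort(tr$item_class), 1:5)
  # truncated-Poisson targets stay in 1..5
  expect_true(all(s$target_position >= 1L & s$target_position <= 5L))
})

test_that("targets follow the truncated Poisson shape (later > earlier mass)", {
  s <- make_sequence_schedule(19L)
  tgt <- vapply(split(s, s$trial_id), function(tr) tr$target_position[1L],
                integer(1))
  # Poisson(1.9) truncated to 1..5 puts more mass on 2 than on 5
  expect_gt(sum(tgt == 2L), sum(tgt == 5L))
})

test_that("repetition schedule has the switch-position structure", {
  s <- make_repetition_schedule(5L)
  expect_equal(length(unique(s$trial_id)), 45L)
  trials <- split(s, s$trial_id)
  n_items <- vapply(trials, nrow, integer(1))
  expect_equal(sum(n_items == 9L), 40L)
  expect_equal(sum(n_items == 16L), 5L)
  # every trial has exactly two distinct classes
  expect_true(all(vapply(trials, function(tr)
    length(unique(tr$item_class)), integer(1)) == 2L))
  # per first-class: 8 nine-item trials, switch positions 2..9 each once
  nine <- trials[n_items == 9L]
  firsts <- unname(vapply(nine, function(tr) tr$item_class[1L], integer(1)))
  switches <- unname(vapply(nine, function(tr) tr$switch_position[1L], integer(1)))
  expect_true(all(table(firsts) == 8L))
  for (k in 1:5)
    expect_equal(sort(switches[firsts == k]), 2:9)
  # fixed 32 ms ISI everywhere
  expect_true(all(s$isi_seconds == 0.032))
  # 16-item trials: each class precedes once and follows once
  long <- trials[n_items == 16L]
  expect_equal(sort(unname(vapply(long, function(tr) tr$item_class[1L], integer(1)))), 1:5)
  expect_equal(sort(unname(vapply(long, function(tr) tr$item_class[16L], integer(1)))), 1:5)
})

test_that("schedules are reproducible by seed and differ across seeds", {
  expect_identical(make_sequence_schedule(4L), make_sequence_schedule(4L))
  expect_false(identical(make_sequence_schedule(4L), make_sequence_schedule(5L)))
  expect_identical(make_slow_schedule(4L), make_slow_schedule(4L))
  expect_identical(make_repetition_schedule(4L), make_repetition_schedule(4L))
})

test_that("simulated probabilities are simplex rows with ordered forward window", {
  tcs <- fixture_seq_tcs()
  for (tc in tcs[1:10]) {
    expect_equal(rowSums(tc$probs), rep(1, 13), tolerance = 1e-9)
    expect_true(all(tc$probs >= 0 & tc$probs <= 1))
  }
  # zero-noise: earlier items have >= probability while every response is
  # still in its rising phase (t <= d + lambda/2, i.e. TRs up to 4); later
  # forward-window TRs of the slow conditions can already have the first
  # item's response decaying below later items'
  acq <- acquisition_params()
  for (ms in c(32, 512, 2048)) {
    for (tc in fixture_by_speed(ms)[1:3]) {
      pw <- compute_periods(5.24, 0.56, delta_trs(speed_condition(ms / 1000), acq), 13)
      ord <- order(tc$position_map)
      for (k in pw$forward_start_tr:min(pw$forward_end_tr, 4L)) {
        p_by_pos <- tc$probs[k, ord]
        expect_true(all(diff(p_by_pos) <= 1e-12))
      }
    }
  }
})

test_that("simultaneous items give equal probabilities by symmetry", {
  # delta = 0: all five items share one onset
  sched <- data.frame(trial_id = 1L, condition = "sequence", run_id = 1L,
                      onset = rep(10, 5), duration = 0.1, item_class = 1:5,
                      serial_position = 1:5, orientation = "upright",
                      isi_seconds = 0, target_position = 1L)
  tc <- simulate_probabilities(sched)[[1L]]
  expect_true(all(abs(tc$probs - 0.2) < 1e-12))
})

test_that("unknown schedule conditions are rejected", {
  sched <- data.frame(trial_id = 1L, condition = "mystery", run_id = 1L,
                      onset = 0, duration = 0.1, item_class = 1L,
                      serial_position = 1L, orientation = "upright",
                      isi_seconds = 0, target_position = 1L)
  expect_error(simulate_probabilities(sched), "unknown condition")
})

test_that("rest simulation is a seeded simplex process with tunable spikiness", {
  rest <- simulate_rest(n_trs = 120L, seed = 9L)
  expect_equal(n_trs(rest), 120L)
  expect_equal(rowSums(rest$probs), rep(1, 120), tolerance = 1e-9)
  expect_identical(simulate_rest(n_trs = 50L, seed = 2L)$probs,
                   simulate_rest(n_trs = 50L, seed = 2L)$probs)
  # lower concentration => spikier rows => higher mean per-TR SD
  sd_low <- probability_sd_per_tr(simulate_rest(233L, 3L, concentration = 0.3))
  sd_high <- probability_sd_per_tr(simulate_rest(233L, 3L, concentration = 3.0))
  expect_gt(sd_low, sd_high)
})

test_that("voxel simulation is deterministic with template structure", {
  sched <- make_slow_schedule(2L)
  sched <- sched[sched$run_id <= 2L, ]
  spec <- voxel_pattern_spec(n_voxels = 40L, noise_sd = 0, n_runs = 2L)
  vd <- simulate_voxels(sched, spec, seed = 3L)
  vd2 <- simulate_voxels(sched, spec, seed = 3L)
  expect_identical(vd$runs, vd2$runs)
  # requested negative template correlations
  ct <- stats::cor(vd$templates)
  expect_true(all(ct[upper.tri(ct)] <= 0))
  # noiseless: at the peak TR the pattern correlates maximally with the
  # template of the class that was shown
  ev <- vd$events[vd$events$run_id == 1L, ][1:20, ]
  hits <- vapply(seq_len(nrow(ev)), function(i) {
    pat <- vd$runs[["1"]][ev$peak_tr[i], ]
    which.max(stats::cor(pat, vd$templates))
  }, integer(1))
  expect_gt(mean(hits == ev$item_class), 0.9)
})

test_that("event insertion blends by kappa and keeps the simplex", {
  rest <- simulate_rest(233L, seed = 4L)
  segs <- lapply(fixture_by_speed(32)[1:8], sequence_insert_segment)
  # kappa = 1: inserted rows equal the trial rows exactly
  ins1 <- insert_events(rest, segs, blend_spec(1, n_inserts = 3L, seed = 6L))
  for (j in seq_along(ins1$insert_starts)) {
    span <- ins1$insert_starts[j]:(ins1$insert_starts[j] + 11L)
    expect_equal(ins1$tc$probs[span, ], segs[[ins1$trial_idx[j]]][1:12, ])
  }
  # kappa = 0: inserted rows are pure relocated rest rows
  ins0 <- insert_events(rest, segs, blend_spec(0, n_inserts = 3L, seed = 6L))
  for (j in seq_along(ins0$insert_starts)) {
    span <- ins0$insert_starts[j]:(ins0$insert_starts[j] + 11L)
    donor <- ins0$donor_starts[j]:(ins0$donor_starts[j] + 11L)
    expect_equal(ins0$tc$probs[span, ], rest$probs[donor, ])
  }
  # any kappa: rows still sum to 1; segments pairwise non-overlapping
  ins <- insert_events(rest, segs, blend_spec(0.5, n_inserts = 6L, seed = 8L))
  expect_equal(rowSums(ins$tc$probs), rep(1, 233), tolerance = 1e-9)
  starts <- sort(ins$insert_starts)
  expect_true(all(diff(starts) >= 12L))
  # infeasible placement errors out
  short_rest <- simulate_rest(20L, seed = 1L)
  expect_error(insert_events(short_rest, segs, blend_spec(0.5, 6L)),
               "do not fit|non-overlapping")
})
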