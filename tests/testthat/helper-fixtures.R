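# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# zero-noise sequence-trial time courses for the default 5-speed design
fixture_seq_tcs <- function() {
  if (is.null(.fixtures$seq_tcs)) {
    sched <- make_sequence_schedule(3L)
    .fixtures$seq_sched <- sched
    .fixtures$seq_tcs <- simulate_probabilities(sched)
  }
  .fixtures$seq_tcs
}

fixture_seq_sched <- function() {
  fixture_seq_tcs()
  .fixtures$seq_sched
}

fixture_by_speed <- function(ms) {
  Filter(function(tc) tc$speed_ms == ms, fixture_seq_tcs())
}

# a small probability_timecourse with hand-set values
toy_tc <- function(probs, position_map = seq_len(ncol(probs))) {
  probability_timecourse(as.matrix(probs), position_map = position_map)
}

# random simplex rows
random_prob_matrix <- function(n_trs, n_classes = 5L) {
  m <- matrix(stats::runif(n_trs * n_classes), n_trs)
  m / rowSums(m)
}

# O(n^2) concordant/discordant pair counter (independent Kendall oracle)
kendall_bruteforce <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1L
    if (s < 0) disc <- disc + 1L
  }
  (conc - disc) / (n * (n - 1L) / 2)
}

# independent OLS slope via lm()
slope_bruteforce <- function(pos, probs) {
  unname(stats::coef(stats::lm(probs ~ pos))[2L])
}
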