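# ECG-triggered ventilation simulation and retrospective phase assignment.

# independent event-by-event replay used as the oracle for the trigger logic
brute_force_triggers <- function(r_waves, T_signal) {
  triggers <- numeric(0)
  high_until <- -Inf
  for (t in r_waves) {
    if (t > high_until) {
      triggers <- c(triggers, t)
      high_until <- t + T_signal
    }
  }
  triggers
}

test_that("trigger logic reproduces the beats-per-cycle arithmetic", {
  cfg <- gating_config(T_signal = 0.75)
  ecg <- simulate_ecg(period = 0.39, jitter = 0, duration = 60)
  tr <- simulate_triggers(ecg, cfg)
  expect_setequal(unique(attr(tr, "beats_per_cycle")), 2L)

  # a window shorter than the period triggers on every beat
  tr2 <- simulate_triggers(ecg, gating_config(T_signal = 0.1))
  expect_setequal(unique(attr(tr2, "beats_per_cycle")), 1L)

  expect_error(simulate_triggers(numeric(0), cfg), "empty")
})

test_that("jittered trigger trains match the brute-force replay oracle", {
  cfg <- gating_config(T_signal = 0.75)
  for (seed in c(2, 9)) {
    ecg <- simulate_ecg(period = 0.39, jitter = 0.01, duration = 120, seed = seed)
    expect_equal(as.numeric(simulate_triggers(ecg, cfg)),
                 brute_force_triggers(ecg, 0.75))
  }
})

test_that("phase assignment bins projections like an exhaustive search", {
  cfg <- gating_config(T_signal = 0.75, delta_t = 0.01)
  ecg <- simulate_ecg(period = 0.39, jitter = 0.01, duration = 100, seed = 5)
  tr <- as.numeric(simulate_triggers(ecg, cfg))
  set.seed(11)
  times <- sort(runif(1000, 0, max(tr) + 0.5))
  asg <- assign_phase(times, triggers = tr, cfg = cfg)

  # brute force over all (projection, cycle) pairs
  bf_cycle <- rep(NA_integer_, length(times))
  for (i in seq_along(times)) {
    j <- NA
    for (k in seq_along(tr)) if (times[i] >= tr[k]) j <- k
    bf_cycle[i] <- j
  }
  got <- asg$projections
  expect_true(all(!got$assigned[is.na(bf_cycle)]))
  sel <- got$assigned & !is.na(bf_cycle)
  expect_equal(got$cycle[sel], bf_cycle[sel] - 1)
  expect_equal(got$t_star[sel], times[sel] - tr[bf_cycle[sel]])
  expect_equal(got$bin[sel], floor((times[sel] - tr[bf_cycle[sel]]) / 0.01))
  # conservation: every projection is assigned exactly once or flagged
  expect_equal(sum(got$assigned) + asg$n_unassigned, length(times))
})

test_that("a projection exactly at a trigger lands in bin zero", {
  cfg <- gating_config(delta_t = 0.01)
  tr <- c(1, 1.78, 2.56)
  asg <- assign_phase(c(1.78), triggers = tr, cfg = cfg)
  expect_equal(asg$projections$t_star, 0)
  expect_equal(asg$projections$bin, 0)
})

test_that("periodic breathing at two 0.39 s beats per cycle gives 78 bins", {
  cfg <- gating_config(T_signal = 0.75, delta_t = 0.01)
  ecg <- simulate_ecg(period = 0.39, jitter = 0, duration = 200)
  tr <- simulate_triggers(ecg, cfg)
  times <- sort(runif(2000, min(tr), max(tr)))
  asg <- assign_phase(times, triggers = tr, cfg = cfg)
  expect_identical(asg$n_bins, 78L)
})

test_that("bin occupancy is uniform for uniform projection times", {
  cfg <- gating_config(T_signal = 0.75, delta_t = 0.01)
  ecg <- simulate_ecg(period = 0.39, jitter = 0, duration = 400)
  tr <- simulate_triggers(ecg, cfg)
  set.seed(3)
  n <- 78000
  times <- runif(n, min(tr), max(tr))
  asg <- assign_phase(times, triggers = tr, cfg = cfg)
  counts <- asg$bin_counts[seq_len(asg$n_bins)]
  expected <- sum(counts) / asg$n_bins
  # Poisson fluctuation: all bins within ~4.5 sqrt(N) of the mean
  expect_true(all(abs(counts - expected) < 4.5 * sqrt(expected)))
})

test_that("scan summary reproduces the half-rotation arithmetic", {
  cfg <- gating_config(omega = 0.34, T_signal = 0.75, delta_t = 0.01)
  ss <- scan_summary(cfg, mean_cycle = 0.78)
  expect_equal(ss$duration_min, 8.8)
  expect_equal(ss$n_cycles_rounded, 700)
  ss2 <- scan_summary(gating_config(omega = 1), mean_cycle = 0.78)
  expect_equal(ss2$duration_s, 180)
})
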