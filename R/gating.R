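# Retrospective cardiorespiratory gating: ECG-triggered ventilation
# simulation and phase assignment of timestamped projections.

#' Gating configuration
#'
#' @param T_signal duration of the trigger square signal in seconds; R-wave
#'   detection is disabled while the signal is high, so the square-signal
#'   length sets how many heartbeats fit in one respiratory cycle.
#' @param delta_t phase-bin width in seconds (the reconstruction time
#'   resolution).
#' @param omega rotation speed in degrees per second.
#' @param t0 rotation start time in seconds.
#' @param duty_cycle ventilator duty cycle (metadata only).
#' @return an object of class `gating_config`.
#' @export
gating_config <- function(T_signal = 0.75, delta_t = 0.01, omega = 0.34,
                          t0 = 0, duty_cycle = 0.3) {
  assert_that(T_signal > 0, "T_signal must be positive")
  assert_that(delta_t > 0, "delta_t must be positive")
  assert_that(omega >= 0, "omega must be non-negative")
  structure(
    list(T_signal = T_signal, delta_t = delta_t, omega = omega, t0 = t0,
         duty_cycle = duty_cycle),
    class = "gating_config"
  )
}

#' Simulate ECG-triggered breath starts
#'
#' The first R wave raises the trigger square signal; every R wave falling
#' inside the open-high window `(trigger, trigger + T_signal]` is ignored
#' (detection is disabled for the whole signal duration); the next R wave
#' after the window triggers the next breath.
#'
#' @param r_wave_times strictly increasing R-wave timestamps in seconds.
#' @param cfg a [gating_config()].
#' @return numeric vector of breath-start (trigger) times, with attribute
#'   `beats_per_cycle` giving the number of R waves from each trigger to the
#'   next (length one less than the number of triggers).
#' @export
simulate_triggers <- function(r_wave_times, cfg) {
  assert_that(length(r_wave_times) > 0, "empty R-wave stream")
  assert_that(all(diff(r_wave_times) > 0), "R-wave times must be strictly increasing")
  triggers <- numeric(0)
  beats <- integer(0)
  current <- -Inf
  count <- 0L
  for (t in r_wave_times) {
    count <- count + 1L
    if (t > current + cfg$T_signal) {
      if (is.finite(current)) beats <- c(beats, count)
      triggers <- c(triggers, t)
      current <- t
      count <- 0L
    }
  }
  attr(triggers, "beats_per_cycle") <- beats
  triggers
}

#' Assign projections to respiratory cycles and phase bins
#'
#' Each projection at time t within cycle j (the half-open interval from
#' trigger j to trigger j+1) gets phase time t* = t - trigger_j and bin
#' index floor(t* / delta_t). Projections before the first trigger or beyond
#' the last cycle are flagged "unassigned" rather than dropped.
#'
#' @param times projection acquisition times in seconds.
#' @param angles projection angles in degrees (default omega * (t - t0)).
#' @param triggers breath-start times from [simulate_triggers()] or recorded.
#' @param cfg a [gating_config()].
#' @return an object of class `gating_assignment`: a data.frame (`t`,
#'   `alpha`, `cycle`, `t_star`, `bin`, `assigned`) plus `n_bins` (bins
#'   covering the mean cycle), `bin_counts`, and `cycle_durations`.
#' @export
assign_phase <- function(times, angles = NULL, triggers, cfg) {
  assert_that(length(triggers) >= 2, "need at least two triggers to define a cycle")
  if (is.null(angles)) angles <- cfg$omega * (times - cfg$t0)
  assert_that(length(angles) == length(times), "one angle per projection required")
  durations <- diff(triggers)
  mean_cycle <- mean(durations)
  # last cycle extends one mean duration past the final trigger
  upper <- c(triggers[-1], triggers[length(triggers)] + mean_cycle)
  j <- findInterval(times, triggers)           # 0 if before first trigger
  assigned <- j >= 1 & times < upper[pmax(j, 1)]
  t_star <- ifelse(assigned, times - triggers[pmax(j, 1)], NA_real_)
  bin <- ifelse(assigned, floor(t_star / cfg$delta_t), NA_integer_)
  n_bins <- as.integer(ceiling(mean_cycle / cfg$delta_t - 1e-9))
  tab <- data.frame(t = times, alpha = angles, cycle = ifelse(assigned, j - 1L, NA),
                    t_star = t_star, bin = bin, assigned = assigned)
  counts <- table(factor(tab$bin[tab$assigned], levels = 0:max(c(tab$bin, n_bins - 1), na.rm = TRUE)))
  structure(
    list(projections = tab, n_bins = n_bins,
         bin_counts = as.integer(counts),
         bin_levels = as.integer(names(counts)),
         mean_cycle = mean_cycle, cycle_durations = durations,
         n_unassigned = sum(!assigned)),
    class = "gating_assignment"
  )
}

#' @export
print.gating_assignment <- function(x, ...) {
  cat(sprintf("<gating_assignment> %d projections, %d bins (mean cycle %.3f s), %d unassigned\n",
              nrow(x$projections), x$n_bins, x$mean_cycle, x$n_unassigned))
  invisible(x)
}

#' Scan geometry and sampling summary
#'
#' @param cfg a [gating_config()] (omega must be positive).
#' @param mean_cycle mean respiratory cycle duration in seconds.
#' @param n_projections optional projection count for per-bin density.
#' @param integration_time optional per-projection integration time, seconds.
#' @return list with `duration_s` (half rotation, 180/omega), `duration_min`,
#'   `n_cycles` (expected respiratory cycles), `n_cycles_rounded` (nearest
#'   hundred), and optionally projections per bin.
#' @export
scan_summary <- function(cfg, mean_cycle, n_projections = NULL,
                         integration_time = NULL) {
  assert_that(cfg$omega > 0, "omega must be positive for a scan summary")
  duration <- 180 / cfg$omega
  n_cycles <- duration / mean_cycle
  n_bins <- ceiling(mean_cycle / cfg$delta_t - 1e-9)
  out <- list(
    duration_s = duration,
    duration_min = round(duration / 60, 1),
    n_cycles = n_cycles,
    n_cycles_rounded = round(n_cycles / 100) * 100,
    n_bins = as.integer(n_bins),
    angle_per_cycle = cfg$omega * mean_cycle
  )
  if (!is.null(n_projections)) {
    out$projections_per_bin <- n_projections / n_bins
    out$angular_step_per_bin <- 180 / (n_projections / n_bins)
  }
  if (!is.null(integration_time)) out$exposure_fraction <- integration_time * n_projections / duration
  out
}

#' Simulate an ECG R-wave stream
#'
#' Periodic heartbeats with optional Gaussian jitter on the period, for
#' driving [simulate_triggers()] in tests and the phantom pipeline.
#'
#' @param period mean heartbeat period in seconds.
#' @param jitter standard deviation of the period in seconds.
#' @param duration total stream length in seconds.
#' @param seed RNG seed.
#' @return increasing vector of R-wave times.
#' @export
simulate_ecg <- function(period = 0.39, jitter = 0, duration = 60, seed = 1L) {
  n_max <- ceiling(duration / period * 1.5) + 10
  gaps <- if (jitter > 0)
    with_seed(seed, pmax(period / 4, rnorm(n_max, period, jitter)))
  else rep(period, n_max)
  tt <- cumsum(gaps)
  tt[tt <= duration]
}
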