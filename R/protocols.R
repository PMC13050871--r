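# Optogenetic stimulation schedules. Two patterned protocols delivering the
# same light dose per session: evenly spaced 5 ms pulses at 5 Hz (oSparse,
# one pulse every 200 ms) and five-pulse 50 Hz bursts once per second
# (oBurst, intra-burst interval 20 ms, then rest to the end of the 1 s
# epoch). A one-hour session delivers 18,000 pulses under either protocol.
#
# Times are represented as exact integer microseconds to avoid float drift
# over hour-long sessions.

.pulse_train <- function(onset_us, duration_us, name, session_s,
                         power_density_mW_mm2) {
  stopifnot(length(onset_us) == length(duration_us))
  if (length(onset_us) > 1 && any(diff(onset_us) <= 0))
    stop("pulse onsets must be strictly increasing")
  if (length(onset_us) > 1 &&
      any(onset_us[-1] < onset_us[-length(onset_us)] +
            duration_us[-length(duration_us)]))
    stop("pulses must not overlap")
  if (length(onset_us) &&
      max(onset_us + duration_us) > session_s * 1e6 + 1e-6)
    stop("pulses must end within the session")
  structure(list(pulses = data.frame(onset_us = as.numeric(onset_us),
                                     duration_us = as.numeric(duration_us)),
                 protocol = name, session_s = session_s,
                 power_density_mW_mm2 = power_density_mW_mm2),
            class = "rq_pulse_train")
}

#' @export
print.rq_pulse_train <- function(x, ...) {
  cat(sprintf("<rq_pulse_train '%s'> %d pulses over %g s\n", x$protocol,
              nrow(x$pulses), x$session_s))
  invisible(x)
}

#' oSparse: evenly spaced pulse schedule
#'
#' `rate_hz` pulses of `pulse_ms` per second, evenly spaced from t = 0
#' (defaults: 5 ms pulses at 5 Hz, i.e. one pulse every 200 ms; a 3600 s
#' session delivers 18,000 pulses).
#'
#' @param session_s session duration (s), >= 0.
#' @param pulse_ms pulse duration (ms).
#' @param rate_hz pulse rate (Hz); the duty cycle
#'   `rate_hz * pulse_ms / 1000` must be < 1.
#' @param power_density_mW_mm2 irradiance metadata (default 27.2).
#' @return an `rq_pulse_train`.
#' @export
make_osparse <- function(session_s = 3600, pulse_ms = 5, rate_hz = 5,
                         power_density_mW_mm2 = 27.2) {
  stopifnot(session_s >= 0, pulse_ms > 0, rate_hz > 0)
  if (rate_hz * pulse_ms / 1000 >= 1)
    stop("duty cycle must be < 1")
  n <- floor(session_s * rate_hz)
  period_us <- round(1e6 / rate_hz)
  onsets <- (seq_len(n) - 1) * period_us
  .pulse_train(onsets, rep(pulse_ms * 1000, n), "oSparse", session_s,
               power_density_mW_mm2)
}

#' oBurst: burst pulse schedule
#'
#' Each epoch (default 1 s) starts with `pulses_per_burst` pulses at the
#' intra-burst rate (default five 5 ms pulses at 50 Hz, i.e. 20 ms apart),
#' followed by rest until the epoch ends. A 3600 s session delivers 18,000
#' pulses, matching the oSparse dose.
#'
#' @param session_s session duration (s), >= 0.
#' @param pulse_ms pulse duration (ms).
#' @param pulses_per_burst pulses per burst (>= 0).
#' @param intra_hz intra-burst pulse rate (Hz).
#' @param epoch_s epoch (burst period) duration (s); the burst span must fit
#'   within the epoch.
#' @param power_density_mW_mm2 irradiance metadata.
#' @return an `rq_pulse_train`.
#' @export
make_oburst <- function(session_s = 3600, pulse_ms = 5, pulses_per_burst = 5,
                        intra_hz = 50, epoch_s = 1,
                        power_density_mW_mm2 = 27.2) {
  stopifnot(session_s >= 0, pulse_ms > 0, pulses_per_burst >= 0,
            intra_hz > 0, epoch_s > 0)
  if (pulses_per_burst > 0 &&
      (pulses_per_burst - 1) / intra_hz + pulse_ms / 1000 >= epoch_s)
    stop("burst does not fit within the epoch")
  n_epochs <- floor(session_s / epoch_s)
  if (n_epochs == 0 || pulses_per_burst == 0)
    return(.pulse_train(numeric(), numeric(), "oBurst", session_s,
                        power_density_mW_mm2))
  epoch_us <- round(epoch_s * 1e6)
  intra_us <- round(1e6 / intra_hz)
  onsets <- as.vector(outer((seq_len(pulses_per_burst) - 1) * intra_us,
                            (seq_len(n_epochs) - 1) * epoch_us, "+"))
  .pulse_train(onsets, rep(pulse_ms * 1000, length(onsets)), "oBurst",
               session_s, power_density_mW_mm2)
}

#' Audit a pulse train
#'
#' Exact bookkeeping from the pulse list; raises if the train violates its
#' non-overlap invariant.
#'
#' @param train an `rq_pulse_train`.
#' @return list: `pulse_count`, `total_on_time_s`, `duty_cycle` (on-time /
#'   session), `min_onset_interval_s`, `max_onset_interval_s` (NA with < 2
#'   pulses).
#' @export
audit_train <- function(train) {
  stopifnot(inherits(train, "rq_pulse_train"))
  p <- train$pulses
  if (nrow(p) > 1) {
    if (any(diff(p$onset_us) <= 0) ||
        any(p$onset_us[-1] < p$onset_us[-nrow(p)] + p$duration_us[-nrow(p)]))
      stop("invariant violation: overlapping or unordered pulses")
  }
  iv <- if (nrow(p) > 1) diff(p$onset_us) / 1e6 else NA_real_
  list(pulse_count = nrow(p),
       total_on_time_s = sum(p$duration_us) / 1e6,
       duty_cycle = if (train$session_s > 0)
         sum(p$duration_us) / 1e6 / train$session_s else 0,
       min_onset_interval_s = if (all(is.na(iv))) NA_real_ else min(iv),
       max_onset_interval_s = if (all(is.na(iv))) NA_real_ else max(iv))
}

#' Export a pulse train as a TTL-style CSV (onset_us, duration_us)
#' @param train an `rq_pulse_train`.
#' @param path output file.
#' @export
write_train_csv <- function(train, path) {
  write.csv(train$pulses, path, row.names = FALSE)
  invisible(path)
}

#' Re-import a pulse train written by [write_train_csv()]
#' @param path CSV file.
#' @param name protocol name to record.
#' @param session_s session duration (s).
#' @param power_density_mW_mm2 irradiance metadata.
#' @export
read_train_csv <- function(path, name = "imported", session_s,
                           power_density_mW_mm2 = NA_real_) {
  p <- read.csv(path)
  .pulse_train(p$onset_us, p$duration_us, name, session_s,
               power_density_mW_mm2)
}
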