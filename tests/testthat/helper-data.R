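# Shared fixtures, all generated in code. Expensive objects are built once
# per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 4-participant protocol dataset + extracted windows, reused across files
tiny_dataset <- function() cached("tiny_ds", simulate_dataset(4, seed = 101))
tiny_windows <- function() cached("tiny_win", extract_windows(tiny_dataset()))

# wrap raw 600 x 3 matrices as a window frame
mk_window <- function(static, dynamic,
                      posture = "not_upright", activity = 1L) {
  structure(list(participant_id = "T01", activity_code = activity,
                 minute_id = 1L, window_index = 1L,
                 observed_posture = posture,
                 static = static, dynamic = dynamic),
            class = "window_frame")
}

const_mat <- function(x, y, z, n = 600L) {
  cbind(x = rep(x, n), y = rep(y, n), z = rep(z, n))
}

# closed-form magnitude response of the bilinear-transform Butterworth
# design (independent oracle for the filter gain at any frequency)
butter_digital_gain <- function(f, fc, fs, order) {
  1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * order))
}

# a minimal synthetic recording built by hand (not via the simulator):
# `segments` is a data.frame(activity_code, len_s, posture); gas minutes
# are marked over given offsets
mk_recording <- function(segments, fs = 60, gas_offsets = list(c(120, 180),
                                                               c(180, 240))) {
  total <- sum(segments$len_s) * fs
  set.seed(99)
  xyz <- cbind(x = rnorm(total, 0, 0.02),
               y = rnorm(total, 1, 0.02),
               z = rnorm(total, 0, 0.02))
  ann <- list()
  start <- 0
  for (i in seq_len(nrow(segments))) {
    ann[[length(ann) + 1L]] <- data.frame(
      participant_id = "T01", activity_code = segments$activity_code[i],
      start_s = start, end_s = start + segments$len_s[i], gas_minute = 0L,
      observed_posture = segments$posture[i])
    for (g in seq_along(gas_offsets)) {
      off <- gas_offsets[[g]]
      if (off[2] <= segments$len_s[i]) {
        ann[[length(ann) + 1L]] <- data.frame(
          participant_id = "T01", activity_code = segments$activity_code[i],
          start_s = start + off[1], end_s = start + off[2],
          gas_minute = g, observed_posture = segments$posture[i])
      }
    }
    start <- start + segments$len_s[i]
  }
  structure(list(participant_id = "T01", sample_rate_hz = fs,
                 samples = xyz, time_s = (seq_len(total) - 1) / fs,
                 annotations = do.call(rbind, ann)),
            class = "acc_recording")
}

# published cross-validation confusion matrices (rows = predicted,
# columns = reference, class order Sedentary/Standing/LIPA/MVPA) and the
# printed per-class statistics they must reproduce
published_confusions <- function() {
  list(
    svm = list(
      counts = rbind(c(1463, 0, 12, 0),
                     c(0, 588, 48, 0),
                     c(1, 48, 448, 61),
                     c(0, 0, 272, 2951)),
      sensitivity = c(99.9, 92.5, 57.4, 98.0),
      specificity = c(99.7, 99.1, 97.8, 90.6),
      balanced_accuracy = c(99.8, 95.8, 77.6, 94.3)),
    ima = list(
      counts = rbind(c(1463, 0, 12, 0),
                     c(0, 588, 48, 0),
                     c(1, 48, 469, 66),
                     c(0, 0, 251, 2946)),
      sensitivity = c(99.9, 92.5, 60.1, 97.8),
      specificity = c(99.7, 99.1, 97.8, 91.3),
      balanced_accuracy = c(99.8, 95.8, 78.9, 94.5)),
    tm = list(
      counts = rbind(c(1454, 0, 12, 0),
                     c(0, 588, 48, 0),
                     c(10, 47, 398, 67),
                     c(0, 1, 322, 2945)),
      sensitivity = c(99.3, 92.5, 51.0, 97.8),
      specificity = c(99.7, 99.1, 97.6, 88.8),
      balanced_accuracy = c(99.5, 95.8, 74.3, 93.3)),
    random_forest = list(
      counts = rbind(c(1463, 0, 34, 0),
                     c(0, 585, 48, 0),
                     c(1, 47, 497, 82),
                     c(0, 4, 201, 2930)),
      sensitivity = c(99.9, 92.0, 63.7, 97.3),
      specificity = c(99.2, 99.1, 97.5, 92.9),
      balanced_accuracy = c(99.6, 95.5, 80.6, 95.1)))
}
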