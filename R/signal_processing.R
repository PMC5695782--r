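# Signal conditioning: zero-phase Butterworth filtering, static/dynamic
# decomposition and 10-s windowing of the gas-sampling minutes.

#' Zero-phase low-pass Butterworth filter
#'
#' Designs an n-th order digital Butterworth low-pass filter and applies it
#' forward and backward (zero net phase, squared magnitude response). Edges
#' are handled by odd reflection of the series combined with steady-state
#' filter initial conditions, so a constant series passes through unchanged
#' and startup transients decay inside the reflected padding.
#'
#' @param x Numeric vector, one axis of a uniformly sampled series.
#' @param cutoff_hz Low-pass cut-off frequency in Hz (must be below Nyquist).
#' @param sample_rate_hz Sampling rate in Hz (default 60).
#' @param order Butterworth filter order for the single-pass design
#'   (default 4). The forward-backward application squares the magnitude
#'   response.
#' @param pad Number of reflected samples prepended/appended per edge;
#'   `"auto"` scales the padding with the filter time constant
#'   (`3 * sample_rate / cutoff`, at least `3 * order`, at most `n - 1`).
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' lowpass_filter(rep(0.7, 600), cutoff_hz = 20) # constant in, constant out
#' @export
lowpass_filter <- function(x, cutoff_hz, sample_rate_hz = 60, order = 4,
                           pad = "auto") {
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("series must be finite numeric")
  }
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate_hz / 2) {
    stop("cutoff_hz must lie in (0, Nyquist = ", sample_rate_hz / 2, ")")
  }
  n <- length(x)
  if (n <= 3 * order) {
    stop("series too short (", n, " samples) for edge padding of a ",
         order, "th order filter")
  }
  if (identical(pad, "auto")) {
    pad <- max(3L * order, ceiling(3 * sample_rate_hz / cutoff_hz))
  }
  pad <- as.integer(min(pad, n - 1L))
  bf <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), type = "low")
  b <- bf$b
  a <- bf$a
  k <- max(length(a), length(b)) - 1L
  g <- sum(b) / sum(a) # DC gain of the single-pass design (~1)
  one_pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], k),
                              init.y = rep(z[1] * g, k)))
  }
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Decompose a recording into static and dynamic acceleration
#'
#' Applies the two-stage filtering used for thigh-worn accelerometry: a
#' 20 Hz low-pass removes sensor noise, then a 0.5 Hz low-pass of the
#' noise-filtered signal isolates the gravity-dominated static component.
#' The dynamic (movement) component is the residual, so
#' `static + dynamic == noise_filtered` holds exactly by construction.
#'
#' @param recording An `acc_recording`, see [read_recording()] or
#'   [simulate_dataset()].
#' @param noise_cutoff_hz Noise low-pass cut-off (default 20 Hz).
#' @param static_cutoff_hz Gravity low-pass cut-off (default 0.5 Hz).
#' @param order Butterworth order per pass (default 4).
#' @return An object of class `acc_decomposed`: list with n x 3 matrices
#'   `noise_filtered`, `static` and `dynamic` (columns x, y, z) and the
#'   originating `participant_id` and `sample_rate_hz`.
#' @export
decompose_recording <- function(recording, noise_cutoff_hz = 20,
                                static_cutoff_hz = 0.5, order = 4) {
  stopifnot(inherits(recording, "acc_recording"))
  raw <- recording$samples
  fs <- recording$sample_rate_hz
  nf <- apply(raw, 2, lowpass_filter, cutoff_hz = noise_cutoff_hz,
              sample_rate_hz = fs, order = order)
  st <- apply(nf, 2, lowpass_filter, cutoff_hz = static_cutoff_hz,
              sample_rate_hz = fs, order = order)
  dimnames(nf) <- dimnames(st) <- list(NULL, c("x", "y", "z"))
  structure(list(participant_id = recording$participant_id,
                 sample_rate_hz = fs,
                 noise_filtered = nf,
                 static = st,
                 dynamic = nf - st),
            class = "acc_decomposed")
}

#' Cut the gas-sampling minutes into non-overlapping 10-s windows
#'
#' Only the annotated gas-sampling minutes are windowed; each yields exactly
#' six 10-s windows of 600 samples per stream at 60 Hz.
#'
#' @param decomposed An `acc_decomposed` from [decompose_recording()].
#' @param recording The matching `acc_recording` (provides annotations).
#' @param window_s Window length in seconds (default 10).
#' @return List of `window_frame` objects. Each is a list with
#'   `participant_id`, `activity_code`, `minute_id`, `window_index`,
#'   `observed_posture`, and 600 x 3 matrices `static` and `dynamic`.
#' @export
segment_windows <- function(decomposed, recording, window_s = 10) {
  stopifnot(inherits(decomposed, "acc_decomposed"),
            inherits(recording, "acc_recording"))
  fs <- recording$sample_rate_hz
  ann <- recording$annotations
  gas <- ann[ann$gas_minute > 0L, , drop = FALSE]
  if (nrow(gas) == 0L) stop("no gas-sampling minutes annotated")
  wlen <- as.integer(window_s * fs)
  n <- nrow(decomposed$static)
  out <- vector("list", 0L)
  widx <- 0L
  for (i in seq_len(nrow(gas))) {
    i0 <- as.integer(round(gas$start_s[i] * fs)) + 1L
    i1 <- as.integer(round(gas$end_s[i] * fs))
    if (i1 > n) stop("annotation for activity ", gas$activity_code[i],
                     " extends past the end of the recording")
    nsamp <- i1 - i0 + 1L
    if (nsamp < 60L * fs) {
      stop("gas-sampling minute of activity ", gas$activity_code[i],
           " has only ", nsamp, " samples (< ", 60L * fs, ")")
    }
    nwin <- nsamp %/% wlen # trailing partial window dropped
    for (w in seq_len(nwin)) {
      j0 <- i0 + (w - 1L) * wlen
      sel <- j0:(j0 + wlen - 1L)
      widx <- widx + 1L
      out[[widx]] <- structure(list(
        participant_id = recording$participant_id,
        activity_code = gas$activity_code[i],
        minute_id = minute_id(gas$activity_code[i], gas$gas_minute[i]),
        window_index = widx,
        observed_posture = gas$observed_posture[i],
        static = decomposed$static[sel, , drop = FALSE],
        dynamic = decomposed$dynamic[sel, , drop = FALSE]),
        class = "window_frame")
    }
  }
  out
}

# one integer id per (activity, gas minute) pair: 1..20 for the full protocol
minute_id <- function(activity_code, gas_minute) {
  as.integer((activity_code - 1L) * 2L + gas_minute)
}
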