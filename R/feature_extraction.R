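# Time- and frequency-domain window features. Sixteen per-axis features are
# computed for each of the three axes of both the static and dynamic
# streams, plus per-stream cross-axis correlations and resultant vectors
# and, from the static stream only, the orientation angles.

PER_AXIS_FEATURES <- c("mean", "sd", "min", "max", "median", "iqr",
                       "skewness", "kurtosis", "rms", "peak_to_peak",
                       "peak_intensity", "zero_crossings",
                       "lag1_autocorrelation",
                       "dominant_frequency", "dominant_frequency_amplitude",
                       "spectral_entropy")

#' Time-domain features of one window axis
#'
#' Conventions: sample (n-1) standard deviation; adjusted Fisher-Pearson
#' skewness and excess kurtosis (both 0 on a constant window); rms of the
#' raw values; peak-to-peak = max - min; peak intensity = number of local
#' maxima of the mean-removed signal exceeding half its maximum absolute
#' value; zero crossings counted on the mean-removed series with zero
#' samples inheriting the previous sign; lag-1 autocorrelation with
#' overall-mean centring.
#'
#' @param x Numeric vector of exactly 600 finite samples (10 s at 60 Hz).
#' @return Named numeric vector of 13 time-domain features.
#' @export
time_domain_features <- function(x) {
  if (!all(is.finite(x))) stop("non-finite sample in window")
  n <- length(x)
  if (n != 600L) stop("window must hold exactly 600 samples, got ", n)
  m <- mean(x)
  s <- sd(x)
  centred <- x - m
  if (s > 0) {
    skew <- e1071::skewness(x, type = 2)
    kurt <- e1071::kurtosis(x, type = 2)
  } else {
    skew <- kurt <- 0 # constant window convention
  }
  c(mean = m,
    sd = s,
    min = min(x),
    max = max(x),
    median = median(x),
    iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    skewness = skew,
    kurtosis = kurt,
    rms = sqrt(mean(x^2)),
    peak_to_peak = max(x) - min(x),
    peak_intensity = peak_intensity(centred),
    zero_crossings = zero_crossings(centred),
    lag1_autocorrelation = lag1_autocorrelation(x))
}

peak_intensity <- function(centred) {
  n <- length(centred)
  amax <- max(abs(centred))
  if (amax == 0) return(0)
  interior <- 2:(n - 1)
  local_max <- centred[interior] > centred[interior - 1] &
    centred[interior] >= centred[interior + 1]
  sum(local_max & centred[interior] > 0.5 * amax)
}

zero_crossings <- function(centred) {
  s <- sign(centred)
  # zero samples inherit the previous sign
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 1
  sum(s[-1] != s[-length(s)])
}

lag1_autocorrelation <- function(x) {
  m <- mean(x)
  d <- x - m
  denom <- sum(d^2)
  if (denom == 0) return(0)
  n <- length(x)
  sum(d[-n] * d[-1]) / denom
}

#' Frequency-domain features of one window axis
#'
#' One-sided periodogram of the mean-removed, Hann-windowed signal.
#' Dominant frequency is the argmax bin excluding DC (0.1 Hz resolution for
#' a 600-point window at 60 Hz); spectral entropy is the Shannon entropy of
#' the normalised power spectrum (DC excluded) divided by `log2` of the
#' number of bins, so it lies in \[0, 1\].
#'
#' @param x Numeric vector of 600 samples.
#' @param sample_rate_hz Sampling rate (default 60).
#' @return Named vector: `dominant_frequency` (Hz),
#'   `dominant_frequency_amplitude`, `spectral_entropy`.
#' @export
frequency_domain_features <- function(x, sample_rate_hz = 60) {
  n <- length(x)
  centred <- x - mean(x)
  if (all(centred == 0)) {
    return(c(dominant_frequency = 0, dominant_frequency_amplitude = 0,
             spectral_entropy = 0))
  }
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  spec <- abs(fft(centred * hann))^2
  nb <- n %/% 2
  power <- spec[2:(nb + 1)] # one-sided, DC excluded
  freqs <- (1:nb) * sample_rate_hz / n
  k <- which.max(power)
  p <- power / sum(power)
  p <- p[p > 0]
  entropy <- -sum(p * log2(p)) / log2(nb)
  # amplitude of the dominant component, undoing the Hann coherent gain (1/2)
  amp <- 2 * sqrt(power[k]) / (sum(hann))
  c(dominant_frequency = freqs[k],
    dominant_frequency_amplitude = amp,
    spectral_entropy = entropy)
}

#' Orientation angles from the static (gravity) vector
#'
#' Roll, pitch and yaw of the window-mean static acceleration vector, each
#' the arctangent of one axis against the Euclidean norm of the other two:
#' `roll = atan2(mx, sqrt(my^2 + mz^2))`, `pitch = atan2(my, sqrt(mx^2 +
#' mz^2))`, `yaw = atan2(mz, sqrt(mx^2 + my^2))`, in degrees. With the
#' device worn on the anterior thigh, pitch is near 90 degrees when
#' standing (gravity along Y) and near 0 when the thigh is horizontal.
#'
#' @param static_window 600 x 3 matrix of static samples (columns x, y, z).
#' @return Named vector `roll`, `pitch`, `yaw` in degrees.
#' @export
orientation_angles <- function(static_window) {
  mv <- colMeans(static_window)
  if (sqrt(sum(mv^2)) == 0) {
    stop("zero mean static vector: free-fall is unphysical for worn devices")
  }
  deg <- 180 / pi
  c(roll  = atan2(mv[[1]], sqrt(mv[[2]]^2 + mv[[3]]^2)) * deg,
    pitch = atan2(mv[[2]], sqrt(mv[[1]]^2 + mv[[3]]^2)) * deg,
    yaw   = atan2(mv[[3]], sqrt(mv[[1]]^2 + mv[[2]]^2)) * deg)
}

#' Pairwise axis cross-correlations at lag zero
#'
#' Pearson correlation between each pair of axes over the window; a pair
#' involving a constant axis returns 0 by convention.
#'
#' @param window 600 x 3 matrix (columns x, y, z).
#' @return Named vector `cross_correlation_xy`, `cross_correlation_xz`,
#'   `cross_correlation_yz`.
#' @export
cross_correlations <- function(window) {
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  c(cross_correlation_xy = safe_cor(window[, 1], window[, 2]),
    cross_correlation_xz = safe_cor(window[, 1], window[, 3]),
    cross_correlation_yz = safe_cor(window[, 2], window[, 3]))
}

axis_features <- function(x, sample_rate_hz = 60) {
  c(time_domain_features(x), frequency_domain_features(x, sample_rate_hz))
}

stream_features <- function(mat, prefix, sample_rate_hz = 60) {
  out <- c()
  for (ax in c("x", "y", "z")) {
    f <- axis_features(mat[, ax], sample_rate_hz)
    names(f) <- paste(prefix, ax, names(f), sep = "_")
    out <- c(out, f)
  }
  cc <- cross_correlations(mat)
  names(cc) <- paste(prefix, names(cc), sep = "_")
  mv <- colMeans(mat)
  sds <- apply(mat, 2, sd)
  res <- c(resultant_mean = sqrt(sum(mv^2)), resultant_sd = sqrt(sum(sds^2)))
  names(res) <- paste(prefix, names(res), sep = "_")
  c(out, cc, res)
}

#' Feature vector of one window
#'
#' @param window A `window_frame` from [segment_windows()].
#' @param sample_rate_hz Sampling rate (default 60).
#' @return Named numeric vector following [feature_schema()].
#' @export
window_features <- function(window, sample_rate_hz = 60) {
  stopifnot(inherits(window, "window_frame"))
  ori <- orientation_angles(window$static)
  names(ori) <- paste("static", names(ori), sep = "_")
  c(stream_features(window$static, "static", sample_rate_hz),
    stream_features(window$dynamic, "dynamic", sample_rate_hz),
    ori)
}

#' Declared feature-column schema
#'
#' The source of truth for feature-table column order: 16 per-axis features
#' for each of 3 axes and 2 streams, 3 cross-axis correlations and 2
#' resultant-vector features per stream, and 3 orientation angles from the
#' static stream (109 columns).
#'
#' @return Data frame with columns `column`, `stream`, `axis`, `feature`,
#'   `units`.
#' @export
feature_schema <- function() {
  rows <- list()
  for (stream in c("static", "dynamic")) {
    for (ax in c("x", "y", "z")) {
      rows[[length(rows) + 1L]] <- data.frame(
        column = paste(stream, ax, PER_AXIS_FEATURES, sep = "_"),
        stream = stream, axis = ax, feature = PER_AXIS_FEATURES)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      column = paste(stream, c("cross_correlation_xy", "cross_correlation_xz",
                               "cross_correlation_yz",
                               "resultant_mean", "resultant_sd"), sep = "_"),
      stream = stream, axis = NA,
      feature = c("cross_correlation_xy", "cross_correlation_xz",
                  "cross_correlation_yz", "resultant_mean", "resultant_sd"))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    column = paste("static", c("roll", "pitch", "yaw"), sep = "_"),
    stream = "static", axis = NA, feature = c("roll", "pitch", "yaw"))
  out <- do.call(rbind, rows)
  out$units <- ifelse(out$feature %in% c("roll", "pitch", "yaw"), "degrees",
               ifelse(out$feature == "dominant_frequency", "Hz",
               ifelse(out$feature %in% c("zero_crossings", "peak_intensity",
                                         "spectral_entropy", "skewness",
                                         "kurtosis", "lag1_autocorrelation"),
                      "dimensionless", "g")))
  # keep order: static axes, static cross/resultant, dynamic axes,
  # dynamic cross/resultant, orientation
  rownames(out) <- NULL
  out
}

#' Feature matrix for a list of windows
#'
#' @param windows List of `window_frame` objects.
#' @param sample_rate_hz Sampling rate (default 60).
#' @return Data frame: metadata columns (`participant_id`, `activity_code`,
#'   `minute_id`, `window_index`, `observed_posture`) followed by the 109
#'   feature columns of [feature_schema()]. One row per window, no missing
#'   values.
#' @export
build_feature_matrix <- function(windows, sample_rate_hz = 60) {
  if (length(windows) == 0L) stop("empty window list")
  schema <- feature_schema()$column
  feats <- matrix(NA_real_, nrow = length(windows), ncol = length(schema),
                  dimnames = list(NULL, schema))
  meta <- data.frame(participant_id = character(length(windows)),
                     activity_code = integer(length(windows)),
                     minute_id = integer(length(windows)),
                     window_index = integer(length(windows)),
                     observed_posture = character(length(windows)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    fv <- tryCatch(window_features(w, sample_rate_hz), error = function(e) {
      stop("feature extraction failed for window ", w$window_index,
           " of participant ", w$participant_id, ": ", conditionMessage(e))
    })
    feats[i, ] <- fv[schema]
    meta$participant_id[i] <- as.character(w$participant_id)
    meta$activity_code[i] <- w$activity_code
    meta$minute_id[i] <- w$minute_id
    meta$window_index[i] <- w$window_index
    meta$observed_posture[i] <- w$observed_posture
  }
  if (any(!is.finite(feats))) {
    bad <- which(!is.finite(feats), arr.ind = TRUE)[1, ]
    stop("non-finite feature ", schema[bad[2]], " in window row ", bad[1])
  }
  cbind(meta, as.data.frame(feats))
}

#' Write a feature table with its JSON schema side-car
#'
#' @param features Data frame from [build_feature_matrix()].
#' @param path CSV output path; the side-car is written to
#'   `paste0(path, ".schema.json")`.
#' @return Invisibly, the two paths written.
#' @export
write_feature_table <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  side <- paste0(path, ".schema.json")
  jsonlite::write_json(feature_schema(), side, dataframe = "rows")
  invisible(c(path, side))
}
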