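# Cut-off point classifiers: the three window metrics (SVM, IMA, TM)
# computed on the dynamic stream, MET-anchored trend-line calibration, and
# posture-gated classification.

check_window_mat <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != 600L || ncol(mat) != 3L) {
    stop("expected a 600 x 3 dynamic sample matrix, got ",
         paste(dim(mat), collapse = " x "))
  }
}

#' Sum of vector magnitudes (SVM) of a window
#'
#' Sum over the 600 window samples of the Euclidean magnitude of the
#' dynamic acceleration vector, in g. (Unrelated to support vector
#' machines.)
#'
#' @param window A `window_frame`, or a 600 x 3 dynamic sample matrix.
#' @return SVM in g.
#' @export
compute_svm <- function(window) {
  mat <- if (inherits(window, "window_frame")) window$dynamic else window
  check_window_mat(mat)
  sum(sqrt(rowSums(mat^2)))
}

#' Integrated moduli of acceleration (IMA) of a window
#'
#' Sum over the three axes of the time integral of absolute dynamic
#' acceleration over the 10-s window, in g s. Numerical quadrature at the
#' sampling interval (1/60 s); rectangle rule by default.
#'
#' @param window A `window_frame` or a 600 x 3 dynamic sample matrix.
#' @param sample_rate_hz Sampling rate (default 60).
#' @param method `"rectangle"` (default) or `"trapezoid"` quadrature.
#' @return IMA in g s.
#' @export
compute_ima <- function(window, sample_rate_hz = 60,
                        method = c("rectangle", "trapezoid")) {
  mat <- if (inherits(window, "window_frame")) window$dynamic else window
  check_window_mat(mat)
  method <- match.arg(method)
  dt <- 1 / sample_rate_hz
  a <- abs(mat)
  if (method == "rectangle") {
    sum(a) * dt
  } else {
    sum(apply(a, 2, function(v) {
      dt * (sum(v) - (v[1] + v[length(v)]) / 2)
    }))
  }
}

#' Total movement (TM) of a window
#'
#' Euclidean norm of the three per-axis sample standard deviations of the
#' dynamic stream, in g. Identical to the dynamic `resultant_sd` feature.
#'
#' @param window A `window_frame` or a 600 x 3 dynamic sample matrix.
#' @return TM in g.
#' @export
compute_tm <- function(window) {
  mat <- if (inherits(window, "window_frame")) window$dynamic else window
  check_window_mat(mat)
  sqrt(sum(apply(mat, 2, sd)^2))
}

#' Upright-posture detection from the static Y axis
#'
#' With the device on the anterior thigh, the gravity projection on the
#' (standing-)vertical Y axis is near 1 g when upright and near 0 g when
#' the thigh is horizontal. The absolute value makes detection robust to a
#' flipped device (Y near -1 g upright).
#'
#' @param static_y_mean Window arithmetic mean of static Y acceleration (g).
#' @param threshold Decision threshold in g (default 0.5, the midpoint of
#'   the two gravity projections); upright iff `|static_y_mean| >
#'   threshold` (strictly).
#' @return Character vector, `"upright"` or `"not_upright"`.
#' @export
detect_posture <- function(static_y_mean, threshold = 0.5) {
  if (any(!is.finite(static_y_mean))) stop("static_y_mean must be finite")
  ifelse(abs(static_y_mean) > threshold, "upright", "not_upright")
}

#' All window metrics for a list of windows
#'
#' @param windows List of `window_frame` objects.
#' @param sample_rate_hz Sampling rate (default 60).
#' @return Data frame with metadata columns and `svm`, `ima`, `tm`,
#'   `static_y_mean`.
#' @export
window_metrics <- function(windows, sample_rate_hz = 60) {
  rows <- lapply(windows, function(w) {
    data.frame(participant_id = as.character(w$participant_id),
               activity_code = w$activity_code,
               minute_id = w$minute_id,
               window_index = w$window_index,
               observed_posture = w$observed_posture,
               svm = compute_svm(w),
               ima = compute_ima(w, sample_rate_hz),
               tm = compute_tm(w),
               static_y_mean = mean(w$static[, "y"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- trend-line calibration -------------------------------------------------

trend_families <- function() {
  # ordered by parameter count then fixed order, for R^2 tie-breaking
  list(
    linear = list(
      npar = 2,
      valid = function(m, met) TRUE,
      fit = function(m, met) {
        cf <- coef(lm(met ~ m))
        list(coefficients = cf,
             predict = function(x) cf[[1]] + cf[[2]] * x)
      }),
    logarithmic = list(
      npar = 2,
      valid = function(m, met) all(m > 0),
      fit = function(m, met) {
        cf <- coef(lm(met ~ log(m)))
        list(coefficients = cf,
             predict = function(x) cf[[1]] + cf[[2]] * log(x))
      }),
    power = list(
      npar = 2,
      valid = function(m, met) all(m > 0) && all(met > 0),
      fit = function(m, met) {
        cf <- coef(lm(log(met) ~ log(m)))
        list(coefficients = c(a = unname(exp(cf[[1]])), b = unname(cf[[2]])),
             predict = function(x) exp(cf[[1]]) * x^cf[[2]])
      }),
    exponential = list(
      npar = 2,
      valid = function(m, met) all(met > 0),
      fit = function(m, met) {
        cf <- coef(lm(log(met) ~ m))
        list(coefficients = c(a = unname(exp(cf[[1]])), b = unname(cf[[2]])),
             predict = function(x) exp(cf[[1]]) * exp(cf[[2]] * x))
      }),
    quadratic = list(
      npar = 3,
      valid = function(m, met) TRUE,
      fit = function(m, met) {
        cf <- coef(lm(met ~ m + I(m^2)))
        list(coefficients = cf,
             predict = function(x) cf[[1]] + cf[[2]] * x + cf[[3]] * x^2)
      })
  )
}

is_monotone_increasing <- function(f, lo, hi, n = 201L) {
  g <- seq(lo, hi, length.out = n)
  v <- f(g)
  all(is.finite(v)) && all(diff(v) > -1e-12 * max(1, diff(range(v))))
}

solve_for_met <- function(f, target, lo, hi) {
  flo <- f(lo)
  fhi <- f(hi)
  if ((flo - target) * (fhi - target) > 0) {
    stop("no metric value within the observed range [", signif(lo, 4), ", ",
         signif(hi, 4), "] maps to MET ", target)
  }
  uniroot(function(x) f(x) - target, lower = lo, upper = hi,
          tol = 1e-10 * max(1, hi - lo))$root
}

#' Calibrate metric cut-off points against MET
#'
#' Fits the five spreadsheet trend-line families (linear, logarithmic,
#' power, exponential, quadratic) of MET on the window metric, keeps the
#' family with the highest proportion of explained variance (R-squared on
#' the MET scale; ties within 1e-9 broken toward fewer parameters), and
#' inverts the chosen curve at MET 1.5 and MET 3 to obtain the two metric
#' cut-off points. The fit must be monotone increasing over the observed
#' metric range for the inversion to be unique; if no family is monotone,
#' the linear fit is used with a warning.
#'
#' @param metric Numeric vector of per-window metric values (SVM, IMA or
#'   TM).
#' @param met Matching per-window MET values.
#' @param metric_name Optional label, `"svm"`, `"ima"` or `"tm"`.
#' @param posture_threshold Posture-gate threshold in g stored with the
#'   model (default 0.5).
#' @return A `cutpoint_model`: list with `metric_name`, `trend_family`,
#'   `coefficients`, `r_squared`, `cutoff_lipa` (metric at MET 1.5),
#'   `cutoff_mvpa` (metric at MET 3) and `posture_threshold`.
#' @export
calibrate_cutpoints <- function(metric, met, metric_name = "metric",
                                posture_threshold = 0.5) {
  keep <- is.finite(metric) & is.finite(met)
  metric <- metric[keep]
  met <- met[keep]
  if (length(unique(metric)) < 2L) stop("need at least 2 distinct metric values")
  if (min(met) >= 1.5 || max(met) <= 3) {
    stop("calibration data must span MET < 1.5 and MET > 3")
  }
  lo <- min(metric)
  hi <- max(metric)
  sst <- sum((met - mean(met))^2)
  fams <- trend_families()
  fits <- lapply(names(fams), function(nm) {
    fam <- fams[[nm]]
    if (!fam$valid(metric, met)) return(NULL)
    ft <- tryCatch(fam$fit(metric, met), error = function(e) NULL)
    if (is.null(ft)) return(NULL)
    pred <- ft$predict(metric)
    if (any(!is.finite(pred))) return(NULL)
    list(name = nm, npar = fam$npar, fit = ft,
         r2 = 1 - sum((met - pred)^2) / sst,
         monotone = is_monotone_increasing(ft$predict, lo, hi))
  })
  fits <- Filter(Negate(is.null), fits)
  mono <- Filter(function(f) f$monotone, fits)
  if (length(mono) == 0L) {
    warning("no monotone-increasing trend family over the observed range; ",
            "falling back to the linear fit")
    chosen <- fits[[which(vapply(fits, `[[`, "", "name") == "linear")]]
  } else {
    r2 <- vapply(mono, `[[`, 0, "r2")
    best <- max(r2)
    chosen <- mono[[which(r2 > best - 1e-9)[1]]] # list is ordered by npar
  }
  f <- chosen$fit$predict
  structure(list(metric_name = metric_name,
                 trend_family = chosen$name,
                 coefficients = chosen$fit$coefficients,
                 r_squared = chosen$r2,
                 cutoff_lipa = solve_for_met(f, 1.5, lo, hi),
                 cutoff_mvpa = solve_for_met(f, 3, lo, hi),
                 metric_range = c(lo, hi),
                 posture_threshold = posture_threshold,
                 n = length(metric)),
            class = "cutpoint_model")
}

#' @export
print.cutpoint_model <- function(x, ...) {
  cat("Cut-off point model (", x$metric_name, ")\n", sep = "")
  cat("  trend family:", x$trend_family,
      sprintf("(R^2 = %.4f, n = %d)\n", x$r_squared, x$n))
  cat(sprintf("  cut-offs: MET 1.5 -> %.4g, MET 3 -> %.4g\n",
              x$cutoff_lipa, x$cutoff_mvpa))
  cat(sprintf("  posture threshold: |static Y mean| > %.2f g\n",
              x$posture_threshold))
  invisible(x)
}

#' Classify windows with a calibrated cut-off point model
#'
#' Mirrors the MET rule set in metric space: metric at or below the
#' 1.5-MET cut-off resolves to Sedentary or Standing by posture detection;
#' between the cut-offs to LIPA; at or above the 3-MET cut-off to MVPA.
#'
#' @param metric Numeric vector of window metric values.
#' @param static_y_mean Matching window mean static Y values (g).
#' @param model A `cutpoint_model` from [calibrate_cutpoints()].
#' @return Factor of intensity classes.
#' @export
classify_cutpoint <- function(metric, static_y_mean, model) {
  if (!inherits(model, "cutpoint_model")) {
    stop("model must be a calibrated cutpoint_model")
  }
  stopifnot(length(metric) == length(static_y_mean))
  posture <- detect_posture(static_y_mean, model$posture_threshold)
  cls <- ifelse(metric >= model$cutoff_mvpa, "MVPA",
         ifelse(metric > model$cutoff_lipa, "LIPA",
         ifelse(posture == "upright", "Standing", "Sedentary")))
  factor(cls, levels = INTENSITY_LEVELS)
}

#' Serialize / restore a cut-point model as JSON
#'
#' @param model A `cutpoint_model`.
#' @param path File path.
#' @return `write_cutpoint_model` returns the path invisibly;
#'   `read_cutpoint_model` returns the model.
#' @export
write_cutpoint_model <- function(model, path) {
  stopifnot(inherits(model, "cutpoint_model"))
  x <- unclass(model)
  x$coefficients <- as.list(x$coefficients)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutpoint_model
#' @export
read_cutpoint_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- unlist(x$coefficients)
  structure(x, class = "cutpoint_model")
}
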