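# Leave-one-subject-out evaluation: confusion matrices, one-vs-rest
# sensitivity/specificity/balanced accuracy, benchmarking, robustness
# against baseline characteristics, multiple-comparison corrections and
# reliability coefficients of variation.

#' Leave-one-subject-out folds
#'
#' @param participants Vector of unique participant ids.
#' @return List of folds; each a list with `train` (all other ids) and
#'   `test` (one id). Every participant is the test set exactly once.
#' @export
loso_split <- function(participants) {
  participants <- as.character(participants)
  if (anyDuplicated(participants)) stop("duplicate participant ids")
  if (length(participants) < 2L) stop("need at least 2 participants")
  lapply(participants, function(p) {
    list(train = setdiff(participants, p), test = p)
  })
}

#' Confusion matrix of predicted vs reference classes
#'
#' @param predicted Factor/character of predicted classes.
#' @param reference Matching reference classes.
#' @param participant_id Label stored with the matrix (default "overall").
#' @return A `confusion_matrix`: 4 x 4 integer matrix, rows = predicted,
#'   columns = reference, class order Sedentary, Standing, LIPA, MVPA,
#'   with attribute `participant_id`.
#' @export
confusion <- function(predicted, reference, participant_id = "overall") {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must have equal length")
  }
  bad <- setdiff(unique(c(as.character(predicted), as.character(reference))),
                 INTENSITY_LEVELS)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  predicted <- factor(as.character(predicted), levels = INTENSITY_LEVELS)
  reference <- factor(as.character(reference), levels = INTENSITY_LEVELS)
  m <- table(predicted = predicted, reference = reference)
  m <- matrix(as.integer(m), 4, 4, dimnames = dimnames(m))
  structure(m, participant_id = participant_id, class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' @param counts 4 x 4 numeric matrix, rows = predicted, columns =
#'   reference, in canonical class order.
#' @param participant_id Label (default "overall").
#' @return A `confusion_matrix`.
#' @export
as_confusion <- function(counts, participant_id = "overall") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) == 4L, all(counts >= 0))
  m <- matrix(as.integer(counts), 4, 4,
              dimnames = list(predicted = INTENSITY_LEVELS,
                              reference = INTENSITY_LEVELS))
  structure(m, participant_id = participant_id, class = "confusion_matrix")
}

#' Sum confusion matrices element-wise
#'
#' @param matrices List of `confusion_matrix` objects.
#' @return The overall `confusion_matrix` (participant_id "overall").
#' @export
sum_confusions <- function(matrices) {
  stopifnot(length(matrices) > 0L)
  as_confusion(Reduce(`+`, lapply(matrices, unclass)), "overall")
}

#' One-vs-rest class performance from a confusion matrix
#'
#' For the given class: sensitivity = TP / (TP + FN), specificity =
#' TN / (TN + FP), balanced accuracy = their arithmetic mean, all as
#' percentages. A class absent from the reference column makes sensitivity
#' undefined and raises an error.
#'
#' @param matrix A `confusion_matrix`.
#' @param class One of the four intensity classes; `NULL` (default) returns
#'   all four as a data frame.
#' @param acceptable_threshold Balanced-accuracy acceptability cut (default
#'   80 percent).
#' @return Data frame with columns `class`, `sensitivity`, `specificity`,
#'   `balanced_accuracy` (percent) and `acceptable`.
#' @export
class_performance <- function(matrix, class = NULL,
                              acceptable_threshold = 80) {
  stopifnot(inherits(matrix, "confusion_matrix"))
  classes <- if (is.null(class)) INTENSITY_LEVELS else match.arg(
    class, INTENSITY_LEVELS, several.ok = TRUE)
  total <- sum(matrix)
  rows <- lapply(classes, function(cl) {
    tp <- matrix[cl, cl]
    ref_total <- sum(matrix[, cl])
    if (ref_total == 0L) {
      stop("sensitivity undefined: no reference windows of class ", cl)
    }
    fn <- ref_total - tp
    fp <- sum(matrix[cl, ]) - tp
    tn <- total - ref_total - fp
    sens <- 100 * tp / (tp + fn)
    spec <- 100 * tn / (tn + fp)
    data.frame(class = cl, sensitivity = sens, specificity = spec,
               balanced_accuracy = (sens + spec) / 2,
               acceptable = (sens + spec) / 2 >= acceptable_threshold)
  })
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = INTENSITY_LEVELS)
  out
}

#' Share of participants with acceptable balanced accuracy
#'
#' @param balanced_accuracies Numeric vector of per-participant balanced
#'   accuracies (percent) for one class.
#' @param threshold Acceptability threshold (default 80; inclusive).
#' @return Percentage of participants at or above the threshold.
#' @export
benchmark <- function(balanced_accuracies, threshold = 80) {
  stopifnot(length(balanced_accuracies) >= 1L)
  100 * mean(balanced_accuracies >= threshold)
}

#' Multiple-comparison adjustment of a p-value
#'
#' Bonferroni: `min(1, p * k)`; Sidak: `1 - (1 - p)^k`.
#'
#' @param p Raw p-value(s) in \[0, 1\].
#' @param k Number of comparisons (>= 1).
#' @param method `"bonferroni"` or `"sidak"`.
#' @return Adjusted p-value(s).
#' @export
adjust_p <- function(p, k, method = c("bonferroni", "sidak")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]")
  }
  if (k < 1) stop("k must be >= 1")
  switch(method,
         bonferroni = pmin(1, p * k),
         sidak = 1 - (1 - p)^k)
}

#' Coefficient of variation of repeated measurements
#'
#' `CV (%) = sample SD / arithmetic mean * 100`.
#'
#' @param values Numeric vector, at least 2 values, non-zero mean.
#' @return CV in percent.
#' @export
reliability_cv <- function(values) {
  if (length(values) < 2L) stop("need at least 2 repeated measurements")
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  100 * sd(values) / m
}

#' Sample-based summary of per-activity CVs
#'
#' Summarises the moduli of a set of per-activity-per-participant CVs:
#' Shapiro-Wilk normality (alpha 0.05) chooses the arithmetic mean with a
#' normal-theory 95 percent CI, or the median with an approximate 95
#' percent CI (order-statistic based).
#'
#' @param cvs Numeric vector of CVs (percent).
#' @param acceptable_threshold CV acceptability cut (default 10 percent).
#' @return List: `centre`, `ci` (length 2), `summary` ("mean" or
#'   "median"), `acceptable` (share of |CV| below the threshold, percent).
#' @export
summarise_cvs <- function(cvs, acceptable_threshold = 10) {
  a <- abs(cvs[is.finite(cvs)])
  if (length(a) < 3L) stop("need at least 3 CVs to summarise")
  normal <- shapiro.test(a)$p.value >= 0.05
  if (normal) {
    se <- sd(a) / sqrt(length(a))
    list(centre = mean(a), ci = mean(a) + c(-1.96, 1.96) * se,
         summary = "mean",
         acceptable = 100 * mean(a < acceptable_threshold))
  } else {
    s <- sort(a)
    n <- length(s)
    # ~95% CI of the median from binomial order statistics
    lo <- max(1L, qbinom(0.025, n, 0.5))
    hi <- min(n, qbinom(0.975, n, 0.5) + 1L)
    list(centre = median(a), ci = c(s[lo], s[hi]), summary = "median",
         acceptable = 100 * mean(a < acceptable_threshold))
  }
}

#' Robustness of per-participant balanced accuracies
#'
#' Tests whether per-participant balanced accuracies depend on baseline
#' characteristics. Continuous characteristics: Shapiro-Wilk (alpha 0.05)
#' on both variables gates Pearson (both normal) vs Spearman correlation.
#' Two-level characteristics: Shapiro-Wilk on the balanced accuracies
#' within each group gates the independent t-test vs the Mann-Whitney U
#' test. P-values are adjusted for the number of characteristics tested.
#'
#' @param ba Named numeric vector of per-participant balanced accuracies
#'   (percent), names = participant ids.
#' @param baselines Baseline data frame (one row per participant, with a
#'   `participant_id` column).
#' @param characteristics Character vector of baseline columns to test;
#'   default: every numeric or two-level column except `participant_id`.
#' @param adjust `"bonferroni"` or `"sidak"`.
#' @return Data frame: `characteristic`, `test`, `statistic`, `p`,
#'   `p_adjusted`, `adjust_method`, `k`.
#' @export
robustness <- function(ba, baselines,
                       characteristics = NULL,
                       adjust = c("bonferroni", "sidak")) {
  adjust <- match.arg(adjust)
  if (length(ba) < 3L) stop("need at least 3 participants")
  base <- baselines[match(names(ba), as.character(baselines$participant_id)),
                    , drop = FALSE]
  if (anyNA(base$participant_id)) stop("baselines missing for some participants")
  if (is.null(characteristics)) {
    characteristics <- setdiff(names(base), "participant_id")
    usable <- vapply(characteristics, function(cc) {
      v <- base[[cc]]
      is.numeric(v) || length(unique(na.omit(v))) == 2L
    }, TRUE)
    characteristics <- characteristics[usable]
  }
  k <- length(characteristics)
  shapiro_ok <- function(v) {
    v <- v[is.finite(v)]
    if (length(unique(v)) < 3L) return(FALSE)
    shapiro.test(v)$p.value >= 0.05
  }
  rows <- lapply(characteristics, function(cc) {
    v <- base[[cc]]
    if (is.numeric(v) && length(unique(na.omit(v))) > 2L) {
      ok <- is.finite(ba) & is.finite(v)
      method <- if (shapiro_ok(ba[ok]) && shapiro_ok(v[ok]))
        "pearson" else "spearman"
      test_name <- if (method == "pearson") "Pearson r" else "Spearman rho"
      if (sd(ba[ok]) == 0 || sd(v[ok]) == 0) {
        # no variance, correlation undefined: nothing to detect
        data.frame(characteristic = cc, test = test_name,
                   statistic = NA_real_, p = NA_real_)
      } else {
        ct <- suppressWarnings(cor.test(ba[ok], v[ok], method = method))
        data.frame(characteristic = cc, test = test_name,
                   statistic = unname(ct$estimate), p = ct$p.value)
      }
    } else {
      g <- as.factor(v)
      if (nlevels(droplevels(g)) != 2L) {
        stop("characteristic ", cc, " is neither continuous nor two-level")
      }
      sp <- split(ba, droplevels(g))
      if (sd(ba) == 0) {
        return(data.frame(characteristic = cc, test = "t-test",
                          statistic = NA_real_, p = NA_real_))
      }
      parametric <- all(vapply(sp, shapiro_ok, TRUE))
      if (parametric) {
        tt <- t.test(sp[[1]], sp[[2]])
        data.frame(characteristic = cc, test = "t-test",
                   statistic = unname(tt$statistic), p = tt$p.value)
      } else {
        wt <- suppressWarnings(wilcox.test(sp[[1]], sp[[2]]))
        data.frame(characteristic = cc, test = "Mann-Whitney U",
                   statistic = unname(wt$statistic), p = wt$p.value)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- ifelse(is.na(out$p), NA_real_,
                           adjust_p(ifelse(is.na(out$p), 0, out$p), k, adjust))
  out$adjust_method <- adjust
  out$k <- k
  out
}

#' Compare algorithms on per-participant balanced accuracies
#'
#' Paired comparison of the four algorithms for one intensity class.
#' Shapiro-Wilk on the per-participant differences of every algorithm pair
#' gates a repeated-measures ANOVA (all pairs normal) vs the Friedman
#' test; pairwise follow-ups use paired t / Wilcoxon signed-rank tests
#' with the configured p adjustment.
#'
#' @param ba_matrix Numeric matrix, rows = participants, columns =
#'   algorithms (per-participant balanced accuracies, percent).
#' @param adjust `"bonferroni"` or `"sidak"`.
#' @return List: `omnibus` (test name, statistic, p) and `pairwise` data
#'   frame (`pair`, `difference`, `p`, `p_adjusted`).
#' @export
compare_algorithms <- function(ba_matrix, adjust = c("bonferroni", "sidak")) {
  adjust <- match.arg(adjust)
  ba_matrix <- as.matrix(ba_matrix)
  stopifnot(ncol(ba_matrix) >= 2L, nrow(ba_matrix) >= 3L)
  algs <- colnames(ba_matrix)
  if (is.null(algs)) algs <- paste0("alg", seq_len(ncol(ba_matrix)))
  pairs <- utils::combn(seq_along(algs), 2)
  diffs_normal <- apply(pairs, 2, function(ij) {
    d <- ba_matrix[, ij[1]] - ba_matrix[, ij[2]]
    d <- d[is.finite(d)]
    if (length(unique(d)) < 3L) return(FALSE)
    shapiro.test(d)$p.value >= 0.05
  })
  n <- nrow(ba_matrix)
  if (all(diffs_normal)) {
    long <- data.frame(ba = as.vector(ba_matrix),
                       alg = factor(rep(algs, each = n)),
                       id = factor(rep(seq_len(n), times = ncol(ba_matrix))))
    fit <- aov(ba ~ alg + Error(id / alg), data = long)
    tab <- summary(fit)[["Error: id:alg"]][[1]]
    omnibus <- list(test = "repeated-measures ANOVA",
                    statistic = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
  } else {
    ft <- friedman.test(ba_matrix)
    omnibus <- list(test = "Friedman", statistic = unname(ft$statistic),
                    p = ft$p.value)
  }
  k <- ncol(pairs)
  pw <- apply(pairs, 2, function(ij) {
    a <- ba_matrix[, ij[1]]
    b <- ba_matrix[, ij[2]]
    d <- a - b
    parametric <- length(unique(d)) >= 3L && shapiro.test(d)$p.value >= 0.05
    pv <- if (parametric) t.test(a, b, paired = TRUE)$p.value
          else suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
    data.frame(pair = paste(algs[ij[1]], "vs", algs[ij[2]]),
               difference = mean(d),
               test = if (parametric) "paired t" else "Wilcoxon signed-rank",
               p = pv)
  })
  pw <- do.call(rbind, pw)
  pw$p_adjusted <- adjust_p(pw$p, k, adjust)
  list(omnibus = omnibus, pairwise = pw)
}

#' Training-sample check for overfitting
#'
#' Applies the cross-validation performance machinery to predictions made
#' on the classifier's own training rows.
#'
#' @param predicted Predictions on the training rows.
#' @param reference Training reference labels.
#' @return Data frame from [class_performance()] on the training confusion
#'   matrix.
#' @export
training_sample_check <- function(predicted, reference) {
  class_performance(confusion(predicted, reference, "training"))
}
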