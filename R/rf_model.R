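# Random-Forest modelling: correlation pruning, shadow-feature selection
# and 100-tree forest training/prediction.

#' Greedy pruning of highly correlated features
#'
#' Removes features until no pair has `|r|` above the threshold. For each
#' offending pair the member with the larger mean absolute correlation to
#' all remaining features is dropped (a deterministic rule). Correlations
#' with constant columns are defined as 0.
#'
#' @param features Numeric data frame or matrix (rows = windows).
#' @param r_threshold Absolute Pearson correlation above which one member
#'   of a pair is removed (default 0.75, strictly greater).
#' @return A `feature_selection` list: `kept` (column names surviving),
#'   `pruned_pairs` (data frame `kept`, `removed`, `r`), and the threshold.
#' @export
prune_correlated <- function(features, r_threshold = 0.75) {
  x <- as.matrix(features)
  if (!is.numeric(x)) stop("feature table must be numeric")
  if (ncol(x) < 2L) stop("need at least 2 feature columns")
  cm <- suppressWarnings(cor(x))
  cm[!is.finite(cm)] <- 0 # constant columns correlate with nothing
  diag(cm) <- 0
  keep <- colnames(x)
  pairs <- list()
  repeat {
    sub <- abs(cm[keep, keep, drop = FALSE])
    worst <- max(sub)
    if (worst <= r_threshold) break
    idx <- which(sub == worst, arr.ind = TRUE)[1, ]
    a <- keep[idx[1]]
    b <- keep[idx[2]]
    # drop the member more redundant with everything else
    ma <- mean(sub[a, ])
    mb <- mean(sub[b, ])
    drop <- if (ma >= mb) a else b
    kept <- if (drop == a) b else a
    pairs[[length(pairs) + 1L]] <- data.frame(
      kept = kept, removed = drop, r = cm[a, b])
    keep <- setdiff(keep, drop)
  }
  structure(list(kept = keep,
                 pruned_pairs = if (length(pairs)) do.call(rbind, pairs)
                                else data.frame(kept = character(),
                                                removed = character(),
                                                r = numeric()),
                 r_threshold = r_threshold),
            class = "feature_selection")
}

#' Shadow-feature relevance selection
#'
#' A shadow-feature wrapper around Random-Forest importance: at every
#' iteration each feature is duplicated with its values permuted (the
#' "shadow"), a forest is grown on the doubled table, and a feature scores
#' a hit when its importance exceeds the maximum shadow importance. Hits
#' are tested against a Binomial(iterations, 0.5) null (two-sided, at
#' `alpha`); features significantly above chance are confirmed, those
#' significantly below are rejected, and testing stops when everything is
#' decided or `max_runs` is reached. Features still tentative at the end
#' are confirmed when their median importance over all iterations exceeds
#' the median of the per-iteration maximum shadow importance.
#'
#' @param features Numeric data frame/matrix of candidate features
#'   (typically after [prune_correlated()]).
#' @param labels Factor (or coercible) class labels, one per row, at least
#'   2 classes.
#' @param seed Integer seed; the procedure is reproducible given the seed.
#' @param max_runs Maximum iterations (default 50, capped at 100).
#' @param alpha Two-sided test level (default 0.05).
#' @param num_trees Trees per importance forest (default 100).
#' @return A `feature_selection` list with `confirmed`, `rejected`,
#'   `tentative` name vectors, per-feature `hits`, and `iterations`.
#' @export
shadow_select <- function(features, labels, seed = 1L, max_runs = 50L,
                          alpha = 0.05, num_trees = 100L) {
  x <- as.data.frame(features)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) stop("need at least 2 classes")
  if (nrow(x) != length(labels)) stop("labels must align with feature rows")
  max_runs <- min(as.integer(max_runs), 100L)
  p <- ncol(x)
  feat_names <- colnames(x)
  hits <- setNames(integer(p), feat_names)
  imp_hist <- matrix(NA_real_, nrow = max_runs, ncol = p,
                     dimnames = list(NULL, feat_names))
  shadow_max_hist <- rep(NA_real_, max_runs)
  status <- setNames(rep("tentative", p), feat_names)
  set.seed(as.integer(seed))
  it <- 0L
  while (it < max_runs && any(status == "tentative")) {
    it <- it + 1L
    shadow <- as.data.frame(lapply(x, sample))
    names(shadow) <- paste0(".shadow.", feat_names)
    dat <- cbind(x, shadow)
    fit <- ranger::ranger(x = dat, y = droplevels(labels),
                          num.trees = num_trees,
                          importance = "impurity",
                          seed = sample.int(.Machine$integer.max, 1),
                          num.threads = 1)
    imp <- fit$variable.importance
    smax <- max(imp[names(shadow)])
    shadow_max_hist[it] <- smax
    imp_hist[it, ] <- imp[feat_names]
    hits <- hits + as.integer(imp[feat_names] > smax)
    if (it >= 5L) { # need a few iterations before the binomial test bites
      for (f in feat_names[status == "tentative"]) {
        pv <- binom.test(hits[[f]], it, p = 0.5,
                         alternative = "two.sided")$p.value
        if (pv < alpha) {
          status[f] <- if (hits[[f]] > it / 2) "confirmed" else "rejected"
        }
      }
    }
  }
  # resolve leftovers by median importance against the median shadow max
  med_shadow <- median(shadow_max_hist[seq_len(it)])
  for (f in feat_names[status == "tentative"]) {
    status[f] <- if (median(imp_hist[seq_len(it), f]) > med_shadow)
      "confirmed" else "rejected"
  }
  structure(list(confirmed = feat_names[status == "confirmed"],
                 rejected = feat_names[status == "rejected"],
                 tentative = character(0),
                 hits = hits,
                 iterations = it,
                 alpha = alpha,
                 seed = as.integer(seed)),
            class = "feature_selection")
}

#' Train the Random-Forest intensity classifier
#'
#' Bootstrap-aggregated classification trees (majority vote) with the tree
#' count fixed at 100 by out-of-bag error analysis; remaining
#' hyperparameters follow the original Random Forest formulation
#' (`floor(sqrt(p))` candidate features per split, unlimited depth,
#' bootstrap samples of size n).
#'
#' @param features Numeric data frame of selected features.
#' @param labels Class labels aligned with rows.
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed.
#' @param mtry Candidate features per split; default `floor(sqrt(p))`.
#' @return A `forest_model`: list with the fitted `randomForest` object,
#'   `feature_names`, `classes`, `oob_error_curve` (length `n_trees`) and
#'   `seed`.
#' @export
train_forest <- function(features, labels, n_trees = 100L, seed = 1L,
                         mtry = NULL) {
  x <- as.data.frame(features)
  labels <- droplevels(as.factor(labels))
  if (nrow(x) != length(labels)) stop("labels must align with feature rows")
  if (nlevels(labels) < 2L) stop("need at least 2 classes to train")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = x, y = labels, ntree = n_trees,
                                    mtry = mtry)
  structure(list(forest = fit,
                 feature_names = colnames(x),
                 classes = levels(labels),
                 n_trees = as.integer(n_trees),
                 oob_error_curve = unname(fit$err.rate[, "OOB"]),
                 seed = as.integer(seed)),
            class = "forest_model")
}

#' Predict intensity classes with a trained forest
#'
#' Majority vote over the trees; exact ties are broken by the fixed class
#' order Sedentary < Standing < LIPA < MVPA.
#'
#' @param model A `forest_model` from [train_forest()].
#' @param features Data frame of feature rows; must contain every training
#'   column.
#' @return Factor of predicted classes (levels in canonical order).
#' @export
predict_forest <- function(model, features) {
  stopifnot(inherits(model, "forest_model"))
  x <- as.data.frame(features)
  missing_cols <- setdiff(model$feature_names, colnames(x))
  if (length(missing_cols)) {
    stop("feature schema mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[, model$feature_names, drop = FALSE]
  if (nrow(x) == 0L) {
    return(factor(character(0), levels = INTENSITY_LEVELS))
  }
  votes <- predict(model$forest, newdata = x, type = "vote", norm.votes = FALSE)
  ord <- intersect(INTENSITY_LEVELS, colnames(votes))
  ord <- c(ord, setdiff(colnames(votes), ord))
  votes <- votes[, ord, drop = FALSE]
  pred <- colnames(votes)[apply(votes, 1, which.max)] # first max = fixed order
  factor(pred, levels = intersect(INTENSITY_LEVELS, model$classes))
}
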